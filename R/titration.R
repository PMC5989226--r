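#' Construct a titration series
#'
#' An ordered set of (total hemin, observed absorbance) points recorded at
#' one monitor wavelength during stepwise hemin additions to a fixed
#' protein solution.
#'
#' @param h_total Total hemin concentrations, molar; non-negative and
#'   strictly increasing.
#' @param a_obs Observed absorbances, AU; finite, same length as `h_total`.
#' @param d_total Total protein concentration, molar (scalar, > 0). When
#'   the series carries a per-point `d_total_point` (dilution during the
#'   titration), this is the pre-addition concentration.
#' @param wavelength Monitor wavelength, nm (default 425).
#' @param path_length Optical path length, cm (default 1).
#' @param d_total_point Optional per-point total protein concentration,
#'   molar, accounting for dilution by the added aliquots.
#' @return A data frame of class `titration_series` with columns
#'   `h_total`, `a_obs` (and `d_total_point` if given) and attributes
#'   `d_total`, `wavelength`, `path_length`.
#' @export
#' @examples
#' titration_series(h_total = (0:10) * 1e-6, a_obs = seq(0, 0.8, length.out = 11),
#'                  d_total = 9.4e-6)
titration_series <- function(h_total, a_obs, d_total, wavelength = 425,
                             path_length = 1, d_total_point = NULL) {
  stopifnot(is.numeric(h_total), is.numeric(a_obs),
            length(h_total) == length(a_obs))
  if (any(!is.finite(h_total)) || any(h_total < 0))
    stop("'h_total' must be non-negative and finite")
  if (any(diff(h_total) <= 0))
    stop("'h_total' must be strictly increasing; offending row: ",
         which(diff(h_total) <= 0)[1] + 1)
  if (any(!is.finite(a_obs)))
    stop("'a_obs' must be finite")
  if (!is.numeric(d_total) || length(d_total) != 1 || !is.finite(d_total) ||
      d_total <= 0)
    stop("'d_total' must be a single positive protein concentration in molar")
  out <- data.frame(h_total = as.numeric(h_total), a_obs = as.numeric(a_obs))
  if (!is.null(d_total_point)) {
    stopifnot(is.numeric(d_total_point), length(d_total_point) == length(h_total))
    if (any(!is.finite(d_total_point)) || any(d_total_point <= 0))
      stop("'d_total_point' must be positive and finite")
    out$d_total_point <- as.numeric(d_total_point)
  }
  structure(out,
            d_total = d_total,
            wavelength = as.numeric(wavelength),
            path_length = as.numeric(path_length),
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Hemin titration series: %d points, %.3g uM protein, %g nm, %g cm path\n",
    nrow(x), attr(x, "d_total") * 1e6, attr(x, "wavelength"),
    attr(x, "path_length")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# per-point protein concentration used by the model
.series_d_total <- function(series, dilution = TRUE) {
  if (dilution && !is.null(series$d_total_point)) series$d_total_point
  else rep(attr(series, "d_total"), nrow(series))
}
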