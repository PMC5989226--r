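#' Configuration for dual-wavelength heme-protein quantification
#'
#' Holds the coefficients of the two-wavelength concentration
#' decomposition: the bound-heme extinction coefficient at the Soret
#' monitor wavelength, the Reinheitszahl (the A_Soret/A280 ratio of a
#' fully heme-bound preparation, used to derive the bound-heme
#' contribution at 280 nm as `eps_dh_soret / reinheitszahl`), and the
#' apo-protein extinction coefficient at 280 nm.
#'
#' @param eps_dh_soret Bound-heme extinction coefficient at the monitor
#'   wavelength, M^-1 cm^-1 (default 79,400, the fitted wild-type value).
#' @param reinheitszahl Purity ratio A_Soret/A280 of fully bound protein
#'   (default 1.43).
#' @param eps_d280 Apo-protein extinction coefficient at 280 nm,
#'   M^-1 cm^-1; see [epsilon280_from_sequence()].
#' @param wavelength Soret monitor wavelength, nm. 425 for the wild-type
#'   protein; 418 and 416 for the H245A and H245AH249A heme-pocket
#'   mutants.
#' @param path_length Optical path length, cm (default 1).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(eps_dh_soret = 79400,
                         reinheitszahl = heme_constants()$reinheitszahl,
                         eps_d280,
                         wavelength = 425,
                         path_length = 1) {
  vals <- c(eps_dh_soret, reinheitszahl, eps_d280, wavelength, path_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all quantification coefficients must be positive and finite")
  structure(list(eps_dh_soret = eps_dh_soret,
                 reinheitszahl = reinheitszahl,
                 eps_d280 = eps_d280,
                 wavelength = wavelength,
                 path_length = path_length),
            class = "quant_config")
}

#' Protein and heme content from A280 and Soret absorbance
#'
#' Decomposes a two-wavelength absorbance reading into bound and free
#' protein concentrations:
#' \deqn{[DH] = A_{Soret} / (\varepsilon_{DH}(Soret)\,L)}
#' \deqn{[D]_f = \{A_{280} - \varepsilon_{DH}(280)\,[DH]\} /
#'       (\varepsilon_D(280)\,L)}
#' with \eqn{\varepsilon_{DH}(280) = \varepsilon_{DH}(Soret)/Rz}. The 280 nm
#' reading thus contains both the bound-heme and the apo-protein
#' contribution; the Soret reading is attributed entirely to bound heme
#' (free heme is assumed removed by chromatography). A negative free-protein
#' estimate -- possible when noise makes the readings inconsistent -- is
#' clamped to zero with a warning.
#'
#' @param a280 Absorbance at 280 nm, AU (> 0).
#' @param a_soret Absorbance at the Soret monitor wavelength, AU (>= 0).
#' @param cfg A [quant_config()].
#' @return An object of class `spectrum_quant`: list with `a280`,
#'   `a_soret`, `dh`, `d_f`, `d_total` (all molar), `bound_fraction`
#'   (`dh / d_total`), and `inconsistent` (TRUE when clamping occurred).
#' @export
#' @examples
#' cfg <- quant_config(eps_d280 = 30000)
#' quantify_heme_protein(a280 = 0.519, a_soret = 0.611, cfg)
quantify_heme_protein <- function(a280, a_soret, cfg) {
  stopifnot(inherits(cfg, "quant_config"))
  if (!is.numeric(a280) || length(a280) != 1 || !is.finite(a280) || a280 <= 0)
    stop("'a280' must be a single positive absorbance")
  if (!is.numeric(a_soret) || length(a_soret) != 1 || !is.finite(a_soret) ||
      a_soret < 0)
    stop("'a_soret' must be a single non-negative absorbance")
  L <- cfg$path_length
  eps_dh280 <- cfg$eps_dh_soret / cfg$reinheitszahl
  dh <- a_soret / (cfg$eps_dh_soret * L)
  d_f <- (a280 - eps_dh280 * dh * L) / (cfg$eps_d280 * L)
  inconsistent <- FALSE
  if (d_f < 0) {
    inconsistent <- TRUE
    warning(sprintf(
      "A280 (%.4g) below the bound-heme contribution (%.4g): free protein clamped to 0",
      a280, eps_dh280 * dh * L))
    d_f <- 0
  }
  d_total <- dh + d_f
  bf <- if (d_total > 0) dh / d_total else 0
  structure(list(a280 = a280, a_soret = a_soret,
                 dh = dh, d_f = d_f, d_total = d_total,
                 bound_fraction = bf, inconsistent = inconsistent),
            class = "spectrum_quant")
}

#' @export
print.spectrum_quant <- function(x, ...) {
  cat("Dual-wavelength heme-protein quantification\n")
  cat(sprintf("  [DH] %.4g uM, [D]_f %.4g uM, [D]_total %.4g uM\n",
              x$dh * 1e6, x$d_f * 1e6, x$d_total * 1e6))
  cat(sprintf("  heme-bound fraction: %.1f%%%s\n", 100 * x$bound_fraction,
              if (x$inconsistent) "  (readings inconsistent; D_f clamped)" else ""))
  invisible(x)
}

#' Apo-protein extinction coefficient at 280 nm from sequence
#'
#' Sums per-residue contributions at 280 nm using the Pace /
#' Gill-von Hippel coefficients: 5500 (Trp) and 1490 (Tyr) M^-1 cm^-1,
#' plus 125 M^-1 cm^-1 per cystine (disulfide-paired cysteine pair) when
#' `cystines_paired = TRUE`. Under reducing conditions (DTT in the
#' buffer) cysteines are free thiols and contribute nothing, the default.
#'
#' @param sequence Amino-acid sequence, standard one-letter codes
#'   (case-insensitive; whitespace ignored).
#' @param cystines_paired If `TRUE`, count `floor(nC / 2)` cystines at
#'   125 M^-1 cm^-1 each. Default `FALSE`.
#' @return Extinction coefficient at 280 nm, M^-1 cm^-1.
#' @export
#' @examples
#' epsilon280_from_sequence("WYC")            # 6990
#' epsilon280_from_sequence("WWCC", cystines_paired = TRUE)  # 11125
epsilon280_from_sequence <- function(sequence, cystines_paired = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq_clean <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(seq_clean, "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!(chars %in% valid))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1]], bad[1]))
  k <- heme_constants()
  n_w <- sum(chars == "W")
  n_y <- sum(chars == "Y")
  n_c <- sum(chars == "C")
  eps <- k$eps280_trp * n_w + k$eps280_tyr * n_y
  if (cystines_paired) eps <- eps + k$eps280_cystine * (n_c %/% 2)
  eps
}

#' Hemin stock concentration from A385
#'
#' Alkaline hemin stock solutions are standardized using the extinction
#' coefficient 58,440 M^-1 cm^-1 at 385 nm.
#'
#' @param a385 Absorbance at 385 nm, AU (>= 0).
#' @param path_length Optical path length, cm (default 1).
#' @return Hemin concentration, molar.
#' @export
#' @examples
#' hemin_stock_concentration(0.58440)  # 1e-5 M
hemin_stock_concentration <- function(a385, path_length = 1) {
  if (!is.numeric(a385) || any(!is.finite(a385)) || any(a385 < 0))
    stop("'a385' must be a non-negative absorbance")
  if (!is.numeric(path_length) || path_length <= 0)
    stop("'path_length' must be positive")
  a385 / (heme_constants()$eps_hemin_385 * path_length)
}
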