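# Delimited-text readers/writers. Titration tables use a required header
# `h_total_uM,a_obs` (optional `d_total_uM` per-point column) with
# metadata on `#key=value` comment lines; spectra are two-column
# `wavelength_nm,absorbance`. Comma and tab delimiters are accepted.

.read_meta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^\\s*#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  list(meta = meta, data_lines = lines[setdiff(seq_along(lines), meta_idx)])
}

.read_delim_table <- function(data_lines, path) {
  body <- data_lines[nzchar(trimws(data_lines))]
  if (!length(body)) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  utils::read.table(text = body, sep = sep, header = TRUE,
                    strip.white = TRUE, check.names = TRUE)
}

#' Read a titration series from delimited text
#'
#' Expects a header row with columns `h_total_uM` and `a_obs` (optionally
#' `d_total_uM` with per-point diluted protein concentrations), comma- or
#' tab-separated. Metadata may be supplied as `#key=value` comment lines
#' (`d_total_uM`, `wavelength_nm`, `path_cm`) or through the arguments,
#' which take precedence.
#'
#' @param path File path.
#' @param d_total_uM Total protein concentration, micromolar; required
#'   here or in the file metadata.
#' @param wavelength_nm Monitor wavelength (default from metadata,
#'   else 425).
#' @param path_cm Path length (default from metadata, else 1).
#' @return A [titration_series()] (concentrations converted to molar).
#' @export
read_titration <- function(path, d_total_uM = NULL, wavelength_nm = NULL,
                           path_cm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .read_meta_lines(path)
  tab <- .read_delim_table(parsed$data_lines, path)
  need <- c("h_total_uM", "a_obs")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  meta_num <- function(key) {
    v <- parsed$meta[[key]]
    if (is.null(v)) NULL else as.numeric(v)
  }
  d_uM <- d_total_uM %||% meta_num("d_total_uM")
  if (is.null(d_uM))
    stop("protein concentration missing: supply 'd_total_uM' as an ",
         "argument or a '#d_total_uM=' line in ", path)
  wl <- wavelength_nm %||% meta_num("wavelength_nm") %||% 425
  L <- path_cm %||% meta_num("path_cm") %||% 1
  titration_series(
    h_total = tab$h_total_uM * 1e-6,
    a_obs = tab$a_obs,
    d_total = d_uM * 1e-6,
    wavelength = wl,
    path_length = L,
    d_total_point = if ("d_total_uM" %in% names(tab)) tab$d_total_uM * 1e-6
                    else NULL)
}

#' Write a titration series to delimited text
#'
#' Writes the `#key=value` metadata lines followed by a CSV table that
#' [read_titration()] reads back bit-for-bit (concentrations serialized
#' in micromolar with full precision).
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  meta <- c(
    sprintf("#d_total_uM=%.17g", attr(series, "d_total") * 1e6),
    sprintf("#wavelength_nm=%g", attr(series, "wavelength")),
    sprintf("#path_cm=%g", attr(series, "path_length")))
  tab <- data.frame(h_total_uM = sprintf("%.17g", series$h_total * 1e6),
                    a_obs = sprintf("%.17g", series$a_obs))
  if (!is.null(series$d_total_point))
    tab$d_total_uM <- sprintf("%.17g", series$d_total_point * 1e6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an absorption spectrum from two-column delimited text
#'
#' Columns `wavelength_nm, absorbance` with a header row; comma- or
#' tab-separated; `#` comment lines ignored.
#'
#' @param path File path.
#' @param label Label stored on the spectrum (default: file name).
#' @return An [absorption_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .read_meta_lines(path)
  tab <- .read_delim_table(parsed$data_lines, path)
  need <- c("wavelength_nm", "absorbance")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  absorption_spectrum(tab$wavelength_nm, tab$absorbance, label = label)
}

#' Write an absorption spectrum to CSV
#'
#' @param spectrum An [absorption_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  tab <- data.frame(wavelength_nm = sprintf("%.17g", spectrum$wavelength),
                    absorbance = sprintf("%.17g", spectrum$absorbance))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an amino-acid sequence from FASTA
#'
#' @param path FASTA file path.
#' @param id Record id, required when the file holds more than one
#'   record; matched against the first whitespace-delimited token of the
#'   header.
#' @return A single character string (the sequence).
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  if (length(set) > 1 && is.null(id))
    stop(path, " holds ", length(set),
         " records; pass 'id' to pick one")
  if (!is.null(id)) {
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
    hit <- which(ids == id)
    if (!length(hit)) stop("no record with id '", id, "' in ", path)
    set <- set[hit[1]]
  }
  as.character(set[[1]])
}

#' Write a fit report as JSON
#'
#' Machine-readable report of a titration fit: parameters in molar units
#' and in bench units (nM, mM^-1 cm^-1), residuals, RSS, convergence,
#' multi-start seed, and the package version.
#'
#' @param fit A [fit_titration()] result.
#' @param path Output path, or `NULL` to return the report list.
#' @return The report list, invisibly when written.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "heme_fit"))
  p <- fit$params
  rep <- list(
    model = "tight_binding_1to1_active_fraction",
    parameters = list(
      kd_M = p$kd, eps_dh_M_cm = p$eps_dh, eps_h_M_cm = p$eps_h, x = p$x),
    parameters_bench_units = list(
      kd_nM = p$kd * 1e9,
      eps_dh_mM_cm = p$eps_dh / 1000,
      eps_h_mM_cm = p$eps_h / 1000,
      x = p$x),
    fixed = as.list(fit$fixed),
    rss = fit$rss,
    n_points = length(fit$residuals),
    residuals = fit$residuals,
    converged = fit$converged,
    n_starts = fit$n_starts_used,
    seed = fit$seed,
    dilution_correction = fit$dilution,
    d_total_M = attr(fit$series, "d_total"),
    wavelength_nm = attr(fit$series, "wavelength"),
    bootstrap_ci = if (!is.null(fit$ci)) list(
      level = attr(fit$ci, "level"), n_boot = attr(fit$ci, "n_boot"),
      lower = as.list(stats::setNames(fit$ci$lower, rownames(fit$ci))),
      upper = as.list(stats::setNames(fit$ci$upper, rownames(fit$ci)))),
    package_version = as.character(utils::packageVersion("hemebind")))
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(rep)
}
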