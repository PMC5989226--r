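#' Titration protocol description
#'
#' The stepwise-addition protocol: `n_additions` aliquots of
#' `aliquot_volume` of hemin stock at `stock_concentration` added to
#' `initial_volume` of protein solution. Defaults mirror the standard
#' bench protocol of 1 uL aliquots of 1 mM hemin into 1 mL; twenty
#' additions then reach about two mol equivalents over 10 uM protein
#' while diluting the sample by only ~2%.
#'
#' @param initial_volume Initial sample volume, L (default 1e-3).
#' @param aliquot_volume Volume per addition, L (default 1e-6).
#' @param stock_concentration Hemin stock concentration, M (default 1e-3).
#' @param n_additions Number of additions (default 20).
#' @param dilution_correction If `TRUE` (default), concentrations are
#'   computed with the growing sample volume; if `FALSE`, added hemin is
#'   referred to the initial volume and the protein concentration is held
#'   fixed, matching the bare model equations.
#' @return An object of class `titration_protocol`.
#' @export
titration_protocol <- function(initial_volume = 1e-3, aliquot_volume = 1e-6,
                               stock_concentration = 1e-3, n_additions = 20,
                               dilution_correction = TRUE) {
  if (initial_volume <= 0 || aliquot_volume <= 0 || stock_concentration <= 0)
    stop("volumes and stock concentration must be positive")
  if (n_additions < 1) stop("'n_additions' must be at least 1")
  structure(list(initial_volume = initial_volume,
                 aliquot_volume = aliquot_volume,
                 stock_concentration = stock_concentration,
                 n_additions = as.integer(n_additions),
                 dilution_correction = isTRUE(dilution_correction)),
            class = "titration_protocol")
}

#' Simulate a hemin titration series
#'
#' Generates a [titration_series()] from the forward absorbance model:
#' for each addition the total hemin (and, with dilution correction, the
#' diluted protein concentration) is computed from the protocol, the
#' equilibrium is solved, and Gaussian noise of standard deviation
#' `noise_sd` is added to the predicted absorbance. The first point is
#' the pre-addition baseline at zero hemin.
#'
#' @param protocol A [titration_protocol()].
#' @param d_total_initial Protein concentration before the first
#'   addition, molar.
#' @param params Generating [binding_params()].
#' @param noise_sd Absorbance noise standard deviation, AU (default 0).
#' @param seed Integer seed for the noise draws (default `NULL`: only
#'   valid with `noise_sd = 0`; any stochastic simulation must state its
#'   seed).
#' @param wavelength Monitor wavelength recorded on the series
#'   (default 425).
#' @param path_length Optical path length, cm (default 1).
#' @return A [titration_series()] with `n_additions + 1` points; when the
#'   protocol has dilution correction on, the series carries the diluted
#'   per-point protein concentrations.
#' @export
#' @examples
#' p <- binding_params(59e-9, 79400, 27400, 0.81)
#' simulate_titration(titration_protocol(), 9.4e-6, p)
simulate_titration <- function(protocol, d_total_initial, params,
                               noise_sd = 0, seed = NULL, wavelength = 425,
                               path_length = 1) {
  stopifnot(inherits(protocol, "titration_protocol"),
            inherits(params, "binding_params"))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  k <- 0:protocol$n_additions
  v0 <- protocol$initial_volume
  va <- protocol$aliquot_volume
  if (protocol$dilution_correction) {
    vol <- v0 + k * va
    h_total <- k * va * protocol$stock_concentration / vol
    d_total <- d_total_initial * v0 / vol
  } else {
    h_total <- k * va * protocol$stock_concentration / v0
    d_total <- rep(d_total_initial, length(k))
  }
  a <- predict_absorbance(d_total, h_total, params, path_length)
  if (noise_sd > 0)
    a <- a + .with_seed(seed, function() stats::rnorm(length(a), 0, noise_sd))
  titration_series(
    h_total = h_total, a_obs = a, d_total = d_total_initial,
    wavelength = wavelength, path_length = path_length,
    d_total_point = if (protocol$dilution_correction) d_total else NULL)
}

#' Default spectral band library
#'
#' Gaussian band sets (center nm, sigma nm, amplitude M^-1 cm^-1 at unit
#' concentration-pathlength) for the four species the simulator knows:
#' \describe{
#'   \item{low_spin_heme}{hexacoordinate low-spin Fe(III) heme-protein
#'     complex: delta 360, Soret 425 (amplitude 79,400, the fitted
#'     bound-heme coefficient), beta 543, alpha 575 nm (weak/broad, so it
#'     renders as a shoulder of the beta band), plus the 280 nm protein
#'     band at 79,400/1.43 so a pure complex shows Reinheitszahl 1.43.}
#'   \item{high_spin_heme}{pentacoordinate high-spin form: Soret near
#'     390 nm plus the ~645 nm charge-transfer band, and a 280 nm band.}
#'   \item{free_hemin}{free hemin Soret near 385 nm with amplitude
#'     58,440, the standardization coefficient.}
#'   \item{apo_protein}{a single 280 nm band.}
#' }
#' Widths and relative heights other than the anchored Soret amplitudes
#' are plausible round numbers, configurable by passing a modified
#' library to [simulate_spectrum()].
#'
#' @return A named list of data frames with columns `center`, `width`,
#'   `amplitude`.
#' @export
default_band_library <- function() {
  rz <- heme_constants()$reinheitszahl
  list(
    low_spin_heme = data.frame(
      center    = c(280, 360, 425, 543, 575),
      width     = c(20, 12, 12, 15, 15),
      amplitude = c(79400 / rz, 30000, 79400, 11000, 2500)),
    high_spin_heme = data.frame(
      center    = c(280, 390, 645),
      width     = c(20, 12, 15),
      amplitude = c(55000, 75000, 4000)),
    free_hemin = data.frame(
      center = 385, width = 18, amplitude = 58440),
    apo_protein = data.frame(
      center = 280, width = 20, amplitude = 30000)
  )
}

#' Simulate an absorption spectrum from Gaussian bands
#'
#' Sums, over the given species, concentration-scaled Gaussian bands on a
#' wavelength grid (1 nm steps over 250-800 nm by default), adds a flat
#' baseline, and optionally seeded Gaussian noise. Absorbances are linear
#' in each species concentration by construction (Beer-Lambert).
#'
#' @param species Named numeric vector of species concentrations, molar;
#'   names must exist in `band_library`.
#' @param band_library Band definitions per species; see
#'   [default_band_library()].
#' @param baseline Flat baseline offset, AU (default 0).
#' @param noise_sd Per-point Gaussian noise standard deviation, AU
#'   (default 0).
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @param wavelengths Wavelength grid, nm (default `250:800`).
#' @param path_length Optical path length, cm (default 1).
#' @param label Label stored on the spectrum.
#' @return An [absorption_spectrum()].
#' @export
#' @examples
#' sp <- simulate_spectrum(c(low_spin_heme = 1e-5))
#' classify_coordination(sp)$state
simulate_spectrum <- function(species, band_library = default_band_library(),
                              baseline = 0, noise_sd = 0, seed = NULL,
                              wavelengths = 250:800, path_length = 1,
                              label = "") {
  stopifnot(is.numeric(species))
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("'species' must be a named concentration vector")
  unknown <- setdiff(names(species), names(band_library))
  if (length(unknown))
    stop("no band definition for species: ", paste(unknown, collapse = ", "))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  a <- rep(as.numeric(baseline), length(wavelengths))
  for (sp in names(species)) {
    bands <- band_library[[sp]]
    stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
    for (b in seq_len(nrow(bands))) {
      a <- a + species[[sp]] * path_length * bands$amplitude[b] *
        exp(-(wavelengths - bands$center[b])^2 / (2 * bands$width[b]^2))
    }
  }
  if (noise_sd > 0)
    a <- a + .with_seed(seed, function() stats::rnorm(length(a), 0, noise_sd))
  absorption_spectrum(wavelengths, a, label = label)
}
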