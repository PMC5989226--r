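test_that("a single Gaussian band is located to sub-nanometre precision", {
  sp <- simulate_spectrum(
    c(low_spin_heme = 1e-5),
    band_library = list(low_spin_heme = data.frame(
      center = 425, width = 12, amplitude = 79400)))
  pk <- detect_peaks(sp, min_prominence = 0.01)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$wavelength - 425), 0.5)
})

test_that("flat and zero spectra yield no peaks and a no_heme call", {
  flat <- absorption_spectrum(250:800, rep(0.2, 551))
  expect_equal(nrow(detect_peaks(flat)), 0)
  zero <- absorption_spectrum(250:800, rep(0, 551))
  expect_identical(classify_coordination(zero)$state, "no_heme")
})

test_that("the low-spin composite reports its delta, Soret and beta bands", {
  sp <- simulate_spectrum(c(low_spin_heme = 1e-5))
  pk <- detect_peaks(sp, min_prominence = 0.005)
  for (center in c(360, 425, 543)) {
    hit <- pk$wavelength[which.min(abs(pk$wavelength - center))]
    expect_lt(abs(hit - center), 1)
  }
  # the 575 nm alpha band rides the beta band as a shoulder: no local
  # maximum of its own at the default band library
  expect_false(any(abs(pk$wavelength - 575) < 8))
})

test_that("peak positions are invariant to scaling and baseline offset", {
  sp <- simulate_spectrum(c(low_spin_heme = 1e-5))
  pk <- detect_peaks(sp, min_prominence = 0.005)

  scaled <- absorption_spectrum(sp$wavelength, sp$absorbance * 7)
  pk_s <- detect_peaks(scaled, min_prominence = 0.005 * 7)
  expect_equal(pk_s$wavelength, pk$wavelength, tolerance = 1e-10)

  offset <- absorption_spectrum(sp$wavelength, sp$absorbance + 0.35)
  pk_o <- detect_peaks(offset, min_prominence = 0.005)
  expect_equal(pk_o$wavelength, pk$wavelength, tolerance = 1e-10)
  expect_equal(pk_o$prominence, pk$prominence, tolerance = 1e-8)
})

test_that("coordination calls match the generating species", {
  set.seed(13)
  for (i in 1:100) {
    conc <- runif(1, 2e-6, 3e-5)
    lab <- if (i %% 2) "low_spin_heme" else "high_spin_heme"
    sp <- simulate_spectrum(stats::setNames(conc, lab))
    want <- if (i %% 2) "hexacoordinate_low_spin" else "pentacoordinate_high_spin"
    expect_identical(classify_coordination(sp)$state, want)
  }
  # 50/50 mixture shows both signatures
  mix <- simulate_spectrum(c(low_spin_heme = 5e-6, high_spin_heme = 5e-6))
  expect_identical(classify_coordination(mix)$state, "mixed")
})

test_that("high-spin calls require the charge-transfer band", {
  # a 390 nm Soret alone (e.g. free hemin-like) is ambiguous, not high spin
  sp <- simulate_spectrum(
    c(s = 1e-5),
    band_library = list(s = data.frame(center = 390, width = 12,
                                       amplitude = 75000)))
  call <- classify_coordination(sp)
  expect_identical(call$state, "mixed")
  expect_false(call$ct_band_645)
})

test_that("smoothing does not displace the Soret maximum", {
  sp <- simulate_spectrum(c(low_spin_heme = 1e-5))
  call <- classify_coordination(sp)
  expect_lt(abs(call$soret_lambda_max - 425), 0.5)
})

test_that("Reinheitszahl is the interpolated Soret / 280 nm ratio", {
  grid <- 250:800
  a <- 0.2 + 0 * grid
  a[grid == 280] <- 1.0
  a[grid == 425] <- 1.43
  sp <- absorption_spectrum(grid, a)
  expect_equal(reinheitszahl(sp), 1.43)

  sp_eq <- absorption_spectrum(grid, rep(0.8, length(grid)))
  expect_equal(reinheitszahl(sp_eq), 1.0)

  # fully bound complex built with the anchored Soret amplitudes
  full <- simulate_spectrum(c(low_spin_heme = 1e-5))
  expect_equal(reinheitszahl(full), 1.43, tolerance = 1e-6)

  zero <- absorption_spectrum(grid, rep(0, length(grid)))
  expect_error(reinheitszahl(zero), "undefined")
})

test_that("spectrum validation rejects malformed grids", {
  expect_error(absorption_spectrum(c(300, 300, 301), c(1, 1, 1)),
               "strictly increasing")
  expect_error(absorption_spectrum(c(200, 300), c(1, 1)), "250")
  expect_error(absorption_spectrum(c(300, 900), c(1, 1)), "800")
  expect_error(absorption_spectrum(c(300, 301), c(1, NA)), "finite")
  short <- absorption_spectrum(seq(300, 400, by = 10), rep(1, 11))
  expect_error(detect_peaks(short), "20 grid points")
})
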