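# shared fixtures: all synthetic, generated in code

# wild-type ground-truth parameter set used across recovery tests
wt_params <- function() binding_params(kd = 59e-9, eps_dh = 79400,
                                       eps_h = 27400, x = 0.81)

# independent equilibrium oracle: bisection on Kd = [D]_f [H]_f,active / [DH]
# (never calls the closed form under test)
bisect_dh <- function(d_total, h_total, kd, x) {
  xh <- x * h_total
  hi <- min(d_total, xh)
  if (hi <= 0) return(0)
  f <- function(dh) (d_total - dh) * (xh - dh) - kd * dh
  stats::uniroot(f, c(0, hi), tol = 1e-18)$root
}

# noiseless 20-addition series reaching ~2 protein equivalents
make_series <- function(params, d0 = 9.4e-6, n_additions = 20,
                        dilution = TRUE, noise_sd = 0, seed = NULL,
                        wavelength = 425) {
  simulate_titration(
    titration_protocol(n_additions = n_additions,
                       dilution_correction = dilution),
    d_total_initial = d0, params = params, noise_sd = noise_sd,
    seed = seed, wavelength = wavelength)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
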