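test_that("equilibrium solver handles the no-ligand and limiting-reagent limits", {
  p <- wt_params()
  eq0 <- solve_equilibrium(9.4e-6, 0, p)
  expect_identical(eq0$dh, 0)
  expect_equal(eq0$d_f, 9.4e-6)
  expect_identical(eq0$h_f, 0)

  # K_d -> 0: all active hemin is consumed (active pool is limiting)
  p_tight <- binding_params(kd = 1e-15, eps_dh = 1, eps_h = 1, x = 1)
  eq <- solve_equilibrium(1e-5, 5e-6, p_tight)
  expect_equal(eq$dh, 5e-6, tolerance = 1e-9)
})

test_that("closed-form [DH] matches the bisection oracle on the reference point", {
  # frozen from the independent bisection oracle at tolerance 1e-15 M
  eq <- solve_equilibrium(9.4e-6, 9.4e-6, wt_params())
  expect_equal(eq$dh, 7.39622273109e-6, tolerance = 1e-9)
})

test_that("closed form agrees with the bisection oracle over random valid tuples", {
  set.seed(42)
  n <- 10000
  d <- 10^runif(n, -8, -4)
  h <- 10^runif(n, -8, -4)
  kd <- 10^runif(n, -10, -5)
  x <- runif(n, 0.01, 1)
  worst <- 0
  for (i in seq_len(n)) {
    p <- binding_params(kd[i], 1, 1, x[i])
    dh_cf <- solve_equilibrium(d[i], h[i], p)$dh
    dh_or <- bisect_dh(d[i], h[i], kd[i], x[i])
    worst <- max(worst, abs(dh_cf - dh_or))
  }
  expect_lt(worst, 1e-12)
})

test_that("mass balances hold and concentrations stay physical", {
  set.seed(7)
  for (i in 1:200) {
    d <- 10^runif(1, -8, -4); h <- 10^runif(1, -8, -4)
    p <- binding_params(10^runif(1, -10, -5), 1, 1, runif(1, 0.01, 1))
    eq <- solve_equilibrium(d, h, p)
    expect_true(eq$dh >= 0 && eq$d_f >= -1e-18 && eq$h_f_active >= -1e-18)
    expect_lte(eq$dh, min(d, p$x * h) + 1e-18)
    expect_equal(eq$dh + eq$d_f, d, tolerance = 1e-12)
    expect_equal(eq$dh + eq$h_f_active, p$x * h, tolerance = 1e-12)
    expect_equal(eq$dh + eq$h_f, h, tolerance = 1e-12)
  }
})

test_that("[DH] is monotone in h_total, x, and kd", {
  d <- 9.4e-6
  h_grid <- seq(0, 2e-5, length.out = 41)
  dh_h <- solve_equilibrium(d, h_grid, wt_params())$dh
  expect_true(all(diff(dh_h) >= -1e-18))

  x_grid <- seq(0.05, 1, length.out = 40)
  dh_x <- vapply(x_grid, function(x)
    solve_equilibrium(d, 9.4e-6, binding_params(59e-9, 1, 1, x))$dh, numeric(1))
  expect_true(all(diff(dh_x) >= 0))

  kd_grid <- 10^seq(-10, -5, length.out = 40)
  dh_kd <- vapply(kd_grid, function(kd)
    solve_equilibrium(d, 9.4e-6, binding_params(kd, 1, 1, 0.81))$dh, numeric(1))
  expect_true(all(diff(dh_kd) <= 0))
})

test_that("invalid concentrations and parameters are rejected", {
  p <- wt_params()
  expect_error(solve_equilibrium(-1e-6, 1e-6, p), "non-negative")
  expect_error(solve_equilibrium(1e-6, -1e-6, p), "non-negative")
  expect_error(binding_params(0, 1, 1, 0.8), "positive")
  expect_error(binding_params(1e-9, -1, 1, 0.8), "non-negative")
  expect_error(binding_params(1e-9, 1, 1, 0), "0, 1")
  expect_error(binding_params(1e-9, 1, 1, 1.2), "0, 1")
})

test_that("predicted absorbance follows the two-species Beer-Lambert form", {
  p <- wt_params()
  expect_identical(predict_absorbance(9.4e-6, 0, p), 0)

  # indistinguishable species: A depends only on total hemin
  p_eq <- binding_params(59e-9, 5e4, 5e4, 0.81)
  h <- c(1e-6, 5e-6, 1.3e-5)
  expect_equal(predict_absorbance(9.4e-6, h, p_eq), 5e4 * h, tolerance = 1e-12)

  # no protein: only free hemin absorbs
  expect_equal(predict_absorbance(0, h, p), p$eps_h * h, tolerance = 1e-12)

  # composition with the oracle [DH] at the reference point
  dh <- bisect_dh(9.4e-6, 9.4e-6, 59e-9, 0.81)
  expect_equal(predict_absorbance(9.4e-6, 9.4e-6, p),
               p$eps_dh * dh + p$eps_h * (9.4e-6 - dh), tolerance = 1e-10)

  # monotone non-decreasing in h_total
  a <- predict_absorbance(9.4e-6, seq(0, 2e-5, length.out = 50), p)
  expect_true(all(diff(a) >= -1e-15))

  # path length scales linearly and must be positive
  expect_equal(predict_absorbance(9.4e-6, 9.4e-6, p, path_length = 0.5),
               0.5 * predict_absorbance(9.4e-6, 9.4e-6, p))
  expect_error(predict_absorbance(9.4e-6, 9.4e-6, p, path_length = 0),
               "positive")
})
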