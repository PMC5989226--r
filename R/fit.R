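#' Default starting values for a titration fit
#'
#' Heuristics computable from any series: `eps_h` from the slope of the
#' last three points against total hemin (past the equivalence point the
#' signal grows at the free-hemin coefficient), `eps_dh` from the
#' absorbance nearest one protein equivalent divided by the protein
#' concentration, `x = 0.9`, and `kd = d_total / 100` (a tight-binding
#' guess well below the working concentration).
#'
#' @param series A [titration_series()].
#' @return A [binding_params()] object.
#' @export
default_init <- function(series) {
  h <- series$h_total
  a <- series$a_obs
  d0 <- attr(series, "d_total")
  L <- attr(series, "path_length")
  n <- nrow(series)
  tail_idx <- seq(max(1, n - 2), n)
  eps_h <- if (length(tail_idx) >= 2) {
    slope <- stats::coef(stats::lm(a[tail_idx] ~ h[tail_idx]))[2] / L
    max(as.numeric(slope), 1)
  } else 1e4
  i_eq <- which.min(abs(h - d0))
  eps_dh <- max(a[i_eq] / (d0 * L), eps_h, 1)
  binding_params(kd = d0 / 100, eps_dh = eps_dh, eps_h = eps_h, x = 0.9)
}

# residuals of the absorbance model for a parameter vector
# theta = (log10_kd, eps_dh, eps_h, x)
.titration_residuals <- function(theta, series, dilution) {
  p <- binding_params(kd = 10^theta[1], eps_dh = theta[2],
                      eps_h = theta[3], x = theta[4])
  d <- .series_d_total(series, dilution)
  series$a_obs - predict_absorbance(d, series$h_total, p,
                                    attr(series, "path_length"))
}

.theta_from_params <- function(p) {
  c(log10_kd = log10(p$kd), eps_dh = p$eps_dh, eps_h = p$eps_h, x = p$x)
}

.params_from_theta <- function(theta) {
  binding_params(kd = 10^theta[[1]], eps_dh = theta[[2]],
                 eps_h = theta[[3]], x = theta[[4]])
}

#' Fit the tight-binding model to a hemin titration
#'
#' Least-squares fit of the four-parameter absorbance model
#' \eqn{A_{obs} = L(\varepsilon_{DH}[DH] + \varepsilon_H [H]_f)} (with
#' \eqn{[DH]} from the mass-action quadratic, see [solve_equilibrium()])
#' to an observed titration series. Minimization uses
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) with box bounds, with the
#' dissociation constant fitted on the log10 scale. Because the active
#' fraction and the bound-heme coefficient are nearly degenerate in the
#' tight-binding regime, the optimizer is restarted `n_starts` times from
#' log-uniformly perturbed dissociation constants and jittered
#' coefficients; the lowest residual sum of squares wins.
#'
#' @param series A [titration_series()] with at least 6 points.
#' @param init Optional [binding_params()] starting values; defaults to
#'   [default_init()].
#' @param lower,upper Named bounds on `kd` (M), `eps_dh`, `eps_h`
#'   (M^-1 cm^-1) and `x`. Defaults: `kd` in \[1e-12, 1e-3\], epsilons in
#'   \[0, 1e6\], `x` in \[0.01, 1\].
#' @param fixed Character vector of parameter names (`"kd"`, `"eps_dh"`,
#'   `"eps_h"`, `"x"`) to hold fixed at their `init` values.
#' @param n_starts Number of multi-start restarts (default 8).
#' @param seed Integer seed for the restart perturbations (default 0).
#' @param dilution If `TRUE` (default) and the series carries per-point
#'   protein concentrations (`d_total_point`), the model uses them so that
#'   dilution by the titrant aliquots is accounted for; if `FALSE`, the
#'   nominal `d_total` is used at every point, matching the bare model
#'   equations.
#' @return An object of class `heme_fit`: a list with elements `params`
#'   ([binding_params()]), `fixed`, `residuals`, `fitted`, `rss`,
#'   `converged`, `n_starts_used`, `message`, `series`, `dilution`, `seed`
#'   and `ci` (`NULL` until [bootstrap_ci()] is run).
#' @seealso [bootstrap_ci()], [simulate_titration()]
#' @export
#' @examples
#' p <- binding_params(59e-9, 79400, 27400, 0.81)
#' ser <- simulate_titration(titration_protocol(n_additions = 20),
#'                           d_total_initial = 9.4e-6, params = p)
#' fit <- fit_titration(ser)
#' coef(fit)
fit_titration <- function(series, init = NULL,
                          lower = c(kd = 1e-12, eps_dh = 0, eps_h = 0, x = 0.01),
                          upper = c(kd = 1e-3, eps_dh = 1e6, eps_h = 1e6, x = 1),
                          fixed = NULL, n_starts = 8, seed = 0,
                          dilution = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 6)
    stop("at least 6 titration points are required for a 4-parameter fit")
  if (stats::sd(series$a_obs) < 1e-12 * max(1, abs(mean(series$a_obs))))
    stop("degenerate fit: absorbances are flat; no binding signal to fit ",
         "(check monitor wavelength and units)")
  if (is.null(init)) init <- default_init(series)
  stopifnot(inherits(init, "binding_params"))
  par_names <- c("kd", "eps_dh", "eps_h", "x")
  if (!is.null(fixed) && !all(fixed %in% par_names))
    stop("'fixed' must name parameters among: ", paste(par_names, collapse = ", "))
  free <- setdiff(par_names, fixed)

  lo <- c(log10(lower[["kd"]]), lower[["eps_dh"]], lower[["eps_h"]], lower[["x"]])
  hi <- c(log10(upper[["kd"]]), upper[["eps_dh"]], upper[["eps_h"]], upper[["x"]])
  theta0 <- pmin(pmax(.theta_from_params(init), lo), hi)
  free_idx <- match(free, par_names)

  # multi-start sweep: start 1 is the supplied/default init, the rest
  # draw log-uniform kd over its bounds and jitter the linear parameters
  starts <- vector("list", n_starts)
  starts[[1]] <- theta0
  if (n_starts > 1) {
    runif_local <- .with_seed(seed, function() {
      lapply(seq_len(n_starts - 1), function(i)
        c(stats::runif(1, lo[1], hi[1]),
          theta0[2] * stats::runif(1, 0.5, 2),
          theta0[3] * stats::runif(1, 0.5, 2),
          stats::runif(1, 0.5, 1)))
    })
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- pmin(pmax(runif_local[[i]], lo), hi)
  }

  obj <- function(th_free) {
    th <- theta0
    th[free_idx] <- th_free
    .titration_residuals(th, series, dilution)
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st[free_idx], fn = obj,
                         lower = lo[free_idx], upper = hi[free_idx],
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-10, maxiter = 1024)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("optimizer failed from every start; inspect the series")

  theta_hat <- theta0
  theta_hat[free_idx] <- best$par
  params <- .params_from_theta(theta_hat)
  resid <- .titration_residuals(theta_hat, series, dilution)
  structure(list(
    params = params,
    fixed = fixed %||% character(0),
    residuals = as.numeric(resid),
    fitted = series$a_obs - as.numeric(resid),
    rss = sum(resid^2),
    converged = best$info %in% 1:4,
    n_starts_used = n_starts,
    message = best$message,
    series = series,
    dilution = dilution,
    seed = seed,
    ci = NULL
  ), class = "heme_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run fn with a temporarily seeded RNG, restoring global state afterwards
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' @export
coef.heme_fit <- function(object, ...) {
  p <- object$params
  c(kd = p$kd, eps_dh = p$eps_dh, eps_h = p$eps_h, x = p$x)
}

#' @export
print.heme_fit <- function(x, ...) {
  cat("Tight-binding titration fit\n")
  print(x$params)
  cat(sprintf("  RSS %.4g over %d points; converged: %s; %d starts\n",
              x$rss, length(x$residuals), x$converged, x$n_starts_used))
  if (length(x$fixed)) cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% intervals:\n")
    print(x$ci)
  }
  invisible(x)
}

#' Residual-resampling bootstrap intervals for a titration fit
#'
#' Resamples the fit residuals with replacement, adds them back to the
#' fitted curve, refits, and returns percentile (2.5/97.5 by default)
#' intervals over the `n_boot` refits. Refits start from the point
#' estimate with a single start, which is adequate because the resampled
#' data stay close to the fitted curve.
#'
#' @param fit A converged [fit_titration()] result.
#' @param n_boot Number of bootstrap replicates (default 500). Fewer than
#'   100 triggers a warning recorded on the result.
#' @param seed Integer seed (default 0); identical seeds give identical
#'   intervals.
#' @param level Confidence level (default 0.95).
#' @return The `heme_fit` with `ci` set: a data frame with rows `kd`,
#'   `eps_dh`, `eps_h`, `x` and columns `lower`, `upper`, plus attributes
#'   `n_boot`, `level`, and `n_failed`.
#' @export
bootstrap_ci <- function(fit, n_boot = 500, seed = 0, level = 0.95) {
  stopifnot(inherits(fit, "heme_fit"))
  if (!fit$converged)
    stop("bootstrap requires a converged fit")
  low_boot <- n_boot < 100
  if (low_boot)
    warning("n_boot < 100 gives unstable percentile intervals")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ser <- fit$series
  draws <- .with_seed(seed, function() {
    out <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                  dimnames = list(NULL, c("kd", "eps_dh", "eps_h", "x")))
    for (b in seq_len(n_boot)) {
      a_b <- fit$fitted + sample(fit$residuals, replace = TRUE)
      ser_b <- ser
      ser_b$a_obs <- a_b
      f_b <- tryCatch(
        fit_titration(ser_b, init = fit$params, fixed = fit$fixed,
                      n_starts = 1, dilution = fit$dilution),
        error = function(e) NULL)
      if (!is.null(f_b)) out[b, ] <- coef(f_b)
    }
    out
  })
  ok <- stats::complete.cases(draws)
  ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = probs))
  ci <- data.frame(lower = ci[, 1], upper = ci[, 2],
                   row.names = colnames(draws))
  attr(ci, "n_boot") <- n_boot
  attr(ci, "level") <- level
  attr(ci, "n_failed") <- sum(!ok)
  attr(ci, "low_boot_warning") <- low_boot
  fit$ci <- ci
  fit
}
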