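#' Binding-model parameters for a 1:1 heme-protein titration
#'
#' Bundles the four parameters of the tight-binding absorbance model:
#' the dissociation constant `kd` (M), the extinction coefficients of
#' protein-bound heme (`eps_dh`) and free hemin (`eps_h`) at the monitor
#' wavelength (M^-1 cm^-1), and the active hemin fraction `x` -- the
#' fraction of the hemin stock that is monomeric and competent to bind,
#' as opposed to aggregated.
#'
#' @param kd Dissociation constant, molar. Must be positive.
#' @param eps_dh Extinction coefficient of the protein-heme complex at the
#'   monitor wavelength, M^-1 cm^-1. Non-negative.
#' @param eps_h Extinction coefficient of free hemin at the monitor
#'   wavelength, M^-1 cm^-1. Non-negative.
#' @param x Active hemin fraction, in (0, 1].
#' @return An object of class `binding_params`.
#' @export
#' @examples
#' binding_params(kd = 59e-9, eps_dh = 79400, eps_h = 27400, x = 0.81)
binding_params <- function(kd, eps_dh, eps_h, x) {
  stopifnot(is.numeric(kd), is.numeric(eps_dh), is.numeric(eps_h),
            is.numeric(x), length(kd) == 1, length(eps_dh) == 1,
            length(eps_h) == 1, length(x) == 1)
  if (!is.finite(kd) || kd <= 0)
    stop("'kd' must be a positive, finite dissociation constant in molar")
  if (!is.finite(eps_dh) || eps_dh < 0)
    stop("'eps_dh' must be a non-negative extinction coefficient")
  if (!is.finite(eps_h) || eps_h < 0)
    stop("'eps_h' must be a non-negative extinction coefficient")
  if (!is.finite(x) || x <= 0 || x > 1)
    stop("active hemin fraction 'x' must lie in (0, 1]")
  structure(list(kd = kd, eps_dh = eps_dh, eps_h = eps_h, x = x),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("1:1 tight-binding model parameters\n")
  cat(sprintf("  K_d    : %.4g nM\n", x$kd * 1e9))
  cat(sprintf("  eps_DH : %.4g mM-1 cm-1\n", x$eps_dh / 1000))
  cat(sprintf("  eps_H  : %.4g mM-1 cm-1\n", x$eps_h / 1000))
  cat(sprintf("  x      : %.4g (active hemin fraction)\n", x$x))
  invisible(x)
}

#' @export
as.list.binding_params <- function(x, ...) unclass(x)

#' Solve the 1:1 binding equilibrium with an active ligand pool
#'
#' Computes the bound-complex concentration \[DH\] from total protein
#' `d_total`, total hemin `h_total` and the binding parameters, using the
#' closed-form root of the mass-action quadratic
#' \deqn{[DH] = \frac{S - \sqrt{S^2 - 4 x [H]_{tot} [D]_{tot}}}{2}, \quad
#'       S = [D]_{tot} + x [H]_{tot} + K_d.}
#' Only the active fraction `x` of the total hemin participates in the
#' equilibrium. The smaller ("minus") quadratic root is the physical one:
#' the "plus" root exceeds the total protein concentration. The
#' discriminant is clamped at zero to guard against floating-point
#' round-off in the tight-binding limit.
#'
#' @param d_total Total protein concentration, molar (scalar, >= 0).
#' @param h_total Total hemin concentration(s), molar (vector, >= 0).
#' @param params A [binding_params()] object.
#' @return A data frame of class `equilibrium_state` with one row per
#'   `h_total` value and columns:
#'   \describe{
#'     \item{dh}{bound-complex concentration, M}
#'     \item{d_f}{free protein, M (`d_total - dh`)}
#'     \item{h_f}{free hemin including the inactive pool, M
#'       (`h_total - dh`); this is the pool that contributes absorbance}
#'     \item{h_f_active}{free *active* hemin, M (`x * h_total - dh`);
#'       this is the pool that enters the mass-action law}
#'   }
#' @export
#' @examples
#' p <- binding_params(59e-9, 79400, 27400, 0.81)
#' solve_equilibrium(9.4e-6, 9.4e-6, p)
solve_equilibrium <- function(d_total, h_total, params) {
  stopifnot(inherits(params, "binding_params"),
            is.numeric(d_total), length(d_total) %in% c(1, length(h_total)),
            is.numeric(h_total))
  if (any(!is.finite(d_total)) || any(d_total < 0))
    stop("'d_total' must be non-negative and finite")
  if (any(!is.finite(h_total)) || any(h_total < 0))
    stop("'h_total' must be non-negative and finite")
  xh <- params$x * h_total
  s <- d_total + xh + params$kd
  disc <- s^2 - 4 * xh * d_total
  # round-off can push the discriminant a hair below zero at tight binding
  disc[disc < 0] <- 0
  dh <- (s - sqrt(disc)) / 2
  dh <- pmin(dh, d_total, xh)   # numerical guard; exact math already obeys this
  dh[dh < 0] <- 0
  out <- data.frame(dh = dh,
                    d_f = d_total - dh,
                    h_f = h_total - dh,
                    h_f_active = xh - dh)
  class(out) <- c("equilibrium_state", "data.frame")
  out
}

#' Predict observed absorbance for a titration point
#'
#' Forward absorbance model of the titration:
#' \deqn{A_{obs} = L\,(\varepsilon_{DH} [DH] + \varepsilon_H [H]_f)}
#' with \eqn{[H]_f = [H]_{tot} - [DH]}: the bound complex absorbs with
#' `eps_dh` and *all* unbound hemin -- monomeric and aggregated alike --
#' absorbs with the single effective coefficient `eps_h`.
#'
#' @inheritParams solve_equilibrium
#' @param path_length Optical path length, cm (default 1).
#' @return Numeric vector of predicted absorbances (AU), one per
#'   `h_total`.
#' @export
#' @examples
#' p <- binding_params(59e-9, 79400, 27400, 0.81)
#' predict_absorbance(9.4e-6, c(0, 5e-6, 1e-5), p)
predict_absorbance <- function(d_total, h_total, params, path_length = 1) {
  if (!is.numeric(path_length) || length(path_length) != 1 ||
      !is.finite(path_length) || path_length <= 0)
    stop("'path_length' must be a positive length in cm")
  eq <- solve_equilibrium(d_total, h_total, params)
  path_length * (params$eps_dh * eq$dh + params$eps_h * eq$h_f)
}
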