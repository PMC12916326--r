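#' Creep-compliance curve
#'
#' A sampled creep compliance J(t) with the two tail quantities needed by the
#' discrete creep-to-modulus conversion: the instantaneous compliance `J0`
#' and the steady-state viscosity `eta` (the long-time extrapolation
#' J(t) ~ J0' + t/eta). Both are typically obtained with [fit_creep_tail()].
#'
#' Compliance units: for a bead of radius R um pulled with f pN and
#' displaced x um, `J = 6 pi R x / f` expressed in um^2/pN is numerically
#' equal to 1/Pa (1 um^2/pN = 1 m^2/N), so no conversion factor is needed.
#'
#' @param times sample times t_k (s), strictly increasing with `times[1] > 0`.
#' @param compliance J_k (1/Pa), non-negative.
#' @param J0 instantaneous compliance J(0) (1/Pa), or `NA` until fitted.
#' @param eta steady-state viscosity (Pa s), or `NA` until fitted.
#' @param bead_radius bead radius (um), optional bookkeeping.
#' @return An object of class `creep_curve`.
#' @export
creep_curve <- function(times, compliance, J0 = NA_real_, eta = NA_real_,
                        bead_radius = NA_real_) {
  check_increasing(times)
  if (length(times) != length(compliance))
    stop_invalid("times and compliance must have equal length")
  if (length(times) < 1L || times[1] <= 0)
    stop_invalid("creep times must be positive (t_1 > 0)")
  if (any(compliance < 0)) stop_invalid("compliance must be non-negative")
  if (!is.na(J0) && J0 < 0) stop_invalid("J0 must be non-negative")
  if (!is.na(eta)) check_positive(eta, "eta")
  structure(list(times = times, compliance = compliance, J0 = J0, eta = eta,
                 bead_radius = bead_radius),
            class = "creep_curve")
}

#' Creep compliance from a force-pulse response
#'
#' Pointwise creep compliance over the loading window of a pulse,
#' \deqn{J(t) = 6\pi R\, x(t) / f(t),}
#' with R the bead radius. Only samples with `0 < t <= tp` are used (the
#' relaxation branch is not a creep measurement). With x in um, f in pN and
#' R in um the result is numerically in 1/Pa.
#'
#' @param pulse a [pulse_response()].
#' @param force_series applied force f(t) in pN, one value per `pulse$times`
#'   sample, or a single number recycled.
#' @param bead_radius bead radius (um).
#' @return a [creep_curve()] (with `J0`, `eta` unset; see [fit_creep_tail()]).
#' @export
creep_from_pulse <- function(pulse, force_series, bead_radius) {
  stopifnot(inherits(pulse, "pulse_response"))
  check_positive(bead_radius, "bead_radius")
  t <- pulse$times
  if (length(force_series) == 1L) force_series <- rep(force_series, length(t))
  if (length(force_series) != length(t))
    stop_invalid("force_series must match the pulse time grid")
  on <- which(t > 0 & t <= pulse$tp)
  if (length(on) == 0L) stop_invalid("empty loading window")
  bad <- on[force_series[on] <= 0]
  if (length(bad))
    stop_invalid("non-positive force at sample index ", bad[1])
  J <- 6 * pi * bead_radius * pulse$displacement[on] / force_series[on]
  creep_curve(t[on], J, bead_radius = bead_radius)
}

#' Phenomenological creep-tail fit
#'
#' Fits the creep compliance to `b + a t + c exp(-d t)`, which captures an
#' initial transient plus the long-time viscous flow. The derived quantities
#' are the instantaneous compliance `J0 = b + c` and the steady-state
#' viscosity `eta = 1/a`; both are needed by [creep_to_modulus()].
#'
#' @param curve a [creep_curve()] with at least 6 samples.
#' @return An object of class `creep_tail_fit` with fields `b`, `slope_a`,
#'   `amp_c`, `rate_d`, `J0`, `eta`, `residual_norm`.
#' @export
fit_creep_tail <- function(curve) {
  stopifnot(inherits(curve, "creep_curve"))
  t <- curve$times; J <- curve$compliance
  if (length(t) < 6L) stop_invalid("need at least 6 samples")
  # line through the tail initialises (b, a); the early residual sets (c, d)
  tail_idx <- seq.int(ceiling(length(t) / 2), length(t))
  lf <- ls_slope(t[tail_idx], J[tail_idx])
  a0 <- max(lf$slope, 1e-12)
  b0 <- lf$intercept
  c0 <- J[1] - (b0 + a0 * t[1])
  if (abs(c0) < 1e-12 * max(abs(J), 1e-12)) c0 <- sign(c0 + 1e-30) * 1e-6 * max(abs(J), 1e-6)
  d0 <- 3 / max(t)
  resid_fn <- function(p) p[1] + p[2] * t + p[3] * exp(-p[4] * t) - J
  starts <- list(c(b0, a0, c0, d0), c(b0, a0, c0, 10 * d0),
                 c(b0, a0, -c0, d0))
  fit <- lm_multistart(resid_fn, starts,
                       lower = c(-Inf, 1e-15, -Inf, 1e-12),
                       upper = rep(Inf, 4), what = "creep tail")
  p <- fit$par
  structure(list(b = p[1], slope_a = p[2], amp_c = p[3], rate_d = p[4],
                 J0 = p[1] + p[3], eta = 1 / p[2],
                 residual_norm = sqrt(sum(fit$fvec^2))),
            class = "creep_tail_fit")
}

#' @export
print.creep_tail_fit <- function(x, ...) {
  cat(sprintf("Creep tail fit: b = %.4g, a = %.4g, c = %.4g, d = %.4g\n",
              x$b, x$slope_a, x$amp_c, x$rate_d))
  cat(sprintf("  J(0) = b + c = %.4g 1/Pa, eta = 1/a = %.4g Pa s\n",
              x$J0, x$eta))
  invisible(x)
}

#' Attach tail-fit quantities to a creep curve
#'
#' Convenience wrapper: runs [fit_creep_tail()] and returns the curve with
#' `J0` and `eta` filled in, ready for [creep_to_modulus()].
#'
#' @param curve a [creep_curve()].
#' @return the curve with `J0` and `eta` set; the fit is attached as
#'   attribute `"tail_fit"`.
#' @export
apply_creep_tail <- function(curve) {
  fit <- fit_creep_tail(curve)
  curve$J0 <- max(fit$J0, 0)
  curve$eta <- fit$eta
  attr(curve, "tail_fit") <- fit
  curve
}

#' Convert a creep compliance to the complex shear modulus
#'
#' Discrete conversion of a sampled creep compliance J(t_k) to G*(omega)
#' (Evans-type direct conversion):
#' \deqn{\frac{i\omega}{G^*(\omega)} = i\omega J(0)
#'  + \frac{(1 - e^{-i\omega t_1})\,[J_1 - J(0)]}{t_1}
#'  + \frac{e^{-i\omega t_N}}{\eta}
#'  + \sum_{k=2}^{N} \frac{J_k - J_{k-1}}{t_k - t_{k-1}}
#'    \left(e^{-i\omega t_{k-1}} - e^{-i\omega t_k}\right),}
#' where `J(0)` is the instantaneous compliance and `eta` the steady-state
#' viscosity (both from [fit_creep_tail()] / [apply_creep_tail()]).
#'
#' The discrete sum is reliable only for angular frequencies within the
#' window set by the sampling, roughly `2 pi / t_N` to `pi / dt`; a warning
#' is emitted for frequencies outside it.
#'
#' @param curve a [creep_curve()] with `J0` and `eta` set.
#' @param omega angular frequencies (rad/s), positive.
#' @param label phase/condition label stored in the output spectrum.
#' @return a [modulus_spectrum()] on `omega / 2 pi` Hz.
#' @export
creep_to_modulus <- function(curve, omega, label = "") {
  stopifnot(inherits(curve, "creep_curve"))
  if (length(curve$times) < 2L)
    stop_invalid("need at least 2 creep samples")
  if (is.na(curve$J0) || is.na(curve$eta))
    stop_invalid("curve must carry J0 and eta; see apply_creep_tail()")
  if (any(omega <= 0)) stop_invalid("omega must be positive")
  t <- curve$times; J <- curve$compliance
  check_increasing(t)
  dtmin <- min(diff(t)); tN <- t[length(t)]
  lo <- 2 * pi / tN; hi <- pi / dtmin
  if (any(omega < lo - 1e-12) || any(omega > hi + 1e-12))
    warning(sprintf(
      "omega outside the resolvable window [%.3g, %.3g] rad/s implied by sampling",
      lo, hi))
  N <- length(t)
  slopes <- diff(J) / diff(t)          # (J_k - J_{k-1})/(t_k - t_{k-1}), k=2..N
  G <- vapply(omega, function(w) {
    e <- exp(-1i * w * t)
    rhs <- 1i * w * curve$J0 +
      (1 - e[1]) * (J[1] - curve$J0) / t[1] +
      e[N] / curve$eta +
      sum(slopes * (e[-N] - e[-1]))
    (1i * w) / rhs
  }, complex(1))
  modulus_spectrum(frequency_hz = omega / (2 * pi),
                   g_prime = Re(G), g_double_prime = Im(G), label = label)
}
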