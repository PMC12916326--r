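#' Jeffreys viscoelastic material parameters
#'
#' A Jeffreys material is a Kelvin--Voigt element (spring `k` in parallel with
#' a dashpot `gamma1`) in series with a second dashpot `gamma2`. It shows
#' transient elasticity on short times and unbounded viscous flow on long
#' times, which is the phenomenology of embryonic cytoplasm probed with
#' force pulses on microinjected beads.
#'
#' Units follow the bead-pulling convention used throughout the package:
#' `k` in pN/um and `gamma1`, `gamma2` in pN s/um, so that `k * t / gamma1`
#' is dimensionless and `F0 / k` is a displacement in um. The cytoplasm
#' parameter sets measured in the two cell-cycle phases are available as
#' [interphase_params()] and [mphase_params()].
#'
#' @param k spring constant (pN/um), strictly positive.
#' @param gamma1 Kelvin--Voigt damping coefficient (pN s/um), strictly positive.
#' @param gamma2 series damping coefficient (pN s/um), strictly positive.
#' @return An object of class `jeffreys_params`.
#' @seealso [jeffreys_displacement()], [jeffreys_recovery()], [fit_jeffreys()]
#' @export
#' @examples
#' jeffreys_params(k = 32.4, gamma1 = 56.1, gamma2 = 189.8)
jeffreys_params <- function(k, gamma1, gamma2) {
  check_positive(k, "k")
  check_positive(gamma1, "gamma1")
  check_positive(gamma2, "gamma2")
  structure(list(k = k, gamma1 = gamma1, gamma2 = gamma2),
            class = "jeffreys_params")
}

#' @export
print.jeffreys_params <- function(x, ...) {
  cat(sprintf("Jeffreys material: k = %.4g pN/um, gamma1 = %.4g pN s/um, gamma2 = %.4g pN s/um\n",
              x$k, x$gamma1, x$gamma2))
  cat(sprintf("  (KV relaxation time gamma1/k = %.3g s)\n", x$gamma1 / x$k))
  invisible(x)
}

#' Cytoplasm Jeffreys parameters in interphase and M-phase
#'
#' Parameter sets fitted from magnetic-tweezers pulses on beads in zebrafish
#' blastomere cytoplasm: the interphase cytoplasm (microtubule asters
#' present) is stiffer and more elastic than the M-phase cytoplasm.
#'
#' @return A `jeffreys_params` object.
#' @export
interphase_params <- function() jeffreys_params(k = 32.4, gamma1 = 56.1, gamma2 = 189.8)

#' @rdname interphase_params
#' @export
mphase_params <- function() jeffreys_params(k = 21.4, gamma1 = 27.0, gamma2 = 41.7)

#' Bead displacement under a rectangular force pulse (Jeffreys model)
#'
#' Closed-form response of a Jeffreys material to a constant force `F0`
#' applied for `tp` seconds and then released:
#' \deqn{x(t) = \frac{F_0}{k}(1 - e^{-kt/\gamma_1}) + \frac{F_0 t}{\gamma_2},
#'   \quad t \le t_p}
#' and for `t > tp`, with recovery fraction `a` from [jeffreys_recovery()],
#' \deqn{x(t) = x(t_p)\left(a\,e^{-k (t - t_p)/\gamma_1} + (1 - a)\right),}
#' i.e. the displacement decays from `x(tp)` toward the unrecovered viscous
#' part `(1 - a) x(tp)`. The relaxation clock starts at the end of the pulse
#' so the response is continuous at `t = tp`.
#'
#' @param params a [jeffreys_params()] object.
#' @param F0 mean force during the pulse (pN).
#' @param tp pulse duration (s), strictly positive.
#' @param t times (s), non-negative; vectorised.
#' @return displacement in um, same length as `t`.
#' @export
#' @examples
#' jeffreys_displacement(interphase_params(), F0 = 40, tp = 5, t = 5) # ~2.22 um
jeffreys_displacement <- function(params, F0, tp, t) {
  stopifnot(inherits(params, "jeffreys_params"))
  check_positive(tp, "tp")
  if (any(t < 0)) stop_invalid("t must be non-negative")
  k <- params$k; g1 <- params$gamma1; g2 <- params$gamma2
  xtp <- F0 / k * (1 - exp(-k * tp / g1)) + F0 * tp / g2
  a <- jeffreys_recovery(params, tp)
  on <- t <= tp
  x <- numeric(length(t))
  x[on] <- F0 / k * (1 - exp(-k * t[on] / g1)) + F0 * t[on] / g2
  x[!on] <- xtp * (a * exp(-k * (t[!on] - tp) / g1) + (1 - a))
  x
}

#' Recovery fraction of a Jeffreys material after a force pulse
#'
#' Fraction of the pulse displacement that is recovered after the force is
#' released:
#' \deqn{a = 1 - \frac{1}{1 + \frac{\gamma_2}{k t_p}(1 - e^{-k t_p/\gamma_1})}.}
#' `a` tends to 1 for an elastic solid (`gamma2` large) and to 0 for a fluid
#' (`tp` long compared to the flow time).
#'
#' @inheritParams jeffreys_displacement
#' @return recovery fraction in (0, 1).
#' @export
#' @examples
#' jeffreys_recovery(interphase_params(), tp = 5) # ~0.525
#' jeffreys_recovery(mphase_params(), tp = 5)     # ~0.277
jeffreys_recovery <- function(params, tp) {
  stopifnot(inherits(params, "jeffreys_params"))
  check_positive(tp, "tp")
  k <- params$k; g1 <- params$gamma1; g2 <- params$gamma2
  1 - 1 / (1 + g2 / (k * tp) * (1 - exp(-k * tp / g1)))
}

#' Complex shear response of a Jeffreys material
#'
#' Closed-form frequency response
#' \deqn{G^*_J(\omega) = \frac{(k + i\omega\gamma_1)\, i\omega\gamma_2}
#'   {k + i\omega\gamma_1 + i\omega\gamma_2}}
#' in the same force/displacement units as the parameters (pN/um). Used as
#' the analytic cross-check for the creep-to-modulus conversion.
#'
#' @param params a [jeffreys_params()] object.
#' @param omega angular frequency (rad/s), positive; vectorised.
#' @return a list with components `g_prime` and `g_double_prime`.
#' @export
jeffreys_modulus <- function(params, omega) {
  stopifnot(inherits(params, "jeffreys_params"))
  if (any(omega <= 0)) stop_invalid("omega must be positive")
  k <- params$k; g1 <- params$gamma1; g2 <- params$gamma2
  iw <- 1i * omega
  G <- (k + iw * g1) * (iw * g2) / (k + iw * g1 + iw * g2)
  list(g_prime = Re(G), g_double_prime = Im(G))
}

#' Force-pulse response record
#'
#' Container for one (possibly averaged) displacement curve under a
#' rectangular force pulse: a uniform time grid starting at 0, displacement
#' starting at 0, the mean applied force and the pulse duration.
#'
#' @param times times (s), strictly increasing from 0.
#' @param displacement bead displacement (um), same length as `times`.
#' @param F0 mean applied force during the pulse (pN).
#' @param tp pulse duration (s); must not exceed the last time.
#' @return An object of class `pulse_response`.
#' @export
pulse_response <- function(times, displacement, F0, tp) {
  check_increasing(times)
  if (length(times) != length(displacement))
    stop_invalid("times and displacement must have equal length")
  if (abs(displacement[1]) > 1e-9)
    stop_invalid("displacement must start at 0")
  check_positive(tp, "tp")
  if (tp > max(times)) stop_invalid("tp must not exceed the last time")
  structure(list(times = times, displacement = displacement, F0 = F0, tp = tp),
            class = "pulse_response")
}

#' Fit the Jeffreys model to a force-pulse response
#'
#' Least-squares fit of the piecewise pulse response (loading branch plus
#' relaxation branch, see [jeffreys_displacement()]) over the whole curve.
#' Levenberg--Marquardt with positivity bounds and a deterministic
#' multi-start: the data-driven initial guess `k0 = F0/x(tp)`,
#' `gamma1_0 = k0 tp/3`, `gamma2_0 = F0 tp/(0.5 x(tp))`, plus fixed
#' multiplicative jitters of that guess.
#'
#' @param pulse a [pulse_response()] with at least 10 samples spanning both
#'   the loading and the relaxation branch.
#' @return An object of class `jeffreys_fit`: `params` ([jeffreys_params()]),
#'   `residual_norm`, `fitted`, and `recovery` (the fitted-parameter recovery
#'   fraction at `tp`).
#' @export
fit_jeffreys <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_response"))
  t <- pulse$times; x <- pulse$displacement
  if (length(t) < 10L) stop_invalid("need at least 10 samples")
  if (max(t) <= pulse$tp)
    stop_invalid("pulse must include samples after tp (relaxation branch)")
  xtp <- approx(t, x, xout = pulse$tp, rule = 2)$y
  if (!is.finite(xtp) || xtp <= 0 || max(abs(x)) < 1e-12)
    stop_fit_failure("degenerate pulse: no positive displacement at tp")
  F0 <- pulse$F0; tp <- pulse$tp
  k0 <- F0 / xtp
  p0 <- c(k = k0, gamma1 = k0 * tp / 3, gamma2 = F0 * tp / (0.5 * xtp))
  starts <- list(p0, p0 * c(0.3, 3, 0.5), p0 * c(3, 0.3, 2))
  resid_fn <- function(p) {
    pr <- jeffreys_params(p[1], p[2], p[3])
    jeffreys_displacement(pr, F0, tp, t) - x
  }
  fit <- lm_multistart(resid_fn, starts, lower = rep(1e-8, 3),
                       upper = rep(Inf, 3), what = "Jeffreys")
  par <- jeffreys_params(fit$par[1], fit$par[2], fit$par[3])
  structure(list(params = par,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 fitted = jeffreys_displacement(par, F0, tp, t),
                 recovery = jeffreys_recovery(par, tp),
                 info = fit$info),
            class = "jeffreys_fit")
}

#' @export
print.jeffreys_fit <- function(x, ...) {
  cat("Jeffreys pulse fit\n")
  print(x$params)
  cat(sprintf("  recovery a = %.3f, residual norm = %.3g um\n",
              x$recovery, x$residual_norm))
  invisible(x)
}
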