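#' Complex-modulus spectrum
#'
#' A sampled complex shear modulus: storage modulus G' and loss modulus G''
#' on a strictly increasing positive frequency grid, with a phase or
#' treatment label. Frequencies are stored in Hz; every formula that uses
#' angular frequency converts internally via `omega = 2 pi f`.
#'
#' @param frequency_hz frequencies (Hz), strictly increasing, positive.
#' @param g_prime storage modulus G' (Pa).
#' @param g_double_prime loss modulus G'' (Pa), non-negative.
#' @param label phase or treatment tag (e.g. `"interphase"`, `"M-phase"`).
#' @return An object of class `modulus_spectrum` (also a data.frame).
#' @export
modulus_spectrum <- function(frequency_hz, g_prime, g_double_prime,
                             label = "") {
  if (any(frequency_hz <= 0)) stop_invalid("frequencies must be positive")
  check_increasing(frequency_hz, "frequency_hz")
  n <- length(frequency_hz)
  if (length(g_prime) != n || length(g_double_prime) != n)
    stop_invalid("G' and G'' must match the frequency grid")
  structure(data.frame(frequency_hz = frequency_hz, g_prime = g_prime,
                       g_double_prime = g_double_prime,
                       label = rep(label, length.out = n)),
            class = c("modulus_spectrum", "data.frame"))
}

#' Fractional Kelvin--Voigt parameters
#'
#' Power-law rheology `G*(omega) = c_alpha (i omega)^alpha +
#' c_beta (i omega)^beta` with `0 <= alpha <= beta <= 1`: the alpha branch
#' dominates at low frequency (nearly elastic for small alpha), the beta
#' branch at high frequency (nearly viscous for beta near 1).
#'
#' @param c_alpha prefactor of the low-exponent branch (Pa s^alpha), positive.
#' @param alpha low exponent, in \[0, 1\].
#' @param c_beta prefactor of the high-exponent branch (Pa s^beta), positive.
#' @param beta high exponent, in \[alpha, 1\].
#' @return An object of class `fractional_kv_params`.
#' @export
fractional_kv_params <- function(c_alpha, alpha, c_beta, beta) {
  check_positive(c_alpha, "c_alpha")
  check_positive(c_beta, "c_beta")
  if (alpha < 0 || beta > 1 || alpha > beta)
    stop_invalid("need 0 <= alpha <= beta <= 1")
  structure(list(c_alpha = c_alpha, alpha = alpha,
                 c_beta = c_beta, beta = beta),
            class = "fractional_kv_params")
}

#' @export
print.fractional_kv_params <- function(x, ...) {
  cat(sprintf(
    "Fractional Kelvin-Voigt: c_alpha = %.4g Pa s^%.3g, c_beta = %.4g Pa s^%.3g\n",
    x$c_alpha, x$alpha, x$c_beta, x$beta))
  invisible(x)
}

#' Fractional Kelvin--Voigt complex modulus
#'
#' Evaluates `G*(omega) = c_alpha (i omega)^alpha + c_beta (i omega)^beta`,
#' i.e. `G' = c_alpha omega^alpha cos(pi alpha/2) + c_beta omega^beta
#' cos(pi beta/2)` and the analogous sine form for `G''`.
#'
#' @param params a [fractional_kv_params()] object.
#' @param omega angular frequency (rad/s), positive; vectorised.
#' @return a list with components `g_prime` and `g_double_prime` (Pa).
#' @export
fractional_kv_modulus <- function(params, omega) {
  stopifnot(inherits(params, "fractional_kv_params"))
  if (any(omega <= 0)) stop_invalid("omega must be positive")
  a <- params$alpha; b <- params$beta
  gp <- params$c_alpha * omega^a * cos(pi * a / 2) +
    params$c_beta * omega^b * cos(pi * b / 2)
  gpp <- params$c_alpha * omega^a * sin(pi * a / 2) +
    params$c_beta * omega^b * sin(pi * b / 2)
  list(g_prime = gp, g_double_prime = gpp)
}

#' Fit the fractional Kelvin--Voigt model to a modulus spectrum
#'
#' Joint least squares on `log G'` and `log G''` with equal weight (the
#' measured spectra span 3.5 decades of frequency, so fitting in log space
#' keeps the decades balanced). Deterministic multi-start over a small set
#' of exponent pairs; the exponents are constrained to \[0, 1\] and the
#' branches are sorted so `alpha <= beta` on output.
#'
#' @param spectrum a [modulus_spectrum()] with at least 4 frequencies
#'   spanning at least one decade.
#' @return An object of class `fractional_kv_fit` with fields `params`
#'   ([fractional_kv_params()]) and `residual_norm` (log-space).
#' @export
fit_fractional_kv <- function(spectrum) {
  stopifnot(inherits(spectrum, "modulus_spectrum"))
  f <- spectrum$frequency_hz
  if (length(f) < 4L) stop_invalid("need at least 4 frequencies")
  if (max(f) / min(f) < 10) stop_invalid("frequencies must span >= 1 decade")
  w <- 2 * pi * f
  gp <- spectrum$g_prime; gpp <- spectrum$g_double_prime
  if (any(gp <= 0) || any(gpp <= 0))
    stop_invalid("log-space fit needs positive G' and G''")
  obs <- c(log(gp), log(gpp))
  resid_fn <- function(p) {
    pr <- tryCatch(fractional_kv_params(exp(p[1]), min(max(p[2], 0), 1),
                                        exp(p[3]), min(max(p[4], 0), 1)),
                   error = function(e) NULL)
    if (is.null(pr)) return(rep(1e6, length(obs)))
    m <- fractional_kv_modulus(pr, w)
    pred <- c(m$g_prime, m$g_double_prime)
    if (any(pred <= 0)) return(rep(1e6, length(obs)))
    log(pred) - obs
  }
  # amplitude guesses from the spectrum end points
  ca0 <- gp[1] / max(w[1]^0.1, 1e-12)
  cb0 <- gpp[length(w)] / w[length(w)]^0.9
  starts <- list(c(log(ca0), 0.1, log(cb0), 0.9),
                 c(log(ca0), 0.3, log(cb0), 0.7),
                 c(log(gp[1]), 0.05, log(cb0), 0.95),
                 c(log(ca0), 0.2, log(cb0), 1.0))
  fit <- lm_multistart(resid_fn, starts,
                       lower = c(-Inf, 0, -Inf, 0),
                       upper = c(Inf, 1, Inf, 1),
                       what = "fractional KV")
  p <- fit$par
  br <- list(c(exp(p[1]), p[2]), c(exp(p[3]), p[4]))
  if (br[[1]][2] > br[[2]][2]) br <- rev(br)   # the model is branch-symmetric
  params <- fractional_kv_params(br[[1]][1], br[[1]][2],
                                 br[[2]][1], br[[2]][2])
  structure(list(params = params,
                 residual_norm = sqrt(sum(fit$fvec^2))),
            class = "fractional_kv_fit")
}

#' @export
print.fractional_kv_fit <- function(x, ...) {
  cat("Fractional Kelvin-Voigt spectrum fit\n")
  print(x$params)
  cat(sprintf("  log-space residual norm = %.3g\n", x$residual_norm))
  invisible(x)
}

#' Bootstrapped low-frequency fold change between two conditions
#'
#' Compares the magnitude of G' (and G'') between two conditions at low
#' frequency: measurements are resampled with replacement within each
#' condition, the mean spectrum per condition is formed, the A/B ratio is
#' averaged over frequencies in `[f_lo, f_hi]`, and this is repeated
#' `n_boot` times to give a mean fold change with a 95 percent percentile
#' interval for each modulus.
#'
#' @param spec_a,spec_b a single [modulus_spectrum()] or a list of replicate
#'   spectra per condition (all on the same frequency grid).
#' @param f_lo,f_hi low-frequency averaging window (Hz); default 0.5--16 Hz.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed (required for reproducible intervals).
#' @return A list with elements `g_prime` and `g_double_prime`, each a list
#'   `(mean, ci)` with `ci` the 2.5/97.5 percentiles, plus `n_freq` used.
#' @export
low_freq_fold_change <- function(spec_a, spec_b, f_lo = 0.5, f_hi = 16,
                                 n_boot = 1000, seed) {
  as_list <- function(s) if (inherits(s, "modulus_spectrum")) list(s) else s
  la <- as_list(spec_a); lb <- as_list(spec_b)
  f <- la[[1]]$frequency_hz
  for (s in c(la, lb))
    if (!isTRUE(all.equal(s$frequency_hz, f)))
      stop_invalid("all spectra must share one frequency grid")
  sel <- which(f >= f_lo & f <= f_hi)
  if (length(sel) == 0L) stop_invalid("empty frequency window")
  mat <- function(l, col) vapply(l, function(s) s[[col]][sel],
                                 numeric(length(sel)))  # freq x replicate
  boot_one <- function(ma, mb) {
    r <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      ia <- sample.int(ncol(ma), ncol(ma), replace = TRUE)
      ib <- sample.int(ncol(mb), ncol(mb), replace = TRUE)
      r[i] <- mean(rowMeans(ma[, ia, drop = FALSE]) /
                     rowMeans(mb[, ib, drop = FALSE]))
    }
    list(mean = mean(r),
         ci = unname(quantile(r, c(0.025, 0.975))))
  }
  with_seed(seed, {
    list(g_prime = boot_one(mat(la, "g_prime"), mat(lb, "g_prime")),
         g_double_prime = boot_one(mat(la, "g_double_prime"),
                                   mat(lb, "g_double_prime")),
         n_freq = length(sel))
  })
}
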