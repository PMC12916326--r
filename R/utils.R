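# internal helpers shared across modules

stop_invalid <- function(...) {
  stop(structure(class = c("bandratchet_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_fit_failure <- function(msg, best = NULL) {
  stop(structure(class = c("bandratchet_fit_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1), best = best)))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a single finite positive number")
  invisible(x)
}

check_increasing <- function(t, name = "times") {
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_invalid(name, " must be strictly increasing")
  invisible(t)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# closed-form least-squares slope (and intercept, slope SE); avoids lm()
# overhead in hot loops and doubles as the independent slope oracle's target
ls_slope <- function(t, y) {
  n <- length(t)
  if (n < 2L) stop_invalid("need at least 2 samples for a slope fit")
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  if (sxx == 0) stop_invalid("degenerate abscissa for slope fit")
  b <- sum((t - tm) * (y - ym)) / sxx
  a <- ym - b * tm
  res <- y - a - b * t
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = b, intercept = a, se = se, residuals = res)
}

# Levenberg-Marquardt with deterministic multi-start; returns best nls.lm fit
lm_multistart <- function(resid_fn, starts, lower, upper,
                          what = "model") {
  best <- NULL; best_ss <- Inf
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) { best <- fit; best_ss <- ss }
  }
  if (is.null(best))
    stop_fit_failure(paste0(what, " fit failed to converge from all starts"))
  best
}
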