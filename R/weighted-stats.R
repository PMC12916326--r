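#' Weighted Welch (unequal-variance) t-test
#'
#' Two-sided Welch t-test on embryo-level values with per-embryo weights.
#' Within each group the weights are normalised to sum to the number of
#' embryos (weight = tracks per embryo / total tracks x number of embryos),
#' so with equal weights the test reduces exactly to the ordinary Welch
#' test. Weighted means and variances use
#' `m = sum(w x)/sum(w)` and `s^2 = sum(w (x - m)^2)/(sum(w) - 1)`, with
#' standard errors `s^2/n` and Welch--Satterthwaite degrees of freedom.
#'
#' @param x,y embryo-level values per group (>= 2 each).
#' @param wx,wy positive weights (e.g. tracks per embryo); default equal.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
weighted_welch_ttest <- function(x, y, wx = rep(1, length(x)),
                                 wy = rep(1, length(y))) {
  if (length(x) < 2L || length(y) < 2L)
    stop_invalid("need at least 2 embryos per group")
  if (any(wx <= 0) || any(wy <= 0)) stop_invalid("weights must be positive")
  one <- function(v, w) {
    n <- length(v)
    w <- w / sum(w) * n
    m <- sum(w * v) / n
    s2 <- sum(w * (v - m)^2) / (n - 1)
    list(n = n, m = m, se2 = s2 / n)
  }
  a <- one(x, wx); b <- one(y, wy)
  denom <- a$se2 + b$se2
  if (denom == 0) {
    t_stat <- if (a$m == b$m) 0 else sign(a$m - b$m) * Inf
    df <- a$n + b$n - 2
  } else {
    t_stat <- (a$m - b$m) / sqrt(denom)
    df <- denom^2 / (a$se2^2 / (a$n - 1) + b$se2^2 / (b$n - 1))
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, mean_x = a$m, mean_y = b$m)
}

#' Weighted bootstrap of a group mean
#'
#' Resamples embryos with replacement with probability proportional to
#' their weights, takes the mean of each resample, and repeats `n_boot`
#' times; reports the bootstrap mean and the 2.5/97.5 percentile interval.
#' Deterministic under a fixed seed.
#'
#' @param values embryo-level values.
#' @param weights positive weights (tracks per embryo); default equal.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed (required).
#' @return list with `mean`, `ci` (length 2), `replicates`.
#' @export
weighted_bootstrap_mean <- function(values, weights = rep(1, length(values)),
                                    n_boot = 1000, seed) {
  if (length(values) == 0L) stop_invalid("values must be non-empty")
  if (any(weights <= 0)) stop_invalid("weights must be positive")
  n <- length(values)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i)
      mean(values[sample.int(n, n, replace = TRUE, prob = weights)]),
      numeric(1))
    list(mean = mean(reps),
         ci = unname(quantile(reps, c(0.025, 0.975))),
         replicates = reps)
  })
}
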