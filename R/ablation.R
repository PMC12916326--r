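#' Laser-ablation recoil trace
#'
#' Post-cut recoil of the severed band ends: time since the cut (the frames
#' during which the sample was still moving with the cutting stage are
#' assumed cropped, so the first frame is t = 0) and the recoil distance,
#' optionally with the actin grey value measured between the cut ends and
#' its pre-cut reference.
#'
#' @param times times since the cut (s), starting at 0, strictly increasing.
#' @param recoil recoil distance (um), non-negative.
#' @param grey_value optional grey-value series between the cut ends.
#' @param grey_reference optional positive pre-cut reference grey value.
#' @return An object of class `recoil_trace`.
#' @export
recoil_trace <- function(times, recoil, grey_value = NULL,
                         grey_reference = NULL) {
  check_increasing(times)
  if (times[1] < 0) stop_invalid("times must start at or after 0")
  if (length(recoil) != length(times))
    stop_invalid("recoil must match times")
  if (any(recoil < 0)) stop_invalid("recoil distances must be non-negative")
  if (!is.null(grey_reference)) check_positive(grey_reference, "grey_reference")
  structure(list(times = times, recoil = recoil, grey_value = grey_value,
                 grey_reference = grey_reference),
            class = "recoil_trace")
}

#' Fit the recoil curve and extract the initial recoil velocity
#'
#' Least-squares fit of `y = A (1 - exp(-x/x0)) + c` to a recoil trace; the
#' initial recoil velocity `v0 = A/x0` (um/s) is the tension proxy reported
#' for ablation experiments. A trace with no rise (constant within noise)
#' raises a fit-failure error.
#'
#' @param trace a [recoil_trace()] with at least 6 samples.
#' @return An object of class `recoil_fit`: `A` (plateau, um), `x0`
#'   (timescale, s), `c` (offset, um), `v0` (= A/x0, um/s),
#'   `residual_norm`.
#' @export
fit_recoil <- function(trace) {
  stopifnot(inherits(trace, "recoil_trace"))
  t <- trace$times; y <- trace$recoil
  if (length(t) < 6L) stop_invalid("need at least 6 samples")
  rng <- max(y) - min(y)
  if (rng <= 1e-9 * max(abs(y), 1))
    stop_fit_failure("degenerate recoil trace: no rise to fit (A ~ 0)")
  A0 <- max(y) - y[1]
  half <- y[1] + A0 / 2
  x0_0 <- t[which(y >= half)[1]]
  if (!is.finite(x0_0) || x0_0 <= 0) x0_0 <- max(t) / 4
  resid_fn <- function(p) p[1] * (1 - exp(-t / p[2])) + p[3] - y
  starts <- list(c(A0, x0_0, y[1]), c(A0, x0_0 / 3, y[1]),
                 c(1.5 * A0, 3 * x0_0, y[1]))
  fit <- lm_multistart(resid_fn, starts,
                       lower = c(1e-12, 1e-9, -Inf), upper = rep(Inf, 3),
                       what = "recoil")
  p <- fit$par
  structure(list(A = p[1], x0 = p[2], c = p[3], v0 = p[1] / p[2],
                 residual_norm = sqrt(sum(fit$fvec^2))),
            class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat(sprintf(
    "Recoil fit: A = %.3g um, x0 = %.3g s, c = %.3g um; v0 = A/x0 = %.3g um/s\n",
    x$A, x$x0, x$c, x$v0))
  invisible(x)
}

#' Normalise a recoil trace and its healing grey value
#'
#' Min--max normalises the recoil length to \[0, 1\] and divides the grey
#' value between the cut ends by the pre-cut reference, putting recoil and
#' band healing on comparable scales (healing that overtakes the recoil
#' shows up as the two normalised curves crossing).
#'
#' @param trace a [recoil_trace()] with non-constant recoil (and, for the
#'   grey-value part, `grey_value` and `grey_reference` set).
#' @return list with `times`, `recoil_norm`, and `grey_norm` (NULL when no
#'   grey value is present).
#' @export
normalize_recoil_and_healing <- function(trace) {
  stopifnot(inherits(trace, "recoil_trace"))
  r <- trace$recoil
  rng <- max(r) - min(r)
  if (rng <= 0) stop_invalid("constant recoil cannot be normalized")
  grey <- NULL
  if (!is.null(trace$grey_value)) {
    if (is.null(trace$grey_reference))
      stop_invalid("grey_value present but grey_reference missing")
    grey <- trace$grey_value / trace$grey_reference
  }
  list(times = trace$times, recoil_norm = (r - min(r)) / rng,
       grey_norm = grey)
}

#' Velocity-field series (band-aligned frame)
#'
#' A series of 2D velocity fields on a fixed grid, aligned so the
#' contractile band runs along the y axis. Velocities in um/min.
#'
#' @param x,y grid coordinates (um).
#' @param times frame times (min).
#' @param vx,vy arrays of dim `(length(y), length(x), length(times))`.
#' @return An object of class `velocity_field_series`.
#' @export
velocity_field_series <- function(x, y, times, vx, vy) {
  dims <- c(length(y), length(x), length(times))
  if (!identical(dim(vx), as.integer(dims)) ||
      !identical(dim(vy), as.integer(dims)))
    stop_invalid("vx and vy must have dim (n_y, n_x, n_frames)")
  structure(list(x = x, y = y, times = times, vx = vx, vy = vy),
            class = "velocity_field_series")
}

#' Average the flow field within a strip around the band axis
#'
#' Averages the velocity components over the grid columns with
#' `|x| <= half_width` (25 um by default), giving the along-band average
#' profile `v_bar(y, t)` used for band-end detection.
#'
#' @param field a [velocity_field_series()].
#' @param half_width strip half width (um).
#' @return list with `y`, `times`, `vy_bar` and `vx_bar` (matrices
#'   `n_y x n_frames`).
#' @export
band_axis_average <- function(field, half_width = 25) {
  stopifnot(inherits(field, "velocity_field_series"))
  cols <- which(abs(field$x) <= half_width)
  if (length(cols) == 0L)
    stop_invalid("no grid columns within the averaging strip")
  nt <- length(field$times)
  vy_bar <- vapply(seq_len(nt), function(k)
    rowMeans(field$vy[, cols, k, drop = FALSE]), numeric(length(field$y)))
  vx_bar <- vapply(seq_len(nt), function(k)
    rowMeans(field$vx[, cols, k, drop = FALSE]), numeric(length(field$y)))
  list(y = field$y, times = field$times, vy_bar = vy_bar, vx_bar = vx_bar)
}

#' Detect the band ends from an averaged flow profile
#'
#' Per frame, the band ends are the y positions of the highest positive and
#' highest negative along-band speed in `v_bar(y, t)`. Ties are broken
#' toward the previous frame's end position (first frame: toward larger
#' |y|) to keep the end trajectories continuous.
#'
#' @param profile output of [band_axis_average()].
#' @param tie_tol relative tolerance for treating speeds as tied.
#' @return An object of class `band_end_series`: data.frame with `time`,
#'   `y_pos`, `flow_pos`, `y_neg`, `flow_neg` (positions um, flows um/min).
#' @export
detect_band_ends <- function(profile, tie_tol = 1e-9) {
  y <- profile$y; nt <- length(profile$times)
  pick <- function(v, prev_y, maximize) {
    s <- if (maximize) v else -v
    m <- max(s)
    if (!is.finite(m) || diff(range(v)) == 0)
      stop_invalid("profile is constant in a frame; ends undefined")
    cand <- which(s >= m - tie_tol * max(abs(m), 1))
    if (length(cand) > 1L) {
      if (is.na(prev_y)) cand <- cand[which.max(abs(y[cand]))]
      else cand <- cand[which.min(abs(y[cand] - prev_y))]
    }
    cand[1]
  }
  y_pos <- numeric(nt); y_neg <- numeric(nt)
  f_pos <- numeric(nt); f_neg <- numeric(nt)
  prev_p <- NA_real_; prev_n <- NA_real_
  for (k in seq_len(nt)) {
    v <- profile$vy_bar[, k]
    ip <- pick(v, prev_p, TRUE)
    im <- pick(v, prev_n, FALSE)
    y_pos[k] <- y[ip]; f_pos[k] <- v[ip]
    y_neg[k] <- y[im]; f_neg[k] <- v[im]
    prev_p <- y_pos[k]; prev_n <- y_neg[k]
  }
  structure(data.frame(time = profile$times, y_pos = y_pos, flow_pos = f_pos,
                       y_neg = y_neg, flow_neg = f_neg),
            class = c("band_end_series", "data.frame"))
}

#' Band-end kinematics: end velocity, flow at the ends, growth speed
#'
#' Decomposes the motion of the band ends: the end velocity is the linear
#' slope of each end trajectory, the contractile flow speed is the mean
#' flow recorded at the end positions, and the band growth speed is the
#' difference of the two. All three are oriented outward (positive =
#' lengthening), with each end's outward direction taken from the sign of
#' its mean position along the band axis; growth = end velocity - flow
#' holds exactly by construction.
#'
#' @param series a [detect_band_ends()] result with >= 2 frames.
#' @return list with `end_velocity`, `flow_velocity`, `growth_speed`
#'   (um/min, outward-positive, averaged over the two ends) and the per-end
#'   breakdown `per_end`.
#' @export
end_kinematics <- function(series) {
  if (nrow(series) < 2L) stop_invalid("need at least 2 frames")
  v_pos <- ls_slope(series$time, series$y_pos)$slope
  v_neg <- ls_slope(series$time, series$y_neg)$slope
  # outward orientation per end, from where the end actually sits
  s_pos <- if (mean(series$y_pos) >= 0) 1 else -1
  s_neg <- if (mean(series$y_neg) >= 0) 1 else -1
  ends <- data.frame(
    end = c("pos", "neg"),
    end_velocity = c(s_pos * v_pos, s_neg * v_neg),
    flow_velocity = c(s_pos * mean(series$flow_pos),
                      s_neg * mean(series$flow_neg)))
  ends$growth_speed <- ends$end_velocity - ends$flow_velocity
  list(end_velocity = mean(ends$end_velocity),
       flow_velocity = mean(ends$flow_velocity),
       growth_speed = mean(ends$growth_speed),
       per_end = ends)
}

#' Mean band retraction velocity from manual end tracks
#'
#' Normalises each end-position track by its lowest value (alignment),
#' fits each track with a line, and reports the arithmetic mean of the
#' slopes together with the root mean square error of the fits.
#'
#' @param tracks list of data.frames with columns `time` (min) and
#'   `position` (um), one per embryo; >= 2 points each.
#' @return list with `mean_slope` (um/min), `rmse`, `slopes`.
#' @export
retraction_velocity <- function(tracks) {
  slopes <- numeric(length(tracks)); resids <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (nrow(tr) < 2L) stop_invalid("each track needs at least 2 points")
    pos <- tr$position - min(tr$position)
    f <- ls_slope(tr$time, pos)
    slopes[i] <- f$slope
    resids[[i]] <- f$residuals
  }
  list(mean_slope = mean(slopes),
       rmse = sqrt(mean(unlist(resids)^2)),
       slopes = slopes)
}

#' Phase-windowed ingression slopes
#'
#' Least-squares slope (with its standard error) of a mean ingression
#' series within each named, non-overlapping time window — the ingression
#' velocity per cell-cycle phase.
#'
#' @param times times (min).
#' @param ingression mean ingression series (um).
#' @param windows named list of `c(t0, t1)` windows (min).
#' @return data.frame with `window`, `slope` (um/min), `se`, `n`.
#' @export
ingression_slope <- function(times, ingression, windows) {
  ws <- do.call(rbind, windows)
  if (nrow(ws) > 1L) {
    o <- order(ws[, 1])
    if (any(ws[o, 1][-1] < ws[o, 2][-nrow(ws)]))
      stop_invalid("windows must be non-overlapping")
  }
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    sel <- times >= w[1] & times <= w[2]
    if (sum(sel) < 2L)
      stop_invalid("window ", names(windows)[i] %||% i,
                   " contains fewer than 2 samples")
    f <- ls_slope(times[sel], ingression[sel])
    data.frame(window = names(windows)[i] %||% as.character(i),
               slope = f$slope, se = f$se, n = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
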