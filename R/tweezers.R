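#' Bead track record
#'
#' One bead trajectory from a magnetic-tweezers experiment: 2D positions
#' over time with the per-sample distance to the magnetic tip, plus
#' embryo/phase/condition metadata. Positions in um, time in seconds.
#'
#' @param track_id,embryo_id identifiers.
#' @param times sample times (s), strictly increasing.
#' @param positions n x 2 matrix of positions (um).
#' @param distance_to_tip distance to the magnet tip per sample (um), > 0;
#'   computed from `tip` if omitted.
#' @param phase cell-cycle phase or treatment label.
#' @param condition condition tag.
#' @param tip optional c(x, y) tip position (um).
#' @return An object of class `bead_track`.
#' @export
bead_track <- function(track_id, embryo_id, times, positions,
                       distance_to_tip = NULL, phase = "interphase",
                       condition = "control", tip = NULL) {
  check_increasing(times)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(times) || ncol(positions) != 2L)
    stop_invalid("positions must be an n x 2 matrix matching times")
  if (is.null(distance_to_tip)) {
    if (is.null(tip)) stop_invalid("need distance_to_tip or tip position")
    distance_to_tip <- sqrt((positions[, 1] - tip[1])^2 +
                              (positions[, 2] - tip[2])^2)
  }
  if (any(distance_to_tip <= 0)) stop_invalid("distance_to_tip must be positive")
  structure(list(track_id = track_id, embryo_id = embryo_id, times = times,
                 positions = positions, distance_to_tip = distance_to_tip,
                 phase = phase, condition = condition, tip = tip),
            class = "bead_track")
}

#' Stokes-drag force on a bead (pN)
#'
#' `f = 6 pi eta R v` with viscosity in Pa s, radius in um and speed in
#' um/s; the result is numerically in pN (the 1e-12 factors cancel).
#'
#' @param velocity bead speed (um/s).
#' @param viscosity medium viscosity (Pa s).
#' @param bead_radius bead radius (um).
#' @return force in pN.
#' @export
stokes_force <- function(velocity, viscosity, bead_radius) {
  6 * pi * viscosity * bead_radius * velocity
}

#' Force--distance calibration of the magnetic tweezers
#'
#' Calibrates the tip from bead tracks recorded in glycerol: each
#' inter-frame velocity gives an instantaneous Stokes-drag force
#' `f = 6 pi eta R v`, paired with the mid-interval distance to the tip,
#' and the (distance, force) cloud is fitted with the double exponential
#' `f(x) = a1 exp(-k1 x) + a2 exp(-k2 x)` (amplitudes constrained
#' non-negative, so the fitted law is monotone decreasing).
#'
#' @param tracks list of [bead_track()] recorded in glycerol.
#' @param viscosity calibration-medium viscosity (Pa s); glycerol at 20 C
#'   is 1.412 Pa s.
#' @param bead_radius bead radius (um); the ferromagnetic beads are 1.4 um.
#' @param min_speed interframe speeds below this (um/s) are dropped as
#'   stationary.
#' @return An object of class `force_calibration`: fields `a1`, `k1`, `a2`,
#'   `k2`, `n_samples`, `residual_norm`.
#' @export
fit_force_calibration <- function(tracks, viscosity = 1.412,
                                  bead_radius = 1.4, min_speed = 1e-4) {
  check_positive(viscosity, "viscosity")
  check_positive(bead_radius, "bead_radius")
  xs <- numeric(0); fs <- numeric(0)
  for (tr in tracks) {
    dt <- diff(tr$times)
    v <- sqrt(rowSums(diff(tr$positions)^2)) / dt
    d <- (head(tr$distance_to_tip, -1) + tail(tr$distance_to_tip, -1)) / 2
    ok <- v > min_speed
    xs <- c(xs, d[ok]); fs <- c(fs, stokes_force(v[ok], viscosity, bead_radius))
  }
  if (length(xs) < 10L)
    stop_invalid("need at least 10 usable (distance, velocity) samples")
  # single-exponential seed, then split the rate
  lf <- ls_slope(xs, log(pmax(fs, 1e-12)))
  k_one <- max(-lf$slope, 1e-6)
  a_one <- exp(lf$intercept)
  resid_fn <- function(p) p[1] * exp(-p[2] * xs) + p[3] * exp(-p[4] * xs) - fs
  starts <- list(c(0.8 * a_one, 2 * k_one, 0.2 * a_one, 0.5 * k_one),
                 c(a_one, k_one, 0.1 * a_one, 0.1 * k_one),
                 c(2 * a_one, 4 * k_one, 0.5 * a_one, k_one))
  fit <- lm_multistart(resid_fn, starts,
                       lower = c(0, 1e-9, 0, 1e-9), upper = rep(Inf, 4),
                       what = "force calibration")
  p <- fit$par
  if (p[2] < p[4]) p <- p[c(3, 4, 1, 2)]   # order: a1/k1 the steep branch
  structure(list(a1 = p[1], k1 = p[2], a2 = p[3], k2 = p[4],
                 n_samples = length(xs),
                 residual_norm = sqrt(sum(fit$fvec^2))),
            class = "force_calibration")
}

#' Predicted tip force at a distance
#'
#' @param calib a [fit_force_calibration()] object (or a list with fields
#'   `a1`, `k1`, `a2`, `k2`).
#' @param x distance to the tip (um); vectorised.
#' @return force (pN).
#' @export
predict_force <- function(calib, x) {
  calib$a1 * exp(-calib$k1 * x) + calib$a2 * exp(-calib$k2 * x)
}

#' @export
print.force_calibration <- function(x, ...) {
  cat(sprintf(
    "Tip force calibration: f(x) = %.4g exp(-%.4g x) + %.4g exp(-%.4g x) pN (x in um; n = %d)\n",
    x$a1, x$k1, x$a2, x$k2, x$n_samples))
  invisible(x)
}

#' Segment a bead track into force-pulse cycles
#'
#' Tiles the track with non-overlapping pulse cycles (`on_s` seconds of
#' force followed by `off_s` seconds of rest, the instrument schedule being
#' 5 s on / 15 s off) from the known schedule start; a trailing partial
#' cycle is dropped. A track shorter than one full cycle yields an empty
#' list, not an error.
#'
#' @param track a [bead_track()].
#' @param start_s time of the first pulse onset (s).
#' @param on_s,off_s pulse and rest durations (s).
#' @return list of windows, each `list(on_start, on_end, off_end, index)`.
#' @export
segment_pulses <- function(track, start_s = 0, on_s = 5, off_s = 15) {
  cycle <- on_s + off_s
  t_end <- max(track$times)
  n <- max(0L, floor((t_end - start_s) / cycle + 1e-9))
  lapply(seq_len(n), function(i) {
    on_start <- start_s + (i - 1) * cycle
    list(on_start = on_start, on_end = on_start + on_s,
         off_end = on_start + cycle, index = i)
  })
}

# scalar bead coordinate: displacement along the bead -> tip axis, so
# motion toward the tip (the force direction) is positive
tip_axis_coordinate <- function(track) {
  -track$distance_to_tip
}

#' Drift-correct one pulse cycle
#'
#' Cytoplasmic reorganisation produces slow spontaneous flows; the drift
#' velocity is measured as the linear slope of the tip-axis coordinate over
#' the last `fit_s` seconds of the relaxation period preceding the pulse
#' and subtracted as `v (t - on_start)` across the cycle. For the first
#' pulse (no preceding rest) the tail of its own following relaxation is
#' used and the measurement is flagged.
#'
#' @param track a [bead_track()].
#' @param window one window from [segment_pulses()].
#' @param fit_s length of the drift-fit window (s).
#' @return list with `times`, `displacement` (um, zeroed at pulse onset,
#'   drift-subtracted), `drift_velocity` (um/s), `first_pulse_flag`.
#' @export
drift_correct <- function(track, window, fit_s = 5) {
  s <- tip_axis_coordinate(track)
  t <- track$times
  if (window$index > 1L) {
    lo <- window$on_start - fit_s; hi <- window$on_start
    flag <- FALSE
  } else {
    lo <- window$off_end - fit_s; hi <- window$off_end
    flag <- TRUE
  }
  fit_sel <- t >= lo - 1e-9 & t <= hi + 1e-9
  if (sum(fit_sel) < 2L)
    stop_invalid("drift window contains fewer than 2 samples")
  v <- ls_slope(t[fit_sel], s[fit_sel])$slope
  sel <- t >= window$on_start - 1e-9 & t <= window$off_end + 1e-9
  tt <- t[sel]
  disp <- s[sel] - v * (tt - window$on_start)
  disp <- disp - disp[1]
  list(times = tt, displacement = disp, drift_velocity = v,
       first_pulse_flag = flag)
}

#' Summarise one drift-corrected pulse
#'
#' Computes the per-pulse summary statistics: total displacement (value at
#' the end of the pulse minus at its start), relaxation (end of pulse minus
#' end of the rest window), recovery = relaxation / displacement, the mean
#' force during the pulse, and the force-normalised displacement. Pulses
#' with non-positive displacement are flagged invalid (kept in the output
#' but excluded from averages downstream).
#'
#' @param corrected output of [drift_correct()].
#' @param force force during the cycle: a vector matching
#'   `corrected$times` or a single mean value (pN).
#' @param window the matching [segment_pulses()] window.
#' @return one-row data.frame (a `pulse_measurement`): `pulse`, `F0`,
#'   `displacement`, `normalized_displacement`, `recovery`,
#'   `drift_velocity`, `valid`, `first_pulse_flag`.
#' @export
summarize_pulse <- function(corrected, force, window) {
  t <- corrected$times; x <- corrected$displacement
  on <- t <= window$on_end + 1e-9
  F0 <- if (length(force) == 1L) force else mean(force[on])
  if (!is.finite(F0) || F0 <= 0) stop_invalid("mean pulse force must be positive")
  x_on_end <- x[max(which(on))]
  x_off_end <- x[length(x)]
  displacement <- x_on_end - x[1]
  relaxation <- x_on_end - x_off_end
  valid <- is.finite(displacement) && displacement > 0
  data.frame(pulse = window$index, F0 = F0, displacement = displacement,
             normalized_displacement = displacement / F0,
             recovery = if (valid) relaxation / displacement else NA_real_,
             drift_velocity = corrected$drift_velocity,
             valid = valid, first_pulse_flag = corrected$first_pulse_flag)
}

#' Per-pulse measurements for a whole track
#'
#' Convenience pipeline: segment, drift-correct and summarise every full
#' pulse cycle of a track, inferring the force from the calibration law and
#' the bead-tip distance during each pulse.
#'
#' @param track a [bead_track()].
#' @param calib a [fit_force_calibration()] (or compatible list).
#' @param start_s,on_s,off_s schedule, as in [segment_pulses()].
#' @return data.frame of pulse measurements with track/embryo/phase columns.
#' @export
analyze_track <- function(track, calib, start_s = 0, on_s = 5, off_s = 15) {
  wins <- segment_pulses(track, start_s, on_s, off_s)
  if (length(wins) == 0L) return(NULL)
  rows <- lapply(wins, function(w) {
    corr <- drift_correct(track, w)
    on <- corr$times <= w$on_end + 1e-9
    sel <- track$times >= w$on_start - 1e-9 & track$times <= w$off_end + 1e-9
    F_t <- predict_force(calib, track$distance_to_tip[sel])
    m <- summarize_pulse(corr, F_t[on], w)
    m
  })
  out <- do.call(rbind, rows)
  out$track_id <- track$track_id
  out$embryo_id <- track$embryo_id
  out$phase <- track$phase
  out$condition <- track$condition
  out
}

#' Restrict pulse measurements to a force range
#'
#' Keeps measurements with `lo <= F0 <= hi` (boundaries inclusive). The
#' comparison force range of interest is 20--60 pN, where both phases are
#' well sampled.
#'
#' @param measurements data.frame of pulse measurements (needs `F0`).
#' @param lo,hi force bounds (pN).
#' @return the filtered data.frame.
#' @export
filter_force_range <- function(measurements, lo = 20, hi = 60) {
  measurements[measurements$F0 >= lo & measurements$F0 <= hi, , drop = FALSE]
}

#' Embryo-level averages of pulse measurements
#'
#' Averages the per-pulse statistics per embryo and phase, counting the
#' distinct tracks per group; the track counts are the weight basis for the
#' weighted statistics ([weighted_welch_ttest()],
#' [weighted_bootstrap_mean()]). Invalid pulses are excluded.
#'
#' @param measurements data.frame from [analyze_track()] rows.
#' @return data.frame with one row per (embryo, phase): `embryo_id`,
#'   `phase`, `n_tracks`, `n_pulses`, `mean_normalized_displacement`,
#'   `mean_recovery`.
#' @export
embryo_average <- function(measurements) {
  m <- measurements[measurements$valid, , drop = FALSE]
  if (nrow(m) == 0L) stop_invalid("no valid measurements to average")
  key <- interaction(m$embryo_id, m$phase, drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    data.frame(embryo_id = g$embryo_id[1], phase = g$phase[1],
               n_tracks = length(unique(g$track_id)),
               n_pulses = nrow(g),
               mean_normalized_displacement = mean(g$normalized_displacement),
               mean_recovery = mean(g$recovery, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average pulse curves on a common time grid
#'
#' Pointwise mean of drift-corrected pulse displacement curves, linearly
#' resampled onto a common uniform grid (flagged when resampling was
#' needed). Used to form the per-embryo and per-phase averaged response
#' that the Jeffreys model is fitted to.
#'
#' @param curves list of [drift_correct()] outputs.
#' @param grid_dt grid spacing (s); defaults to the median sampling step.
#' @return list with `times` (from 0), `displacement` (mean curve),
#'   `n_curves`, `resampled`.
#' @export
average_pulse_curves <- function(curves, grid_dt = NULL) {
  if (length(curves) == 0L) stop_invalid("no curves to average")
  rel <- lapply(curves, function(cv)
    list(t = cv$times - cv$times[1], x = cv$displacement))
  if (is.null(grid_dt))
    grid_dt <- median(unlist(lapply(rel, function(r) diff(r$t))))
  t_max <- min(vapply(rel, function(r) max(r$t), numeric(1)))
  grid <- seq(0, t_max, by = grid_dt)
  resampled <- !all(vapply(rel, function(r)
    isTRUE(all.equal(r$t, grid)), logical(1)))
  mat <- vapply(rel, function(r) approx(r$t, r$x, xout = grid)$y,
                numeric(length(grid)))
  list(times = grid, displacement = rowMeans(mat),
       n_curves = length(curves), resampled = resampled)
}
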