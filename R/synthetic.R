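#' Specification of a synthetic bead-pulse cohort
#'
#' Describes the cohort the bead-track generator emulates: the study
#' conditions are 8 embryos per phase with ~50 bead tracks each, 8
#' consecutive 5 s-on / 15 s-off force pulses per track, force inferred
#' from the tip calibration law at the bead's distance, additive Gaussian
#' position noise and a slow cytoplasmic drift.
#'
#' @param n_embryos embryos per phase.
#' @param tracks_per_embryo bead tracks per embryo.
#' @param pulses_per_track full pulse cycles per track.
#' @param phases named list of [jeffreys_params()], one per phase label.
#' @param calibration force-calibration truth (fields `a1`, `k1`, `a2`,
#'   `k2`).
#' @param on_s,off_s pulse schedule (s).
#' @param sample_dt sampling interval (s).
#' @param noise_sd additive position noise (um).
#' @param drift_sd s.d. of the per-track drift velocity (um/s).
#' @param dist_range range of bead--tip distances to draw from (um).
#' @param seed RNG seed (required).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_embryos = 8, tracks_per_embryo = 50,
                        pulses_per_track = 8,
                        phases = list(interphase = interphase_params(),
                                      "M-phase" = mphase_params()),
                        calibration = list(a1 = 800, k1 = 0.02,
                                           a2 = 120, k2 = 0.004),
                        on_s = 5, off_s = 15, sample_dt = 0.5,
                        noise_sd = 0.05, drift_sd = 0.01,
                        dist_range = c(150, 450), seed) {
  stopifnot(n_embryos >= 1, tracks_per_embryo >= 1, pulses_per_track >= 1)
  if (missing(seed)) stop_invalid("seed is required")
  structure(list(n_embryos = n_embryos, tracks_per_embryo = tracks_per_embryo,
                 pulses_per_track = pulses_per_track, phases = phases,
                 calibration = calibration, on_s = on_s, off_s = off_s,
                 sample_dt = sample_dt, noise_sd = noise_sd,
                 drift_sd = drift_sd, dist_range = dist_range, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic magnetic-tweezers bead cohort
#'
#' Each track is the Jeffreys-model response of its phase's material to the
#' pulse train (linear superposition of pulse responses, so viscous creep
#' accumulates across pulses), with the pulse force set by the calibration
#' law at the track's bead--tip distance, plus a per-track linear drift and
#' additive Gaussian noise. The bead moves along the bead--tip axis; the
#' tip sits at the origin.
#'
#' @param spec a [cohort_spec()].
#' @return list with `tracks` (list of [bead_track()]), `manifest`
#'   (data.frame: track_id, embryo_id, phase, condition, pulse schedule,
#'   distance, F0 truth), and `truth` (the generating parameters).
#' @export
gen_bead_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cycle <- spec$on_s + spec$off_s
  t_total <- spec$pulses_per_track * cycle
  times <- seq(0, t_total, by = spec$sample_dt)
  onsets <- (seq_len(spec$pulses_per_track) - 1) * cycle
  with_seed(spec$seed, {
    tracks <- list(); man <- list()
    for (ph in names(spec$phases)) {
      params <- spec$phases[[ph]]
      for (e in seq_len(spec$n_embryos)) {
        embryo_id <- sprintf("%s_e%02d", gsub("[^A-Za-z]", "", ph), e)
        for (b in seq_len(spec$tracks_per_embryo)) {
          d0 <- runif(1, spec$dist_range[1], spec$dist_range[2])
          F0 <- predict_force(spec$calibration, d0)
          drift_v <- rnorm(1, 0, spec$drift_sd)
          resp <- numeric(length(times))
          for (on in onsets) {
            tt <- times - on
            act <- tt > 0
            resp[act] <- resp[act] +
              jeffreys_displacement(params, F0, spec$on_s, tt[act])
          }
          s <- resp + drift_v * times +
            if (spec$noise_sd > 0) rnorm(length(times), 0, spec$noise_sd) else 0
          # bead on the +x axis, moving toward the tip at the origin
          posx <- d0 - s
          if (any(posx <= 0)) posx <- pmax(posx, 1e-6)
          track_id <- sprintf("%s_t%03d", embryo_id, b)
          tracks[[track_id]] <- bead_track(
            track_id, embryo_id, times, cbind(posx, 0),
            distance_to_tip = posx, phase = ph, condition = "control",
            tip = c(0, 0))
          man[[track_id]] <- data.frame(
            track_id = track_id, embryo_id = embryo_id, phase = ph,
            condition = "control", pulse_start_s = 0,
            pulse_on_s = spec$on_s, pulse_off_s = spec$off_s,
            n_pulses = spec$pulses_per_track,
            distance_um = d0, F0_pN = F0, drift_um_s = drift_v)
        }
      }
    }
    manifest <- do.call(rbind, man)
    rownames(manifest) <- NULL
    list(tracks = tracks, manifest = manifest,
         truth = list(phases = spec$phases, calibration = spec$calibration))
  })
}

#' Generate synthetic glycerol calibration tracks
#'
#' Beads released at assorted distances from the tip in a Newtonian
#' calibration fluid: the instantaneous velocity is `f(d) / (6 pi eta R)`
#' (Stokes drag), integrated toward the tip, with optional position noise.
#'
#' @param truth calibration truth (fields `a1`, `k1`, `a2`, `k2`).
#' @param viscosity fluid viscosity (Pa s); glycerol at 20 C is 1.412.
#' @param bead_radius bead radius (um).
#' @param n_tracks number of tracks.
#' @param duration_s track duration (s).
#' @param sample_dt sampling interval (s).
#' @param dist_range release-distance range (um).
#' @param noise_sd additive position noise (um).
#' @param seed RNG seed (required).
#' @return list of [bead_track()] objects.
#' @export
gen_glycerol_calibration <- function(truth, viscosity = 1.412,
                                     bead_radius = 1.4, n_tracks = 22,
                                     duration_s = 10, sample_dt = 0.2,
                                     dist_range = c(80, 400),
                                     noise_sd = 0, seed) {
  if (missing(seed)) stop_invalid("seed is required")
  mobility <- 1 / (6 * pi * viscosity * bead_radius)  # (um/s)/pN
  times <- seq(0, duration_s, by = sample_dt)
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      d0 <- runif(1, dist_range[1], dist_range[2])
      d <- numeric(length(times)); d[1] <- d0
      # midpoint integration of dd/dt = -mobility * f(d)
      for (k in seq_along(times)[-1]) {
        v1 <- mobility * predict_force(truth, d[k - 1])
        dm <- max(d[k - 1] - v1 * sample_dt / 2, 1e-3)
        v <- mobility * predict_force(truth, dm)
        d[k] <- max(d[k - 1] - v * sample_dt, 1e-3)
      }
      obs <- d + if (noise_sd > 0) rnorm(length(d), 0, noise_sd) else 0
      bead_track(sprintf("cal_%03d", i), "glycerol", times,
                 cbind(obs, 0), distance_to_tip = pmax(obs, 1e-3),
                 phase = "calibration", condition = "glycerol",
                 tip = c(0, 0))
    })
  })
}

#' Generate synthetic laser-ablation recoil traces
#'
#' Saturating-exponential recoils `A (1 - exp(-t/x0))` with per-trace
#' initial velocity `v0` drawn around a mean (so `A = v0 x0`), sampled at
#' the kymograph frame interval with additive noise.
#'
#' @param n number of traces.
#' @param v0_mean,v0_sd mean and s.d. of the initial recoil velocity
#'   (um/s); the interphase band scale is ~0.32 um/s.
#' @param x0 recoil timescale (s).
#' @param duration_s trace length (s).
#' @param dt frame interval (s); kymographs were recorded at 0.3 s.
#' @param noise_sd additive recoil noise (um).
#' @param seed RNG seed (required).
#' @return list with `traces` (list of [recoil_trace()]) and `truth`
#'   (data.frame of per-trace v0, A, x0).
#' @export
gen_recoil_traces <- function(n, v0_mean = 0.32, v0_sd = 0.1, x0 = 2,
                              duration_s = 10, dt = 0.3, noise_sd = 0.1,
                              seed) {
  if (missing(seed)) stop_invalid("seed is required")
  times <- seq(0, duration_s, by = dt)
  with_seed(seed, {
    v0 <- pmax(rnorm(n, v0_mean, v0_sd), 0.05 * v0_mean)
    traces <- lapply(seq_len(n), function(i) {
      y <- v0[i] * x0 * (1 - exp(-times / x0)) +
        if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
      recoil_trace(times, pmax(y, 0))
    })
    list(traces = traces,
         truth = data.frame(trace = seq_len(n), v0 = v0, A = v0 * x0,
                            x0 = x0))
  })
}

#' Generate synthetic complex-modulus spectra
#'
#' Replicate oscillatory-microrheology measurements per condition:
#' fractional Kelvin--Voigt spectra evaluated on a log-spaced frequency
#' grid with multiplicative log-normal noise.
#'
#' @param truth named list of [fractional_kv_params()], one per condition.
#' @param frequencies frequency grid (Hz); default 20 log-spaced points
#'   over the measured 0.5--2056 Hz range.
#' @param n_per_condition replicate measurements per condition.
#' @param noise_rel relative (multiplicative) noise level.
#' @param seed RNG seed (required).
#' @return named list (per condition) of lists of [modulus_spectrum()].
#' @export
gen_modulus_spectra <- function(truth,
                                frequencies = exp(seq(log(0.5), log(2056),
                                                      length.out = 20)),
                                n_per_condition = 12, noise_rel = 0.05,
                                seed) {
  if (missing(seed)) stop_invalid("seed is required")
  w <- 2 * pi * frequencies
  with_seed(seed, {
    lapply(truth, function(params) {
      m <- fractional_kv_modulus(params, w)
      lapply(seq_len(n_per_condition), function(i) {
        fac_p <- if (noise_rel > 0)
          exp(rnorm(length(w), 0, noise_rel)) else 1
        fac_pp <- if (noise_rel > 0)
          exp(rnorm(length(w), 0, noise_rel)) else 1
        modulus_spectrum(frequencies, m$g_prime * fac_p,
                         m$g_double_prime * fac_pp)
      })
    })
  })
}

#' Generate a synthetic PIV velocity-field series with two band ends
#'
#' Emulates the averaged flow around a retracting or growing band: two
#' Gaussian speed bumps of opposite sign centred at the moving end
#' positions +/-L(t), with a Gaussian profile across the band axis and
#' additive noise.
#'
#' @param L_fun function of time (min) returning the end half-position
#'   L(t) (um).
#' @param flow_amp bump amplitude (um/min); positive puts the positive-
#'   velocity bump at +L (outward flow / growth), negative reverses it
#'   (retraction).
#' @param bump_width bump s.d. along y (um).
#' @param x,y grid coordinates (um).
#' @param times frame times (min).
#' @param x_width profile s.d. across the band (um).
#' @param noise_sd additive velocity noise (um/min).
#' @param seed RNG seed (required when noise_sd > 0).
#' @return a [velocity_field_series()].
#' @export
gen_velocity_fields <- function(L_fun, flow_amp = 10, bump_width = 15,
                                x = seq(-50, 50, by = 10),
                                y = seq(-250, 250, by = 5),
                                times = seq(0, 4, by = 0.5),
                                x_width = 25, noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) stop_invalid("seed is required with noise")
  nx <- length(x); ny <- length(y); nt <- length(times)
  vx <- array(0, c(ny, nx, nt)); vy <- array(0, c(ny, nx, nt))
  xprof <- exp(-x^2 / (2 * x_width^2))
  gen <- function() {
    for (k in seq_len(nt)) {
      L <- L_fun(times[k])
      bump <- exp(-(y - L)^2 / (2 * bump_width^2)) -
        exp(-(y + L)^2 / (2 * bump_width^2))
      vy[, , k] <<- flow_amp * outer(bump, xprof)
      if (noise_sd > 0)
        vy[, , k] <<- vy[, , k] + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
    }
  }
  if (noise_sd > 0) with_seed(seed, gen()) else gen()
  velocity_field_series(x, y, times, vx, vy)
}
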