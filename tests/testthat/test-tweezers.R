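test_that("Stokes drag reproduces the hand-computed calibration force", {
  # 6 pi * 1.412 Pa s * 1.4 um * 2.69 um/s, evaluated independently
  expect_equal(stokes_force(2.69, 1.412, 1.4), 100.2342, tolerance = 1e-4)
})

test_that("force calibration round-trips noiseless glycerol tracks", {
  truth <- list(a1 = 800, k1 = 0.02, a2 = 120, k2 = 0.004)
  tracks <- gen_glycerol_calibration(truth, n_tracks = 30, seed = 5)
  fit <- fit_force_calibration(tracks)
  for (nm in c("a1", "k1", "a2", "k2"))
    expect_lt(abs(fit[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
  # the fitted law is monotone decreasing on the observed range
  xs <- seq(80, 400, by = 5)
  expect_true(all(diff(predict_force(fit, xs)) < 0))
})

test_that("calibration rejects stationary tracks", {
  t <- seq(0, 10, by = 0.5)
  still <- bead_track("s1", "g", t, cbind(rep(100, length(t)), 0),
                      distance_to_tip = rep(100, length(t)))
  expect_error(fit_force_calibration(list(still)), "at least 10")
})

test_that("pulse segmentation tiles the schedule without overlap", {
  t <- seq(0, 100, by = 0.5)
  tr <- bead_track("t", "e", t, cbind(100 - 0 * t, 0),
                   distance_to_tip = rep(100, length(t)))
  w <- segment_pulses(tr, start_s = 0, on_s = 5, off_s = 15)
  expect_length(w, 5)
  expect_equal(vapply(w, `[[`, numeric(1), "on_start"), seq(0, 80, by = 20))
  expect_equal(w[[1]]$off_end, 20)
  # a 19 s track holds no complete cycle
  t19 <- seq(0, 19, by = 0.5)
  tr19 <- bead_track("t", "e", t19, cbind(rep(100, length(t19)), 0),
                     distance_to_tip = rep(100, length(t19)))
  expect_length(segment_pulses(tr19), 0)
})

test_that("drift correction removes affine drift exactly", {
  t <- seq(0, 40, by = 0.5)
  v <- 0.05
  tr <- bead_track("t", "e", t, cbind(100 - v * t, 0),
                   distance_to_tip = 100 - v * t)
  w <- segment_pulses(tr)[[2]]
  corr <- drift_correct(tr, w)
  expect_equal(corr$drift_velocity, v, tolerance = 1e-12)
  expect_lt(max(abs(corr$displacement)), 1e-12)
  expect_false(corr$first_pulse_flag)
})

test_that("drift correction recovers the drift-free Jeffreys response", {
  p <- interphase_params()
  t <- seq(0, 40, by = 0.1)
  v <- 0.03
  resp <- jeffreys_displacement(p, 40, 5, pmax(t - 20, 0))
  tr <- bead_track("t", "e", t, cbind(150 - resp - v * t, 0),
                   distance_to_tip = 150 - resp - v * t)
  w <- segment_pulses(tr)[[2]]    # the pulse starting at t = 20
  corr <- drift_correct(tr, w)
  truth <- jeffreys_displacement(p, 40, 5, corr$times - 20)
  expect_equal(corr$displacement, truth, tolerance = 1e-9)
  # zero drift leaves the series unchanged
  tr0 <- bead_track("t", "e", t, cbind(150 - resp, 0),
                    distance_to_tip = 150 - resp)
  corr0 <- drift_correct(tr0, w)
  expect_equal(corr0$drift_velocity, 0, tolerance = 1e-12)
  # first pulse uses its own relaxation tail and is flagged
  w1 <- segment_pulses(tr0)[[1]]
  expect_true(drift_correct(tr0, w1)$first_pulse_flag)
})

test_that("pulse summary implements the displacement/recovery definitions", {
  # a synthetic cycle with displacement 2 um and relaxation 1 um
  t <- seq(0, 20, by = 0.5)
  x <- ifelse(t <= 5, 2 * t / 5, 2 - (t - 5) / 15 * 1)
  m <- summarize_pulse(list(times = t, displacement = x, drift_velocity = 0,
                            first_pulse_flag = FALSE),
                       force = 40,
                       window = list(on_start = 0, on_end = 5, off_end = 20,
                                     index = 1))
  expect_equal(m$displacement, 2)
  expect_equal(m$recovery, 0.5)
  expect_equal(m$normalized_displacement, 2 / 40)
  expect_true(m$valid)
  # an ideal Jeffreys pulse reproduces the closed-form recovery
  p <- interphase_params()
  tj <- seq(0, 20, by = 0.1)
  xj <- jeffreys_displacement(p, 40, 5, tj)
  mj <- summarize_pulse(list(times = tj, displacement = xj,
                             drift_velocity = 0, first_pulse_flag = FALSE),
                        force = 40,
                        window = list(on_start = 0, on_end = 5, off_end = 20,
                                      index = 1))
  expect_equal(mj$recovery, jeffreys_recovery(p, 5), tolerance = 1e-3)
  # non-positive displacement is flagged invalid
  bad <- summarize_pulse(list(times = t, displacement = -x,
                              drift_velocity = 0, first_pulse_flag = FALSE),
                         force = 40,
                         window = list(on_start = 0, on_end = 5,
                                       off_end = 20, index = 1))
  expect_false(bad$valid)
})

test_that("force-range filter is boundary-inclusive and idempotent", {
  m <- data.frame(F0 = c(10, 20, 40, 60, 61),
                  normalized_displacement = 1:5 / 10,
                  recovery = rep(0.5, 5), valid = TRUE,
                  track_id = letters[1:5], embryo_id = "e", phase = "p")
  kept <- filter_force_range(m)
  expect_equal(kept$F0, c(20, 40, 60))
  expect_identical(filter_force_range(kept), kept)
  empty <- filter_force_range(m[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("embryo averaging weights by track counts and is order-invariant", {
  m <- data.frame(
    F0 = rep(40, 6),
    normalized_displacement = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    recovery = c(0.5, 0.5, 0.6, 0.6, 0.4, 0.4),
    valid = TRUE,
    track_id = c("a", "a", "b", "b", "c", "c"),
    embryo_id = c("e1", "e1", "e1", "e1", "e2", "e2"),
    phase = "interphase")
  s <- embryo_average(m)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_tracks, c(2, 1))
  expect_equal(s$mean_normalized_displacement[1], mean(c(0.1, 0.2, 0.3, 0.4)))
  s_perm <- embryo_average(m[sample(nrow(m)), ])
  expect_equal(s[order(s$embryo_id), ], s_perm[order(s_perm$embryo_id), ],
               ignore_attr = TRUE)
  # two identical curves average to either; opposite curves cancel
  c1 <- list(times = 0:10, displacement = sin(0:10), drift_velocity = 0,
             first_pulse_flag = FALSE)
  avg <- average_pulse_curves(list(c1, c1))
  expect_equal(avg$displacement, sin(0:10))
  c2 <- c1; c2$displacement <- -c1$displacement
  avg0 <- average_pulse_curves(list(c1, c2))
  expect_equal(avg0$displacement, rep(0, 11))
})
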