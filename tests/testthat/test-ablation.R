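test_that("recoil fit recovers exact parameters and v0", {
  t <- seq(0, 10, by = 0.3)
  tr <- recoil_trace(t, 7.8 * (1 - exp(-t / 2)))
  fit <- fit_recoil(tr)
  expect_equal(fit$A, 7.8, tolerance = 1e-9)
  expect_equal(fit$x0, 2, tolerance = 1e-9)
  expect_equal(fit$v0, 3.9, tolerance = 1e-8)
  expect_lt(abs(fit$c), 1e-9)
})

test_that("recoil fit rejects a flat trace", {
  t <- seq(0, 10, by = 0.3)
  expect_error(fit_recoil(recoil_trace(t, rep(2, length(t)))), "degenerate")
  expect_error(fit_recoil(recoil_trace(c(0, 1, 2), c(0, 1, 2))), "at least 6")
})

test_that("recoil fit is scale-equivariant", {
  t <- seq(0, 10, by = 0.3)
  y <- 3 * (1 - exp(-t / 1.5)) + 0.2
  f1 <- fit_recoil(recoil_trace(t, y))
  f5 <- fit_recoil(recoil_trace(t, 5 * y))
  expect_equal(f5$A, 5 * f1$A, tolerance = 1e-6)
  expect_equal(f5$v0, 5 * f1$v0, tolerance = 1e-6)
  expect_equal(f5$x0, f1$x0, tolerance = 1e-6)
})

test_that("noisy recoil ensemble recovers the generating velocity scale", {
  gen <- gen_recoil_traces(n = 200, v0_mean = 0.32, v0_sd = 0, x0 = 2,
                           noise_sd = 0.05, seed = 14)
  v0_hat <- vapply(gen$traces, function(tr) fit_recoil(tr)$v0, numeric(1))
  expect_lt(abs(median(v0_hat) - 0.32) / 0.32, 0.10)
})

test_that("recoil and healing normalisation follow their definitions", {
  tr <- recoil_trace(c(0, 1, 2), c(0, 4, 8), grey_value = c(50, 75, 100),
                     grey_reference = 100)
  nz <- normalize_recoil_and_healing(tr)
  expect_equal(nz$recoil_norm, c(0, 0.5, 1))
  expect_equal(nz$grey_norm, c(0.5, 0.75, 1))
  # grey equal to the reference normalises to one everywhere
  tr2 <- recoil_trace(c(0, 1, 2), c(0, 1, 3), grey_value = rep(80, 3),
                      grey_reference = 80)
  expect_equal(normalize_recoil_and_healing(tr2)$grey_norm, rep(1, 3))
  expect_error(normalize_recoil_and_healing(
    recoil_trace(c(0, 1, 2), rep(1, 3))), "constant")
  # healing that overtakes the recoil: normalised curves cross
  t <- seq(0, 12, by = 0.3)
  rec <- 6 * (1 - exp(-t / 3))
  grey <- 100 * pmin(t / 4, 1)             # heals fully by 4 s
  tr3 <- recoil_trace(t, rec, grey_value = grey, grey_reference = 100)
  nz3 <- normalize_recoil_and_healing(tr3)
  d <- nz3$grey_norm - nz3$recoil_norm
  expect_true(any(d[-1] > 0) && any(d < 0))
})

test_that("band-axis averaging respects the strip and symmetries", {
  x <- seq(-50, 50, by = 10); y <- seq(-100, 100, by = 10)
  times <- c(0, 1)
  vy <- array(3, c(length(y), length(x), 2))
  vx <- array(0, c(length(y), length(x), 2))
  fld <- velocity_field_series(x, y, times, vx, vy)
  prof <- band_axis_average(fld)
  expect_true(all(prof$vy_bar == 3))
  # a field antisymmetric in x averages to zero over the strip
  vy2 <- array(rep(x, each = length(y)), c(length(y), length(x), 2))
  fld2 <- velocity_field_series(x, y, times, vx, vy2)
  expect_lt(max(abs(band_axis_average(fld2)$vy_bar)), 1e-12)
  # a grid with no columns inside the strip is an error
  off <- velocity_field_series(c(-40, -30), y, times,
                               array(0, c(length(y), 2, 2)),
                               array(1, c(length(y), 2, 2)))
  expect_error(band_axis_average(off, half_width = 5), "no grid columns")
})

test_that("band-end detection tracks moving speed extrema", {
  L_fun <- function(t) 150 - 15.6 * t     # retracting ends
  fld <- gen_velocity_fields(L_fun, flow_amp = -10,
                             times = seq(0, 4, by = 0.25))
  ends <- detect_band_ends(band_axis_average(fld))
  # detected extremum positions follow -L(t) and +L(t) within the grid
  expect_lt(max(abs(ends$y_pos + L_fun(ends$time))), 5 + 1e-9)
  expect_lt(max(abs(ends$y_neg - L_fun(ends$time))), 5 + 1e-9)
  kin <- end_kinematics(ends)
  # both ends move inward at ~15.6 um/min
  expect_equal(kin$end_velocity, -15.6, tolerance = 0.05)
  # static bumps give zero end velocity
  fld0 <- gen_velocity_fields(function(t) 100, flow_amp = 5)
  kin0 <- end_kinematics(detect_band_ends(band_axis_average(fld0)))
  expect_equal(kin0$end_velocity, 0, tolerance = 1e-9)
})

test_that("band-end detection is equivariant under y-reflection", {
  L_fun <- function(t) 120 - 10 * t
  fld <- gen_velocity_fields(L_fun, flow_amp = -8,
                             times = seq(0, 3, by = 0.5))
  prof <- band_axis_average(fld)
  ends <- detect_band_ends(prof)
  refl <- prof
  refl$vy_bar <- -prof$vy_bar[rev(seq_along(prof$y)), , drop = FALSE]
  ends_r <- detect_band_ends(refl)
  # reflected field swaps the ends and negates positions/flows
  expect_equal(ends_r$y_pos, -ends$y_neg, tolerance = 1e-9)
  expect_equal(ends_r$flow_pos, -ends$flow_neg, tolerance = 1e-9)
})

test_that("end kinematics decomposition is exact by construction", {
  s <- data.frame(time = 0:4, y_pos = rep(100, 5), flow_pos = rep(-5, 5),
                  y_neg = rep(-100, 5), flow_neg = rep(5, 5))
  class(s) <- c("band_end_series", "data.frame")
  kin <- end_kinematics(s)
  # static ends with inward flow 5: growth compensates at +5
  expect_equal(kin$end_velocity, 0)
  expect_equal(kin$flow_velocity, -5)
  expect_equal(kin$growth_speed, 5)
  expect_equal(kin$per_end$growth_speed,
               kin$per_end$end_velocity - kin$per_end$flow_velocity)
  # end velocity equal to the flow: zero growth
  s2 <- data.frame(time = 0:4, y_pos = 100 + 3 * (0:4), flow_pos = rep(3, 5),
                   y_neg = -100 - 3 * (0:4), flow_neg = rep(-3, 5))
  class(s2) <- c("band_end_series", "data.frame")
  expect_equal(end_kinematics(s2)$growth_speed, 0, tolerance = 1e-9)
  expect_error(end_kinematics(s[1, , drop = FALSE]), "at least 2")
})

test_that("retraction velocity averages per-track slopes", {
  t <- seq(0, 4, by = 0.25)
  five <- lapply(1:5, function(i)
    data.frame(time = t, position = 10.25 * t + i * 7))
  rv <- retraction_velocity(five)
  expect_equal(rv$mean_slope, 10.25, tolerance = 1e-12)
  expect_equal(rv$rmse, 0, tolerance = 1e-12)
  three <- lapply(1:3, function(i) data.frame(time = t, position = i * t))
  expect_equal(retraction_velocity(three)$mean_slope, 2, tolerance = 1e-12)
  set.seed(8)
  noisy <- lapply(1:12, function(i)
    data.frame(time = t, position = 4 * t + rnorm(length(t), 0, 0.5)))
  rvn <- retraction_velocity(noisy)
  expect_lt(abs(rvn$mean_slope - 4), 2 * 0.5 / sqrt(12))
  expect_gt(rvn$rmse, 0)
})

test_that("phase-windowed ingression slopes are recovered exactly", {
  pw <- make_piecewise_series(slopes = c(2.71, 9.86))
  sl <- ingression_slope(pw$times, pw$ingression, pw$windows)
  expect_equal(sl$slope, c(2.71, 9.86), tolerance = 1e-9)
  # photoactivation-style fixture with a different pair of slopes
  pw2 <- make_piecewise_series(slopes = c(2.642, 9.004), t_switch = 10,
                               t_end = 20)
  sl2 <- ingression_slope(pw2$times, pw2$ingression, pw2$windows)
  expect_equal(sl2$slope, c(2.642, 9.004), tolerance = 1e-9)
  flat <- ingression_slope(pw$times, rep(2, length(pw$times)),
                           list(all = c(0, 25)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(ingression_slope(pw$times, pw$ingression,
                                list(a = c(0, 20), b = c(10, 25))),
               "non-overlapping")
})

test_that("slope operations agree with the closed-form least-squares oracle", {
  set.seed(99)
  t <- sort(runif(40, 0, 10)); y <- 3 + 1.7 * t + rnorm(40, 0, 0.3)
  ours <- ingression_slope(t, y, list(w = c(0, 10)))
  ref <- lm(y ~ t)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(ours$se, unname(summary(ref)$coefficients[2, 2]),
               tolerance = 1e-10)
})
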