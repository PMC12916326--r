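# a three-edge toy arc exercised exactly as the growth procedure prescribes
test_that("band growth follows the sequential covering procedure", {
  m <- build_mesh(350, 35)
  arc1 <- m$equator$arc_pos
  lens <- m$rest_lengths
  p0 <- numeric(nrow(m$edges))

  # hand-walk: G = 0.25 um on ~34 um edges covers 0.25/l of the first edge
  p <- grow_band(m, p0, 0.25)
  expect_equal(p[arc1[1]], 0.25 / lens[arc1[1]], tolerance = 1e-12)
  expect_equal(p[arc1[2]], 0)
  # and the same amount on the first edge of the other arc
  arc2 <- m$equator$arc_neg
  expect_equal(p[arc2[1]], 0.25 / lens[arc2[1]], tolerance = 1e-12)

  # a fully covered first edge is skipped; the overflow lands on edge 2
  p1 <- p0; p1[arc1[1]] <- 1; p1[arc2[1]] <- 1
  p2 <- grow_band(m, p1, 4)
  expect_equal(p2[arc1[1]], 1)
  expect_equal(p2[arc1[2]], 4 / lens[arc1[2]], tolerance = 1e-12)

  # zero budget changes nothing; negative is rejected
  expect_identical(grow_band(m, p, 0), p)
  expect_error(grow_band(m, p, -1), "non-negative")
})

test_that("band growth conserves the length budget until saturation", {
  m <- build_mesh(350, 35)
  p <- numeric(nrow(m$edges))
  G <- 25 * 0.01
  for (s in 1:200) p <- grow_band(m, p, G)
  added <- sum(p * m$rest_lengths)
  expect_equal(added, 2 * 200 * G, tolerance = 1e-9)
  # saturation: the band never exceeds the equator length
  for (s in 1:6000) p <- grow_band(m, p, G)
  eq_len <- sum(m$rest_lengths[m$equator$edge_ids])
  expect_equal(sum(p * m$rest_lengths), eq_len, tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("stress update has the printed decay factor and fixed points", {
  p <- interphase_params()
  k <- p$k; gsum <- p$gamma1 + p$gamma2
  dt <- 0.1
  # constant strain: geometric decay by (1 - k dt/(g1+g2)) per step
  s1 <- update_edge_stress(p, 2, 0.3, 0.3, 0.3, dt)
  expect_equal(s1, 2 * (1 - k * dt / gsum), tolerance = 1e-12)
  # zero history stays zero
  expect_equal(update_edge_stress(p, 0, 0, 0, 0, dt), 0)
  # steady strain rate: sigma converges to the fluid stress gamma2 * rate
  rate <- 0.05
  sig <- 0
  for (n in 2:4000) {
    eps <- rate * dt * c(n, n - 1, n - 2)
    sig <- update_edge_stress(p, sig, eps[1], eps[2], eps[3], dt)
  }
  expect_equal(sig, p$gamma2 * rate, tolerance = 1e-6)
  expect_error(update_edge_stress(p, 0, 0, 0, 0, -1), "positive")
})

test_that("vertex forces obey symmetry and momentum conservation", {
  m <- build_mesh(350, 140)
  # random tensions: forces sum to zero over the closed mesh
  set.seed(1)
  ten <- runif(nrow(m$edges), -1, 1)
  f <- vertex_forces(m, ten)
  expect_lt(max(abs(colSums(f))), 1e-9 * nrow(m$vertices))
  # a single tensioned edge pulls its endpoints together, antiparallel
  ten1 <- numeric(nrow(m$edges)); ten1[5] <- 1
  f1 <- vertex_forces(m, ten1)
  a <- m$edges[5, 1]; b <- m$edges[5, 2]
  expect_equal(f1[a, ], -f1[b, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(f1[a, ]^2)), 1, tolerance = 1e-12)
  u <- (m$vertices[b, ] - m$vertices[a, ]) / m$rest_lengths[5]
  expect_equal(f1[a, ], u, tolerance = 1e-12)
})

test_that("a middle vertex between equal collinear tensions feels no force", {
  # explicit 3-vertex chain as a minimal mesh-like structure
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  E <- rbind(c(1L, 2L), c(2L, 3L))
  f <- bandratchet:::cpp_vertex_forces(V, E, c(0.7, 0.7))
  expect_equal(f[2, ], c(0, 0, 0), tolerance = 1e-15)
})

test_that("relax returns immediately on an equilibrated stress-free mesh", {
  m <- build_mesh(350, 140)
  st <- list(sigma = numeric(nrow(m$edges)),
             eps_prev = numeric(nrow(m$edges)),
             eps_prev2 = numeric(nrow(m$edges)),
             lambda = numeric(nrow(m$edges)))
  co <- bandratchet:::phase_coeffs(interphase_params(), 0.01)
  r <- relax(m, m$vertices, st, co)
  expect_equal(r$iterations, 0)
  expect_identical(r$positions, m$vertices)
  # tol = Inf returns the input unchanged even with forces present
  st$lambda[m$equator$edge_ids] <- 1.5
  r2 <- relax(m, m$vertices, st, co, tol = Inf)
  expect_identical(r2$positions, m$vertices)
})

test_that("a tensioned equatorial ring pulls the band inward on relaxation", {
  # the hollow shell keeps this cheap and lets the simple descent oracle run
  m <- build_mesh(350, 140, type = "shell")
  nE <- nrow(m$edges)
  st <- list(sigma = numeric(nE), eps_prev = numeric(nE),
             eps_prev2 = numeric(nE), lambda = numeric(nE))
  st$lambda[m$equator$edge_ids] <- 1.5
  co <- bandratchet:::phase_coeffs(interphase_params(), 0.01)
  r <- relax(m, m$vertices, st, co, tol = 1e-5)
  eq_v <- m$equator$vertex_ids
  r_before <- sqrt(rowSums(m$vertices[eq_v, ]^2))
  r_after <- sqrt(rowSums(r$positions[eq_v, ]^2))
  expect_true(all(r_after < r_before))

  # independent energy-descent oracle on the same configuration: plain
  # fixed-step gradient descent on the elastic + line-tension energy,
  # iterated until its own forces are small
  X <- m$vertices
  C <- co$c1 + co$c2
  ia <- m$edges[, 1]; ib <- m$edges[, 2]
  nv <- nrow(X)
  for (it in 1:60000) {
    d <- X[ib, , drop = FALSE] - X[ia, , drop = FALSE]
    l <- sqrt(rowSums(d^2))
    ten <- (C * (l - m$rest_lengths) / m$rest_lengths + st$lambda) / l
    f <- matrix(0, nv, 3)
    for (dim in 1:3) {
      comp <- ten * d[, dim]
      f[, dim] <- unname(
        rowsum(c(comp, -comp), c(ia, ib), reorder = TRUE)[, 1])
    }
    if (max(sqrt(rowSums(f^2))) < 1e-4) break
    X <- X + 0.05 * f
  }
  oracle_r <- sqrt(rowSums(X[eq_v, ]^2))
  # both routes agree on how far the ring moves inward
  expect_equal(mean(r_before - r_after), mean(r_before - oracle_r),
               tolerance = 0.05)
})

test_that("zero tension produces no ingression and linear band growth", {
  cfg <- coarse_config(Lambda = 0)
  res <- run_cycle(cfg)
  expect_lt(max(abs(res$ingression_um)), 1e-9)
  # band length grows at 2 g per minute before saturation
  early <- res[res$time_min <= 2, ]
  fit <- lm(band_length_um ~ time_min, early)
  expect_equal(unname(coef(fit)[2]), 2 * cfg$g, tolerance = 0.01)
})

test_that("identical phase materials make the phase switch invisible", {
  # with the same material in both phases the nominal switch time cannot
  # affect the dynamics: moving it must leave the trajectory unchanged
  mesh <- build_mesh(350, 140)
  cfg_a <- coarse_config(mphase = interphase_params(), Lambda = 1.5,
                         interphase_duration = 2, mphase_duration = 2)
  cfg_b <- coarse_config(mphase = interphase_params(), Lambda = 1.5,
                         interphase_duration = 2.5, mphase_duration = 1.5)
  res_a <- run_cycle(cfg_a, mesh = mesh)
  res_b <- run_cycle(cfg_b, mesh = mesh)
  common <- intersect(res_a$time_min, res_b$time_min)
  ia <- match(common, res_a$time_min); ib <- match(common, res_b$time_min)
  expect_equal(res_a$ingression_um[ia], res_b$ingression_um[ib],
               tolerance = 1e-9)
})

test_that("ingression is faster in fluid than in stiff surroundings", {
  for (Lam in c(0.5, 1.5, 3)) {
    slopes <- vapply(list(interphase_params(), mphase_params()),
                     function(par) {
      cfg <- sim_config(target_edge_length = 140, interphase_duration = 1,
                        mphase_duration = 1, interphase = par, mphase = par,
                        Lambda = Lam, record_every = 20L)
      res <- run_cycle(cfg)
      ingression_velocity(res, c(0.5, 2))$slope
    }, numeric(1))
    expect_gte(slopes[2], slopes[1])
  }
})

test_that("ingression velocity extraction matches simple slopes", {
  t <- seq(0, 10, by = 0.5)
  lin <- data.frame(time_min = t, ingression_um = 2 * t,
                    phase = "interphase")
  expect_equal(ingression_velocity(lin, "interphase")$slope, 2,
               tolerance = 1e-12)
  flat <- data.frame(time_min = t, ingression_um = rep(1, length(t)),
                     phase = "M-phase")
  expect_equal(ingression_velocity(flat, "M-phase")$slope, 0,
               tolerance = 1e-12)
  pw <- make_piecewise_series()
  df <- data.frame(time_min = pw$times, ingression_um = pw$ingression,
                   phase = ifelse(pw$times <= 15, "interphase", "M-phase"))
  expect_equal(ingression_velocity(df, c(0, 15))$slope, 2.71,
               tolerance = 1e-9)
  expect_equal(ingression_velocity(df, c(15, 25))$slope, 9.86,
               tolerance = 1e-9)
  expect_error(ingression_velocity(df, c(30, 31)), "fewer than 2")
})

test_that("band-tension fitting recovers the generating tension", {
  cfg <- sim_config(target_edge_length = 140, interphase_duration = 1.5,
                    mphase_duration = 1, Lambda = 1.5, record_every = 20L)
  mesh <- build_mesh(cfg$R, cfg$target_edge_length)
  target <- run_cycle(cfg, mesh = mesh)
  fit <- fit_band_tension(cfg,
                          data.frame(time_min = target$time_min,
                                     ingression_um = target$ingression_um),
                          lambda_grid = c(0.5, 1.5, 3), mesh = mesh)
  expect_equal(fit$Lambda, 1.5)
  expect_gt(fit$r_squared, 0.999)
  # a single-point grid is reported, not an error
  fit0 <- fit_band_tension(cfg,
                           data.frame(time_min = target$time_min,
                                      ingression_um = target$ingression_um),
                           lambda_grid = 0, mesh = mesh)
  expect_equal(fit0$Lambda, 0)
  expect_lt(fit0$r_squared, 0.5)
  expect_error(fit_band_tension(cfg, target, lambda_grid = numeric(0)),
               "empty")
})
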