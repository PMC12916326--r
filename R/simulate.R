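#' Simulation configuration for the mechanical-ratchet model
#'
#' Collects every tunable of the contractile-band mesh simulation. The
#' defaults are the study configuration: a 350 um cell, dt = 0.01 min,
#' 15 min of interphase followed by 10 min of M-phase with the
#' phase-specific cytoplasm Jeffreys parameters, band growth speed
#' g = 25 um/min (per band end), band tension Lambda = 1.5, and a
#' force-balance tolerance of 1e-5.
#'
#' Time inside the simulation is in minutes; the Jeffreys damping
#' coefficients are given in pN s/um as measured and converted to minutes
#' internally, so only the ratios dt/gamma enter the discretization.
#'
#' @param R cell radius (um).
#' @param target_edge_length mesh resolution (um).
#' @param dt time step (min).
#' @param interphase_duration,mphase_duration phase durations (min).
#' @param interphase,mphase [jeffreys_params()] per phase.
#' @param g band growth speed (um/min), applied per band end.
#' @param Lambda band line tension (simulation stress units), >= 0.
#' @param tol force-balance tolerance (max per-vertex force norm).
#' @param max_iter relaxation iteration cap per time step.
#' @param step_cap_frac per-iteration vertex displacement cap, as a fraction
#'   of the shortest rest length.
#' @param record_every store one result row every this many steps (the
#'   underlying dynamics always run at `dt`).
#' @param seed mesh-construction seed (the build is deterministic; kept for
#'   interface symmetry with the generators).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(R = 350, target_edge_length = 35, dt = 0.01,
                       interphase_duration = 15, mphase_duration = 10,
                       interphase = interphase_params(),
                       mphase = mphase_params(),
                       g = 25, Lambda = 1.5, tol = 1e-5,
                       max_iter = 1000000L, step_cap_frac = 0.1,
                       record_every = 10L, seed = 1L) {
  check_positive(R, "R"); check_positive(dt, "dt")
  check_positive(interphase_duration, "interphase_duration")
  check_positive(mphase_duration, "mphase_duration")
  check_positive(g, "g"); check_positive(tol, "tol")
  if (Lambda < 0) stop_invalid("Lambda must be non-negative")
  stopifnot(inherits(interphase, "jeffreys_params"),
            inherits(mphase, "jeffreys_params"))
  structure(list(R = R, target_edge_length = target_edge_length, dt = dt,
                 interphase_duration = interphase_duration,
                 mphase_duration = mphase_duration,
                 interphase = interphase, mphase = mphase,
                 g = g, Lambda = Lambda, tol = tol,
                 max_iter = as.integer(max_iter),
                 step_cap_frac = step_cap_frac,
                 record_every = as.integer(record_every),
                 seed = seed),
            class = "sim_config")
}

# discretization coefficients for one phase; gammas arrive in seconds,
# dt in minutes
phase_coeffs <- function(params, dt_min) {
  g1 <- params$gamma1 / 60; g2 <- params$gamma2 / 60; k <- params$k
  list(c_decay = 1 - k * dt_min / (g1 + g2),
       c1 = g2 * k / (g1 + g2),
       c2 = g1 * g2 / ((g1 + g2) * dt_min))
}

#' Grow the contractile band along the equator
#'
#' Distributes a length budget `G` of new band along each equatorial arc,
#' starting at the band-centre vertex and walking outward: a fully covered
#' edge (p = 1) is skipped; if the budget exceeds the uncovered length
#' `(1 - p) l` of the current edge the edge is filled and the walk
#' continues; otherwise the remaining budget is deposited as `p + G/l` and
#' the arc stops. The same budget `G` is applied independently to the
#' phi = 0 and phi = pi arcs, so the band grows from both ends; leftover
#' budget is discarded once the equator is saturated.
#'
#' @param mesh a [build_mesh()] object.
#' @param p per-edge band coverage fractions (length = number of edges).
#' @param G band length to add per arc (um), >= 0.
#' @param lengths current edge lengths (um); defaults to rest lengths.
#' @return updated coverage vector `p`.
#' @export
grow_band <- function(mesh, p, G, lengths = mesh$rest_lengths) {
  if (G < 0) stop_invalid("G must be non-negative")
  for (arc in list(mesh$equator$arc_pos, mesh$equator$arc_neg)) {
    budget <- G
    for (ei in arc) {
      if (budget <= 0) break
      avail <- (1 - p[ei]) * lengths[ei]
      if (avail <= 0) next
      if (budget >= avail) {
        p[ei] <- 1
        budget <- budget - avail
      } else {
        p[ei] <- p[ei] + budget / lengths[ei]
        budget <- 0
      }
    }
  }
  p
}

#' Explicit stress update of the discretized Jeffreys constitutive law
#'
#' Solves the time-discretized constitutive equation
#' \deqn{\sigma(t_{n-1}) + \frac{\gamma_1+\gamma_2}{k}
#'   \frac{\sigma(t_n)-\sigma(t_{n-1})}{dt} =
#'   \gamma_2 \frac{\epsilon(t_n)-\epsilon(t_{n-1})}{dt} +
#'   \frac{\gamma_1\gamma_2}{k}
#'   \frac{\epsilon(t_n)-2\epsilon(t_{n-1})+\epsilon(t_{n-2})}{dt^2}}
#' explicitly for `sigma(t_n)`. Under constant strain the stress decays
#' geometrically with factor `1 - k dt/(gamma1+gamma2)` per step; under a
#' steady strain rate it approaches the fluid stress `gamma2 * d(eps)/dt`.
#'
#' @param params a [jeffreys_params()] (gammas in pN s/um as usual).
#' @param sigma_prev stress at t_{n-1}.
#' @param eps_now,eps_prev,eps_prev2 strains at t_n, t_{n-1}, t_{n-2}.
#' @param dt time step, in the same time unit as the gammas (use seconds
#'   here, or convert consistently; [run_cycle()] works in minutes).
#' @return stress at t_n (vectorised over edges).
#' @export
update_edge_stress <- function(params, sigma_prev, eps_now, eps_prev,
                               eps_prev2, dt) {
  stopifnot(inherits(params, "jeffreys_params"))
  check_positive(dt, "dt")
  g1 <- params$gamma1; g2 <- params$gamma2; k <- params$k
  A <- (g1 + g2) / k
  sigma_prev * (1 - dt / A) + (g2 / A) * (eps_now - eps_prev) +
    (g1 * g2 / (k * A * dt)) * (eps_now - 2 * eps_prev + eps_prev2)
}

#' Per-vertex forces of a mesh configuration
#'
#' The force on vertex j is `f_j = sum_i (sigma_i + lambda_i) t_hat_i` over
#' the edges meeting j, with `t_hat_i` the unit vector along edge i pointing
#' away from j: positive total edge tension pulls the two endpoints toward
#' each other, so every edge contributes equal and opposite forces and the
#' net force over a closed mesh vanishes.
#'
#' @param mesh a [build_mesh()] object.
#' @param tension per-edge total tension `sigma + lambda`.
#' @param positions optional current vertex positions.
#' @return V x 3 matrix of forces.
#' @export
vertex_forces <- function(mesh, tension, positions = mesh$vertices) {
  if (length(tension) != nrow(mesh$edges))
    stop_invalid("tension must have one entry per edge")
  cpp_vertex_forces(positions, mesh$edges, tension)
}

#' Relax a mesh configuration to force balance
#'
#' Finds the configuration in which the maximum per-vertex force norm is
#' below `tol`, with strains and stresses recomputed from the frozen
#' previous-step histories (one simulator time step). Because the stress is
#' affine in the strain within a step, the forces are the exact negative
#' gradient of a step energy; that energy is minimised by damped Newton-CG
#' (inexact Newton steps from conjugate-gradient solves with analytic
#' Hessian-vector products, Armijo backtracking on the exact edge-wise
#' energy difference), capped so no vertex moves more than `cap_disp` per
#' iteration. Edge lengths enter through the smooth regularisation
#' `sqrt(l^2 + (1e-2 l0)^2)`, so band-covered edges that contract to zero
#' (see the vignette) remain well-behaved.
#'
#' @param mesh a [build_mesh()] object.
#' @param positions current V x 3 vertex positions.
#' @param state list with `sigma`, `eps_prev`, `eps_prev2`, `lambda`
#'   (per-edge vectors).
#' @param coeffs discretization coefficients (`c_decay`, `c1`, `c2`); see
#'   [update_edge_stress()] for their meaning.
#' @param tol force tolerance.
#' @param max_iter iteration cap; exceeding it raises a convergence error.
#' @param cap_disp per-iteration displacement cap (um).
#' @return list with `positions`, `sigma`, `eps`, `iterations`, `max_force`.
#' @export
relax <- function(mesh, positions, state, coeffs, tol = 1e-5,
                  max_iter = 1000000L, cap_disp = 0.1 * min(mesh$rest_lengths)) {
  res <- cpp_relax(positions, mesh$edges, mesh$rest_lengths,
                   state$sigma, state$eps_prev, state$eps_prev2,
                   state$lambda, coeffs$c_decay, coeffs$c1, coeffs$c2,
                   tol, as.integer(max_iter), cap_disp)
  if (!res$converged && is.finite(tol))
    stop(sprintf(
      "relaxation did not converge: max force %.3g > tol %.3g after %d iterations",
      res$max_force, tol, res$iterations))
  res
}

#' Run one simulated cell cycle of the mechanical ratchet
#'
#' Simulates band growth and ingression through one interphase (stiff
#' cytoplasm, band anchored and growing) followed by one M-phase (fluid
#' cytoplasm, band ingressing): at every time step the band grows by
#' `G = g dt` per arc, the edge stresses follow the discretized Jeffreys
#' law of the current phase, and the vertices are relaxed to force balance.
#' Ingression is the inward displacement of the band-centre vertex along
#' its initial outward normal.
#'
#' @param config a [sim_config()].
#' @param mesh optional prebuilt mesh (else built from the config).
#' @return An object of class `sim_result`: a data.frame with columns
#'   `time_min`, `phase`, `ingression_um`, `band_length_um`, plus attributes
#'   `config`, `final_positions`, `mesh`.
#' @export
run_cycle <- function(config, mesh = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(mesh))
    mesh <- build_mesh(config$R, config$target_edge_length, config$seed)
  nE <- nrow(mesh$edges)
  pos <- mesh$vertices
  centre <- mesh$equator$centre_vertex
  n_hat <- mesh$vertices[centre, ] / sqrt(sum(mesh$vertices[centre, ]^2))
  x0 <- mesh$vertices[centre, ]
  sigma <- numeric(nE); eps_prev <- numeric(nE); eps_prev2 <- numeric(nE)
  p <- numeric(nE)
  cap_disp <- config$step_cap_frac * min(mesh$rest_lengths)
  co_i <- phase_coeffs(config$interphase, config$dt)
  co_m <- phase_coeffs(config$mphase, config$dt)
  n_steps <- as.integer(round(
    (config$interphase_duration + config$mphase_duration) / config$dt))
  n_int <- as.integer(round(config$interphase_duration / config$dt))
  keep <- unique(c(seq(config$record_every, n_steps, by = config$record_every),
                   n_int, n_steps))
  rec_t <- numeric(0); rec_phase <- character(0)
  rec_ing <- numeric(0); rec_len <- numeric(0)
  G <- config$g * config$dt
  for (s in seq_len(n_steps)) {
    in_interphase <- s <= n_int
    co <- if (in_interphase) co_i else co_m
    lens <- edge_lengths(mesh, pos)
    p <- grow_band(mesh, p, G, lens)
    res <- tryCatch(
      cpp_relax(pos, mesh$edges, mesh$rest_lengths, sigma, eps_prev,
                eps_prev2, config$Lambda * p, co$c_decay, co$c1, co$c2,
                config$tol, config$max_iter, cap_disp),
      error = function(e) stop(sprintf("step %d: %s", s, conditionMessage(e))))
    if (!res$converged)
      stop(sprintf(
        "relaxation failed at step %d (t = %.2f min): max force %.3g > tol %.3g",
        s, s * config$dt, res$max_force, config$tol))
    pos <- res$positions
    eps_prev2 <- eps_prev; eps_prev <- res$eps; sigma <- res$sigma
    if (s %in% keep) {
      rec_t <- c(rec_t, s * config$dt)
      rec_phase <- c(rec_phase, if (in_interphase) "interphase" else "M-phase")
      rec_ing <- c(rec_ing, sum((x0 - pos[centre, ]) * n_hat))
      rec_len <- c(rec_len, sum(p * edge_lengths(mesh, pos)))
    }
  }
  out <- data.frame(time_min = rec_t, phase = rec_phase,
                    ingression_um = rec_ing, band_length_um = rec_len)
  out <- out[order(out$time_min), ]
  rownames(out) <- NULL
  structure(out, class = c("sim_result", "data.frame"),
            config = config, final_positions = pos, mesh = mesh,
            band_fraction = p)
}

#' Ingression velocity over a phase window
#'
#' Least-squares slope of band-centre ingression versus time over one phase
#' of a simulation result (or any sub-window).
#'
#' @param result a [run_cycle()] result (or any data.frame with `time_min`,
#'   `ingression_um`, `phase`).
#' @param window `"interphase"`, `"M-phase"`, or a numeric `c(t0, t1)` in
#'   minutes.
#' @return list with `slope` (um/min), `se`, `n`.
#' @export
ingression_velocity <- function(result, window) {
  if (is.character(window)) {
    sel <- result$phase == window
  } else {
    sel <- result$time_min >= window[1] & result$time_min <= window[2]
  }
  if (sum(sel) < 2L) stop_invalid("window contains fewer than 2 samples")
  f <- ls_slope(result$time_min[sel], result$ingression_um[sel])
  list(slope = f$slope, se = f$se, n = sum(sel))
}

#' Fit the band tension against a target ingression curve
#'
#' Runs the simulator over a grid of tensions and selects the tension whose
#' predicted band-centre ingression has the lowest mean squared error
#' against the supplied displacement curve (resampled onto the simulation
#' time grid by linear interpolation). Also reports the R^2 score of the
#' selected tension.
#'
#' @param config a [sim_config()]; its `Lambda` is overridden by the grid.
#' @param target data.frame with columns `time_min` and `ingression_um`.
#' @param lambda_grid tensions to scan (default 0 to 10 in steps of 0.5).
#' @param mesh optional prebuilt mesh reused across the scan.
#' @return list with `Lambda`, `r_squared`, `mse`, and the per-grid `scan`
#'   data.frame.
#' @export
fit_band_tension <- function(config, target,
                             lambda_grid = seq(0, 10, by = 0.5),
                             mesh = NULL) {
  if (length(lambda_grid) == 0L) stop_invalid("empty tension grid")
  if (is.null(mesh))
    mesh <- build_mesh(config$R, config$target_edge_length, config$seed)
  mse <- numeric(length(lambda_grid))
  r2 <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    cfg <- config; cfg$Lambda <- lambda_grid[i]
    res <- run_cycle(cfg, mesh = mesh)
    tgt <- approx(target$time_min, target$ingression_um,
                  xout = res$time_min, rule = 2)$y
    mse[i] <- mean((res$ingression_um - tgt)^2)
    ss_tot <- sum((tgt - mean(tgt))^2)
    r2[i] <- if (ss_tot > 0) 1 - sum((res$ingression_um - tgt)^2) / ss_tot
             else NA_real_
  }
  best <- which.min(mse)
  list(Lambda = lambda_grid[best], r_squared = r2[best], mse = mse[best],
       scan = data.frame(Lambda = lambda_grid, mse = mse, r_squared = r2))
}
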