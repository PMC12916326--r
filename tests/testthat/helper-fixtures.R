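# shared fixtures built in code

# a noiseless Jeffreys pulse on a uniform grid (loading + relaxation)
make_jeffreys_pulse <- function(params = interphase_params(), F0 = 40,
                                tp = 5, t_end = 20, dt = 0.1) {
  t <- seq(0, t_end, by = dt)
  pulse_response(t, jeffreys_displacement(params, F0, tp, t), F0, tp)
}

# piecewise-linear ingression series with prescribed phase slopes
make_piecewise_series <- function(slopes = c(2.71, 9.86), t_switch = 15,
                                  t_end = 25, dt = 0.1) {
  t <- seq(0, t_end, by = dt)
  y <- ifelse(t <= t_switch, slopes[1] * t,
              slopes[1] * t_switch + slopes[2] * (t - t_switch))
  list(times = t, ingression = y,
       windows = list(interphase = c(0, t_switch),
                      mphase = c(t_switch, t_end)))
}

# tiny coarse simulation config for fast qualitative runs
coarse_config <- function(...) {
  args <- modifyList(list(target_edge_length = 140, interphase_duration = 2,
                          mphase_duration = 2, record_every = 20L),
                     list(...))
  do.call(sim_config, args)
}
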