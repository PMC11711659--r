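# Shared fixtures: all synthetic, built in code at test time.

# quiet params: no noise, no heartbeat, no latency modulation -> analytically
# predictable rendered traces
quiet_params <- function(...) {
  ear_sim_params(noise_sd = 0, aep_noise_sd = 0, heartbeat_amp = 0,
                 abr_lat_slope = 0, aep_lat_level_slope = 0,
                 aep_lat_iti_slope = 0, ...)
}

# construct an epoched_average directly from a function of time
make_avg <- function(f, time_ms = seq(-10, 150, by = 1), sem = 1,
                     condition = list()) {
  m <- f(time_ms)
  epoched_average(time_ms, m, rep(sem, length(time_ms))[seq_along(m)],
                  n_epochs = 100, condition = condition)
}

gauss_bump <- function(t, lat, amp, width) amp * exp(-(t - lat)^2 / (2 * width^2))

# a synthetic click level series from deflection amplitudes per level:
# deflection at 3 ms, unit SEM
make_level_series <- function(amps, levels = seq(20, 90, by = 5), sem = 1) {
  stopifnot(length(amps) == length(levels))
  mapply(function(a, lv) {
    make_avg(function(t) gauss_bump(t, 3, a, 0.4),
             time_ms = seq(-1, 12, by = 0.05), sem = sem,
             condition = list(level_db = lv))
  }, amps, levels, SIMPLIFY = FALSE)
}

# independent least-squares oracle via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(crossprod(X), crossprod(X, y)))  # (intercept, slope)
}
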