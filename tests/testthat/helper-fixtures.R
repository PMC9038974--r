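# Shared fixtures. Simulations are memoized across test files because the
# default integration (dt = 0.05 s over 360 s) is the expensive step.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Ideal-filter (no recirculation) stress simulation at defaults.
sim_ideal <- function() {
  cached("sim_ideal", simulate_circuit(
    circuit_config(filter_efficiency = 1)))
}

# Realistic leaky filters (efficiency 0.9).
sim_recirc <- function() {
  cached("sim_recirc", simulate_circuit(circuit_config()))
}

# Build a fake simulation truth directly from concentration functions, to
# test the acquisition forward model without the ODE in the loop.
synthetic_truth <- function(aif_fun, tissue_fun = function(t) 0 * t,
                            duration = 345, dt = 0.05,
                            injected_total = 500) {
  cfg <- circuit_config()
  t <- seq(0, duration, by = dt)
  tis_act <- tissue_fun(t) * cfg$tissue_voi_volume  # invert the VOI division
  zmat <- matrix(rep(tis_act, 3), ncol = 3,
                 dimnames = list(NULL, paste0("MYO", 1:3)))
  structure(list(
    time_grid = t,
    in_transit_activity = 0 * t,
    lvc_activity = aif_fun(t) * cfg$lvc_volume,
    segment_free_activity = zmat,
    segment_trapped_activity = zmat * 0,
    reservoir_activity = 0 * t,
    filtered_activity = 0 * t,
    decayed_activity = 0 * t,
    injected_cumulative = 0 * t + injected_total,
    injected_total = injected_total,
    config = cfg,
    sorbents = default_sorbents(),
    injection = injection_protocol(activity = injected_total),
    dt = dt, include_decay = FALSE
  ), class = "simulation_result")
}

# Gamma-variate bolus shape used as a realistic analytic AIF.
gamma_variate <- function(t, t0 = 5, alpha = 3, beta = 4, scale = 1) {
  out <- numeric(length(t))
  up <- t > t0
  out[up] <- scale * ((t[up] - t0) / (alpha * beta))^alpha *
    exp(alpha - (t[up] - t0) / beta)
  out
}

make_tac <- function(times, values, roi = "AIF", ...) {
  tac(times, values, roi = roi, ...)
}
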