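test_that("zero injected activity yields identically zero curves", {
  sim <- simulate_circuit(circuit_config(),
                          injection = injection_protocol(activity = 0),
                          duration = 30)
  expect_equal(max(abs(lvc_concentration(sim))), 0)
  expect_equal(max(abs(sim$segment_trapped_activity)), 0)
  expect_equal(sim$injected_total, 0)
  expect_equal(mass_balance_error(sim), 0)
})

test_that("mass balance holds within 0.1% across configurations", {
  configs <- list(
    default = list(circuit_config(), default_sorbents()),
    ideal = list(circuit_config(filter_efficiency = 1), default_sorbents()),
    zeolite = list(circuit_config(),
                   replicate(3, sorbent_config("zeolite", 7),
                             simplify = FALSE)),
    deficit = list(circuit_config(segment_flows = c(40, 80, 80)),
                   default_sorbents()),
    no_filter = list(circuit_config(filter_efficiency = 0),
                     default_sorbents())
  )
  for (nm in names(configs)) {
    sim <- simulate_circuit(configs[[nm]][[1]], configs[[nm]][[2]],
                            duration = 240)
    expect_lt(mass_balance_error(sim), 1e-3, label = nm)
    expect_true(all(sim$segment_trapped_activity >= 0), label = nm)
    expect_true(all(sim$reservoir_activity >= 0), label = nm)
  }
})

test_that("with perfect filters and irreversible trapping, activity ends up trapped or filtered", {
  sim <- sim_ideal()
  n <- length(sim$time_grid)
  expect_lt(sim$reservoir_activity[n], 1e-6 * sim$injected_total)
  recovered <- sum(sim$segment_trapped_activity[n, ]) + sim$filtered_activity[n]
  expect_equal(recovered, sim$injected_total, tolerance = 1e-3)
  # trapped activity is non-decreasing for every segment
  for (i in 1:3) {
    expect_true(all(diff(sim$segment_trapped_activity[, i]) >= -1e-12))
  }
})

test_that("measured extraction matches the well-mixed closed form E = kV/(Q+kV)", {
  # k_ads*V = 120 mL/min at Q = 80 -> 0.60
  expect_equal(measure_extraction(sim_ideal(), 1), 0.60, tolerance = 0.02)
  # no sorbent -> zero extraction
  sim0 <- simulate_circuit(
    circuit_config(filter_efficiency = 1),
    replicate(3, sorbent_config("none", 0), simplify = FALSE))
  expect_equal(measure_extraction(sim0, 1), 0, tolerance = 1e-6)
  # very strong sorption -> extraction approaches 1
  sim_inf <- simulate_circuit(
    circuit_config(filter_efficiency = 1),
    replicate(3, sorbent_config("activated_carbon", 7, k_ads = 400),
              simplify = FALSE))
  expect_gt(measure_extraction(sim_inf, 1), 0.98)
  # recirculating setup flags a warning
  expect_warning(measure_extraction(sim_recirc(), 1), "recirculating")
})

test_that("default configuration lands inside the physiological 55-65% first-pass window", {
  e <- measure_extraction(sim_ideal(), 2)
  expect_gte(e, 0.55)
  expect_lte(e, 0.65)
})

test_that("curves are linear in the injected activity", {
  sim1 <- cached("sim_lin1", simulate_circuit(
    circuit_config(), injection = injection_protocol(activity = 250),
    duration = 120))
  sim2 <- cached("sim_lin2", simulate_circuit(
    circuit_config(), injection = injection_protocol(activity = 500),
    duration = 120))
  expect_equal(2 * lvc_concentration(sim1), lvc_concentration(sim2),
               tolerance = 1e-10)
  expect_equal(2 * sim1$segment_trapped_activity,
               sim2$segment_trapped_activity, tolerance = 1e-10)
})

test_that("halving a segment flow reduces that segment's early uptake", {
  sim_full <- cached("sim_q80", simulate_circuit(
    circuit_config(filter_efficiency = 1), duration = 120))
  sim_half <- cached("sim_q40", simulate_circuit(
    circuit_config(segment_flows = c(40, 80, 80), filter_efficiency = 1),
    duration = 120))
  auc <- function(sim, i) {
    keep <- sim$time_grid <= 120
    pracma::trapz(sim$time_grid[keep],
                  (sim$segment_free_activity[keep, i] +
                     sim$segment_trapped_activity[keep, i]))
  }
  expect_lt(auc(sim_half, 1), auc(sim_full, 1))
  # untouched segments are barely affected (recirculation is off)
  expect_equal(auc(sim_half, 2), auc(sim_full, 2), tolerance = 0.02)
})

test_that("late tissue slope is positive iff the filters leak", {
  late_slope <- function(sim, i) {
    keep <- sim$time_grid > 120
    tis <- sim$segment_free_activity[keep, i] +
      sim$segment_trapped_activity[keep, i]
    unname(stats::coef(stats::lm(tis ~ sim$time_grid[keep]))[2])
  }
  expect_gt(late_slope(sim_recirc(), 1), 1e-5)   # MBq/s, clearly positive
  expect_lt(abs(late_slope(sim_ideal(), 1)), 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(circuit_config(segment_flows = c(2000, 2000, 2000)),
               "exceeds arterial_flow")
  expect_error(circuit_config(filter_efficiency = 1.2), "filter_efficiency")
  expect_error(circuit_config(reservoir_volume = -1), "positive")
  expect_error(sorbent_config("activated_carbon", 7, k_des = 0.1),
               "irreversibly")
  expect_error(sorbent_config("zeolite", 7, k_des = 0), "reversibly")
  expect_error(simulate_circuit(circuit_config(), dt = 0.5), "dt")
})

test_that("perfusion rate percentages reproduce the protocol table", {
  expect_equal(perfusion_rate_percent(circuit_config(4000, c(80, 40, 80))),
               5.0)
  expect_equal(perfusion_rate_percent(circuit_config(4500, c(100, 100, 100))),
               6.7)
  expect_equal(perfusion_rate_percent(circuit_config(4000, c(50, 100, 100))),
               6.3)
  expect_equal(perfusion_rate_percent(circuit_config(4000, c(0, 0, 0))), 0.0)
})

test_that("sensor log exports tidy 1 Hz series", {
  log <- sensor_log(sim_recirc())
  expect_setequal(names(log), c("time_s", "compartment", "value_MBq"))
  expect_equal(sort(unique(log$time_s)), 0:360)
  expect_equal(length(unique(log$compartment)), 10)
})
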