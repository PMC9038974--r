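test_that("injected-activity normalization scales by reference/injected", {
  t <- seq(0, 100, 5)
  v <- gamma_variate(t)
  same <- normalize_to_injected(make_tac(t, v, injected_activity = 500))
  expect_equal(same$values, v)
  low <- normalize_to_injected(make_tac(t, v, injected_activity = 468))
  expect_equal(low$meta$normalization_factor, 500 / 468)
  expect_equal(low$values, v * 500 / 468)
  high <- normalize_to_injected(make_tac(t, v, injected_activity = 551))
  expect_equal(high$meta$normalization_factor, 500 / 551)
  expect_error(normalize_to_injected(make_tac(t, v)), "injected_activity")
})

test_that("linear resampling preserves endpoints, lines and piecewise-linear AUC", {
  # already-uniform curve at dt comes back unchanged
  t <- seq(0, 20, 0.5)
  v <- sin(t / 3)
  u <- resample_linear(make_tac(t, v), dt = 0.5)
  expect_equal(u$times, t)
  expect_equal(u$values, v)
  # two points interpolate linearly
  two <- resample_linear(make_tac(c(0, 10), c(0, 10)), dt = 5)
  expect_equal(two$times, c(0, 5, 10))
  expect_equal(two$values, c(0, 5, 10))
  # triangle AUC is exact under the trapezoid rule after resampling
  tri <- make_tac(c(0, 30, 60), c(0, 2, 0))
  fine <- resample_linear(tri, dt = 0.5)
  expect_equal(pracma::trapz(fine$times, fine$values), 60)  # 1/2 * 60 * 2
  # non-uniform last interval keeps the exact endpoint
  odd <- resample_linear(make_tac(c(0, 1, 7.3), c(0, 1, 0)), dt = 0.5)
  expect_equal(max(odd$times), 7.3)
})

test_that("spline peak location finds interior maxima to high resolution", {
  # symmetric triangle peaking at t = 30
  tri <- make_tac(seq(0, 60, 2), pmax(0, 30 - abs(seq(0, 60, 2) - 30)))
  expect_equal(locate_peak(tri), 30, tolerance = 0.01)

  # gamma-variate sampled on the clinical frame schedule: spline peak must
  # fall within one frame of the dense-grid argmax oracle
  sched <- default_frame_schedule()
  mid <- sched$start + sched$duration / 2
  g <- make_tac(mid, gamma_variate(mid, t0 = 5, alpha = 3, beta = 4))
  dense_t <- seq(0, 345, 0.001)
  oracle <- dense_t[which.max(gamma_variate(dense_t, t0 = 5, alpha = 3,
                                            beta = 4))]
  expect_lt(abs(locate_peak(g) - oracle), 3)

  # translation equivariance
  shifted <- make_tac(mid + 7.5, g$values)
  expect_equal(locate_peak(shifted), locate_peak(g) + 7.5, tolerance = 1e-6)

  # monotone curve warns and returns the boundary
  mono <- make_tac(0:10, 0:10)
  expect_warning(p <- locate_peak(mono), "boundary")
  expect_equal(p, 10)
})

test_that("AIF peak alignment centres peaks at the mean and shifts TRFs identically", {
  t <- seq(0, 120, 0.5)
  shape <- function(pk) gamma_variate(t, t0 = pk - 12, alpha = 3, beta = 4)
  # identical AIFs: zero shifts
  al0 <- align_curves(list(make_tac(t, shape(30)), make_tac(t, shape(30))))
  expect_equal(al0$shifts, c(0, 0), tolerance = 1e-3)

  # peaks at 28 and 32 s -> shifts +2 and -2
  a1 <- make_tac(t, shape(28))
  a2 <- make_tac(t, shape(32))
  trf1 <- list(MYO1 = make_tac(t, 0.1 * shape(28), roi = "MYO1"))
  trf2 <- list(MYO1 = make_tac(t, 0.1 * shape(32), roi = "MYO1"))
  al <- align_curves(list(a1, a2), list(trf1, trf2))
  expect_equal(al$shifts, c(2, -2), tolerance = 0.02)
  expect_equal(al$trf_sets[[1]]$MYO1$times - t, rep(al$shifts[1], length(t)))

  # curves identical up to a shift: aligning then averaging reproduces the
  # common shape (averaging without alignment would smear it)
  aligned <- common_grid(al$aifs, dt = 0.5)
  ens <- ensemble_stats(aligned, window = c(0, 60))
  ref <- stats::approx(t + al$shifts[1], shape(28),
                       xout = aligned[[1]]$times)$y
  expect_equal(ens$mean_tac$values, ref, tolerance = 0.02)
  expect_lt(max(ens$sd_tac$values), 0.01 * max(ref))

  expect_error(align_curves(list(a1, a2), list(trf1)), "paired")
})

test_that("background subtraction floors at zero and matches paired simulation", {
  t <- seq(1.5, 120, 3)
  stress <- make_tac(t, gamma_variate(t) + 0.05, roi = "MYO1")
  rest0 <- make_tac(t, rep(0, length(t)), roi = "MYO1", scan = "rest")
  expect_equal(subtract_background(stress, rest0)$values, stress$values)

  same <- subtract_background(stress, stress)
  expect_equal(max(abs(same$values)), 0)

  noisy_rest <- make_tac(t, rep(0.06, length(t)), roi = "MYO1", scan = "rest")
  sub <- subtract_background(stress, noisy_rest)
  expect_true(all(sub$values >= 0))
  expect_gt(sub$meta$n_floored, 0)

  expect_error(subtract_background(stress,
                                   make_tac(t, 0 * t, roi = "AIF")),
               "ROI mismatch")

  # paired-simulation oracle: matched forward model, background b vs none
  rest_truth <- simulate_circuit(circuit_config(),
                                 injection = injection_protocol(activity = 0))
  stress_truth <- sim_recirc()
  m_b <- acquisition_model(noise_enabled = FALSE, background_level = 0.04)
  m_0 <- acquisition_model(noise_enabled = FALSE)
  pair <- acquire_rest_stress_pair(rest_truth, stress_truth, model = m_b)
  clean <- acquire_tac(stress_truth, "MYO2", model = m_0)
  recovered <- subtract_background(pair$stress$MYO2, pair$rest$MYO2)
  expect_equal(recovered$values, clean$values, tolerance = 1e-9)
})

test_that("ensemble statistics give sample mean/SD and windowed AUCs", {
  t <- seq(0, 120, 0.5)
  c1 <- make_tac(t, rep(1, length(t)))
  c3 <- make_tac(t, rep(3, length(t)))
  ens <- ensemble_stats(list(c1, c3), window = c(60, 120))
  expect_equal(unique(ens$mean_tac$values), 2)
  expect_equal(unique(ens$sd_tac$values), sqrt(2))
  expect_equal(ens$auc, c(60, 180))           # 60 s window, constants 1 and 3
  expect_equal(ens$auc_mean, 120)
  expect_equal(ens$auc_sd, sd(c(60, 180)))

  # n identical curves -> SD identically zero
  same <- ensemble_stats(list(c1, c1, c1), window = c(0, 60))
  expect_equal(max(same$sd_tac$values), 0)

  # single curve -> SD zero with a flag
  one <- ensemble_stats(list(c1), window = c(0, 60))
  expect_true(one$single_curve)
  expect_equal(max(one$sd_tac$values), 0)

  # AIF curves default to the blood-pool window [0, t1]
  aif_ens <- ensemble_stats(list(c1, c1))
  expect_equal(aif_ens$window, c(0, 60))
  trf_ens <- ensemble_stats(list(make_tac(t, rep(2, length(t)), roi = "MYO1"),
                                 make_tac(t, rep(2, length(t)), roi = "MYO1")))
  expect_equal(trf_ens$window, c(60, 120))
  expect_equal(trf_ens$auc_mean, 120)

  expect_error(ensemble_stats(list(c1, make_tac(t + 1, rep(1, length(t))))),
               "common grid")
})

test_that("normalization and alignment commute", {
  t <- seq(0, 120, 0.5)
  mk <- function(pk, act) make_tac(t, gamma_variate(t, t0 = pk - 12),
                                   injected_activity = act)
  a <- mk(28, 468); b <- mk(32, 551)
  norm_then_align <- align_curves(list(normalize_to_injected(a),
                                       normalize_to_injected(b)))
  align_then_norm <- align_curves(list(a, b))
  align_then_norm$aifs <- lapply(align_then_norm$aifs, normalize_to_injected)
  expect_equal(norm_then_align$shifts, align_then_norm$shifts,
               tolerance = 1e-6)
  expect_equal(norm_then_align$aifs[[1]]$values,
               align_then_norm$aifs[[1]]$values, tolerance = 1e-12)
})

test_that("noise-free matched pipeline reproduces the true tissue curve", {
  sim <- sim_ideal()
  set <- acquire_tac_set(sim, model = acquisition_model(noise_enabled = FALSE))
  # invert the forward model: (P_obs - Sm * Ca_obs) / PV = P_true
  p_rec <- (set$MYO1$values - 0.4 * set$AIF$values) / 0.63
  truth <- frame_average(sim$time_grid, segment_tissue_concentration(sim, 1),
                         default_frame_schedule())
  expect_equal(p_rec, truth, tolerance = 1e-10)
})
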