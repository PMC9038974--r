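test_that("the clinical re-binning schedule has 32 frames over 345 s", {
  sched <- default_frame_schedule()
  expect_equal(nrow(sched), 32)
  expect_equal(sum(sched$duration), 345)
  expect_equal(sched$duration[22], 9)
  expect_equal(sched$duration[1:21], rep(3, 21))
  expect_equal(sched$duration[26:32], rep(30, 7))
  # contiguous, starting at 0
  expect_equal(sched$start[1], 0)
  expect_equal(sched$start[-1], cumsum(sched$duration)[-32])
})

test_that("identity forward model returns frame-averaged truth", {
  truth <- synthetic_truth(aif_fun = function(t) gamma_variate(t),
                           tissue_fun = function(t) 0.1 * pmin(t, 60) / 60)
  model <- acquisition_model(pv_true = 1, spill_blood_to_myo = 0,
                             noise_enabled = FALSE)
  sched <- default_frame_schedule()
  myo <- acquire_tac(truth, "MYO1", sched, model)
  # frame-average oracle computed directly from the dense curve
  expected <- vapply(seq_len(nrow(sched)), function(j) {
    idx <- truth$time_grid >= sched$start[j] - 1e-9 &
      truth$time_grid < sched$start[j] + sched$duration[j] - 1e-9
    mean((truth$segment_free_activity[idx, 1] +
            truth$segment_trapped_activity[idx, 1]) /
           truth$config$tissue_voi_volume)
  }, numeric(1))
  expect_equal(myo$values, expected, tolerance = 1e-12)
  expect_equal(myo$times, sched$start + sched$duration / 2)
})

test_that("with zero tissue truth the myocardial signal is pure spillover", {
  truth <- synthetic_truth(aif_fun = function(t) gamma_variate(t))
  model <- acquisition_model(pv_true = 0.63, spill_blood_to_myo = 0.4,
                             noise_enabled = FALSE)
  myo <- acquire_tac(truth, "MYO1", model = model)
  aif <- acquire_tac(truth, "AIF", model = model)
  expect_equal(myo$values, 0.4 * aif$values, tolerance = 1e-12)
})

test_that("noisy acquisition is reproducible under a seed and unbiased in the mean", {
  truth <- synthetic_truth(aif_fun = function(t) gamma_variate(t, scale = 2))
  m <- acquisition_model(noise_enabled = TRUE, seed = 123)
  a1 <- acquire_tac(truth, "AIF", model = m)
  a2 <- acquire_tac(truth, "AIF", model = m)
  expect_identical(a1$values, a2$values)

  # frame-wise mean over many replicates converges to the noise-off value
  noise_off <- acquire_tac(truth, "AIF",
                           model = acquisition_model(noise_enabled = FALSE))
  sched <- default_frame_schedule()
  n_rep <- 500
  draws <- vapply(seq_len(n_rep), function(r) {
    acquire_tac(truth, "AIF",
                model = acquisition_model(noise_enabled = TRUE,
                                          seed = 1000 + r))$values
  }, numeric(nrow(sched)))
  mu <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(n_rep)
  checkable <- se > 0
  expect_true(all(abs(mu - noise_off$values)[checkable] <=
                    3.5 * se[checkable]))
})

test_that("noise-off acquisition is linear in the truth", {
  truth1 <- synthetic_truth(aif_fun = function(t) gamma_variate(t))
  truth2 <- synthetic_truth(aif_fun = function(t) 3 * gamma_variate(t))
  m <- acquisition_model(noise_enabled = FALSE)
  expect_equal(3 * acquire_tac(truth1, "AIF", model = m)$values,
               acquire_tac(truth2, "AIF", model = m)$values,
               tolerance = 1e-12)
})

test_that("relative frame noise scales as 1/sqrt(sensitivity * duration)", {
  # constant truth, two frame durations differing 9-fold -> noise ratio 3
  truth <- synthetic_truth(aif_fun = function(t) rep(1, length(t)))
  sd_for <- function(dur) {
    sched <- frame_schedule(rep(dur, round(90 / dur)))
    vals <- unlist(lapply(1:200, function(r)
      acquire_tac(truth, "AIF", sched,
                  acquisition_model(noise_enabled = TRUE,
                                    seed = 5000 + r))$values))
    sd(vals)
  }
  ratio <- sd_for(1) / sd_for(9)
  expect_equal(ratio, 3, tolerance = 0.35)
})

test_that("rest/stress pairs behave as baseline plus bolus", {
  rest_truth <- simulate_circuit(circuit_config(),
                                 injection = injection_protocol(activity = 0))
  stress_truth <- sim_recirc()
  sched <- default_frame_schedule()

  # background 0, noise off: rest TACs are exactly zero
  m0 <- acquisition_model(noise_enabled = FALSE)
  pair0 <- acquire_rest_stress_pair(rest_truth, stress_truth, sched, m0)
  expect_equal(max(abs(pair0$rest$AIF$values)), 0)
  expect_equal(max(abs(pair0$rest$MYO2$values)), 0)
  expect_equal(pair0$rest$AIF$scan, "rest")
  expect_equal(pair0$stress$MYO1$scan, "stress")

  # background b, noise off: rest myocardial TAC constant at pv * b
  b <- 0.05
  mb <- acquisition_model(noise_enabled = FALSE, background_level = b)
  pairb <- acquire_rest_stress_pair(rest_truth, stress_truth, sched, mb)
  expect_equal(pairb$rest$MYO1$values, rep(0.63 * b, 32), tolerance = 1e-12)
  # stress minus rest equals the background-free stress acquisition
  expect_equal(pairb$stress$MYO1$values - pairb$rest$MYO1$values,
               pair0$stress$MYO1$values, tolerance = 1e-9)

  # mismatched schedules are rejected at acquisition
  short_sim <- simulate_circuit(circuit_config(), duration = 100)
  expect_error(acquire_tac(short_sim, "AIF", sched), "exceeds")
})

test_that("acquisition model validates its fractions", {
  expect_error(acquisition_model(pv_true = 0), "pv_true")
  expect_error(acquisition_model(spill_blood_to_myo = 1), "spill")
  expect_error(acquisition_model(sensitivity = 0), "sensitivity")
  expect_error(acquisition_model(background_level = c(1, 2)), "background")
})
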