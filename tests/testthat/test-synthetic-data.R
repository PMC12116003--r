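# Synthetic cohort generator: kinetics, IMU, EMG and cohort contracts.

test_that("VO2 kinetics fix to rest at zero intensity and follow the closed-form step response", {
  prof <- subject_profile(vo2_rest = 5, vo2_peak = 40, tau_on = 30)
  cfg <- quiet_config()
  # zero intensity everywhere: rest is the fixed point
  rest <- simulate_vo2_trace(one_bout_script(intensity = 0, load = 0, rate = 0,
                                             duration = 120), prof, cfg)
  expect_equal(rest$vo2, rep(5, 120))
  # full step at t = 0: after 5 time constants the deficit is e^-5
  step <- simulate_vo2_trace(one_bout_script(intensity = 1, duration = 200),
                             prof, cfg)
  expect_lt(abs(step$vo2_truth[151] - prof$vo2_peak) / prof$vo2_peak, 0.01)
  # exact discretization: deficit after n steps is exactly e^(-n/tau)
  expect_equal(step$vo2_truth[151],
               prof$vo2_peak - (prof$vo2_peak - prof$vo2_rest) * exp(-150 / 30),
               tolerance = 1e-10)
})

test_that("VO2 simulation is seed-deterministic and validates its script", {
  prof <- subject_profile()
  cfg <- generator_config(seed = 9L, vo2_noise_sd = 1)
  a <- simulate_vo2_trace(three_bout_script(), prof, cfg)
  b <- simulate_vo2_trace(three_bout_script(), prof, cfg)
  expect_identical(a$vo2, b$vo2)
  cfg2 <- generator_config(seed = 10L, vo2_noise_sd = 1)
  expect_false(identical(a$vo2, simulate_vo2_trace(three_bout_script(), prof, cfg2)$vo2))
  expect_error(activity_script(data.frame()), "at least one bout")
  expect_error(activity_script(data.frame(start_s = 0, duration_s = -5,
                                          intensity = 0.5, load_kg = 0,
                                          motion_rate_hz = 1)),
               "positive")
})

test_that("VO2 stays within the rest/peak envelope widened by 4 noise SDs", {
  prof <- subject_profile()
  cfg <- generator_config(seed = 3L)       # default noise
  v <- simulate_vo2_trace(scaffold_script(bout_s = 120, rest_s = 30), prof, cfg)$vo2
  lo <- prof$vo2_rest - 4 * cfg$vo2_noise_sd
  hi <- prof$vo2_peak + 4 * cfg$vo2_noise_sd
  expect_gte(mean(v >= lo & v <= hi), 0.999)
})

test_that("IMU streams carry gravity at rest and sinusoid variance A^2/2 during bouts", {
  cfg <- quiet_config()
  rest <- simulate_imu(one_bout_script(intensity = 0, load = 0, rate = 0,
                                       duration = 60), cfg)
  res <- sqrt(rowSums(rest$accel^2))
  expect_equal(res, rep(1, length(res)), tolerance = 1e-12)
  # ax carries amplitude 0.5 * intensity; 60 s bout, noise off
  intensity <- 0.8
  imu <- simulate_imu(one_bout_script(intensity = intensity, rate = 1.3,
                                      duration = 60), cfg)
  A <- 0.5 * intensity
  v <- mean(imu$accel[, 1]^2) - mean(imu$accel[, 1])^2
  expect_lt(abs(v - A^2 / 2) / (A^2 / 2), 0.02)
})

test_that("gyro amplitude grows strictly with intensity and motion above Nyquist errors", {
  cfg <- quiet_config()
  sds <- vapply(c(0.2, 0.4, 0.8), function(i) {
    g <- simulate_imu(one_bout_script(intensity = i, duration = 60), cfg)$gyro
    sd(g[, 3])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_error(simulate_imu(one_bout_script(rate = 26), generator_config()),
               "Nyquist")
})

test_that("EMG respects the signed 8-bit range and its envelope tracks load", {
  cfg <- generator_config(seed = 5L)
  script <- activity_script(data.frame(
    start_s = c(0, 70, 140), duration_s = 60, intensity = 0.5,
    load_kg = c(0, 10, 20), motion_rate_hz = 1), total_s = 260)
  emg <- simulate_emg(script, cfg)$emg
  expect_true(all(emg >= -128 & emg <= 127))
  expect_true(all(emg == round(emg)))
  # mean |EMG| per bout ranks with load; rest stays below every bout
  t <- (seq_len(nrow(emg)) - 1) / cfg$emg_rate
  amp <- vapply(c(0, 70, 140), function(s)
    mean(abs(emg[t >= s & t < s + 60, ])), numeric(1))
  rest_amp <- mean(abs(emg[t >= 200, ]))
  expect_identical(order(amp), 1:3)
  expect_true(all(rest_amp < amp))
})

test_that("EMG with zero intensity, load and noise floor is silent", {
  cfg <- quiet_config()
  emg <- simulate_emg(one_bout_script(intensity = 0, load = 0, rate = 0,
                                      duration = 10), cfg)$emg
  expect_true(all(emg == 0L))
})

test_that("stream lengths equal duration times nominal rate for all modalities", {
  script <- three_bout_script(duration = 40, gap = 7)   # total 134 s
  prof <- subject_profile()
  rec <- simulate_recording(script, prof, generator_config(seed = 2L))
  expect_equal(nrow(rec$vo2$values), ceiling(script$total_s))
  expect_equal(nrow(rec$accel$values), script$total_s * 50)
  expect_equal(nrow(rec$gyro$values), script$total_s * 50)
  expect_equal(nrow(rec$emg$values), script$total_s * 200)
})

test_that("cohorts have distinct jittered profiles, full determinism and LOSO-sized minimum", {
  script <- activity_script(data.frame(
    start_s = seq(0, by = 300, length.out = 14), duration_s = 300,
    intensity = rep(c(0.3, 0.6, 0.9), length.out = 14),
    load_kg = rep(c(0, 8, 17), length.out = 14),
    motion_rate_hz = 1.2))
  co <- generate_cohort(2, script, seed = 21L)
  expect_length(co, 2L)
  # 14 five-minute bouts back to back: 4200 one-second VO2 samples
  expect_equal(nrow(co[[1]]$vo2$values), 4200L)
  expect_false(co[[1]]$mass_kg == co[[2]]$mass_kg)
  co2 <- generate_cohort(2, script, seed = 21L)
  expect_identical(co[[1]]$emg$values, co2[[1]]$emg$values)
  expect_identical(co[[2]]$vo2$values, co2[[2]]$vo2$values)
  expect_error(generate_cohort(1, script), "LOSO")
})

test_that("noise-free per-bout feature means are rank-monotone in intensity", {
  script <- three_bout_script(duration = 30, gap = 5,
                              intensities = c(0.2, 0.5, 0.9),
                              loads = c(5, 5, 5))
  rec <- simulate_recording(script, subject_profile(), quiet_config())
  tab <- build_feature_table(rec)
  bouts <- list(c(0, 30), c(35, 65), c(70, 100))
  acc_mean <- vapply(bouts, function(b)
    mean(tab$res_acc_avg[tab$second >= b[1] & tab$second < b[2]]), numeric(1))
  emg_mean <- vapply(bouts, function(b)
    mean(tab$EMGsum_avg[tab$second >= b[1] & tab$second < b[2]]), numeric(1))
  expect_equal(cor(acc_mean, 1:3, method = "spearman"), 1)
  expect_equal(cor(emg_mean, 1:3, method = "spearman"), 1)
})
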