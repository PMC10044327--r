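test_that("identical configurations generate identical sessions", {
  cfg <- session_config("pcm", duration_s = 10, seed = 7)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$emg, s2$emg)
  expect_identical(s1$imu, s2$imu)
  expect_identical(s1$wrench, s2$wrench)
  expect_identical(s1$ground_truth$activations, s2$ground_truth$activations)
})

test_that("streams carry the configured rates and durations", {
  sess <- pcm_session_30()
  expect_equal(nrow(sess$emg), round(30 * 1111.11))
  expect_equal(nrow(sess$imu), round(30 * 148.148))
  expect_equal(nrow(sess$wrench), round(30 * 148.148))
  expect_equal(diff(sess$emg$time[1:2]), 1 / 1111.11, tolerance = 1e-9)
  expect_named(sess$emg, c("time", sprintf("emg_%02d", 1:10)))
  # activations on the 74.074 Hz feature timebase, bounded in [0, 1]
  act <- sess$ground_truth$activations
  expect_equal(diff(act$time[1:2]), 2 / 148.148, tolerance = 1e-9)
  vals <- unlist(act[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("posture-control sessions have no step events; zero sway gives baseline", {
  sess <- pcm_session_30()
  expect_equal(nrow(sess$ground_truth$step_events), 0)
  cfg0 <- session_config("pcm", duration_s = 10, seed = 3,
                         sway_amplitude_deg = 0,
                         noise_levels = list(activation = 0))
  act0 <- generate_activations(cfg0)
  for (ch in sprintf("emg_%02d", 1:10)) {
    expect_lt(diff(range(act0[[ch]])), 1e-12)
  }
  expect_error(session_config("hop"), "motion_type")
})

test_that("step count matches the configured rate and bursts precede shear", {
  sess <- sm_session_40()
  ev <- sess$ground_truth$step_events
  expect_lte(abs(nrow(ev) - round(40 * 0.4)), 1)
  expect_true(all(ev$direction %in% c("left", "right", "forward")))

  # burst peak in the step's prime mover precedes the wrench onset by the
  # electromechanical lead (50-150 ms)
  act <- sess$ground_truth$activations
  prime <- c(left = "emg_06", right = "emg_03", forward = "emg_02")
  leads <- vapply(seq_len(nrow(ev)), function(k) {
    ch <- prime[[ev$direction[k]]]
    win <- act$time > ev$time[k] - 0.35 & act$time < ev$time[k] + 0.1
    peak_t <- act$time[win][which.max(act[[ch]][win])]
    ev$time[k] - peak_t
  }, numeric(1))
  expect_true(all(leads > 0.02 & leads < 0.2))
  expect_gte(mean(leads), 0.05)
  expect_lte(mean(leads), 0.15)
})

test_that("synthesized EMG is carrier-borne in the 20-450 Hz band", {
  cfg <- session_config("pcm", duration_s = 8, seed = 5,
                        noise_levels = list(emg = 0),
                        artifact_amplitude = 0)
  # constant full activation
  act <- generate_activations(cfg)
  act[sprintf("emg_%02d", 1:10)] <- 1
  emg <- synthesize_emg(act, cfg)
  expect_lt(abs(mean(emg$emg_01)), 0.02)
  expect_gt(band_power_fraction(emg$emg_01, 1111.11, 20, 450), 0.95)
  # zero activation, zero noise -> silence
  act[sprintf("emg_%02d", 1:10)] <- 0
  emg0 <- synthesize_emg(act, cfg)
  expect_equal(max(abs(unlist(emg0[, -1]))), 0)
})

test_that("IMU statics and sway spectra behave physically", {
  cfg0 <- session_config("pcm", duration_s = 10, seed = 2,
                         sway_amplitude_deg = 0,
                         noise_levels = list(imu = 0, activation = 0))
  com0 <- generate_com_state(cfg0)
  imu0 <- synthesize_imu(com0, generate_step_events(cfg0), cfg0)
  expect_equal(mean(imu0$imu1_acc_z), 9.81, tolerance = 1e-6)
  expect_lt(max(abs(imu0$imu1_gyro_y)), 1e-9)

  sess <- pcm_session_30()
  peak <- dominant_freq(sess$imu$imu1_gyro_y, 148.148)
  # periodogram resolution at 30 s is 1/30 Hz
  expect_lt(abs(peak - 0.25), 1 / 30 + 1e-6)
  # thigh sensors carry larger tilt gain than shank sensors
  expect_gt(sd(sess$imu$imu7_gyro_y), sd(sess$imu$imu1_gyro_y))
})

test_that("wrench supports body weight and balances over sway cycles", {
  sess <- pcm_session_30()
  mg <- 70 * 9.81
  expect_lt(abs(mean(sess$wrench$Fz) - mg) / mg, 0.01)
  # no net horizontal impulse over whole sway cycles
  w <- sess$wrench
  n_cycles <- floor(max(w$time) * 0.25)
  keep <- w$time <= n_cycles / 0.25
  dt <- 1 / 148.148
  impulse <- sum(w$Fx[keep]) * dt
  expect_lt(abs(impulse), 0.02 * sd(w$Fx) * sum(keep) * dt)
})

test_that("a leftward step produces a positive (leftward) Fy transient at onset", {
  sess <- sm_session_40()
  ev <- sess$ground_truth$step_events
  w <- sess$wrench
  for (k in which(ev$direction == "left")) {
    win <- w$time >= ev$time[k] & w$time <= ev$time[k] + 0.3
    expect_gt(mean(w$Fy[win]), 10)
  }
  for (k in which(ev$direction == "right")) {
    win <- w$time >= ev$time[k] & w$time <= ev$time[k] + 0.3
    expect_lt(mean(w$Fy[win]), -10)
  }
})
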