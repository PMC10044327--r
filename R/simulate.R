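# Synthetic session generator.
#
# Master timebase is the IMU/plate rate (148.148 Hz); muscle activations
# are reported on the 74.074 Hz feature timebase (integer decimation by 2).
# Coordinate convention: x = anteroposterior (+forward), y = mediolateral
# (+left), z = vertical (+up); moments right-handed about these axes.

# Deterministic sub-seeds per generation stage, so every public operation
# is reproducible both standalone and inside generate_session().
stage_seed <- function(config, stage) {
  off <- c(com = 11L, steps = 13L, activation = 17L, emg = 19L,
           imu = 23L, wrench = 29L)[[stage]]
  (config$seed %% 100000L) * 1000L + off
}

# Smooth band-limited noise: white Gaussian low-passed at `cutoff_hz`,
# rescaled to the requested standard deviation.
smooth_noise <- function(n, fs, cutoff_hz, sd_target) {
  if (sd_target <= 0 || n < 60) return(rep(0, n))
  lp <- design_filter("lowpass", cutoff_hz, fs = fs, order = 2)
  x <- apply_filter(rnorm(n), lp)
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  x * (sd_target / s)
}

# Central-difference derivative on a uniform grid.
num_deriv <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Shift a series by `k` samples (k > 0 advances: value at t becomes the
# value at t + k / fs), padding edges with the boundary value.
shift_series <- function(x, k) {
  n <- length(x)
  k <- as.integer(round(k))
  if (k == 0) return(x)
  if (k > 0) c(x[(k + 1):n], rep(x[n], min(k, n))) [seq_len(n)]
  else c(rep(x[1], min(-k, n)), x[seq_len(n + k)]) [seq_len(n)]
}

softplus4 <- function(x) log1p(exp(pmin(4 * x, 30))) / 4

# Biphasic step-transient shape over u in [0, 1]: a main lobe followed by
# a smaller opposite-signed rebound, zero outside.
step_shape <- function(u) {
  ifelse(u >= 0 & u <= 1, sin(2 * pi * u) * exp(-2.5 * u), 0)
}

step_bell <- function(u) ifelse(u >= 0 & u <= 1, sin(pi * u)^2, 0)

STEP_DURATION_S <- 0.8
# step_shape() peaks at ~0.57, so these give peak shear ~20% and peak
# vertical unloading ~9% of body weight -- brisk step initiation
STEP_SHEAR_FRAC <- 0.35
STEP_UNLOAD_FRAC <- 0.15

#' Generate step events for a stepping-motion session
#'
#' Draws step onsets at the configured mean rate with timing jitter, a
#' direction (left / right / forward), a relative amplitude and the
#' per-step activation-to-force lead time.
#'
#' @param config A [session_config()]; `"pcm"` sessions yield zero rows.
#' @return Tibble with `time` (s), `direction`, `amplitude`,
#'   `duration_s` and `lead_s`.
#' @export
generate_step_events <- function(config) {
  stopifnot(inherits(config, "grf_config"))
  if (config$motion_type != "sm") {
    return(tibble::tibble(
      time = numeric(0), direction = character(0),
      amplitude = numeric(0), duration_s = numeric(0), lead_s = numeric(0)
    ))
  }
  withr::with_seed(stage_seed(config, "steps"), {
    n <- round(config$duration_s * config$step_rate_hz)
    onset <- (seq_len(n) - 0.5) / config$step_rate_hz +
      runif(n, -0.25, 0.25)
    keep <- onset > 1.0 & onset < config$duration_s - 1.5
    ord <- order(onset[keep])
    tibble::tibble(
      time = sort(onset[keep]),
      direction = sample(c("left", "right", "forward"), sum(keep),
                         replace = TRUE)[ord],
      amplitude = pmax(1 + 0.25 * rnorm(sum(keep)), 0.5)[ord],
      duration_s = (STEP_DURATION_S * (1 + 0.2 * runif(sum(keep), -1, 1)))[ord],
      lead_s = pmin(pmax(
        config$lead_time_s +
          runif(sum(keep), -config$lead_jitter_s, config$lead_jitter_s),
        0.05), 0.15)[ord]
    )
  })
}

#' Generate the centre-of-mass state of a session
#'
#' Inverted-pendulum sway about the ankle: quasi-periodic anteroposterior
#' and mediolateral tilt (a dominant component, a weaker incommensurate
#' component and a slow stochastic drift), a small vertical bob, and -- for
#' stepping sessions -- per-step horizontal and vertical acceleration
#' transients in the stepped direction.
#'
#' @param config A [session_config()].
#' @param step_events Step event tibble; defaults to
#'   [generate_step_events()] for the config.
#' @return Tibble at 148.148 Hz: `time`, tilt angles `theta_ap`,
#'   `theta_ml` (rad), angular velocities `omega_*` (rad/s), angular
#'   accelerations `alpha_*` (rad/s^2) and linear centre-of-mass
#'   accelerations `acc_x`, `acc_y`, `acc_z` (m/s^2).
#' @export
generate_com_state <- function(config, step_events = generate_step_events(config)) {
  stopifnot(inherits(config, "grf_config"))
  fs <- FS_IMU
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f <- config$sway_frequency_hz
  A <- config$sway_amplitude_deg * pi / 180
  sway_scale <- if (config$motion_type == "sm") 0.3 else 1.0
  A <- A * sway_scale

  withr::with_seed(stage_seed(config, "com"), {
    drift_ap <- smooth_noise(n, fs, 0.15, 0.12 * A)
    drift_ml <- smooth_noise(n, fs, 0.15, 0.12 * A)
    theta_ap <- A * (sin(2 * pi * f * t) +
                       0.35 * sin(2 * pi * 2.2 * f * t + 1.3)) + drift_ap
    theta_ml <- 0.6 * A * (sin(2 * pi * 0.8 * f * t + 0.5) +
                             0.35 * sin(2 * pi * 1.9 * f * t + 2.1)) + drift_ml
    # vertical bob at twice the sway frequency (com height varies with
    # tilt amplitude squared)
    acc_z <- if (A > 0) {
      0.25 * sway_scale * sin(2 * pi * 2 * f * t + 0.7) +
        smooth_noise(n, fs, 1, 0.02 * sway_scale)
    } else rep(0, n)
  })

  omega_ap <- num_deriv(theta_ap, fs)
  omega_ml <- num_deriv(theta_ml, fs)
  alpha_ap <- num_deriv(omega_ap, fs)
  alpha_ml <- num_deriv(omega_ml, fs)

  # horizontal com acceleration from the pendulum (small-angle)
  acc_x <- config$com_height_m * alpha_ap
  acc_y <- config$com_height_m * alpha_ml

  g <- GRAVITY
  if (nrow(step_events) > 0) {
    for (k in seq_len(nrow(step_events))) {
      u <- (t - step_events$time[k]) / step_events$duration_s[k]
      s <- step_events$amplitude[k] * step_shape(u)
      dirn <- step_events$direction[k]
      if (dirn == "left") acc_y <- acc_y + STEP_SHEAR_FRAC * g * s
      if (dirn == "right") acc_y <- acc_y - STEP_SHEAR_FRAC * g * s
      if (dirn == "forward") acc_x <- acc_x + STEP_SHEAR_FRAC * g * s
      acc_z <- acc_z - STEP_UNLOAD_FRAC * g * s
    }
  }

  tibble::tibble(
    time = t,
    theta_ap = theta_ap, theta_ml = theta_ml,
    omega_ap = omega_ap, omega_ml = omega_ml,
    alpha_ap = alpha_ap, alpha_ml = alpha_ml,
    acc_x = acc_x, acc_y = acc_y, acc_z = acc_z
  )
}

# Per-sensor gain of the drive mapping, a fixed mild left/right asymmetry
# so channels are informative but not collinear.
muscle_gain_jitter <- c(1.04, 0.97, 1.02, 0.96, 1.03, 0.99, 1.01, 0.98, 1.02, 0.97)

# Neural drives (before clipping) for the 10 sensors of the sensor map, on
# the master 148.148 Hz grid. Drives respond to the com state *advanced*
# by the nominal lead time: activation precedes force generation.
muscle_drives <- function(config, com, step_events) {
  fs <- FS_IMU
  k_lead <- round(config$lead_time_s * fs)
  A <- max(config$sway_amplitude_deg, 0.5) * pi / 180 *
    (if (config$motion_type == "sm") 0.3 else 1.0)
  s_ap <- shift_series(com$theta_ap + 0.25 * com$omega_ap /
                         (2 * pi * config$sway_frequency_hz), k_lead) / A
  s_ml <- shift_series(com$theta_ml + 0.25 * com$omega_ml /
                         (2 * pi * config$sway_frequency_hz), k_lead) / (0.6 * A)
  base <- 0.12
  drives <- list(
    # sensors 1..10 per the sensor map: TA, GAS, PL (right 1-3, left 4-6),
    # RF, ST (right 7-8, left 9-10)
    base + 0.45 * softplus4(-s_ap),  # 1 TA right
    base + 0.45 * softplus4(s_ap),   # 2 GAS right
    base + 0.40 * softplus4(s_ml),   # 3 PL right (loads when leaning left)
    base + 0.45 * softplus4(-s_ap),  # 4 TA left
    base + 0.45 * softplus4(s_ap),   # 5 GAS left
    base + 0.40 * softplus4(-s_ml),  # 6 PL left
    base + 0.18 * softplus4(s_ap),   # 7 RF right
    base + 0.18 * softplus4(-s_ap),  # 8 ST right
    base + 0.18 * softplus4(s_ap),   # 9 RF left
    base + 0.18 * softplus4(-s_ap)   # 10 ST left
  )
  drives <- purrr::map2(drives, muscle_gain_jitter, `*`)

  if (nrow(step_events) > 0) {
    t <- com$time
    burst_targets <- list(
      left = c(6, 4, 2) , right = c(3, 1, 5), forward = c(2, 5, 1)
    )
    burst_gains <- c(0.55, 0.45, 0.2)
    for (k in seq_len(nrow(step_events))) {
      centre <- step_events$time[k] - step_events$lead_s[k]
      bump <- step_events$amplitude[k] *
        exp(-0.5 * ((t - centre) / 0.07)^2)
      idx <- burst_targets[[step_events$direction[k]]]
      for (j in seq_along(idx)) {
        drives[[idx[j]]] <- drives[[idx[j]]] + burst_gains[j] * bump
      }
    }
  }
  drives
}

#' Generate ground-truth muscle activations
#'
#' Returns the 10 muscle-activation series (one per EMG sensor, bounded in
#' \[0, 1\]) at the 74.074 Hz feature timebase. Posture-control drives are
#' smooth antagonist pairs phase-locked to the sway (TA/GAS for
#' anteroposterior, left/right PL for mediolateral, weaker RF/ST at the
#' thigh); stepping sessions add direction-specific bursts whose peak
#' precedes the step onset by the per-step lead time (50--150 ms).
#'
#' @param config A [session_config()].
#' @param com Optional precomputed [generate_com_state()] output.
#' @param step_events Optional precomputed [generate_step_events()] output.
#' @return Tibble: `time` plus `emg_01` .. `emg_10` activation columns.
#' @export
generate_activations <- function(config,
                                 step_events = generate_step_events(config),
                                 com = generate_com_state(config, step_events)) {
  stopifnot(inherits(config, "grf_config"))
  drives <- muscle_drives(config, com, step_events)
  n <- nrow(com)
  withr::with_seed(stage_seed(config, "activation"), {
    noise <- lapply(seq_len(10), function(j) {
      smooth_noise(n, FS_IMU, 0.8, config$noise_levels$activation)
    })
  })
  act <- purrr::map2(drives, noise, ~ pmin(pmax(.x + .y, 0), 1))
  out <- tibble::as_tibble(stats::setNames(act, emg_col(1:10)))
  out <- dplyr::bind_cols(tibble::tibble(time = com$time), out)
  decimate_stream(out, fs = FS_IMU, fs_out = FS_FEAT)
}

#' Synthesize raw surface EMG from activations
#'
#' Each channel is a zero-mean Gaussian carrier band-limited to 20--450 Hz,
#' amplitude-modulated by the (upsampled) activation, plus baseline white
#' noise and a sub-20 Hz motion-artifact drift. The informative content
#' therefore lives entirely in the 20--450 Hz band, as assumed by the
#' band-pass stage.
#'
#' @param activations Activation tibble at 74.074 Hz
#'   (from [generate_activations()]).
#' @param config A [session_config()].
#' @param fs_emg EMG sampling rate (default 1111.11 Hz).
#' @return Tibble: `time` plus `emg_01` .. `emg_10` raw EMG (arbitrary mV
#'   scale).
#' @export
synthesize_emg <- function(activations, config, fs_emg = FS_EMG) {
  stopifnot(inherits(config, "grf_config"))
  n <- round(config$duration_s * fs_emg)
  t <- (seq_len(n) - 1) / fs_emg
  bp <- design_filter("bandpass", c(20, 450), fs = fs_emg)
  lp_drift <- design_filter("lowpass", 6, fs = fs_emg)
  chans <- emg_col(1:10)
  out <- withr::with_seed(stage_seed(config, "emg"), {
    lapply(chans, function(ch) {
      a <- approx(activations$time, activations[[ch]], xout = t, rule = 2)$y
      carrier <- apply_filter(rnorm(n), bp)
      carrier <- carrier / sd(carrier)
      sig <- a * carrier
      if (config$noise_levels$emg > 0) {
        sig <- sig + config$noise_levels$emg * rnorm(n)
      }
      if (config$artifact_amplitude > 0) {
        drift <- apply_filter(rnorm(n), lp_drift)
        sig <- sig + config$artifact_amplitude * drift / sd(drift)
      }
      sig
    })
  })
  dplyr::bind_cols(
    tibble::tibble(time = t),
    tibble::as_tibble(stats::setNames(out, chans))
  )
}

IMU_SENSORS <- c(1L, 4L, 7L, 9L)
# distinct segment gains: shank sensors (1, 4) move less than thigh
# sensors (7, 9) during ankle-strategy sway
imu_segment_gain <- c(`1` = 0.7, `4` = 0.72, `7` = 1.25, `9` = 1.2)

#' Synthesize IMU signals from the centre-of-mass state
#'
#' Accelerometer channels combine the gravity projection under segment
#' tilt with the segment's share of the linear com acceleration; gyro
#' channels carry the segment angular velocity. Shank sensors (1, 4) and
#' thigh sensors (7, 9) use distinct segment gains, and the stepping leg's
#' sensors receive per-step transients.
#'
#' @param com Tibble from [generate_com_state()].
#' @param step_events Tibble from [generate_step_events()].
#' @param config A [session_config()].
#' @param fs_imu IMU sampling rate (default 148.148 Hz).
#' @return Tibble: `time` plus 6 channels per sensor
#'   (`imu1_acc_x` .. `imu9_gyro_z`); acceleration in m/s^2, angular
#'   velocity in rad/s.
#' @export
synthesize_imu <- function(com, step_events, config, fs_imu = FS_IMU) {
  stopifnot(inherits(config, "grf_config"))
  g <- GRAVITY
  t <- com$time
  n <- length(t)
  acc_sd <- config$noise_levels$imu * g * 0.3
  gyro_sd <- config$noise_levels$imu * 1.0

  step_leg <- c(left = 4L, right = 1L, forward = 1L)
  step_thigh <- c(`1` = 7L, `4` = 9L)

  cols <- list(time = t)
  withr::with_seed(stage_seed(config, "imu"), {
    for (s in IMU_SENSORS) {
      k <- imu_segment_gain[[as.character(s)]]
      acc_x <- g * sin(k * com$theta_ap) + k * com$acc_x
      acc_y <- g * sin(k * com$theta_ml) + k * com$acc_y
      acc_z <- g * cos(k * com$theta_ap) * cos(k * com$theta_ml) + k * com$acc_z
      gyro_x <- k * com$omega_ml
      gyro_y <- k * com$omega_ap
      gyro_z <- 0.05 * k * (com$omega_ap + com$omega_ml)
      if (nrow(step_events) > 0) {
        for (i in seq_len(nrow(step_events))) {
          shank <- step_leg[[step_events$direction[i]]]
          gain <- if (s == shank) 1 else if (s == step_thigh[[as.character(shank)]]) 0.4 else 0.15
          u <- (t - step_events$time[i]) / step_events$duration_s[i]
          bump <- gain * step_events$amplitude[i] * step_bell(u)
          acc_z <- acc_z + 1.5 * bump
          gyro_y <- gyro_y + 1.0 * bump
          sgn <- switch(step_events$direction[i], left = 1, right = -1, forward = 0)
          acc_y <- acc_y + sgn * 1.2 * bump
          if (step_events$direction[i] == "forward") acc_x <- acc_x + 1.2 * bump
        }
      }
      chans <- list(acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z)
      sds <- c(acc_sd, acc_sd, acc_sd, gyro_sd, gyro_sd, gyro_sd)
      chans <- purrr::map2(chans, sds, function(x, s_) {
        if (s_ > 0) x + s_ * rnorm(n) else x
      })
      cols[imu_cols(s)] <- chans
    }
  })
  tibble::as_tibble(cols)
}

#' Synthesize the force-plate wrench
#'
#' Newton--Euler assembly about a common plate origin: `Fz` supports body
#' weight plus the vertical inertial term; `Fx`, `Fy` follow the
#' horizontal centre-of-mass acceleration; `Mx`, `My` arise from
#' centre-of-pressure excursions driven by ankle-muscle activation
#' differences (delayed by the electromechanical lead); `Mz` is a small
#' activation-asymmetry term. Stepping sessions superpose per-step
#' unloading / loading and shear transients in the stepped direction
#' through the com state.
#'
#' @param activations Tibble from [generate_activations()] (74.074 Hz).
#' @param com Tibble from [generate_com_state()].
#' @param step_events Tibble from [generate_step_events()].
#' @param config A [session_config()].
#' @return Tibble at the plate rate (148.148 Hz): `time`, `Fx`, `Fy`, `Fz`
#'   (N), `Mx`, `My`, `Mz` (N m).
#' @export
synthesize_wrench <- function(activations, com, step_events, config) {
  stopifnot(inherits(config, "grf_config"))
  m <- config$body_mass_kg
  g <- GRAVITY
  t <- com$time
  n <- length(t)
  # activations on the master grid, then *delayed* by the lead time:
  # force follows activation
  k_lead <- round(config$lead_time_s * FS_IMU)
  act <- lapply(emg_col(1:10), function(ch) {
    shift_series(approx(activations$time, activations[[ch]], xout = t,
                        rule = 2)$y, -k_lead)
  })
  names(act) <- emg_col(1:10)

  Fx <- m * com$acc_x
  Fy <- m * com$acc_y
  Fz <- m * (g + com$acc_z)

  gas_minus_ta <- ((act$emg_02 + act$emg_05) - (act$emg_01 + act$emg_04)) / 2
  pl_asym <- act$emg_03 - act$emg_06
  x_cop <- 0.08 * (gas_minus_ta - mean(gas_minus_ta))
  y_cop <- 0.08 * (pl_asym - mean(pl_asym))
  if (nrow(step_events) > 0) {
    for (k in seq_len(nrow(step_events))) {
      u <- (t - step_events$time[k]) / step_events$duration_s[k]
      bump <- step_events$amplitude[k] * 0.03 * step_bell(u)
      sgn_y <- switch(step_events$direction[k], left = 1, right = -1, forward = 0)
      y_cop <- y_cop + sgn_y * bump
      if (step_events$direction[k] == "forward") x_cop <- x_cop + bump
    }
  }
  Mx <- y_cop * Fz
  My <- -x_cop * Fz
  ankle_asym <- (act$emg_01 + act$emg_02 + act$emg_03 -
                   act$emg_04 - act$emg_05 - act$emg_06) / 3
  Mz <- 5 * (ankle_asym - mean(ankle_asym))

  out <- tibble::tibble(time = t, Fx = Fx, Fy = Fy, Fz = Fz,
                        Mx = Mx, My = My, Mz = Mz)
  lvl <- config$noise_levels$wrench
  if (lvl > 0) {
    withr::with_seed(stage_seed(config, "wrench"), {
      for (ch in wrench_channels()) {
        s <- sd(out[[ch]])
        if (s > 0) out[[ch]] <- out[[ch]] + lvl * s * rnorm(n)
      }
    })
  }
  out
}

#' Generate a complete synthetic session
#'
#' Runs the full generative model and returns the multi-rate recording
#' (EMG at 1111.11 Hz, IMU and wrench at 148.148 Hz) together with the
#' ground-truth bundle (activations at 74.074 Hz, com state, step events).
#' Identical configurations (including the seed) give identical sessions.
#'
#' @param config A [session_config()].
#' @return A `grf_session`: list with `emg`, `imu`, `wrench` tibbles,
#'   `rates`, `config` and `ground_truth`.
#' @examples
#' sess <- generate_session(session_config("pcm", duration_s = 10, seed = 1))
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "grf_config"))
  step_events <- generate_step_events(config)
  com <- generate_com_state(config, step_events)
  activations <- generate_activations(config, step_events, com)
  structure(
    list(
      emg = synthesize_emg(activations, config),
      imu = synthesize_imu(com, step_events, config),
      wrench = synthesize_wrench(activations, com, step_events, config),
      rates = list(emg = FS_EMG, imu = FS_IMU, wrench = FS_IMU),
      config = config,
      ground_truth = list(
        activations = activations,
        com_state = com,
        step_events = step_events
      )
    ),
    class = "grf_session"
  )
}

#' @export
print.grf_session <- function(x, ...) {
  cat(sprintf(
    "<grf_session> %s, %.5g s (EMG %d x 10 @ %.2f Hz; IMU %d x 24 @ %.3f Hz; wrench %d x 6)\n",
    toupper(x$config$motion_type), x$config$duration_s,
    nrow(x$emg), x$rates$emg, nrow(x$imu), x$rates$imu, nrow(x$wrench)
  ))
  if (nrow(x$ground_truth$step_events) > 0) {
    cat(sprintf("  %d step events\n", nrow(x$ground_truth$step_events)))
  }
  invisible(x)
}
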