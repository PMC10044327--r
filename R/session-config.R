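#' Configuration for a synthetic recording session
#'
#' Defines the study conditions a generated session emulates: a standing
#' subject on force plates either swaying (posture control motion, `"pcm"`)
#' or making discrete steps left / right / forward (`"sm"`), recorded with
#' 10 EMG sensors, 4 IMUs and a force plate wrench.
#'
#' @param motion_type `"pcm"` (posture control) or `"sm"` (stepping).
#' @param duration_s Session length in seconds (default 120).
#' @param seed Integer seed; the whole session is a deterministic function
#'   of the configuration including this seed.
#' @param sway_frequency_hz Dominant anteroposterior sway frequency (Hz).
#' @param sway_amplitude_deg Peak anteroposterior sway angle (degrees).
#'   Zero gives quiet upright stance with constant baseline activations.
#' @param step_rate_hz Mean stepping rate for `"sm"` sessions (Hz).
#' @param body_mass_kg Body mass supported by the plates (kg).
#' @param com_height_m Height of the centre of mass above the ankle (m).
#' @param lead_time_s Nominal electromechanical delay: muscle activation
#'   precedes force generation by this lead (s).
#' @param lead_jitter_s Uniform per-step jitter applied to the lead (s).
#' @param noise_levels Named list of relative noise amplitudes:
#'   `emg` (additive white noise relative to the unit-RMS carrier),
#'   `imu` (accelerometer noise as a fraction of g; gyro noise in rad/s at
#'   the same fraction of 1 rad/s), `wrench` (plate noise relative to each
#'   channel's own standard deviation) and `activation` (smooth
#'   neural-drive variability, activation units).
#' @param artifact_amplitude Relative amplitude of the sub-20 Hz motion
#'   artifact added to raw EMG (removed later by the 20--450 Hz band-pass).
#'
#' @return A `grf_config` list.
#' @examples
#' cfg <- session_config("pcm", duration_s = 30, seed = 7)
#' @export
session_config <- function(motion_type = c("pcm", "sm"),
                           duration_s = 120,
                           seed = 1L,
                           sway_frequency_hz = 0.25,
                           sway_amplitude_deg = 2.5,
                           step_rate_hz = 0.4,
                           body_mass_kg = 70,
                           com_height_m = 1.0,
                           lead_time_s = 0.1,
                           lead_jitter_s = 0.05,
                           noise_levels = list(),
                           artifact_amplitude = 0.3) {
  if (is.character(motion_type)) {
    motion_type <- tolower(motion_type)
  }
  if (length(motion_type) > 2 || !all(motion_type %in% c("pcm", "sm"))) {
    abort(sprintf("Unknown motion_type %s: must be \"pcm\" or \"sm\".",
                  paste(motion_type, collapse = "/")))
  }
  motion_type <- match.arg(motion_type)
  defaults <- list(emg = 0.05, imu = 0.02, wrench = 0.05, activation = 0.04)
  noise_levels <- utils::modifyList(defaults, as.list(noise_levels))
  if (duration_s <= 0) abort("duration_s must be positive.")
  if (any(unlist(noise_levels) < 0)) abort("Noise amplitudes must be >= 0.")
  if (artifact_amplitude < 0) abort("artifact_amplitude must be >= 0.")
  if (sway_amplitude_deg < 0) abort("sway_amplitude_deg must be >= 0.")
  if (step_rate_hz <= 0) abort("step_rate_hz must be positive.")
  if (body_mass_kg <= 0) abort("body_mass_kg must be positive.")
  structure(
    list(
      motion_type = motion_type,
      duration_s = duration_s,
      seed = as.integer(seed),
      sway_frequency_hz = sway_frequency_hz,
      sway_amplitude_deg = sway_amplitude_deg,
      step_rate_hz = step_rate_hz,
      body_mass_kg = body_mass_kg,
      com_height_m = com_height_m,
      lead_time_s = lead_time_s,
      lead_jitter_s = lead_jitter_s,
      noise_levels = noise_levels,
      artifact_amplitude = artifact_amplitude
    ),
    class = "grf_config"
  )
}

#' @export
print.grf_config <- function(x, ...) {
  cat(sprintf(
    "<grf_config> %s session, %.5g s, seed %d\n", toupper(x$motion_type),
    x$duration_s, x$seed
  ))
  cat(sprintf(
    "  sway %.3g Hz / %.3g deg; step rate %.3g Hz; mass %.4g kg\n",
    x$sway_frequency_hz, x$sway_amplitude_deg, x$step_rate_hz, x$body_mass_kg
  ))
  invisible(x)
}
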