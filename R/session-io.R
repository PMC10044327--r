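#' Write a session to a directory
#'
#' One CSV per stream (`emg.csv`, `imu.csv`, `wrench.csv`; first column
#' `time` in seconds, labelled channel columns) plus a `session.json`
#' metadata sidecar recording the configuration, seed, sampling rates and
#' sensor-to-muscle channel map. Ground truth (when present) is written as
#' `activations.csv`, `com_state.csv` and `step_events.csv`.
#'
#' @param session A `grf_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "grf_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$emg, file.path(dir, "emg.csv"))
  readr::write_csv(session$imu, file.path(dir, "imu.csv"))
  readr::write_csv(session$wrench, file.path(dir, "wrench.csv"))
  meta <- list(
    config = unclass(session$config),
    rates = session$rates,
    channel_map = sensor_map(),
    n_samples = list(
      emg = nrow(session$emg), imu = nrow(session$imu),
      wrench = nrow(session$wrench)
    )
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$ground_truth)) {
    readr::write_csv(session$ground_truth$activations,
                     file.path(dir, "activations.csv"))
    readr::write_csv(session$ground_truth$com_state,
                     file.path(dir, "com_state.csv"))
    readr::write_csv(session$ground_truth$step_events,
                     file.path(dir, "step_events.csv"))
  }
  invisible(dir)
}

#' Read and validate a session directory
#'
#' Loads the CSV streams and metadata written by [write_session()],
#' checking sampling rates against the sample counts, channel presence
#' against the sensor map, and stream durations against each other.
#'
#' @param dir Session directory.
#' @return A `grf_session`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("No session.json found in %s.", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- meta$config
  config <- session_config(
    motion_type = cfg$motion_type, duration_s = cfg$duration_s,
    seed = cfg$seed, sway_frequency_hz = cfg$sway_frequency_hz,
    sway_amplitude_deg = cfg$sway_amplitude_deg,
    step_rate_hz = cfg$step_rate_hz, body_mass_kg = cfg$body_mass_kg,
    com_height_m = cfg$com_height_m, lead_time_s = cfg$lead_time_s,
    lead_jitter_s = cfg$lead_jitter_s,
    noise_levels = cfg$noise_levels,
    artifact_amplitude = cfg$artifact_amplitude
  )
  streams <- lapply(c("emg", "imu", "wrench"), function(s) {
    p <- file.path(dir, paste0(s, ".csv"))
    if (!file.exists(p)) abort(sprintf("Missing stream file %s.", p))
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  names(streams) <- c("emg", "imu", "wrench")

  smap <- sensor_map()
  for (s in 1:10) {
    ch <- emg_col(s)
    if (!ch %in% names(streams$emg)) {
      row <- smap[smap$sensor == s, ]
      abort(sprintf(
        "EMG stream is missing channel %s (%s %s / sensor %d).",
        ch, row$muscle, row$side, s
      ))
    }
  }
  want_imu <- unlist(lapply(IMU_SENSORS, imu_cols))
  missing_imu <- setdiff(want_imu, names(streams$imu))
  if (length(missing_imu) > 0) {
    abort(sprintf("IMU stream is missing channel(s): %s.",
                  paste(missing_imu, collapse = ", ")))
  }
  missing_w <- setdiff(wrench_channels(), names(streams$wrench))
  if (length(missing_w) > 0) {
    abort(sprintf("Wrench stream is missing channel(s): %s.",
                  paste(missing_w, collapse = ", ")))
  }

  rates <- meta$rates
  for (s in names(streams)) {
    expected <- round(config$duration_s * rates[[s]])
    if (abs(nrow(streams[[s]]) - expected) > 1) {
      abort(sprintf(
        "Stream %s has %d samples but %.5g s at %.3f Hz implies %d (ragged or truncated file).",
        s, nrow(streams[[s]]), config$duration_s, rates[[s]], expected
      ))
    }
    dt <- diff(streams[[s]]$time[1:2])
    if (abs(dt - 1 / rates[[s]]) > 1e-6) {
      abort(sprintf(
        "Stream %s sample period %.6f s does not match declared rate %.3f Hz.",
        s, dt, rates[[s]]
      ))
    }
  }

  gt <- NULL
  if (file.exists(file.path(dir, "activations.csv"))) {
    gt <- list(
      activations = readr::read_csv(file.path(dir, "activations.csv"),
                                    show_col_types = FALSE, progress = FALSE),
      com_state = readr::read_csv(file.path(dir, "com_state.csv"),
                                  show_col_types = FALSE, progress = FALSE),
      step_events = readr::read_csv(
        file.path(dir, "step_events.csv"),
        col_types = readr::cols(
          time = "d", direction = "c", amplitude = "d", lead_s = "d"
        ), progress = FALSE
      )
    )
  }
  structure(
    list(emg = streams$emg, imu = streams$imu, wrench = streams$wrench,
         rates = list(emg = rates$emg, imu = rates$imu,
                      wrench = rates$wrench),
         config = config, ground_truth = gt),
    class = "grf_session"
  )
}
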