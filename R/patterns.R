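#' Sensor-to-muscle map
#'
#' The ten EMG sensors and the leg muscles they are attached to. Sensors
#' 1--3 and 7--8 are on the right leg, 4--6 and 9--10 on the left; sensors
#' 1, 4 carry the shank IMUs and 7, 9 the thigh IMUs used in the input
#' patterns.
#'
#' @return A tibble with `sensor`, `muscle` (abbreviation), `muscle_name`
#'   and `side`.
#' @export
sensor_map <- function() {
  tibble::tibble(
    sensor = c(1L, 2L, 3L, 7L, 8L, 4L, 5L, 6L, 9L, 10L),
    muscle = rep(c("TA", "GAS", "PL", "RF", "ST"), 2),
    muscle_name = rep(c(
      "Tibialis anterior", "Gastrocnemius medial head", "Peroneus longus",
      "Rectus femoris", "Semitendinosus"
    ), 2),
    side = rep(c("right", "left"), each = 5)
  ) |> dplyr::arrange(.data$sensor)
}

#' The six EMG/IMU input combination patterns
#'
#' Pattern 1 uses all ten EMG channels, 2 the four IMUs (shanks + thighs),
#' 3 both; patterns 4--6 are the below-knee counterparts (EMG 1--6: TA,
#' GAS, PL of both legs; IMUs 1 and 4 on the shanks). The input
#' dimensionality is `|emg| + 6 * |imu|`.
#'
#' @return A tibble with `pattern_id`, list-columns `emg_sensors`,
#'   `imu_sensors`, the `remarks` label and `input_dim`.
#' @examples
#' input_patterns()
#' @export
input_patterns <- function() {
  pat <- tibble::tibble(
    pattern_id = 1:6,
    emg_sensors = list(1:10, integer(0), 1:10, 1:6, integer(0), 1:6),
    imu_sensors = list(integer(0), c(1L, 4L, 7L, 9L), c(1L, 4L, 7L, 9L),
                       integer(0), c(1L, 4L), c(1L, 4L)),
    remarks = c(
      "All muscles", "IMU on thighs and shanks",
      "All muscles and IMU on thighs and shanks", "Muscles (TA, GAS, PL)",
      "IMU on shanks", "Muscles (TA, GAS, PL) and IMU on shanks"
    )
  )
  pat$input_dim <- purrr::map2_int(
    pat$emg_sensors, pat$imu_sensors,
    ~ length(.x) + 6L * length(.y)
  )
  pat
}

emg_col <- function(sensor) sprintf("emg_%02d", sensor)

imu_cols <- function(sensor) {
  paste0("imu", sensor, "_", c("acc_x", "acc_y", "acc_z",
                               "gyro_x", "gyro_y", "gyro_z"))
}

#' Columns selected by an input pattern
#'
#' @param pattern_id Integer 1--6.
#' @return Character vector of feature column names.
#' @export
pattern_columns <- function(pattern_id) {
  pat <- input_patterns()
  if (!pattern_id %in% pat$pattern_id) {
    abort(sprintf("Unknown input pattern %s (must be 1-6).", pattern_id))
  }
  row <- pat[pat$pattern_id == pattern_id, ]
  c(
    emg_col(row$emg_sensors[[1]]),
    unlist(lapply(row$imu_sensors[[1]], imu_cols))
  )
}

#' Restrict a feature frame to one input pattern
#'
#' Keeps `time`, the pattern's feature columns and the six wrench targets
#' (when present).
#'
#' @param features Feature tibble from [preprocess_session()].
#' @param pattern_id Integer 1--6.
#' @return Tibble restricted to the pattern's channels.
#' @export
select_pattern <- function(features, pattern_id) {
  cols <- pattern_columns(pattern_id)
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0) {
    abort(sprintf(
      "Feature frame is missing channel(s) required by pattern %d: %s.",
      pattern_id, paste(missing, collapse = ", ")
    ))
  }
  keep <- c("time", cols, intersect(wrench_channels(), names(features)))
  features[, keep, drop = FALSE]
}
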