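# Readers and writers for the plain-text dialects used across the
# pipeline: landmark tables (OpenFace column convention), ECG voltage
# traces, IBI series, and ground-truth/result JSON.

#' Write / read a landmark trajectory table
#'
#' Columns: `frame`, `timestamp_s`, then `x_0`..`x_67`, `y_0`..`y_67`.
#'
#' @param landmarks Tibble as produced by [gen_face_landmarks()].
#' @param path File path.
#' @return `read_landmarks_csv()` returns the tibble; writers return the
#'   path invisibly.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("frame", "timestamp_s") %in% names(df))) {
    stopf("%s: not a landmark table (missing frame/timestamp_s).", path,
          class = "mmspike_load_error")
  }
  bad <- which(diff(df$timestamp_s) <= 0)
  if (length(bad)) {
    stopf("%s: non-monotone timestamp at row %d.", path, bad[1] + 1,
          class = "mmspike_load_error")
  }
  tibble::as_tibble(df)
}

#' Write / read an ECG record as CSV (`time_s`, `voltage`)
#'
#' @param ecg An `ecg_record`.
#' @param path File path.
#' @export
write_ecg_csv <- function(ecg, path) {
  tt <- (seq_along(ecg$samples) - 1) / ecg$fs
  utils::write.csv(data.frame(time_s = tt, voltage = ecg$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage") %in% names(df))) {
    stopf("%s: not an ECG table (need time_s, voltage).", path,
          class = "mmspike_load_error")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    stopf("%s: non-monotone time at row %d.", path, which(dt <= 0)[1] + 1,
          class = "mmspike_load_error")
  }
  ecg_record(df$voltage, fs = 1 / stats::median(dt))
}

#' Write / read an IBI series as CSV (`r_time_ms`, `ibi_ms`)
#'
#' @param ibi An `ibi_series`.
#' @param path File path.
#' @export
write_ibi_csv <- function(ibi, path) {
  utils::write.csv(
    data.frame(r_time_ms = ibi$r_times,
               ibi_ms = c(NA, ibi$intervals)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibi_csv
#' @export
read_ibi_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"r_time_ms" %in% names(df)) {
    stopf("%s: not an IBI table (need r_time_ms).", path,
          class = "mmspike_load_error")
  }
  build_ibi(df$r_time_ms)
}

#' Read and validate a YAML run configuration
#'
#' Recognized fields: `n_participants`, `duration`, `fps`, `tasks`, `seed`,
#' `loglog_slope`, `loglog_intercept`, `loglog_noise`, `delta_mean`,
#' `delta_sd`, `delta_slope`, `delta_r2_target`, `spike_rate`, and a
#' `coupling` block (`direction`, `lag`, `strength`). Unknown fields are a
#' validation error so typos fail before any computation.
#'
#' @param path YAML file path.
#' @return A validated [cohort_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_participants", "duration", "fps", "tasks", "seed",
             "loglog_slope", "loglog_intercept", "loglog_noise",
             "delta_mean", "delta_sd", "delta_slope", "delta_r2_target",
             "spike_rate", "coupling")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stopf("Unknown config field(s): %s", paste(bad, collapse = ", "),
          class = "mmspike_config_error")
  }
  if (!is.null(cfg$coupling)) {
    cfg$coupling <- do.call(coupling_spec, cfg$coupling)
  }
  do.call(cohort_config, cfg)
}
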