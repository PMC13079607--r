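#' Trigeminal region membership of the 68-point facial landmark grid
#'
#' Partition of the OpenFace-style 68-point grid (0-based landmark indices)
#' into the three trigeminal subregions: ophthalmic (V1, eyebrows/eyes/upper
#' nose), maxillary (V2, lower nose/upper lip) and mandibular (V3, jaw
#' outline/lower lip). The published index listings are internally
#' inconsistent (V1 is described as 26 points but its listed indices count
#' 27; V2 as 17 points but counts 16 under an ascending reading of its
#' ranges), so membership is a data object rather than a hard-coded
#' constant: pass your own table wherever a `region_table` argument is
#' accepted.
#'
#' @return A tibble with columns `region` (`"V1"`, `"V2"`, `"V3"`) and
#'   `landmark` (0-based integer index), in canonical pooling order.
#' @export
#' @examples
#' dplyr::count(face_regions(), region)
face_regions <- function() {
  tibble::tibble(
    region = rep(c("V1", "V2", "V3"), times = c(27L, 16L, 25L)),
    landmark = c(
      c(17:30, 33L, 36:47),
      c(31L, 32L, 34L, 35L, 48:54, 60:64),
      c(0:16, 55:59, 65:67)
    )
  )
}

#' Smooth landmark pixel trajectories with cubic smoothing splines
#'
#' Positional x/y traces from video landmark tracking carry frame-to-frame
#' estimation jitter; the speed profiles differentiate the positions, which
#' amplifies that jitter. Each coordinate is smoothed with a cubic smoothing
#' spline evaluated back on the original uniform frame grid. The effective
#' degrees of freedom default to a fixed fraction of the series length,
#' chosen so unit-variance white noise is attenuated by more than a factor
#' of ten while linear trends pass through unchanged.
#'
#' @param x,y Numeric pixel coordinate series (equal length, >= 4 samples,
#'   no missing values).
#' @param fps Frames per second of the recording (default 30).
#' @param df_frac Spline degrees of freedom as a fraction of the series
#'   length (default 0.05; the floor is 4 df).
#' @return A tibble with columns `frame`, `t` (seconds), `x`, `y`.
#' @export
smooth_positions <- function(x, y, fps = 30, df_frac = 0.05) {
  check_scalar(fps, positive = TRUE)
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length.")
  check_numeric(x, min_len = 4L)
  check_numeric(y, min_len = 4L)
  n <- length(x)
  tt <- seq_len(n)
  df <- max(4, ceiling(n * df_frac))
  smooth1 <- function(v) {
    if (var(v) == 0) return(v)
    stats::predict(stats::smooth.spline(tt, v, df = df), tt)$y
  }
  tibble::tibble(frame = tt, t = (tt - 1) / fps, x = smooth1(x), y = smooth1(y))
}

#' Scalar speed profile of a smoothed trajectory
#'
#' Differentiates the x/y positions by central differences (one-sided at the
#' endpoints), scales by the frame rate, and takes the Euclidean norm to
#' obtain per-frame speed magnitude in pixels/s. Length is preserved.
#'
#' @param traj A data frame with columns `x` and `y` (e.g. from
#'   [smooth_positions()]), or a numeric vector of x positions.
#' @param y If `traj` is a vector, the matching y positions.
#' @param fps Frames per second.
#' @return An object of class `speed_series`: a list with `values`
#'   (pixels/s) and `fps`.
#' @export
speed_profile <- function(traj, y = NULL, fps = 30) {
  if (is.data.frame(traj)) {
    x <- traj$x
    y <- traj$y
  } else {
    x <- traj
  }
  check_numeric(x, min_len = 3L)
  check_numeric(y, min_len = 3L)
  check_scalar(fps, positive = TRUE)
  dx <- central_diff(x) * fps
  dy <- central_diff(y) * fps
  structure(list(values = sqrt(dx^2 + dy^2), fps = fps),
            class = "speed_series")
}

central_diff <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

#' Detect local peaks and their flanking valleys
#'
#' Peaks are samples where the forward slope changes from positive to
#' negative; valleys where it changes from negative to positive. A plateau
#' (run of equal values) bounded by lower neighbours is a single peak at the
#' run's first index, symmetrically for valleys. A boundary sample is a
#' valley when the series moves upward away from it. Every peak is assigned
#' its nearest flanking valleys; a monotone series yields an empty peak set.
#'
#' @param x Numeric series of length >= 3.
#' @return An object of class `peak_set`: a tibble with columns `peak`,
#'   `left_valley`, `right_valley` (1-based frame indices) plus an attribute
#'   `valleys` with every valley index.
#' @export
#' @examples
#' detect_extrema(c(0, 1, 0, 1, 0))
detect_extrema <- function(x) {
  check_numeric(x, min_len = 3L)
  r <- rle(as.numeric(x))
  v <- r$values
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  m <- length(v)
  peaks <- integer(0)
  valleys <- integer(0)
  if (m >= 2) {
    if (v[1] < v[2]) valleys <- c(valleys, starts[1])
    if (v[m] < v[m - 1]) valleys <- c(valleys, starts[m])
  }
  if (m >= 3) {
    for (j in 2:(m - 1)) {
      if (v[j] > v[j - 1] && v[j] > v[j + 1]) {
        peaks <- c(peaks, starts[j])
      } else if (v[j] < v[j - 1] && v[j] < v[j + 1]) {
        valleys <- c(valleys, starts[j])
      }
    }
  }
  valleys <- sort(valleys)
  if (length(peaks)) {
    lv <- vapply(peaks, function(p) max(valleys[valleys < p]), numeric(1))
    rv <- vapply(peaks, function(p) min(valleys[valleys > p]), numeric(1))
  } else {
    lv <- rv <- numeric(0)
  }
  out <- tibble::tibble(peak = as.integer(peaks),
                        left_valley = as.integer(lv),
                        right_valley = as.integer(rv))
  structure(out, valleys = as.integer(valleys),
            class = c("peak_set", class(out)))
}

#' Micro-movement spike series from a scalar series
#'
#' Standardizes a positive scalar series (speed magnitude or inter-beat
#' intervals) into the frame-preserving micro-movement spike (MMS) train.
#' Deviations from the empirically estimated Gamma mean of the raw series
#' peaks are formed, each deviation peak is normalized by
#' `Peak / (Peak + Avg)`, where `Avg` is the mean of the *original* series
#' over the closed valley-to-valley interval that brackets the deviation
#' peak, and every non-peak frame is set to zero (zeros represent motion at
#' the mean level). The local averaging removes allometric scale: rescaling
#' the input by any k > 0 leaves every spike value unchanged.
#'
#' @param series Positive numeric series.
#' @param peaks A [detect_extrema()] peak set computed on the deviation
#'   series `|series - gamma_mean|` (or `pmax(series - gamma_mean, 0)` with
#'   `positive_only = TRUE`). If `NULL`, it is computed internally.
#' @param gamma_mean The Gamma mean fitted to the raw series peaks (see
#'   [mms_transform()] for the full pipeline).
#' @param positive_only Restrict to positive deviations instead of absolute
#'   deviations (default `FALSE`).
#' @param fps Frames per second carried along for downstream alignment.
#' @return An object of class `mms_series`: a list with `values` (per-frame
#'   spikes in \[0, 1)), `peak_frames`, `peak_values`, `gamma_mean`, `fps`,
#'   and `n_skipped` (degenerate flat segments dropped).
#' @export
mms_from_series <- function(series, peaks = NULL, gamma_mean,
                            positive_only = FALSE, fps = 30) {
  check_numeric(series, min_len = 3L)
  check_scalar(gamma_mean)
  dev <- if (positive_only) pmax(series - gamma_mean, 0) else abs(series - gamma_mean)
  if (is.null(peaks)) peaks <- detect_extrema(dev)
  values <- numeric(length(series))
  keep <- logical(nrow(peaks))
  skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    p <- peaks$peak[i]
    pk <- dev[p]
    avg <- mean(series[peaks$left_valley[i]:peaks$right_valley[i]])
    if (pk <= 0 || avg <= 0) {
      skipped <- skipped + 1L
      next
    }
    values[p] <- pk / (pk + avg)
    keep[i] <- TRUE
  }
  if (skipped > 0) {
    warnf("mms_from_series: skipped %d degenerate flat segment(s).", skipped)
  }
  structure(list(values = values,
                 peak_frames = peaks$peak[keep],
                 peak_values = values[peaks$peak[keep]],
                 gamma_mean = gamma_mean,
                 fps = fps,
                 n_skipped = skipped),
            class = "mms_series")
}

#' Full MMS standardization pipeline for one series
#'
#' Runs the complete transform: detect raw series peaks, fit the Gamma
#' family to their magnitudes by maximum likelihood, form deviations from
#' the fitted Gamma mean, and normalize each deviation peak into an MMS
#' spike via [mms_from_series()]. Works identically for facial speed
#' profiles and heart inter-beat interval sequences.
#'
#' @param series Positive numeric series (a `speed_series` is also
#'   accepted).
#' @param fps Frames per second (ignored if `series` is a `speed_series`).
#' @param positive_only Use only positive deviations from the Gamma mean.
#' @param min_peaks Minimum number of raw peaks required for the Gamma fit
#'   (default 30).
#' @return An `mms_series` (see [mms_from_series()]) with the raw-peak
#'   `gamma_fit` attached as attribute `raw_fit`.
#' @export
mms_transform <- function(series, fps = 30, positive_only = FALSE,
                          min_peaks = 30) {
  if (inherits(series, "speed_series")) {
    fps <- series$fps
    series <- series$values
  }
  check_numeric(series, min_len = 3L)
  if (var(series) == 0) {
    # a constant series has no peaks: empty spike set, not an error
    return(structure(list(values = numeric(length(series)),
                          peak_frames = integer(0),
                          peak_values = numeric(0),
                          gamma_mean = series[1], fps = fps, n_skipped = 0L),
                     class = "mms_series"))
  }
  raw <- detect_extrema(series)
  raw_peaks <- series[raw$peak]
  raw_peaks <- raw_peaks[raw_peaks > 0]
  fit <- fit_gamma_mle(raw_peaks, min_n = min_peaks)
  m <- fit$shape * fit$scale
  out <- mms_from_series(series, peaks = NULL, gamma_mean = m,
                         positive_only = positive_only, fps = fps)
  attr(out, "raw_fit") <- fit
  out
}

#' Pool MMS peak values across the landmarks of a facial region
#'
#' Concatenates spike amplitudes across a region's landmarks in the
#' canonical landmark order of the region table, regardless of the order in
#' which the per-landmark series are supplied.
#'
#' @param mms_list Named list of `mms_series`, names being 0-based landmark
#'   indices (as produced per column of a landmark table).
#' @param region Region label present in `region_table`.
#' @param region_table Region membership (default [face_regions()]).
#' @return Numeric vector of pooled spike amplitudes.
#' @export
pool_region_mms <- function(mms_list, region, region_table = face_regions()) {
  ids <- region_table$landmark[region_table$region == region]
  if (!length(ids)) {
    stopf("Unknown or empty region '%s'.", region,
          class = "mmspike_parameter_error")
  }
  have <- as.integer(names(mms_list))
  ids <- ids[ids %in% have]
  if (!length(ids)) {
    stopf("No landmarks from region '%s' present in `mms_list`.", region,
          class = "mmspike_parameter_error")
  }
  fps <- unique(vapply(mms_list, function(m) m$fps, numeric(1)))
  nfr <- unique(vapply(mms_list, function(m) length(m$values), numeric(1)))
  if (length(fps) > 1 || length(nfr) > 1) {
    stopf("All MMS series must share fps and frame count.")
  }
  unlist(lapply(as.character(ids), function(id) mms_list[[id]]$peak_values),
         use.names = FALSE)
}

#' @export
print.mms_series <- function(x, ...) {
  cat(sprintf("<mms_series> %d frames @ %g fps, %d spikes (gamma mean %.4g)\n",
              length(x$values), x$fps, length(x$peak_values), x$gamma_mean))
  invisible(x)
}

#' @export
as.data.frame.mms_series <- function(x, ...) {
  data.frame(frame = seq_along(x$values), value = x$values)
}

#' Tidy an MMS series into a per-frame tibble
#'
#' @param x An `mms_series`.
#' @param ... Unused.
#' @return Tibble with `frame`, `t` (seconds), `value`, `is_spike`.
#' @export
tidy.mms_series <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$values),
                 t = (seq_along(x$values) - 1) / x$fps,
                 value = x$values,
                 is_spike = x$values > 0)
}
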