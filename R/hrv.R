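#' Construct an ECG record object
#'
#' @param samples Voltage samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs) {
  check_numeric(samples, min_len = 2L)
  check_scalar(fs, positive = TRUE)
  structure(list(samples = as.numeric(samples), fs = fs), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Locate R-peaks in an ECG record
#'
#' Detection proceeds in three steps: baseline removal by a running-median
#' detrend, zero-phase band-pass filtering (Butterworth, applied
#' forward-backward so peaks are not displaced), and adaptive-threshold peak
#' picking with a refractory period. Each candidate is refined to the local
#' maximum of the detrended signal, so on clean records the reported time is
#' the exact sample of the R deflection.
#'
#' @param ecg An `ecg_record`.
#' @param band Pass band in Hz (default `c(5, 25)`, matching the spectral
#'   content of the R deflection).
#' @param threshold_frac Threshold as a fraction of the 99.9th percentile of
#'   the filtered signal (default 0.4).
#' @param refractory_ms Minimum distance between successive peaks (default
#'   250 ms, i.e. a 240 bpm ceiling).
#' @return Numeric vector of strictly increasing R-peak times in ms. A flat
#'   or peak-free record returns an empty vector with a warning.
#' @export
detect_r_peaks <- function(ecg, band = c(5, 25), threshold_frac = 0.4,
                           refractory_ms = 250) {
  stopifnot(inherits(ecg, "ecg_record"))
  x <- ecg$samples
  fs <- ecg$fs
  n <- length(x)
  if (n / fs < 10) {
    stopf("ECG record must be at least 10 s long.",
          class = "mmspike_degenerate_input")
  }
  if (sd(x) == 0) {
    warnf("Flat-line ECG; no R-peaks found.")
    return(numeric(0))
  }
  # reflect-pad 1 s at each end so beats at the record boundaries survive
  # the baseline and filter transients
  pad <- min(n - 1, round(fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  # running-median baseline over ~0.6 s
  w <- round(0.6 * fs)
  if (w %% 2 == 0) w <- w + 1
  baseline <- stats::runmed(xp, w, endrule = "median")
  detr_p <- xp - baseline
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt_p <- as.numeric(signal::filtfilt(bf, detr_p))
  detr <- detr_p[(pad + 1):(pad + n)]
  filt <- filt_p[(pad + 1):(pad + n)]
  thr <- threshold_frac * quantile(filt, 0.999, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    warnf("No usable signal above threshold; no R-peaks found.")
    return(numeric(0))
  }
  refr <- round(refractory_ms / 1000 * fs)
  prev <- c(-Inf, filt[-n])
  nxt <- c(filt[-1], -Inf)
  cand <- which(filt >= prev & filt > nxt & filt > thr)
  if (!length(cand)) {
    warnf("No R-peaks found above threshold.")
    return(numeric(0))
  }
  # enforce refractory period, keeping the larger candidate
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (filt[i] > filt[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  # refine within +/- 40 ms on a Gaussian-smoothed copy of the detrended
  # signal: zero-phase smoothing keeps a symmetric R deflection's peak at
  # its exact sample while leaving only strongly correlated noise between
  # neighbouring samples, so the argmax is sample-accurate
  ks <- max(1, round(0.015 * fs))
  kx <- seq(-3 * ks, 3 * ks)
  kern <- exp(-kx^2 / (2 * ks^2))
  kern <- kern / sum(kern)
  sm <- as.numeric(stats::filter(c(rep(detr[1], 3 * ks), detr,
                                   rep(detr[n], 3 * ks)),
                                 kern, sides = 2))[(3 * ks + 1):(3 * ks + n)]
  hw <- round(0.04 * fs)
  refined <- vapply(keep, function(i) {
    lo <- max(1, i - hw)
    hi <- min(n, i + hw)
    lo + which.max(sm[lo:hi]) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  (refined - 1) / fs * 1000
}

#' Build an inter-beat interval series from R-peak times
#'
#' @param r_times Strictly increasing R-peak times in ms.
#' @param flag_bounds Physiological plausibility bounds in ms; intervals
#'   outside are flagged (retained in the raw series, excluded from
#'   [clean_intervals()]). Default `c(300, 2000)`.
#' @return Object of class `ibi_series`: list with `r_times`, `intervals`
#'   (ms, `intervals[i] = r_times[i+1] - r_times[i]`), and logical
#'   `flagged`.
#' @export
build_ibi <- function(r_times, flag_bounds = c(300, 2000)) {
  check_numeric(r_times, min_len = 2L)
  if (any(diff(r_times) <= 0)) {
    stopf("R-peak times must be strictly increasing.",
          class = "mmspike_ordering_error")
  }
  iv <- diff(r_times)
  flagged <- iv < flag_bounds[1] | iv > flag_bounds[2]
  structure(list(r_times = as.numeric(r_times), intervals = as.numeric(iv),
                 flagged = flagged),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats, mean IBI %.1f ms, %d flagged\n",
              length(x$r_times), mean(x$intervals), sum(x$flagged)))
  invisible(x)
}

#' Intervals with flagged artifacts removed
#'
#' @param ibi An `ibi_series` (or plain numeric intervals, returned as-is).
#' @return Numeric vector of plausible intervals (ms).
#' @export
clean_intervals <- function(ibi) {
  if (inherits(ibi, "ibi_series")) ibi$intervals[!ibi$flagged] else as.numeric(ibi)
}

#' Poincare descriptors SD1 and SD2 of an IBI series
#'
#' The lag-1 scatter (x_t, x_(t+1)) of the intervals is summarized by the
#' standard deviations along the two 45-degree ellipse axes: SD1 (short
#' axis, beat-to-beat / parasympathetic variability) is the population SD
#' of (x_(t+1) - x_t)/sqrt(2); SD2 (long axis, longer-term / sympathetic
#' variability) the population SD of (x_(t+1) + x_t)/sqrt(2). Population
#' (1/n) variance is used throughout; SD2 equals the classical
#' sqrt(2 Var(x) - SD1^2) form up to O(1/n) edge terms.
#'
#' @param ibi An `ibi_series` or numeric vector of intervals in ms
#'   (flagged artifacts are excluded first).
#' @return Object of class `poincare_summary`: list with `sd1`, `sd2` (ms)
#'   and `n` (number of lag-1 pairs).
#' @export
poincare_sd <- function(ibi) {
  x <- clean_intervals(ibi)
  check_numeric(x, min_len = 3L)
  n <- length(x)
  x1 <- x[-n]
  x2 <- x[-1]
  sd1sq <- var_pop(x2 - x1) / 2
  sd2sq <- var_pop(x2 + x1) / 2
  structure(list(sd1 = sqrt(max(sd1sq, 0)), sd2 = sqrt(max(sd2sq, 0)),
                 n = n - 1L),
            class = "poincare_summary")
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("<poincare_summary> SD1 = %.2f ms, SD2 = %.2f ms (%d pairs)\n",
              x$sd1, x$sd2, x$n))
  invisible(x)
}

#' @export
tidy.poincare_summary <- function(x, ...) {
  tibble::tibble(term = c("sd1", "sd2"), estimate = c(x$sd1, x$sd2))
}

#' Welch power spectrum of a uniformly resampled tachogram
#'
#' Internal work-horse for [band_powers()]. One-sided PSD, scaled so the
#' integral over frequency recovers the signal variance (Parseval).
#' @noRd
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(seg_len / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / scale
    p <- p[1:nfreq]
    # one-sided: double everything except DC (and Nyquist when seg_len even)
    mult <- rep(2, nfreq)
    mult[1] <- 1
    if (seg_len %% 2 == 0) mult[nfreq] <- 1
    acc <- acc + p * mult
  }
  list(freq = (seq_len(nfreq) - 1) * fs / seg_len,
       psd = acc / length(starts))
}

#' LF and HF spectral band powers of the tachogram
#'
#' The interval series (tachogram) is resampled onto a uniform grid by
#' cubic interpolation, its power spectral density estimated by Welch's
#' method (Hann window, 60-s segments, 50% overlap), and power integrated
#' over the conventional sympathetic low-frequency band (0.04--0.15 Hz) and
#' parasympathetic high-frequency band (0.15--0.40 Hz).
#'
#' @param ibi An `ibi_series` (or numeric intervals with `r_times` implied
#'   by their cumulative sum).
#' @param resample_hz Uniform resampling rate (default 4 Hz).
#' @param min_duration_s Minimum record duration (default 60 s; below 25 s
#'   -- one cycle of the lowest LF frequency -- is an error regardless).
#' @param lf,hf Band edges in Hz.
#' @return Object of class `spectral_bands`: list with `lf_power`,
#'   `hf_power` (ms^2), `lf_hf_ratio`, and the `freq`/`psd` grid.
#' @export
band_powers <- function(ibi, resample_hz = 4, min_duration_s = 60,
                        lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  if (inherits(ibi, "ibi_series")) {
    tt <- ibi$r_times[-1] / 1000
    vv <- ibi$intervals
  } else {
    check_numeric(ibi, min_len = 3L)
    tt <- cumsum(ibi) / 1000
    vv <- as.numeric(ibi)
  }
  dur <- tt[length(tt)] - tt[1]
  if (dur < max(min_duration_s, 1 / lf[1])) {
    stopf("Record too short for band-power analysis (%.1f s < %.1f s).",
          dur, max(min_duration_s, 1 / lf[1]),
          class = "mmspike_insufficient_duration")
  }
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  u <- spline(tt, vv, xout = grid)$y
  u <- u - mean(u)
  ps <- welch_psd(u, fs = resample_hz, seg_len = min(length(u), 60 * resample_hz))
  df <- ps$freq[2] - ps$freq[1]
  in_band <- function(b) sum(ps$psd[ps$freq >= b[1] & ps$freq < b[2]]) * df
  lfp <- in_band(lf)
  hfp <- in_band(hf)
  structure(list(lf_power = lfp, hf_power = hfp,
                 lf_hf_ratio = if (hfp > 0) lfp / hfp else NA_real_,
                 freq = ps$freq, psd = ps$psd),
            class = "spectral_bands")
}

#' @export
print.spectral_bands <- function(x, ...) {
  cat(sprintf("<spectral_bands> LF %.3g ms^2, HF %.3g ms^2, LF/HF %.3g\n",
              x$lf_power, x$hf_power, x$lf_hf_ratio))
  invisible(x)
}

#' MMS standardization of an inter-beat interval series
#'
#' Applies the identical micro-movement-spike pipeline used for facial
#' speed to the IBI sequence: Gamma mean from the raw interval peaks,
#' absolute deviations, and peak normalization by the local original-scale
#' average. Scaling all intervals by a positive constant leaves the spike
#' values unchanged.
#'
#' @param ibi An `ibi_series` or numeric interval vector (ms).
#' @param ... Passed to [mms_transform()] (e.g. `min_peaks`).
#' @return An `mms_series` whose "frames" are beats; the beat times are
#'   attached as attribute `beat_times_ms` for grid alignment.
#' @export
ibi_mms <- function(ibi, ...) {
  if (inherits(ibi, "ibi_series")) {
    iv <- ibi$intervals
    bt <- ibi$r_times[-1]
  } else {
    iv <- as.numeric(ibi)
    bt <- cumsum(iv)
  }
  out <- mms_transform(iv, fps = NA_real_, ...)
  attr(out, "beat_times_ms") <- bt
  out
}

#' Resample a beat-indexed MMS train onto a uniform frame grid
#'
#' Places each beat's spike value at the video frame containing its R-time
#' (zero-order hold at spike frames, zeros elsewhere), bringing the heart
#' MMS onto the same 30 Hz grid as the face MMS so the two streams are
#' comparable for transfer-entropy analysis.
#'
#' @param mms An `mms_series` from [ibi_mms()] (with `beat_times_ms`).
#' @param fps Target frame rate (default 30).
#' @param n_frames Length of the target grid; defaults to cover the last
#'   beat.
#' @return An `mms_series` on the uniform frame grid.
#' @export
mms_to_frames <- function(mms, fps = 30, n_frames = NULL) {
  bt <- attr(mms, "beat_times_ms")
  if (is.null(bt)) stopf("`mms` lacks beat times; use ibi_mms() first.")
  n_frames <- n_frames %||% ceiling(bt[length(bt)] / 1000 * fps)
  values <- numeric(n_frames)
  spike_beats <- mms$peak_frames
  frames <- pmin(pmax(floor(bt[spike_beats] / 1000 * fps) + 1, 1), n_frames)
  values[frames] <- mms$peak_values
  structure(list(values = values,
                 peak_frames = which(values > 0),
                 peak_values = values[values > 0],
                 gamma_mean = mms$gamma_mean,
                 fps = fps,
                 n_skipped = mms$n_skipped),
            class = "mms_series")
}
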