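#' Gamma regime specification
#'
#' Bundles the Gamma shape/scale pair that defines a stochastic regime of
#' micro-movement spike amplitudes, with a condition tag.
#'
#' @param shape,scale Gamma parameters (> 0); the scale is the
#'   noise-to-signal ratio of the regime.
#' @param label Condition tag (default `"control"`).
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(shape, scale, label = "control") {
  check_scalar(shape, positive = TRUE)
  check_scalar(scale, positive = TRUE)
  structure(list(shape = shape, scale = scale, label = label),
            class = "regime_spec")
}

#' Coupling specification for paired face/heart streams
#'
#' @param direction `"heart_to_face"`, `"face_to_heart"` or `"none"`.
#' @param lag Coupling lag in frames (>= 1).
#' @param strength Coupling coefficient in \[0, 1\]; forced to 0 when
#'   `direction = "none"`.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(direction = c("none", "heart_to_face",
                                        "face_to_heart"),
                          lag = 5, strength = 0) {
  direction <- match.arg(direction)
  if (lag < 1) stopf("`lag` must be >= 1.", class = "mmspike_parameter_error")
  if (strength < 0 || strength > 1) {
    stopf("`strength` must be in [0, 1].", class = "mmspike_parameter_error")
  }
  if (direction == "none") strength <- 0
  structure(list(direction = direction, lag = as.integer(lag),
                 strength = strength),
            class = "coupling_spec")
}

#' Draw Gamma-distributed MMS spike amplitudes
#'
#' @param spec A [regime_spec()].
#' @param n Number of draws.
#' @param seed RNG seed (all generator randomness is explicitly seeded; the
#'   caller's RNG state is untouched).
#' @return Numeric vector of `n` positive draws.
#' @export
gen_gamma_mms_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "regime_spec"))
  if (!is.numeric(n) || n < 1) {
    stopf("`n` must be >= 1.", class = "mmspike_parameter_error")
  }
  with_seed(seed, rgamma(n, shape = spec$shape, scale = spec$scale))
}

# Truncated Gamma draws inside [lo, hi]: rejection by redrawing, which
# keeps the kept draws exactly Gamma-distributed on the representable
# window. At physiological NSR values the excluded mass is ~1e-3.
rgamma_trunc <- function(n, shape, scale, lo, hi) {
  out <- rgamma(n, shape = shape, scale = scale)
  bad <- which(out < lo | out > hi)
  guard <- 0
  while (length(bad) && guard < 1000) {
    out[bad] <- rgamma(length(bad), shape = shape, scale = scale)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], lo), hi)
  out
}

# Exact inversion of the MMS transform: build a series whose standardized
# spikes reproduce `spikes` exactly.
#
# Layout: K + 1 near-baseline samples (the "z" samples) interleaved with K
# excursions of three samples (g, D, g) dipping below the baseline. The
# interior z samples are the only local maxima of the series and are
# centered to mean zero, so the Gamma mean fitted to the raw peaks equals
# `base` exactly (the Gamma MLE's fitted mean is the sample mean). Each
# excursion's deviation peak D_k and closed-interval original-scale average
# then solve Peak/(Peak + Avg) = s_k in closed form:
# with g = D/2, D_k = s_k c_k / (1 - 0.6 s_k), c_k = base + (z_k + z_(k+1))/5.
spikes_to_series <- function(spikes, base, z_frac = 0.00075) {
  K <- length(spikes)
  if (any(spikes <= 0 | spikes >= 0.625)) {
    stopf("Representable spike values are in (0, 0.625).",
          class = "mmspike_parameter_error")
  }
  z <- numeric(K + 1)
  if (K >= 2) {
    amp <- runif(K - 1, 0.25, 1) * z_frac * base *
      sample(c(-1, 1), K - 1, replace = TRUE)
    z[2:K] <- amp - mean(amp)
  }
  cvec <- base + (z[1:K] + z[2:(K + 1)]) / 5
  D <- spikes * cvec / (1 - 0.6 * spikes)
  g <- D / 2
  n <- 4 * K + 1
  y <- numeric(n)
  y[seq(1, n, by = 4)] <- base + z
  y[seq(2, n - 1, by = 4)] <- base - g
  y[seq(3, n - 1, by = 4)] <- base - D
  y[seq(4, n - 1, by = 4)] <- base - g
  y
}

#' Synthesize an IBI series with a prescribed spike-amplitude regime
#'
#' Inverse-designs an inter-beat interval sequence around `base_ibi` whose
#' micro-movement spikes, recovered by the standard pipeline
#' ([ibi_mms()]), are exact draws from `Gamma(shape, scale)`. Target draws
#' outside the representable window `s_bounds` are redrawn (negligible mass
#' at physiological noise levels; see the methods vignette).
#'
#' @param base_ibi Baseline interval in ms (> 0).
#' @param spec A [regime_spec()] for the spike amplitudes.
#' @param duration Recording duration in seconds (must cover >= 10 beats).
#' @param seed RNG seed.
#' @param s_bounds Representable spike window (default `c(0.004, 0.55)`).
#' @return An `ibi_series` with the injected spike draws attached as
#'   attribute `true_spikes`.
#' @export
gen_ibi_series <- function(base_ibi, spec, duration, seed,
                           s_bounds = c(0.004, 0.55)) {
  check_scalar(base_ibi, positive = TRUE)
  check_scalar(duration, positive = TRUE)
  stopifnot(inherits(spec, "regime_spec"))
  n_beats <- floor(duration * 1000 / base_ibi)
  if (n_beats < 10) {
    stopf("Duration covers only %d beats; need >= 10.", n_beats,
          class = "mmspike_degenerate_input")
  }
  K <- (n_beats - 1) %/% 4
  if (K < 3) {
    stopf("Duration too short for >= 3 spikes.",
          class = "mmspike_degenerate_input")
  }
  with_seed(seed, {
    s <- rgamma_trunc(K, spec$shape, spec$scale, s_bounds[1], s_bounds[2])
    y <- spikes_to_series(s, base_ibi)
    ibi <- build_ibi(cumsum(c(0, y)),
                     flag_bounds = c(0.3 * base_ibi, 2.5 * base_ibi))
    attr(ibi, "true_spikes") <- s
    ibi
  })
}

#' Synthesize an ECG waveform from an IBI series
#'
#' Places a unit-amplitude Gaussian R deflection (40 ms full width at half
#' maximum) at every cumulative R-time and adds white measurement noise, so
#' the R-peak detector can be validated against exact ground truth.
#'
#' @param ibi An `ibi_series`.
#' @param fs Sampling rate in Hz (>= 100).
#' @param noise_sd White-noise SD relative to the unit R amplitude
#'   (default 0.05).
#' @param seed RNG seed.
#' @return An `ecg_record` with true R-times attached as attribute
#'   `true_r_times`.
#' @export
gen_ecg_from_ibi <- function(ibi, fs = 250, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(ibi, "ibi_series"))
  check_scalar(fs, positive = TRUE)
  if (fs < 100) {
    stopf("`fs` must be >= 100 Hz to separate adjacent beats.",
          class = "mmspike_parameter_error")
  }
  r <- ibi$r_times
  n <- ceiling((r[length(r)] + 500) / 1000 * fs)
  tt <- (seq_len(n) - 1) / fs * 1000
  sd_ms <- 40 / (2 * sqrt(2 * log(2)))  # FWHM 40 ms
  x <- numeric(n)
  for (rt in r) {
    lo <- max(1, floor((rt - 100) / 1000 * fs))
    hi <- min(n, ceiling((rt + 100) / 1000 * fs))
    idx <- lo:hi
    x[idx] <- x[idx] + exp(-(tt[idx] - rt)^2 / (2 * sd_ms^2))
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(n, sd = noise_sd))
  }
  out <- ecg_record(x, fs)
  attr(out, "true_r_times") <- r
  out
}

# Given the target central-difference speed profile w (frames 1..n-1),
# recover the per-step speeds v: v_1 = w_1, v_t = 2 w_t - v_(t-1). The
# recursion is exact; with g = D/2 the alternating sums telescope, so v
# stays within a few percent of the baseline.
speeds_from_profile <- function(w) {
  n <- length(w)
  a <- (-1)^seq_len(n)
  u <- cumsum(c(-w[1], 2 * a[-1] * w[-1]))
  a * u
}

#' Synthesize a 68-point facial landmark trajectory table
#'
#' Builds per-landmark x/y pixel paths by integrating a speed process with
#' a fixed random heading per landmark. Each landmark's speed profile is an
#' exact MMS inversion (see [gen_ibi_series()]) around `base_speed`, with
#' spike amplitudes drawn from its region's Gamma regime, so the
#' region-pooled spikes recovered by [speed_profile()] +
#' [mms_transform()] follow the injected regime.
#'
#' @param region_specs Named list of [regime_spec()]s for `V1`, `V2`, `V3`.
#' @param duration Recording duration in seconds.
#' @param fps Frames per second (default 30).
#' @param seed RNG seed.
#' @param base_speed Baseline speed in pixels/s (default 30).
#' @param region_table Landmark membership (default [face_regions()]).
#' @param s_bounds Representable spike window.
#' @return A tibble in the OpenFace column convention: `frame`,
#'   `timestamp_s`, `x_0`..`x_67`, `y_0`..`y_67`; per-landmark injected
#'   spikes attached as attribute `true_spikes` (named list).
#' @export
gen_face_landmarks <- function(region_specs, duration, fps = 30, seed = 1,
                               base_speed = 30,
                               region_table = face_regions(),
                               s_bounds = c(0.004, 0.55)) {
  if (!all(c("V1", "V2", "V3") %in% names(region_specs))) {
    stopf("`region_specs` must name V1, V2 and V3.",
          class = "mmspike_parameter_error")
  }
  bad <- setdiff(unique(region_table$region), names(region_specs))
  if (length(bad)) {
    stopf("No regime given for region(s): %s", paste(bad, collapse = ", "),
          class = "mmspike_parameter_error")
  }
  n <- floor(duration * fps)
  K <- (n - 3) %/% 4  # leaves >= 1 controlled tail step after the last spike
  if (K < 3) stopf("Duration too short for >= 3 spikes per landmark.",
                   class = "mmspike_degenerate_input")
  landmarks <- sort(region_table$landmark)
  with_seed(seed, {
    xs <- matrix(NA_real_, n, length(landmarks))
    ys <- matrix(NA_real_, n, length(landmarks))
    true_spikes <- vector("list", length(landmarks))
    names(true_spikes) <- as.character(landmarks)
    for (i in seq_along(landmarks)) {
      lm_id <- landmarks[i]
      reg <- region_table$region[region_table$landmark == lm_id][1]
      spec <- region_specs[[reg]]
      s <- rgamma_trunc(K, spec$shape, spec$scale, s_bounds[1], s_bounds[2])
      w <- spikes_to_series(s, base_speed)        # target speed, frames 1..4K+1
      v <- speeds_from_profile(w)                  # per-step speeds
      # pad the speed profile to n - 1 steps with a strictly descending
      # tail below the baseline: the final designed sample then reads as a
      # raw peak of exactly `base_speed` (or no peak at all), so the fitted
      # Gamma mean of the raw peaks stays exactly at the baseline
      extra <- (n - 1) - length(v)
      if (extra > 0) {
        # Tail targets sit well below the baseline; the final target is set
        # below the running speed so the uncontrolled one-sided sample at
        # frame n continues the descent. The deviation series then rises
        # monotonically into the boundary (no spurious spike), and the last
        # designed baseline sample reads as a raw peak of exactly
        # base_speed, keeping the fitted Gamma mean exact.
        last_target <- base_speed
        for (e in seq_len(extra)) {
          target <- if (e < extra) (0.9 - 0.05 * (e - 1)) * base_speed else
            min(v[length(v)] - 0.1 * base_speed,
                last_target - 0.05 * base_speed)
          v <- c(v, 2 * target - v[length(v)])
          last_target <- target
        }
      }
      theta <- runif(1, 0, 2 * pi)
      step <- v / fps
      px <- cumsum(c(runif(1, 100, 540), step * cos(theta)))
      py <- cumsum(c(runif(1, 100, 380), step * sin(theta)))
      xs[, i] <- px[seq_len(n)]
      ys[, i] <- py[seq_len(n)]
      true_spikes[[i]] <- s
    }
    out <- tibble::tibble(frame = seq_len(n), timestamp_s = (seq_len(n) - 1) / fps)
    for (i in seq_along(landmarks)) out[[paste0("x_", landmarks[i])]] <- xs[, i]
    for (i in seq_along(landmarks)) out[[paste0("y_", landmarks[i])]] <- ys[, i]
    attr(out, "true_spikes") <- true_spikes
    out
  })
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions emulated by [gen_coupled_cohort()]: cohort
#' size, stream geometry, the log-log shape--scale law the cohort's Gamma
#' signatures follow, the control-to-pain noise shift and the strength of
#' the linear relation between facial and cardiac shifts, and the directed
#' face--heart coupling.
#'
#' @param n_participants Cohort size (>= 2; default 21, the study's cohort
#'   with simultaneous face and heart recordings).
#' @param duration Stream duration in seconds (default 120).
#' @param fps Frame rate (default 30).
#' @param tasks Task labels (default the four study tasks).
#' @param coupling A [coupling_spec()].
#' @param loglog_slope,loglog_intercept Cohort law on the log10 parameter
#'   plane (defaults -1 and -1).
#' @param loglog_noise Residual SD of the law (default 0.05).
#' @param shape_log10_range Range of log10(shape) across participants
#'   (default `c(0.3, 0.9)`).
#' @param delta_mean,delta_sd Mean and SD of the per-record control-to-pain
#'   NSR increase (defaults 0.08, 0.03).
#' @param delta_slope Slope linking facial to cardiac NSR shifts
#'   (default 1).
#' @param delta_r2_target Intended R-squared of the face~heart shift
#'   relation (default 0.84); the shift-noise SD is derived from it.
#' @param spike_rate Per-frame spike probability of each stream
#'   (default 0.25).
#' @param heart_regimes,face_regimes Optional fixed `list(control =, pain =)`
#'   [regime_spec()] pairs overriding the law-based per-participant draws;
#'   a pain scale below the control scale is a configuration error.
#' @param seed RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 21, duration = 120, fps = 30,
                          tasks = task_levels(),
                          coupling = coupling_spec(),
                          loglog_slope = -1, loglog_intercept = -1,
                          loglog_noise = 0.05,
                          shape_log10_range = c(0.3, 0.9),
                          delta_mean = 0.10, delta_sd = 0.05,
                          delta_slope = 1, delta_r2_target = 0.84,
                          spike_rate = 0.25,
                          heart_regimes = NULL, face_regimes = NULL,
                          seed = 1) {
  if (n_participants < 2) stopf("Need >= 2 participants.",
                                class = "mmspike_parameter_error")
  check_scalar(duration, positive = TRUE)
  check_scalar(fps, positive = TRUE)
  stopifnot(inherits(coupling, "coupling_spec"))
  check_regimes <- function(r, what) {
    if (is.null(r)) return(invisible())
    if (!all(c("control", "pain") %in% names(r))) {
      stopf("`%s` must name control and pain regimes.", what,
            class = "mmspike_config_error")
    }
    if (r$pain$scale < r$control$scale) {
      stopf("`%s`: pain scale (%.4g) below control scale (%.4g).",
            what, r$pain$scale, r$control$scale,
            class = "mmspike_config_error")
    }
  }
  check_regimes(heart_regimes, "heart_regimes")
  check_regimes(face_regimes, "face_regimes")
  if (is.null(heart_regimes) != is.null(face_regimes)) {
    stopf("Provide both or neither of heart_regimes/face_regimes.",
          class = "mmspike_config_error")
  }
  if (delta_r2_target <= 0 || delta_r2_target > 1) {
    stopf("`delta_r2_target` must be in (0, 1].",
          class = "mmspike_config_error")
  }
  structure(list(n_participants = as.integer(n_participants),
                 duration = duration, fps = fps, tasks = tasks,
                 coupling = coupling,
                 loglog_slope = loglog_slope,
                 loglog_intercept = loglog_intercept,
                 loglog_noise = loglog_noise,
                 shape_log10_range = shape_log10_range,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 delta_slope = delta_slope,
                 delta_r2_target = delta_r2_target,
                 spike_rate = spike_rate,
                 heart_regimes = heart_regimes,
                 face_regimes = face_regimes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# One spike stream on the frame grid: Bernoulli spike occurrence with
# Gamma amplitudes, zeros elsewhere (amplitudes capped below 1).
gen_spike_stream <- function(n_frames, shape, scale, spike_rate) {
  values <- numeric(n_frames)
  at <- which(runif(n_frames) < spike_rate)
  if (length(at)) {
    values[at] <- rgamma_trunc(length(at), shape, scale, 0, 0.999)
  }
  values
}

#' Generate a coupled synthetic face/heart cohort
#'
#' For every participant x task x condition record, paired heart-MMS and
#' face-MMS spike streams are generated on a common frame grid. Per-record
#' Gamma signatures are drawn so that log10(scale) follows the configured
#' linear law in log10(shape) (pain points are placed back on the law after
#' the NSR shift); the control-to-pain NSR shifts of face and heart are
#' linearly related with noise calibrated to the configured R-squared
#' target; and, when coupling is requested, the target stream's spike
#' amplitude at frame t mixes its own draw with the source amplitude at
#' t - lag: `target_t = (1 - strength) * own_t + strength * source_(t-lag)`.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (tibble: `participant`, `task`, `condition`,
#'   list-columns `face_mms` and `heart_mms` of per-frame spike streams)
#'   and `truth` (tibble of every injected per-record parameter, plus the
#'   config echo as attribute `config`).
#' @export
gen_coupled_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_frames <- floor(config$duration * config$fps)
  cp <- config$coupling
  # asymptotic variance of the ML scale estimate for a Gamma(a, b) fit on
  # n spikes (inverse observed information)
  var_bhat <- function(a, b, n) trigamma(a) * b^2 / (n * (a * trigamma(a) - 1))
  with_seed(config$seed, {
    grid <- tidyr::expand_grid(participant = seq_len(config$n_participants),
                               task = config$tasks)
    draw_params <- function(stream) {
      fixed <- config[[paste0(stream, "_regimes")]]
      if (!is.null(fixed)) {
        return(tibble::tibble(
          shape_control = rep(fixed$control$shape, nrow(grid)),
          scale_control = fixed$control$scale,
          shape_pain = fixed$pain$shape,
          scale_pain = fixed$pain$scale,
          delta = fixed$pain$scale - fixed$control$scale))
      }
      la <- runif(nrow(grid), config$shape_log10_range[1],
                  config$shape_log10_range[2])
      lb <- config$loglog_intercept + config$loglog_slope * la +
        rnorm(nrow(grid), 0, config$loglog_noise)
      tibble::tibble(shape_control = 10^la, scale_control = 10^lb)
    }
    heart <- draw_params("heart")
    face <- draw_params("face")
    if (is.null(config$heart_regimes)) {
      back_on_law0 <- function(b) {
        10^((log10(b) - config$loglog_intercept) / config$loglog_slope)
      }
      dH <- pmax(rnorm(nrow(grid), config$delta_mean, config$delta_sd), 1e-4)
      # Calibrate the face-shift noise so the *fitted* delta relation
      # attains the configured R^2: the downstream Gamma fits add known
      # estimation noise (var_bhat) on both axes, which attenuates the
      # observed R^2 relative to the latent one; subtract that analytic
      # contribution when solving for the latent noise SD.
      n_spk <- n_frames * config$spike_rate
      sl <- config$delta_slope
      s2d <- var(dH)
      v_uH <- mean(var_bhat(heart$shape_control, heart$scale_control, n_spk) +
                     var_bhat(back_on_law0(heart$scale_control + dH),
                              heart$scale_control + dH, n_spk))
      v_uF <- mean(var_bhat(face$shape_control, face$scale_control, n_spk) +
                     var_bhat(back_on_law0(face$scale_control + sl * dH),
                              face$scale_control + sl * dH, n_spk))
      v_eps <- sl^2 * s2d^2 / (config$delta_r2_target * (s2d + v_uH)) -
        sl^2 * s2d - v_uF
      if (v_eps < 0) {
        warnf(paste("delta_r2_target %.2f unattainable at this stream length;",
                    "using zero shift noise."), config$delta_r2_target)
        v_eps <- 0
      }
      dF <- pmax(sl * dH + rnorm(nrow(grid), 0, sqrt(v_eps)), 1e-4)
      heart$delta <- dH
      face$delta <- dF
      heart$scale_pain <- heart$scale_control + dH
      face$scale_pain <- face$scale_control + dF
      # pain shapes track the law so pain points stay on the log-log line
      back_on_law <- function(b) {
        10^((log10(b) - config$loglog_intercept) / config$loglog_slope)
      }
      heart$shape_pain <- back_on_law(heart$scale_pain)
      face$shape_pain <- back_on_law(face$scale_pain)
    }
    records <- tidyr::expand_grid(grid, condition = condition_levels())
    face_streams <- vector("list", nrow(records))
    heart_streams <- vector("list", nrow(records))
    for (r in seq_len(nrow(records))) {
      g <- which(grid$participant == records$participant[r] &
                   grid$task == records$task[r])
      cond <- records$condition[r]
      hs <- if (cond == "control") {
        c(heart$shape_control[g], heart$scale_control[g])
      } else {
        c(heart$shape_pain[g], heart$scale_pain[g])
      }
      fsp <- if (cond == "control") {
        c(face$shape_control[g], face$scale_control[g])
      } else {
        c(face$shape_pain[g], face$scale_pain[g])
      }
      h_stream <- gen_spike_stream(n_frames, hs[1], hs[2], config$spike_rate)
      f_stream <- gen_spike_stream(n_frames, fsp[1], fsp[2], config$spike_rate)
      if (cp$direction == "heart_to_face" && cp$strength > 0) {
        lagged <- c(numeric(cp$lag), h_stream[seq_len(n_frames - cp$lag)])
        f_stream <- (1 - cp$strength) * f_stream + cp$strength * lagged
      } else if (cp$direction == "face_to_heart" && cp$strength > 0) {
        lagged <- c(numeric(cp$lag), f_stream[seq_len(n_frames - cp$lag)])
        h_stream <- (1 - cp$strength) * h_stream + cp$strength * lagged
      }
      face_streams[[r]] <- f_stream
      heart_streams[[r]] <- h_stream
    }
    truth <- dplyr::bind_cols(
      grid,
      stats::setNames(heart, paste0("heart_", names(heart))),
      stats::setNames(face, paste0("face_", names(face)))
    )
    attr(truth, "config") <- config
    cohort <- dplyr::mutate(records,
                            face_mms = face_streams,
                            heart_mms = heart_streams)
    list(cohort = cohort, truth = truth)
  })
}
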