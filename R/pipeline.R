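# Cohort-level orchestration: landmark tables -> regional MMS, spike
# streams -> Gamma fits, deltas, power law, rank tests, transfer entropy,
# EMD clustering, and the report bundle.

#' Regional MMS spike samples from a landmark table
#'
#' Runs the facial pipeline per landmark (optional spline smoothing, speed
#' magnitude, MMS standardization) and pools spike amplitudes by
#' trigeminal region.
#'
#' @param landmarks Landmark tibble (see [gen_face_landmarks()] /
#'   [read_landmarks_csv()]).
#' @param fps Frame rate (default inferred from `timestamp_s`).
#' @param smooth Apply [smooth_positions()] first (default `FALSE`; enable
#'   for jittery real landmark estimates).
#' @param region_table Region membership (default [face_regions()]).
#' @param min_peaks Gamma-fit floor passed to [mms_transform()].
#' @param ... Passed to [smooth_positions()].
#' @return Named list (`V1`, `V2`, `V3`, ...) of pooled spike-amplitude
#'   vectors, with the per-landmark `mms_series` list as attribute
#'   `per_landmark`.
#' @export
region_mms_samples <- function(landmarks, fps = NULL, smooth = FALSE,
                               region_table = face_regions(),
                               min_peaks = 30, ...) {
  fps <- fps %||% (1 / stats::median(diff(landmarks$timestamp_s)))
  ids <- region_table$landmark[
    paste0("x_", region_table$landmark) %in% names(landmarks)]
  mms_list <- list()
  for (id in ids) {
    x <- landmarks[[paste0("x_", id)]]
    y <- landmarks[[paste0("y_", id)]]
    if (smooth) {
      sm <- smooth_positions(x, y, fps = fps, ...)
      x <- sm$x
      y <- sm$y
    }
    sp <- speed_profile(x, y, fps = fps)
    mms_list[[as.character(id)]] <- mms_transform(sp, min_peaks = min_peaks)
  }
  regions <- unique(region_table$region)
  out <- lapply(regions, function(r) {
    pool_region_mms(mms_list, r, region_table)
  })
  names(out) <- regions
  attr(out, "per_landmark") <- mms_list
  out
}

#' Run the full cohort analysis
#'
#' Given a cohort of paired face/heart spike streams (one record per
#' participant x task x condition), computes: per-record Gamma fits and
#' NSR/skewness descriptors for both streams; the cohort log-log
#' shape--scale law per stream; control-to-pain NSR deltas per
#' participant/task; the face~heart delta linear fit per task; rank-sum
#' control-vs-pain comparisons per task; bidirectional windowed transfer
#' entropy per record; and EMD-based tree clustering of the facial spike
#' distributions. Records whose streams cannot be fitted are skipped and
#' logged, never aborting the cohort.
#'
#' @param cohort Cohort tibble with columns `participant`, `task`,
#'   `condition` and list-columns `face_mms`, `heart_mms` (per-frame spike
#'   streams), as produced by [gen_coupled_cohort()].
#' @param te_cfg [te_config()] for the transfer-entropy stage (default
#'   gaussian estimator at the standard 50/5/300 windowing).
#' @param cluster_k Number of EMD clusters (default 8, capped at the number
#'   of usable records).
#' @param min_spikes Minimum spikes per stream for a Gamma fit
#'   (default 30).
#' @return List of tibbles/objects: `fits`, `powerlaw` (per stream),
#'   `deltas`, `delta_fits` (per task), `ranksum` (per task x stream),
#'   `te`, `clusters`, `skipped`.
#' @export
run_cohort_analysis <- function(cohort,
                                te_cfg = te_config(estimator = "gaussian"),
                                cluster_k = 8, min_spikes = 30) {
  fit_row <- function(stream_values, min_spikes) {
    pk <- stream_values[stream_values > 0]
    if (length(pk) < min_spikes) return(NULL)
    fit_gamma_mle(pk, min_n = min_spikes)
  }
  rows <- list()
  te_rows <- list()
  skipped <- list()
  for (r in seq_len(nrow(cohort))) {
    rec <- cohort[r, ]
    for (stream in c("face", "heart")) {
      v <- rec[[paste0(stream, "_mms")]][[1]]
      fit <- fit_row(v, min_spikes)
      if (is.null(fit)) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          participant = rec$participant, task = rec$task,
          condition = rec$condition, stream = stream,
          reason = "too few spikes for Gamma fit")
        next
      }
      m <- gamma_moments(fit)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = rec$participant, task = rec$task,
        condition = rec$condition, stream = stream,
        shape = fit$shape, scale = fit$scale,
        shape_lo = fit$ci_shape[1], shape_hi = fit$ci_shape[2],
        scale_lo = fit$ci_scale[1], scale_hi = fit$ci_scale[2],
        nsr = m$nsr, skewness = m$skewness, n_spikes = fit$n)
    }
    te <- tryCatch(
      te_both_directions(rec$face_mms[[1]], rec$heart_mms[[1]], te_cfg),
      error = function(e) NULL)
    if (is.null(te)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        participant = rec$participant, task = rec$task,
        condition = rec$condition, stream = "both",
        reason = "transfer entropy failed (streams too short?)")
    } else {
      te_rows[[length(te_rows) + 1]] <- tibble::tibble(
        participant = rec$participant, task = rec$task,
        condition = rec$condition,
        direction = c("heart->face", "face->heart"),
        te_bits = c(te$heart_to_face$te_bits, te$face_to_heart$te_bits),
        n_windows = c(te$heart_to_face$n_windows, te$face_to_heart$n_windows))
    }
  }
  fits <- dplyr::bind_rows(rows)
  te_tbl <- dplyr::bind_rows(te_rows)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(participant = integer(), task = character(),
                   condition = character(), stream = character(),
                   reason = character())

  few_participants <- length(unique(cohort$participant)) < 3
  powerlaw <- NULL
  if (!few_participants) {
    powerlaw <- lapply(split(fits, fits$stream), fit_loglog_law)
  } else {
    skipped <- dplyr::bind_rows(skipped, tibble::tibble(
      participant = NA_integer_, task = NA_character_,
      condition = NA_character_, stream = "cohort",
      reason = "cohort-level law, delta fits and clustering need >= 3 participants"))
  }

  deltas <- NULL
  if (nrow(fits) && all(condition_levels() %in% fits$condition)) {
    deltas <- fits |>
      dplyr::select("participant", "task", "condition", "stream", "nsr",
                    "skewness") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = c("nsr", "skewness")) |>
      dplyr::filter(!is.na(.data$nsr_pain), !is.na(.data$nsr_control)) |>
      dplyr::mutate(delta_nsr = .data$nsr_pain - .data$nsr_control,
                    delta_skewness = .data$skewness_pain - .data$skewness_control)
  }

  delta_fits <- NULL
  if (!few_participants && !is.null(deltas) && nrow(deltas)) {
    wide <- deltas |>
      dplyr::select("participant", "task", "stream", "delta_nsr") |>
      tidyr::pivot_wider(names_from = "stream", values_from = "delta_nsr")
    delta_fits <- wide |>
      dplyr::group_by(.data$task) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 3) return(tibble::tibble())
        glance(delta_linear_fit(delta_face = d$face, delta_heart = d$heart))
      }) |>
      dplyr::ungroup()
  }

  ranksum <- fits |>
    dplyr::group_by(.data$task, .data$stream) |>
    dplyr::group_modify(function(d, key) {
      if (min(table(d$condition)) < 3 || length(unique(d$condition)) < 2) {
        return(tibble::tibble())
      }
      p <- ranksum_matrix(d, "nsr", "condition")["control", "pain"]
      tibble::tibble(p_value = p)
    }) |>
    dplyr::ungroup()

  clusters <- NULL
  samples <- lapply(seq_len(nrow(cohort)), function(r) {
    v <- cohort$face_mms[[r]]
    v[v > 0]
  })
  names(samples) <- paste(cohort$participant, cohort$task, cohort$condition,
                          sep = "_")
  sizes <- vapply(samples, length, integer(1))
  usable <- sizes >= min_spikes
  if (!few_participants && sum(usable) >= 2) {
    k <- min(cluster_k, sum(usable))
    em <- emd_matrix(samples[usable], min_n = min_spikes)
    clusters <- cluster_tree(em, k = k,
                             condition = cohort$condition[usable])
    clusters$emd <- em
  }

  list(fits = fits, powerlaw = powerlaw, deltas = deltas,
       delta_fits = delta_fits, ranksum = ranksum, te = te_tbl,
       clusters = clusters, skipped = skipped)
}

#' Write the analysis report bundle with a checksummed manifest
#'
#' Writes every result table as CSV, the power-law and summary objects as
#' JSON, and a manifest listing each artifact with its SHA-256 checksum,
#' the configuration echo, and the package version. Reruns with the same
#' seed produce byte-identical artifacts.
#'
#' @param results Output of [run_cohort_analysis()].
#' @param outdir Output directory (created if needed; must be writable).
#' @param config Optional [cohort_config()] echoed into the manifest.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
write_report <- function(results, outdir, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({
    writeLines("", probe)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("Output directory '%s' is not writable.", outdir,
                 class = "mmspike_io_error")
  unlink(probe)

  paths <- character(0)
  put_csv <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  put_json <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[length(paths) + 1]] <<- p
  }
  put_csv(results$fits, "fits.csv")
  put_csv(results$deltas, "deltas.csv")
  put_csv(results$delta_fits, "delta_fits.csv")
  put_csv(results$ranksum, "ranksum.csv")
  put_csv(results$te, "te.csv")
  put_csv(results$skipped, "skipped.csv")
  if (!is.null(results$powerlaw)) {
    put_json(lapply(results$powerlaw, function(p) {
      p[c("slope", "intercept", "r_squared", "residual_sd", "n")]
    }), "powerlaw.json")
  }
  if (!is.null(results$clusters)) {
    put_csv(tibble::tibble(record = names(results$clusters$labels),
                           cluster = unname(results$clusters$labels)),
            "clusters.csv")
    put_csv(results$clusters$composition, "cluster_composition.csv")
  }
  n_fitted <- if (nrow(results$fits)) nrow(results$fits) else 0
  put_json(list(n_records_fitted = n_fitted,
                n_skipped = nrow(results$skipped)),
           "summary.json")

  checksum <- function(p) {
    con <- file(p, "rb")
    on.exit(close(con))
    unclass(as.character(openssl::sha256(con)))
  }
  manifest <- list(
    package = "mmspike",
    version = as.character(utils::packageVersion("mmspike")),
    config = if (!is.null(config)) {
      strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
      cfg <- strip(config)
      cfg[!vapply(cfg, is.null, logical(1))]
    } else NULL,
    n_artifacts = length(paths),
    artifacts = lapply(paths, function(p) {
      list(file = basename(p), sha256 = checksum(p))
    })
  )
  put_json(manifest, "manifest.json")
  invisible(manifest)
}

#' Write / load a cohort of spike streams as plain-text files
#'
#' `write_cohort()` stores each record's face and heart streams as CSV
#' (`frame`, `value`) plus a `records.csv` index; `load_cohort()` reads the
#' directory back into the cohort tibble, validating the index (unique
#' keys, closed task/condition vocabularies) and every stream file.
#'
#' @param cohort Cohort tibble (see [gen_coupled_cohort()]).
#' @param dir Directory.
#' @return `load_cohort()` returns the cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- dplyr::select(cohort, "participant", "task", "condition")
  idx$face_file <- sprintf("p%02d_%s_%s_face.csv", cohort$participant,
                           cohort$task, cohort$condition)
  idx$heart_file <- sub("_face", "_heart", idx$face_file)
  for (r in seq_len(nrow(cohort))) {
    utils::write.csv(data.frame(frame = seq_along(cohort$face_mms[[r]]),
                                value = cohort$face_mms[[r]]),
                     file.path(dir, idx$face_file[r]), row.names = FALSE)
    utils::write.csv(data.frame(frame = seq_along(cohort$heart_mms[[r]]),
                                value = cohort$heart_mms[[r]]),
                     file.path(dir, idx$heart_file[r]), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(idx), file.path(dir, "records.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  idx_path <- file.path(dir, "records.csv")
  if (!file.exists(idx_path)) {
    stopf("%s: missing records.csv index.", dir, class = "mmspike_load_error")
  }
  idx <- utils::read.csv(idx_path)
  key <- paste(idx$participant, idx$task, idx$condition)
  if (anyDuplicated(key)) {
    stopf("Duplicate record key: %s", key[duplicated(key)][1],
          class = "mmspike_load_error")
  }
  if (!all(idx$task %in% c(task_levels(), "post_pain"))) {
    stopf("Unknown task label in records.csv.", class = "mmspike_load_error")
  }
  if (!all(idx$condition %in% c(condition_levels(), "post_pain"))) {
    stopf("Unknown condition label in records.csv.",
          class = "mmspike_load_error")
  }
  read_stream <- function(f) {
    df <- utils::read.csv(file.path(dir, f))
    if (any(diff(df$frame) <= 0)) {
      stopf("%s: non-monotone frame index at row %d.", f,
            which(diff(df$frame) <= 0)[1] + 1, class = "mmspike_load_error")
    }
    df$value
  }
  tibble::tibble(
    participant = idx$participant, task = idx$task, condition = idx$condition,
    face_mms = lapply(idx$face_file, read_stream),
    heart_mms = lapply(idx$heart_file, read_stream)
  )
}
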