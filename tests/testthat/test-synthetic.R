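test_that("Gamma spike draws match theoretical moments and are seeded", {
  spec <- regime_spec(4, 0.5)
  x <- gen_gamma_mms_sample(spec, 1e5, seed = 61)
  # mean a*b = 2, variance a*b^2 = 1, within 3 standard errors
  expect_lt(abs(mean(x) - 2), 3 * sqrt(1 / 1e5))
  se_var <- sqrt((moment4 <- mean((x - mean(x))^4)) - var(x)^2) / sqrt(1e5)
  expect_lt(abs(var(x) - 1), 3 * se_var)

  e <- gen_gamma_mms_sample(regime_spec(1, 1), 1e5, seed = 62)
  sk <- mean((e - mean(e))^3) / sd(e)^3
  expect_lt(abs(sk - 2), 3 * sqrt(15 / 1e5) * 6)  # exponential skewness 2

  expect_identical(gen_gamma_mms_sample(spec, 1000, seed = 7),
                   gen_gamma_mms_sample(spec, 1000, seed = 7))
  expect_error(gen_gamma_mms_sample(spec, 0, seed = 1),
               class = "mmspike_parameter_error")
  expect_error(regime_spec(-1, 0.5), class = "mmspike_parameter_error")
})

test_that("synthetic IBI series reproduce their spike regime exactly", {
  ibi <- gen_ibi_series(800, regime_spec(2, 0.05), 600, seed = 63)
  expect_true(all(diff(ibi$r_times) > 0))
  m <- ibi_mms(ibi)
  truth <- attr(ibi, "true_spikes")
  expect_length(m$peak_values, length(truth))
  expect_equal(sort(m$peak_values), sort(truth), tolerance = 1e-10)

  expect_identical(gen_ibi_series(800, regime_spec(2, 0.05), 120, seed = 3),
                   gen_ibi_series(800, regime_spec(2, 0.05), 120, seed = 3))

  # zero-dispersion limit: nearly constant intervals, tiny Poincare axes
  ibi0 <- gen_ibi_series(800, regime_spec(2, 1e-5), 300, seed = 64)
  expect_lt(max(abs(ibi0$intervals - 800)) / 800, 0.02)
  ps <- poincare_sd(ibi0)
  expect_lt(ps$sd1, 5)
  expect_lt(ps$sd2, 5)

  expect_error(gen_ibi_series(800, regime_spec(2, 0.05), 5, seed = 1),
               class = "mmspike_degenerate_input")
})

test_that("downstream Gamma fits recover the injected IBI regime", {
  hits_shape <- 0
  hits_scale <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    ibi <- gen_ibi_series(800, regime_spec(2, 0.05), 600, seed = 1000 + s)
    fit <- fit_gamma_mle(ibi_mms(ibi)$peak_values)
    hits_shape <- hits_shape + (fit$ci_shape[1] <= 2 && 2 <= fit$ci_shape[2])
    hits_scale <- hits_scale +
      (fit$ci_scale[1] <= 0.05 && 0.05 <= fit$ci_scale[2])
  }
  expect_gte(hits_shape / n_seeds, 0.9)
  expect_gte(hits_scale / n_seeds, 0.9)
})

test_that("synthetic ECG round-trips through the R-peak detector", {
  ibi <- gen_ibi_series(800, regime_spec(2, 0.05), 120, seed = 65)
  ecg <- gen_ecg_from_ibi(ibi, fs = 250, noise_sd = 0.05, seed = 66)
  det <- detect_r_peaks(ecg)
  truth <- attr(ecg, "true_r_times")
  expect_lte(abs(length(det) - length(truth)), 0.01 * length(truth))
  hits <- vapply(truth, function(t) min(abs(det - t)) <= 4.001, logical(1))
  expect_gte(mean(hits), 0.99)

  expect_identical(gen_ecg_from_ibi(ibi, fs = 250, seed = 9)$samples,
                   gen_ecg_from_ibi(ibi, fs = 250, seed = 9)$samples)
  expect_error(gen_ecg_from_ibi(ibi, fs = 50), class = "mmspike_parameter_error")
})

test_that("landmark tables reproduce region regimes through the pipeline", {
  specs <- list(V1 = regime_spec(3, 0.05), V2 = regime_spec(2, 0.06),
                V3 = regime_spec(2.5, 0.05))
  lmk <- gen_face_landmarks(specs, duration = 30, seed = 67)
  expect_equal(nrow(lmk), 900)
  expect_equal(sum(grepl("^x_", names(lmk))), 68)

  pooled <- region_mms_samples(lmk)
  truth <- attr(lmk, "true_spikes")
  reg <- face_regions()
  for (rn in c("V1", "V2", "V3")) {
    ids <- as.character(reg$landmark[reg$region == rn])
    tr <- unlist(truth[ids], use.names = FALSE)
    expect_length(pooled[[rn]], length(tr))
    expect_equal(sort(pooled[[rn]]), sort(tr), tolerance = 1e-9)
  }

  expect_identical(gen_face_landmarks(specs, duration = 10, seed = 5),
                   gen_face_landmarks(specs, duration = 10, seed = 5))
  expect_error(gen_face_landmarks(specs[1:2], duration = 10, seed = 1),
               class = "mmspike_parameter_error")
})

test_that("pooled region fits recover the injected scale within its CI", {
  # nominal 95% CI coverage; the threshold leaves binomial room at 30 seeds
  hits <- 0
  rel_err <- numeric(0)
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    lmk <- gen_face_landmarks(list(V1 = regime_spec(3, 0.04),
                                   V2 = regime_spec(2, 0.05),
                                   V3 = regime_spec(2.5, 0.04)),
                              duration = 30, seed = 2000 + s)
    fit <- fit_gamma_mle(region_mms_samples(lmk)$V1)
    hits <- hits + (fit$ci_scale[1] <= 0.04 && 0.04 <= fit$ci_scale[2])
    rel_err <- c(rel_err, abs(fit$scale - 0.04) / 0.04)
  }
  expect_gte(hits / n_seeds, 0.85)
  expect_lt(mean(rel_err), 0.02)
})

test_that("a constant-speed landmark contributes no spikes", {
  m <- mms_transform(structure(list(values = rep(25, 300), fps = 30),
                               class = "speed_series"))
  expect_length(m$peak_values, 0)
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_participants = 1),
               class = "mmspike_parameter_error")
  expect_error(
    cohort_config(heart_regimes = list(control = regime_spec(2, 0.2),
                                       pain = regime_spec(2, 0.1)),
                  face_regimes = list(control = regime_spec(2, 0.1),
                                      pain = regime_spec(2, 0.2))),
    class = "mmspike_config_error")
  expect_error(
    cohort_config(heart_regimes = list(control = regime_spec(2, 0.1),
                                       pain = regime_spec(2, 0.2))),
    class = "mmspike_config_error")
  expect_error(coupling_spec("heart_to_face", lag = 0),
               class = "mmspike_parameter_error")
  expect_error(coupling_spec("heart_to_face", strength = 1.2),
               class = "mmspike_parameter_error")
  expect_equal(coupling_spec("none", strength = 1)$strength, 0)
})

test_that("coupled cohorts carry their ground truth and follow the law", {
  cfg <- cohort_config(n_participants = 12, duration = 20,
                       tasks = c("resting", "peg"), loglog_noise = 0,
                       seed = 68)
  cc <- suppressWarnings(gen_coupled_cohort(cfg))
  expect_equal(nrow(cc$cohort), 12 * 2 * 2)
  expect_true(all(c("face_mms", "heart_mms") %in% names(cc$cohort)))

  # zero cohort noise: the injected parameters sit exactly on the law
  pl <- suppressWarnings(fit_loglog_law(
    data.frame(shape = cc$truth$heart_shape_control,
               scale = cc$truth$heart_scale_control)))
  expect_equal(pl$slope, -1, tolerance = 1e-9)
  expect_equal(pl$r_squared, 1, tolerance = 1e-9)

  # pain NSR strictly above control for every record
  expect_true(all(cc$truth$heart_scale_pain > cc$truth$heart_scale_control))
  expect_true(all(cc$truth$face_scale_pain > cc$truth$face_scale_control))

  cc2 <- suppressWarnings(gen_coupled_cohort(cfg))
  expect_identical(cc$cohort$face_mms, cc2$cohort$face_mms)
  expect_identical(cc$truth$heart_scale_pain, cc2$truth$heart_scale_pain)
})

test_that("uncoupled streams show no systematic TE asymmetry", {
  cfg_te <- te_config(estimator = "gaussian")
  diffs <- vapply(1:10, function(s) {
    cc <- suppressWarnings(gen_coupled_cohort(cohort_config(
      n_participants = 2, duration = 10, tasks = "resting",
      coupling = coupling_spec("none"), seed = 300 + s)))
    rec <- cc$cohort[1, ]
    te <- te_both_directions(rec$face_mms[[1]], rec$heart_mms[[1]], cfg_te)
    te$heart_to_face$te_bits - te$face_to_heart$te_bits
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.1)
})
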