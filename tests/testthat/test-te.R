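test_that("Shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.7, 0.4)), class = "mmspike_domain_error")
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "mmspike_domain_error")
})

test_that("windowing configuration is validated", {
  cfg <- te_config()
  expect_equal(cfg$window, 50L)
  expect_equal(cfg$L, 5L)
  expect_equal(cfg$total_frames, 300L)
  expect_error(te_config(window = 400, total_frames = 300),
               class = "mmspike_parameter_error")
  expect_error(te_config(n_bins = 1), class = "mmspike_parameter_error")
})

test_that("deterministic lagged copy saturates TE at the alphabet entropy", {
  set.seed(41)
  x <- runif(3000)
  y <- c(0, 0, x[1:2998])
  cfg <- te_config(window = 3000, history_fraction = 2 / 3000,
                   total_frames = 3000, estimator = "binned", n_bins = 4)
  fwd <- transfer_entropy(x, y, cfg)
  rev <- transfer_entropy(y, x, cfg)
  # equal-frequency 4-bin alphabet: H = 2 bits
  expect_equal(fwd$te_bits, 2, tolerance = 0.05)
  expect_lt(rev$te_bits, 0.25)
  expect_gt(fwd$te_bits, 5 * rev$te_bits)
})

test_that("gaussian estimator matches the fitted-autoregression closed form", {
  set.seed(42)
  n <- 2000
  x <- rnorm(n)
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.8 * x[t - 1] + 0.6 * rnorm(1)
  cfg <- te_config(window = n, history_fraction = 1 / n, total_frames = n,
                   estimator = "gaussian")
  got <- transfer_entropy(x, y, cfg)$te_bits
  idx <- 2:n
  rss_r <- sum(residuals(lm(y[idx] ~ y[idx - 1]))^2)
  rss_f <- sum(residuals(lm(y[idx] ~ y[idx - 1] + x[idx - 1]))^2)
  expect_equal(got, 0.5 * log2(rss_r / rss_f), tolerance = 1e-3)
  expect_gte(got, 0)
  # reverse direction carries only overfit bias
  expect_lt(transfer_entropy(y, x, cfg)$te_bits, 0.01)
})

test_that("independent streams sit inside the plug-in bias band", {
  n <- 2000
  cfg <- te_config(window = n, history_fraction = 1 / n, total_frames = n,
                   estimator = "binned", n_bins = 4)
  tes <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      transfer_entropy(rnorm(n), rnorm(n), cfg)$te_bits
    })
  }, numeric(1))
  # analytic plug-in bias: df / (2 N ln 2), df = |Yp| (|Yt|-1) (|Xp|-1)
  bias <- 4 * 3 * 3 / (2 * (n - 1) * log(2))
  expect_gt(mean(tes), 0.5 * bias)
  expect_lt(mean(tes), 1.5 * bias)
})

test_that("shuffling the source collapses TE into the independence band", {
  set.seed(43)
  n <- 2000
  x <- rnorm(n)
  y <- c(0, 0.9 * x[-n]) + rnorm(n, 0, 0.3)
  cfg <- te_config(window = n, history_fraction = 1 / n, total_frames = n,
                   estimator = "binned", n_bins = 4)
  coupled <- transfer_entropy(x, y, cfg)$te_bits
  bias <- 4 * 3 * 3 / (2 * (n - 1) * log(2))
  shuffled <- vapply(1:20, function(s) {
    withr::with_seed(s, transfer_entropy(sample(x), y, cfg)$te_bits)
  }, numeric(1))
  expect_gt(coupled, 10 * bias)
  expect_lt(mean(shuffled), 2 * bias)
})

test_that("windowed TE aggregates complete windows and skips constants", {
  set.seed(44)
  x <- runif(300)
  y <- runif(300)
  cfg <- te_config()  # 50-frame windows, L = 5, 300 frames
  r <- transfer_entropy(x, y, cfg, direction = "x->y")
  expect_equal(r$n_windows, 6)
  expect_equal(r$te_bits, mean(r$per_window))

  y2 <- y
  y2[1:50] <- 0.5
  expect_warning(r2 <- transfer_entropy(x, y2, cfg), "constant")
  expect_equal(r2$n_windows, 5)

  expect_error(transfer_entropy(x, y[-1], cfg),
               class = "mmspike_alignment_error")
})

test_that("swapping stream roles swaps the two directions exactly", {
  set.seed(45)
  f <- runif(300)
  h <- runif(300)
  cfg <- te_config(estimator = "gaussian")
  ab <- te_both_directions(f, h, cfg)
  ba <- te_both_directions(h, f, cfg)
  expect_equal(ab$heart_to_face$te_bits, ba$face_to_heart$te_bits)
  expect_equal(ab$face_to_heart$te_bits, ba$heart_to_face$te_bits)
})

test_that("directional coupling in the synthetic cohort is recovered", {
  cfg <- te_config(estimator = "gaussian")
  hits <- 0
  for (s in 1:10) {
    cc <- suppressWarnings(gen_coupled_cohort(cohort_config(
      n_participants = 2, duration = 10, tasks = "resting",
      coupling = coupling_spec("heart_to_face", lag = 5, strength = 0.8),
      seed = s)))
    rec <- cc$cohort[1, ]
    te <- te_both_directions(rec$face_mms[[1]], rec$heart_mms[[1]], cfg)
    hits <- hits + (te$heart_to_face$te_bits > te$face_to_heart$te_bits)
  }
  expect_gte(hits, 9)
})

test_that("sorted and matched TE curves are assembled correctly", {
  tbl <- tibble::tibble(
    participant = rep(1:5, each = 2),
    direction = rep(c("heart->face", "face->heart"), 5),
    te_bits = c(0.3, 0.3, 0.1, 0.1, 0.5, 0.5, 0.2, 0.2, 0.4, 0.4))
  cv <- build_te_curves(tbl, "heart->face")
  expect_equal(cv$difference, rep(0, 5))
  expect_true(all(diff(cv$sorted_te) >= 0))
  expect_equal(cv$participant, c(2L, 4L, 1L, 5L, 3L))

  # participants missing a direction are excluded with a warning
  tbl2 <- tbl[-2, ]
  expect_warning(cv2 <- build_te_curves(tbl2, "heart->face"), "missing")
  expect_equal(nrow(cv2), 4)

  expect_error(build_te_curves(tbl, "nope"),
               class = "mmspike_parameter_error")

  # ground-truth coupling favours the matched curve on a coupled cohort
  cc <- suppressWarnings(gen_coupled_cohort(cohort_config(
    n_participants = 8, duration = 20, tasks = "resting",
    coupling = coupling_spec("heart_to_face", lag = 5, strength = 0.8),
    seed = 7)))
  cfg <- te_config(estimator = "gaussian")
  te_tbl <- purrr::map_dfr(seq_len(nrow(cc$cohort)), function(r) {
    rec <- cc$cohort[r, ]
    if (rec$condition != "control") return(tibble::tibble())
    te <- te_both_directions(rec$face_mms[[1]], rec$heart_mms[[1]], cfg)
    tibble::tibble(participant = rec$participant,
                   direction = c("heart->face", "face->heart"),
                   te_bits = c(te$heart_to_face$te_bits,
                               te$face_to_heart$te_bits))
  })
  cv3 <- build_te_curves(te_tbl, sort_direction = "face->heart")
  expect_gt(mean(cv3$matched_te), mean(cv3$sorted_te))
})
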