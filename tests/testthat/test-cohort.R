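test_that("rank-sum matrix is symmetric with unit diagonal", {
  set.seed(51)
  df <- data.frame(
    v = c(rnorm(30), rnorm(30), rnorm(30, 5)),
    g = rep(c("a", "b", "c"), each = 30))
  df$v[31:60] <- df$v[1:30]          # group b identical to a
  m <- ranksum_matrix(df, "v", "g")
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_gt(m["a", "b"], 0.99)       # identical groups
  expect_lt(m["a", "c"], 1e-6)       # 5-SD shift
  expect_true(all(m > 0 & m <= 1))

  tiny <- rbind(df, data.frame(v = 1:2, g = "d"))
  expect_warning(m2 <- ranksum_matrix(tiny, "v", "g"), "Excluding")
  expect_equal(dim(m2), c(3L, 3L))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(52)
  df <- data.frame(v = rexp(60), g = rep(c("a", "b"), each = 30))
  m1 <- ranksum_matrix(df, "v", "g")
  df2 <- transform(df, v = log(v + 1))
  m2 <- ranksum_matrix(df2, "v", "g")
  expect_equal(m1["a", "b"], m2["a", "b"])

  df3 <- data.frame(v = rexp(90), g = rep(c("a", "b", "c"), each = 30))
  k1 <- kruskal_multcompare(df3, "v", "g")
  df4 <- transform(df3, v = sqrt(v))
  k2 <- kruskal_multcompare(df4, "v", "g")
  expect_equal(k1$statistic, k2$statistic)
})

test_that("Kruskal-Wallis omnibus and pairwise follow-up work", {
  same <- data.frame(v = rep(c(1, 2, 3, 4), 3),
                     g = rep(c("a", "b", "c"), each = 4))
  k0 <- kruskal_multcompare(same, "v", "g")
  expect_equal(k0$statistic, 0)
  expect_equal(k0$p.value, 1)

  # hand-ranked oracle: 3 groups x 4 values with ties
  v <- c(1, 2, 2, 3,  2, 4, 5, 6,  7, 8, 9, 9)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- rank(v)
  N <- 12
  tie_tab <- table(v)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  H <- (12 / (N * (N + 1)) *
          sum(tapply(r, g, function(x) length(x) * mean(x)^2)) -
          3 * (N + 1)) / correction
  k <- kruskal_multcompare(data.frame(v = v, g = g), "v", "g")
  expect_equal(k$statistic, H, tolerance = 1e-12)
  expect_equal(k$statistic, unname(kruskal.test(v, factor(g))$statistic))

  # only the shifted group's pairs are flagged
  set.seed(53)
  df <- data.frame(v = c(rnorm(20), rnorm(20), rnorm(20, 8)),
                   g = rep(c("a", "b", "c"), each = 20))
  kk <- kruskal_multcompare(df, "v", "g")
  flags <- setNames(kk$pairwise$significant,
                    paste(kk$pairwise$group1, kk$pairwise$group2))
  expect_false(flags[["a b"]])
  expect_true(flags[["a c"]])
  expect_true(flags[["b c"]])

  expect_error(kruskal_multcompare(df[df$g != "c", ], "v", "g"),
               class = "mmspike_parameter_error")
})

test_that("Friedman test handles blocks, ties and invariances", {
  m <- matrix(rep(rnorm(6), 3), 6, 3)   # identical conditions per block
  f0 <- friedman_test(m)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p.value, 1)

  set.seed(54)
  m2 <- matrix(rnorm(30), 10, 3)
  m2[, 3] <- m2[, 3] + 2
  f1 <- friedman_test(m2)
  f2 <- friedman_test(m2[sample(10), ])
  expect_equal(f1$statistic, f2$statistic)
  expect_lt(f1$p.value, 0.05)

  # two conditions: direction agrees with the sign test
  m3 <- cbind(rnorm(12), rnorm(12) + 3)
  f3 <- friedman_test(m3)
  expect_lt(f3$p.value, 0.01)

  m4 <- m2
  m4[2, 2] <- NA
  expect_error(friedman_test(m4), class = "mmspike_incomplete_block")
})

test_that("earth mover's distance is exact and metric", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  # point masses: pure translation
  expect_equal(emd_1d(rep(0.3, 40), rep(0.5, 40)), 0.2)
  expect_equal(emd_1d(rep(0.3, 40), rep(0.5, 25)), 0.2)

  set.seed(55)
  for (i in 1:10) {
    x <- rgamma(sample(30:80, 1), 2, scale = 0.1)
    y <- rgamma(sample(30:80, 1), 3, scale = 0.2)
    expect_equal(emd_1d(x, y), emd_quantile_oracle(x, y), tolerance = 1e-9)
  }

  # metric axioms on random triples
  for (i in 1:100) {
    x <- rnorm(40)
    y <- rnorm(35, 1)
    z <- rnorm(50, -1)
    dxy <- emd_1d(x, y)
    dyz <- emd_1d(y, z)
    dxz <- emd_1d(x, z)
    expect_equal(dxy, emd_1d(y, x))
    expect_gte(dxy, 0)
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})

test_that("EMD matrix construction validates and summarizes records", {
  set.seed(56)
  samples <- list(a = rgamma(50, 2, scale = 0.1),
                  b = rgamma(60, 2, scale = 0.1),
                  c = rgamma(55, 2, scale = 0.4))
  m <- emd_matrix(samples)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_gt(m["a", "c"], m["a", "b"])
  expect_warning(emd_matrix(c(samples, list(d = c(0.1, 0.2)))), "Excluding")
})

test_that("tree clustering recovers structure and ignores input order", {
  set.seed(57)
  samples <- c(lapply(1:6, function(i) rnorm(50, 0, 0.1)),
               lapply(1:6, function(i) rnorm(50, 5, 0.1)))
  names(samples) <- paste0("r", 1:12)
  m <- emd_matrix(samples)
  cl <- cluster_tree(m, k = 2)
  expect_equal(length(unique(cl$labels[1:6])), 1)
  expect_equal(length(unique(cl$labels[7:12])), 1)
  expect_false(cl$labels[1] == cl$labels[7])

  # k = n: singletons with 100% own-label composition
  cln <- cluster_tree(m, k = 12, condition = rep(c("control", "pain"), 6))
  expect_equal(sort(unname(cln$labels)), 1:12)
  comp <- cln$composition
  expect_true(all(comp$pct_control + comp$pct_pain == 100))
  expect_true(all(pmax(comp$pct_control, comp$pct_pain) == 100))

  # permuting records permutes labels but not the partition
  perm <- sample(12)
  cl2 <- cluster_tree(m[perm, perm], k = 2)
  same1 <- outer(cl$labels[perm], cl$labels[perm], "==")
  same2 <- outer(cl2$labels, cl2$labels, "==")
  expect_identical(same1, same2)

  expect_error(cluster_tree(m, k = 13), class = "mmspike_parameter_error")
})

test_that("delta linear fit reports slope, R-squared and RMSE", {
  d <- suppressWarnings(delta_linear_fit(delta_face = c(1, 2, 3, 4) * 0.5 + 1,
                                         delta_heart = c(1, 2, 3, 4)))
  expect_equal(d$r_squared, 1)
  expect_equal(d$rmse, 0, tolerance = 1e-12)
  expect_equal(d$slope, 0.5)
  expect_equal(d$intercept, 1)
  expect_lte(d$adj_r_squared, d$r_squared)

  expect_error(delta_linear_fit(delta_face = 1:2, delta_heart = 1:2),
               class = "mmspike_insufficient_sample")
  expect_error(delta_linear_fit(delta_face = 1:4, delta_heart = 1:5),
               class = "mmspike_join_error")

  # independent pairs: R^2 follows the Beta(1/2, (n-2)/2) null
  set.seed(58)
  n <- 21
  r2 <- replicate(300, {
    delta_linear_fit(delta_face = rnorm(n), delta_heart = rnorm(n))$r_squared
  })
  ks <- suppressWarnings(
    stats::ks.test(r2, function(q) stats::pbeta(q, 0.5, (n - 2) / 2)))
  expect_gt(ks$p.value, 0.01)
})
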