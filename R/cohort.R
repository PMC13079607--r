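#' Pairwise Wilcoxon rank-sum p-value matrix
#'
#' Two-sided, tie-corrected rank-sum test for every pair of groups, with no
#' multiple-testing correction by default (raw pairwise p-values are
#' reported; set `p_adjust = "BH"` for Benjamini--Hochberg).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) holding the measurements and
#'   the group labels.
#' @param min_n Groups below this size are excluded with a warning
#'   (default 3).
#' @param p_adjust `"none"` (default) or a method name for
#'   [stats::p.adjust()].
#' @return Symmetric matrix of p-values with unit diagonal, class
#'   `ranksum_matrix`.
#' @export
ranksum_matrix <- function(data, value, group, min_n = 3, p_adjust = "none") {
  v <- data[[value]]
  g <- as.character(data[[group]])
  sizes <- table(g)
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    warnf("Excluding group(s) below n = %d: %s", min_n,
          paste(small, collapse = ", "))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  labs <- sort(unique(g))
  k <- length(labs)
  m <- matrix(1, k, k, dimnames = list(labs, labs))
  ps <- c()
  ij <- which(upper.tri(m), arr.ind = TRUE)
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    p <- suppressWarnings(
      wilcox.test(v[g == labs[i]], v[g == labs[j]], exact = FALSE)$p.value)
    ps <- c(ps, p)
  }
  if (p_adjust != "none") ps <- stats::p.adjust(ps, method = p_adjust)
  for (r in seq_len(nrow(ij))) {
    m[ij[r, 1], ij[r, 2]] <- m[ij[r, 2], ij[r, 1]] <- ps[r]
  }
  structure(m, class = c("ranksum_matrix", "matrix", "array"))
}

#' Kruskal--Wallis omnibus test with rank-based pairwise follow-up
#'
#' Tie-corrected Kruskal--Wallis chi-square across three or more groups,
#' followed by Tukey--Kramer-type pairwise comparisons on the mean joint
#' ranks: a pair is flagged significant when its mean-rank interval is
#' disjoint, i.e. when |R_i - R_j| exceeds q_(alpha,k,Inf)/sqrt(2) times
#' the tie-corrected standard error.
#'
#' @inheritParams ranksum_matrix
#' @param conf Family confidence level (default 0.95).
#' @return List with `statistic`, `p.value`, `df`, and `pairwise` tibble
#'   (`group1`, `group2`, `rank_diff`, `lower`, `upper`, `significant`).
#' @export
kruskal_multcompare <- function(data, value, group, conf = 0.95) {
  v <- data[[value]]
  g <- factor(data[[group]])
  k <- nlevels(g)
  if (k < 3) {
    stopf("Fewer than 3 groups; use ranksum_matrix() instead.",
          class = "mmspike_parameter_error")
  }
  kw <- kruskal.test(v, g)
  N <- length(v)
  r <- rank(v)
  tie_tab <- table(v)
  tie_factor <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tie_factor
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  qcrit <- qtukey(conf, k, Inf) / sqrt(2)
  labs <- levels(g)
  pw <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      group1 = labs[.data$i], group2 = labs[.data$j],
      rank_diff = mr[.data$i] - mr[.data$j],
      se = sqrt(s2 * (1 / ns[.data$i] + 1 / ns[.data$j])),
      lower = .data$rank_diff - qcrit * .data$se,
      upper = .data$rank_diff + qcrit * .data$se,
      significant = abs(.data$rank_diff) > qcrit * .data$se
    ) |>
    dplyr::select("group1", "group2", "rank_diff", "lower", "upper",
                  "significant")
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       df = unname(kw$parameter), pairwise = pw)
}

#' Friedman test on a complete participant-by-condition block design
#'
#' @param blocked Numeric matrix or data frame, rows = participants
#'   (blocks), columns = conditions; no missing cells allowed.
#' @return List with `statistic` (tie-corrected chi-square), `p.value`,
#'   `df`.
#' @export
friedman_test <- function(blocked) {
  m <- as.matrix(blocked)
  if (any(!is.finite(m))) {
    stopf("Friedman test requires complete blocks (no missing cells).",
          class = "mmspike_incomplete_block")
  }
  if (all(apply(m, 1, var) == 0)) {
    # every block fully tied: no evidence of a condition effect
    return(list(statistic = 0, p.value = 1, df = ncol(m) - 1))
  }
  ft <- friedman.test(m)
  list(statistic = unname(ft$statistic), p.value = ft$p.value,
       df = unname(ft$parameter))
}

#' Exact 1-D earth mover's distance between two samples
#'
#' Wasserstein-1 distance between the empirical distributions, computed as
#' the exact integral of |F1 - F2| over the merged support (equivalently
#' the integral of the absolute quantile difference).
#'
#' @param x,y Numeric samples.
#' @return Non-negative distance in the units of the data.
#' @export
emd_1d <- function(x, y) {
  check_numeric(x)
  check_numeric(y)
  if (length(x) == length(y)) return(mean(abs(sort(x) - sort(y))))
  z <- sort(c(x, y))
  zu <- unique(z)
  if (length(zu) < 2) return(0)
  fx <- ecdf(x)(zu)
  fy <- ecdf(y)(zu)
  n <- length(zu)
  sum(abs(fx[-n] - fy[-n]) * diff(zu))
}

#' Pairwise earth mover's distance matrix of MMS spike samples
#'
#' @param samples Named list of numeric spike-amplitude samples, one per
#'   record (participant x condition).
#' @param min_n Records with fewer values are excluded with a warning
#'   (default 30).
#' @return Symmetric non-negative matrix with zero diagonal, class
#'   `emd_matrix`.
#' @export
emd_matrix <- function(samples, min_n = 30) {
  sizes <- vapply(samples, length, integer(1))
  if (any(sizes < min_n)) {
    warnf("Excluding %d record(s) with fewer than %d values.",
          sum(sizes < min_n), min_n)
    samples <- samples[sizes >= min_n]
  }
  k <- length(samples)
  if (k < 2) stopf("Need at least 2 usable records.",
                   class = "mmspike_insufficient_sample")
  labs <- names(samples) %||% as.character(seq_len(k))
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- emd_1d(samples[[i]], samples[[j]])
    }
  }
  structure(m, class = c("emd_matrix", "matrix", "array"))
}

#' Hierarchical tree clustering of records from an EMD matrix
#'
#' Agglomerative clustering (average linkage by default) on the
#' precomputed earth-mover's distance matrix, cut into `k` clusters, with
#' per-cluster condition composition percentages.
#'
#' @param emd An [emd_matrix()] (or any symmetric distance matrix).
#' @param k Number of clusters (default 8).
#' @param condition Optional vector of condition labels (e.g. control/pain)
#'   aligned with the matrix rows, used for the composition summary.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `labels` (cluster id per record), `tree` (`hclust`),
#'   and `composition` tibble (`cluster`, `n`, one percentage column per
#'   condition level; rows sum to 100).
#' @export
cluster_tree <- function(emd, k = 8, condition = NULL, linkage = "average") {
  n <- nrow(emd)
  if (k > n) stopf("k (%d) exceeds the number of records (%d).", k, n,
                   class = "mmspike_parameter_error")
  tree <- hclust(as.dist(emd), method = linkage)
  labels <- cutree(tree, k = k)
  comp <- NULL
  if (!is.null(condition)) {
    comp <- tibble::tibble(cluster = labels, condition = condition) |>
      dplyr::count(.data$cluster, .data$condition) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      tidyr::pivot_wider(id_cols = "cluster", names_from = "condition",
                         values_from = "pct", values_fill = 0,
                         names_prefix = "pct_")
    comp$n <- as.integer(table(labels)[as.character(comp$cluster)])
  }
  list(labels = labels, tree = tree, composition = comp, k = k)
}

#' Linear fit of paired face vs heart noise shifts
#'
#' Ordinary least squares of the facial Delta-NSR (pain minus control) on
#' the cardiac Delta-NSR across participants, with the goodness-of-fit
#' summaries conventionally reported for such calibrations.
#'
#' @param data Optional data frame containing the two columns.
#' @param delta_face,delta_heart Column names (if `data` is given) or
#'   numeric vectors, paired by participant.
#' @return Object of class `delta_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `rmse` (sqrt(SSE/(n-2))), `n`, `model`.
#' @export
delta_linear_fit <- function(data = NULL, delta_face, delta_heart) {
  if (!is.null(data)) {
    delta_face <- data[[delta_face]]
    delta_heart <- data[[delta_heart]]
  }
  if (length(delta_face) != length(delta_heart)) {
    stopf("Delta vectors must be paired (equal length).",
          class = "mmspike_join_error")
  }
  n <- length(delta_face)
  if (n < 3) stopf("Need at least 3 pairs.",
                   class = "mmspike_insufficient_sample")
  m <- lm(delta_face ~ delta_heart)
  sm <- summary(m)
  sse <- sum(residuals(m)^2)
  structure(list(slope = unname(coef(m)[2]),
                 intercept = unname(coef(m)[1]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 rmse = sqrt(sse / (n - 2)),
                 n = n, model = m),
            class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat(sprintf(
    "<delta_fit> face ~ %.3g %+.3g * heart, R^2 = %.3f (adj %.3f), RMSE %.3g, n = %d\n",
    x$intercept, x$slope, x$r_squared, x$adj_r_squared, x$rmse, x$n))
  invisible(x)
}

#' @export
tidy.delta_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.delta_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 rmse = x$rmse, slope = x$slope, intercept = x$intercept,
                 nobs = x$n)
}
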