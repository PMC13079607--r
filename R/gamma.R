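#' Maximum-likelihood Gamma fit of spike amplitudes
#'
#' Fits the two-parameter Gamma family in the shape--scale
#' parameterization, f(x; a, b) = x^(a-1) exp(-x/b) / (b^a Gamma(a)), to a
#' positive sample by maximum likelihood. The shape solves the profile
#' score log(a) - digamma(a) = log(mean(x)) - mean(log(x)) by Newton
#' iteration from the standard closed-form starting value; the scale is
#' mean(x)/a, so the fitted Gamma mean equals the sample mean exactly.
#' 95% confidence intervals come from the observed information at the MLE.
#'
#' The scale parameter is the noise-to-signal ratio (NSR, variance over
#' mean) of the process; the skewness is 2/sqrt(shape). Both are exposed by
#' [gamma_moments()].
#'
#' @param x Positive numeric sample (spike amplitudes).
#' @param min_n Minimum sample size (default 30).
#' @param conf Confidence level for the intervals (default 0.95).
#' @return Object of class `gamma_fit`: list with `shape`, `scale`,
#'   `ci_shape`, `ci_scale`, `se_shape`, `se_scale`, `loglik`, `n`,
#'   `degenerate`.
#' @export
#' @examples
#' fit <- fit_gamma_mle(rgamma(500, shape = 2, scale = 0.05))
#' gamma_moments(fit)
fit_gamma_mle <- function(x, min_n = 30, conf = 0.95) {
  if (!is.numeric(x)) stopf("`x` must be numeric.")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stopf("Gamma fitting requires strictly positive finite values.",
          class = "mmspike_domain_error")
  }
  n <- length(x)
  if (n < min_n) {
    stopf("Need at least %d values for a Gamma fit (got %d).", min_n, n,
          class = "mmspike_insufficient_sample")
  }
  xbar <- mean(x)
  if (var(x) == 0) {
    # all values identical: zero-dispersion limit, flagged rather than fatal
    warnf("Degenerate sample (zero variance); returning flagged fit.")
    return(structure(list(shape = Inf, scale = 0,
                          ci_shape = c(Inf, Inf), ci_scale = c(0, 0),
                          se_shape = NA_real_, se_scale = NA_real_,
                          loglik = Inf, n = n, degenerate = TRUE,
                          mean = xbar),
                     class = "gamma_fit"))
  }
  s <- log(xbar) - mean(log(x))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:60) {
    f <- log(a) - digamma(a) - s
    df <- 1 / a - trigamma(a)
    step <- f / df
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  b <- xbar / a
  ll <- sum(dgamma(x, shape = a, scale = b, log = TRUE))
  # observed information at the MLE (equals Fisher information here);
  # inverted in closed form, stable even for very large shape values
  tg <- trigamma(a)
  det_m <- a * tg - 1
  se <- if (det_m > 0) {
    c(sqrt(a / (n * det_m)), sqrt(tg * b^2 / (n * det_m)))
  } else {
    c(NA_real_, NA_real_)
  }
  z <- qnorm(1 - (1 - conf) / 2)
  structure(list(shape = a, scale = b,
                 ci_shape = c(a - z * se[1], a + z * se[1]),
                 ci_scale = c(b - z * se[2], b + z * se[2]),
                 se_shape = se[1], se_scale = se[2],
                 loglik = ll, n = n, degenerate = FALSE,
                 mean = xbar),
            class = "gamma_fit")
}

#' Closed-form moments and descriptors of a Gamma fit
#'
#' @param fit A `gamma_fit`.
#' @return Tibble with one row: `mean` (a*b), `variance` (a*b^2), `nsr`
#'   (variance/mean = b, the noise-to-signal ratio) and `skewness`
#'   (2/sqrt(a)).
#' @export
gamma_moments <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  if (isTRUE(fit$degenerate)) {
    return(tibble::tibble(mean = fit$mean, variance = 0, nsr = 0, skewness = 0))
  }
  a <- fit$shape
  b <- fit$scale
  tibble::tibble(mean = a * b, variance = a * b^2, nsr = b,
                 skewness = 2 / sqrt(a))
}

#' @export
print.gamma_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<gamma_fit> degenerate (zero variance), n = %d\n", x$n))
    return(invisible(x))
  }
  cat(sprintf(
    "<gamma_fit> shape %.4g [%.4g, %.4g], scale (NSR) %.4g [%.4g, %.4g], n = %d\n",
    x$shape, x$ci_shape[1], x$ci_shape[2],
    x$scale, x$ci_scale[1], x$ci_scale[2], x$n))
  invisible(x)
}

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    std.error = c(x$se_shape, x$se_scale),
    conf.low = c(x$ci_shape[1], x$ci_scale[1]),
    conf.high = c(x$ci_shape[2], x$ci_scale[2])
  )
}

#' @export
glance.gamma_fit <- function(x, ...) {
  m <- gamma_moments(x)
  tibble::tibble(shape = x$shape, scale = x$scale, nsr = m$nsr,
                 skewness = m$skewness, mean = m$mean, variance = m$variance,
                 logLik = x$loglik, nobs = x$n, degenerate = x$degenerate)
}

#' Log-likelihood comparison of candidate distribution families
#'
#' Fits the normal, lognormal, Weibull and Gamma families to the same
#' positive sample by maximum likelihood (via fitdistrplus) and ranks them
#' by log-likelihood. No automatic selection is made beyond the ranking.
#'
#' @inheritParams fit_gamma_mle
#' @return Tibble with columns `family`, `loglik`, `aic`, `rank`
#'   (1 = highest log-likelihood).
#' @export
compare_families <- function(x, min_n = 30) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stopf("Family comparison requires strictly positive values.",
          class = "mmspike_domain_error")
  }
  if (length(x) < min_n) {
    stopf("Need at least %d values (got %d).", min_n, length(x),
          class = "mmspike_insufficient_sample")
  }
  fams <- c(normal = "norm", lognormal = "lnorm", weibull = "weibull",
            gamma = "gamma")
  fits <- purrr::map(fams, function(d) {
    suppressWarnings(fitdistrplus::fitdist(as.numeric(x), d))
  })
  out <- tibble::tibble(
    family = names(fams),
    loglik = unname(purrr::map_dbl(fits, "loglik")),
    aic = unname(purrr::map_dbl(fits, "aic"))
  )
  out$rank <- rank(-out$loglik, ties.method = "first")
  out
}

#' Cohort-level log-log shape--scale power law
#'
#' Across a cohort, the per-record Gamma (shape, scale) points align along a
#' line on the log10-log10 parameter plane with negative slope: noisier
#' (higher NSR) processes have lower shape, closer to the memoryless
#' exponential. This fits that law by ordinary least squares of log10(scale)
#' on log10(shape).
#'
#' @param fits A list of `gamma_fit` objects, or a data frame with columns
#'   `shape` and `scale`.
#' @return Object of class `powerlaw_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `n`, and the fitted `lm` as `model`.
#' @export
fit_loglog_law <- function(fits) {
  if (is.data.frame(fits)) {
    shape <- fits$shape
    scale <- fits$scale
  } else {
    shape <- vapply(fits, function(f) f$shape, numeric(1))
    scale <- vapply(fits, function(f) f$scale, numeric(1))
  }
  keep <- is.finite(shape) & is.finite(scale) & shape > 0 & scale > 0
  shape <- shape[keep]
  scale <- scale[keep]
  if (length(shape) < 3) {
    stopf("Need at least 3 finite (shape, scale) points.",
          class = "mmspike_insufficient_sample")
  }
  lx <- log10(shape)
  ly <- log10(scale)
  if (var(lx) == 0) {
    stopf("All shape values identical; slope undefined.",
          class = "mmspike_degenerate_input")
  }
  m <- lm(ly ~ lx)
  sm <- summary(m)
  structure(list(slope = unname(coef(m)[2]),
                 intercept = unname(coef(m)[1]),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 n = length(lx),
                 model = m),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> log10(scale) = %.4g %+.4g log10(shape), R^2 = %.3f, n = %d\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, residual.sd = x$residual_sd,
                 nobs = x$n)
}

#' Regional NSR/skewness vector summary
#'
#' Combines the per-region Gamma fits of the three facial subregions into
#' the NSR vector (V1, V2, V3), its Euclidean norm from the origin, the
#' matching skewness components and their norm. The norm summarizes facial
#' noise as a single scalar per record.
#'
#' @param v1,v2,v3 `gamma_fit` objects for the three regions.
#' @return One-row tibble with `nsr_v1`, `nsr_v2`, `nsr_v3`, `nsr_norm`,
#'   `skew_v1`, `skew_v2`, `skew_v3`, `skew_norm`.
#' @export
nsr_skew_summary <- function(v1, v2, v3) {
  fits <- list(v1, v2, v3)
  if (any(!vapply(fits, inherits, logical(1), "gamma_fit"))) {
    stopf("All three regions must be fitted `gamma_fit` objects.",
          class = "mmspike_parameter_error")
  }
  nsr <- vapply(fits, function(f) gamma_moments(f)$nsr, numeric(1))
  sk <- vapply(fits, function(f) gamma_moments(f)$skewness, numeric(1))
  tibble::tibble(
    nsr_v1 = nsr[1], nsr_v2 = nsr[2], nsr_v3 = nsr[3],
    nsr_norm = sqrt(sum(nsr^2)),
    skew_v1 = sk[1], skew_v2 = sk[2], skew_v3 = sk[3],
    skew_norm = sqrt(sum(sk^2))
  )
}

#' Pain-minus-control parameter deltas
#'
#' Subtracts control-condition descriptors from pain-condition descriptors,
#' either for two `gamma_fit` objects (returning delta NSR and delta
#' skewness) or for two matching one-row summaries from
#' [nsr_skew_summary()] (returning per-component and per-norm deltas).
#'
#' @param pain,control Matching `gamma_fit` objects or one-row data frames
#'   with identical numeric columns.
#' @return One-row tibble of deltas (pain minus control).
#' @export
delta_params <- function(pain, control) {
  if (inherits(pain, "gamma_fit") && inherits(control, "gamma_fit")) {
    mp <- gamma_moments(pain)
    mc <- gamma_moments(control)
    return(tibble::tibble(delta_nsr = mp$nsr - mc$nsr,
                          delta_skewness = mp$skewness - mc$skewness))
  }
  if (is.data.frame(pain) && is.data.frame(control)) {
    num <- intersect(names(pain)[vapply(pain, is.numeric, logical(1))],
                     names(control)[vapply(control, is.numeric, logical(1))])
    if (!length(num) || nrow(pain) != nrow(control)) {
      stopf("Mismatched inputs to delta_params().", class = "mmspike_join_error")
    }
    out <- purrr::map(num, function(cl) pain[[cl]] - control[[cl]])
    names(out) <- paste0("delta_", num)
    return(tibble::as_tibble(out))
  }
  stopf("Inputs must both be gamma_fit objects or both data frames.",
        class = "mmspike_join_error")
}
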