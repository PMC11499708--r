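#' Construct an MR estimate object
#'
#' Holds one method's causal estimate on the log-OR (or linear) scale with a
#' normal 95% CI and the exponentiated triple for odds-ratio reporting.
#'
#' @param method method label.
#' @param beta point estimate (log-OR per 1 SD exposure for binary outcomes).
#' @param se standard error.
#' @param pval two-sided p-value.
#' @param n_snp number of instruments used.
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, pval, n_snp) {
  beta <- unname(beta); se <- unname(se); pval <- unname(pval)
  z <- stats::qnorm(0.975)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snp = as.integer(n_snp),
                 or_scale = c(or = exp(beta), ci_low = exp(ci_low),
                              ci_high = exp(ci_high))),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s (k=%d): beta = %.*f (SE %.*f), OR = %.*f [%.*f, %.*f], p = %s\n",
              x$method, x$n_snp, digits, x$beta, digits, x$se,
              digits, x$or_scale["or"], digits, x$or_scale["ci_low"],
              digits, x$or_scale["ci_high"], format.pval(x$pval, digits = 2)))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snp = x$n_snp, or = unname(x$or_scale["or"]),
             or_low = unname(x$or_scale["ci_low"]),
             or_high = unname(x$or_scale["ci_high"]),
             stringsAsFactors = FALSE)
}

# inverse of Omega = D rho D via Cholesky; returns function multiplying by
# Omega^{-1}
omega_inverse <- function(se_y, rho, ridge = 1e-6) {
  rho <- ensure_pd(rho, ridge = ridge)
  Omega <- outer(se_y, se_y) * rho
  ch <- chol(Omega)
  function(x) backsolve(ch, forwardsolve(t(ch), x))
}

#' Correlation-adjusted inverse-variance-weighted estimator
#'
#' Generalized weighted least squares of outcome on exposure effects through
#' the origin, with weight matrix the inverse of `Omega = D rho D` where `D =
#' diag(se_y)` and `rho` is the instrument LD correlation matrix. With
#' identity `rho` this reduces to the classical IVW estimator
#' `sum(bx by / se^2) / sum(bx^2 / se^2)`. Under multiplicative random
#' effects the SE is inflated by `max(1, sqrt(Q / (k - 1)))`, where Q is the
#' generalized Cochran heterogeneity statistic. A single instrument gives the
#' first-order Wald ratio `by/bx` with `se = se_y / |bx|` and no Q.
#'
#' @param pairs a `harmonized_pairs` object.
#' @param random_effects logical; inflate the SE multiplicatively when
#'   heterogeneity exceeds its expectation (default TRUE).
#' @param use_ld logical; set FALSE to force identity correlation (default
#'   TRUE, i.e. adjust for the LD carried by `pairs`).
#' @return list with `estimate` (an [mr_estimate()], method
#'   `"ivw_correlated"` or `"wald_ratio"`) and `heterogeneity` (list `Q`,
#'   `df`, `pval`; NULL for a single instrument).
#' @export
ivw_correlated <- function(pairs, random_effects = TRUE, use_ld = TRUE) {
  k <- length(pairs$beta_x)
  assert_that(k >= 1, "no instruments")
  bx <- pairs$beta_x; by <- pairs$beta_y; sy <- pairs$se_y
  if (k == 1) {
    beta <- by / bx
    se <- sy / abs(bx)
    est <- mr_estimate("wald_ratio", beta, se,
                       2 * stats::pnorm(-abs(beta / se)), 1L)
    return(list(estimate = est, heterogeneity = NULL))
  }
  rho <- if (use_ld) pairs$ld else diag(k)
  Oi <- omega_inverse(sy, rho)
  Oibx <- Oi(bx)
  denom <- sum(bx * Oibx)
  beta <- sum(by * Oibx) / denom
  se_fixed <- sqrt(1 / denom)
  resid <- by - beta * bx
  Q <- sum(resid * Oi(resid))
  df <- k - 1
  se <- if (random_effects) se_fixed * max(1, sqrt(Q / df)) else se_fixed
  est <- mr_estimate("ivw_correlated", beta, se,
                     2 * stats::pnorm(-abs(beta / se)), k)
  list(estimate = est,
       heterogeneity = list(Q = Q, df = df,
                            pval = stats::pchisq(Q, df, lower.tail = FALSE)))
}

# flip pairs so that all exposure effects are non-negative (InSIDE
# orientation); LD rows/columns of flipped variants change sign
orient_positive <- function(pairs) {
  neg <- pairs$beta_x < 0
  if (!any(neg)) return(pairs)
  pairs$beta_x[neg] <- -pairs$beta_x[neg]
  pairs$beta_y[neg] <- -pairs$beta_y[neg]
  s <- ifelse(neg, -1, 1)
  pairs$ld <- pairs$ld * outer(s, s)
  pairs
}

#' MR-Egger regression with intercept test
#'
#' Generalized weighted regression of outcome on exposure effects with an
#' unconstrained intercept, using the same `Omega^{-1}` weighting as
#' [ivw_correlated()]. Instruments are first oriented so all exposure effects
#' are non-negative. A non-zero intercept indicates directional pleiotropy;
#' its p-value uses a t distribution with k - 2 degrees of freedom. Standard
#' errors are inflated multiplicatively by `max(1, sqrt(Q / (k - 2)))`.
#'
#' @param pairs `harmonized_pairs` with at least 3 instruments.
#' @param use_ld as in [ivw_correlated()].
#' @return list with `slope` and `intercept` ([mr_estimate()]s) and
#'   `heterogeneity` (`Q`, `df = k - 2`, `pval`). With fewer than 3
#'   instruments, returns `list(applicable = FALSE)`.
#' @export
mr_egger <- function(pairs, use_ld = TRUE) {
  k <- length(pairs$beta_x)
  if (k < 3) return(list(applicable = FALSE, reason = "fewer than 3 instruments"))
  pairs <- orient_positive(pairs)
  bx <- pairs$beta_x; by <- pairs$beta_y
  rho <- if (use_ld) pairs$ld else diag(k)
  Oi <- omega_inverse(pairs$se_y, rho)
  X <- cbind(intercept = 1, slope = bx)
  OiX <- apply(X, 2, Oi)
  XtOiX <- crossprod(X, OiX)
  V <- solve(XtOiX)
  coefs <- drop(V %*% crossprod(OiX, by))
  resid <- by - drop(X %*% coefs)
  Q <- sum(resid * Oi(resid))
  df <- k - 2
  infl <- max(1, sqrt(Q / df))
  ses <- sqrt(diag(V)) * infl
  pvals <- 2 * stats::pt(-abs(coefs / ses), df)
  list(applicable = TRUE,
       slope = mr_estimate("mr_egger", coefs["slope"], ses["slope"],
                           pvals["slope"], k),
       intercept = mr_estimate("mr_egger_intercept", coefs["intercept"],
                               ses["intercept"], pvals["intercept"], k),
       heterogeneity = list(Q = Q, df = df,
                            pval = stats::pchisq(Q, df, lower.tail = FALSE)))
}

# per-SNP ratio estimates and inverse-variance weights; drops bx == 0
ratio_estimates <- function(pairs) {
  nz <- pairs$beta_x != 0
  if (any(!nz)) message(sum(!nz), " instrument(s) with zero exposure effect excluded")
  list(r = pairs$beta_y[nz] / pairs$beta_x[nz],
       w = pairs$beta_x[nz]^2 / pairs$se_y[nz]^2,
       idx = which(nz))
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  stats::approx(cs, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# parametric bootstrap of a statistic of (bx, by)
boot_se <- function(pairs, stat, n_boot, seed) {
  set.seed(seed)
  k <- length(pairs$beta_x)
  vals <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, pairs$beta_x, pairs$se_x)
    by <- stats::rnorm(k, pairs$beta_y, pairs$se_y)
    stat(bx, by, pairs$se_y)
  }, numeric(1))
  stats::sd(vals)
}

#' Weighted-median estimator
#'
#' The weighted median of per-SNP ratio estimates `by_j / bx_j` under
#' inverse-variance weights `bx_j^2 / se_y_j^2`: the ratio at cumulative
#' normalized weight 0.5, linearly interpolated between adjacent order
#' statistics. Consistent when at least half the weight comes from valid
#' instruments. The SE comes from a parametric bootstrap (normal resampling
#' of bx and by).
#'
#' @param pairs `harmonized_pairs` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed bootstrap seed (recorded in the result).
#' @return an [mr_estimate()] (method `"weighted_median"`) with attribute
#'   `"seed"`, or `list(applicable = FALSE)` for k < 3.
#' @export
weighted_median <- function(pairs, n_boot = 5000, seed = 1L) {
  if (length(pairs$beta_x) < 3)
    return(list(applicable = FALSE, reason = "fewer than 3 instruments"))
  re <- ratio_estimates(pairs)
  point <- weighted_median_point(re$r, re$w)
  se <- boot_se(pairs, function(bx, by, sy) {
    nz <- bx != 0
    weighted_median_point(by[nz] / bx[nz], bx[nz]^2 / sy[nz]^2)
  }, n_boot, seed)
  est <- mr_estimate("weighted_median", point, se,
                     2 * stats::pnorm(-abs(point / se)), length(re$r))
  attr(est, "seed") <- seed
  est
}

# kernel-density mode of ratio estimates; modified Silverman bandwidth
mode_point <- function(r, w, bandwidth_factor) {
  s <- stats::sd(r)
  md <- stats::mad(r)
  h <- bandwidth_factor * 0.9 * min(s, if (md > 0) md else s) * length(r)^(-1 / 5)
  if (!is.finite(h) || h <= 0) h <- max(1e-8, diff(range(r)) / 1000)
  grid <- sort(unique(c(r, seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512))))
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, r, h)), numeric(1))
  grid[which.max(dens)]
}

#' Simple and weighted mode estimators
#'
#' The mode of the kernel-smoothed empirical density of per-SNP ratio
#' estimates (normal kernel; bandwidth = `bandwidth_factor` times a modified
#' Silverman rule, `0.9 min(sd, mad) k^(-1/5)`). The simple mode weights all
#' ratios equally; the weighted mode uses the inverse-variance weights of
#' [weighted_median()]. Consistent when the largest group of instruments
#' sharing a ratio value is valid (plurality validity). SEs by parametric
#' bootstrap.
#'
#' @param pairs `harmonized_pairs` with at least 3 instruments.
#' @param bandwidth_factor multiplier on the Silverman bandwidth (default 1).
#' @param n_boot,seed bootstrap control.
#' @return list with `simple_mode` and `weighted_mode` ([mr_estimate()]s), or
#'   `list(applicable = FALSE)` for k < 3.
#' @export
mode_estimators <- function(pairs, bandwidth_factor = 1.0, n_boot = 5000,
                            seed = 1L) {
  if (length(pairs$beta_x) < 3)
    return(list(applicable = FALSE, reason = "fewer than 3 instruments"))
  re <- ratio_estimates(pairs)
  k <- length(re$r)
  simple <- mode_point(re$r, rep(1 / k, k), bandwidth_factor)
  weighted <- mode_point(re$r, re$w / sum(re$w), bandwidth_factor)
  se_simple <- boot_se(pairs, function(bx, by, sy) {
    nz <- bx != 0; r <- by[nz] / bx[nz]
    mode_point(r, rep(1 / length(r), length(r)), bandwidth_factor)
  }, n_boot, seed)
  se_weighted <- boot_se(pairs, function(bx, by, sy) {
    nz <- bx != 0; r <- by[nz] / bx[nz]; w <- bx[nz]^2 / sy[nz]^2
    mode_point(r, w / sum(w), bandwidth_factor)
  }, n_boot, seed + 1L)
  mk <- function(label, b, se) {
    mr_estimate(label, b, se, 2 * stats::pnorm(-abs(b / se)), k)
  }
  list(simple_mode = mk("simple_mode", simple, se_simple),
       weighted_mode = mk("weighted_mode", weighted, se_weighted))
}

#' Run the full estimator suite on one harmonized set
#'
#' Convenience wrapper running [ivw_correlated()] (primary), [mr_egger()],
#' [weighted_median()] and [mode_estimators()] where the instrument count
#' allows, returning a tidy one-row-per-method data frame.
#'
#' @param pairs `harmonized_pairs`.
#' @param n_boot,seed bootstrap control for median/mode.
#' @param use_ld passed through to the regression estimators.
#' @return data frame of estimates (see [as.data.frame.mr_estimate()]) plus
#'   columns `Q`, `Q_df`, `Q_pval` on the IVW/Egger rows.
#' @export
mr_all_methods <- function(pairs, n_boot = 5000, seed = 1L, use_ld = TRUE) {
  ivw <- ivw_correlated(pairs, use_ld = use_ld)
  rows <- list(cbind(as.data.frame(ivw$estimate),
                     Q = ivw$heterogeneity$Q %||% NA_real_,
                     Q_df = ivw$heterogeneity$df %||% NA_real_,
                     Q_pval = ivw$heterogeneity$pval %||% NA_real_))
  egger <- mr_egger(pairs, use_ld = use_ld)
  if (isTRUE(egger$applicable)) {
    rows <- c(rows, list(
      cbind(as.data.frame(egger$slope), Q = egger$heterogeneity$Q,
            Q_df = egger$heterogeneity$df, Q_pval = egger$heterogeneity$pval),
      cbind(as.data.frame(egger$intercept), Q = NA_real_, Q_df = NA_real_,
            Q_pval = NA_real_)))
    wm <- weighted_median(pairs, n_boot = n_boot, seed = seed)
    md <- mode_estimators(pairs, n_boot = n_boot, seed = seed)
    rows <- c(rows, list(
      cbind(as.data.frame(wm), Q = NA_real_, Q_df = NA_real_, Q_pval = NA_real_),
      cbind(as.data.frame(md$simple_mode), Q = NA_real_, Q_df = NA_real_,
            Q_pval = NA_real_),
      cbind(as.data.frame(md$weighted_mode), Q = NA_real_, Q_df = NA_real_,
            Q_pval = NA_real_)))
  }
  do.call(rbind, rows)
}
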