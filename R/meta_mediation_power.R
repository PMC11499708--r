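#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort causal estimates on the log-OR scale. Fixed weights
#' `w = 1/se^2` give the heterogeneity statistic
#' `Q = sum w (b - b_fixed)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(se^2 + tau2)` give the pooled estimate with a normal 95% CI.
#' A single study is returned unchanged with `tau2 = 0`.
#'
#' @param estimates data frame with columns `beta` and `se` (optionally
#'   `label`), or a list of such pairs / [mr_estimate()] objects.
#' @return object of class `meta_result`: `pooled_beta`, `pooled_se`,
#'   `ci_low`, `ci_high`, `pval`, `tau2`, `Q_meta`, `Q_pval`, `k`, and
#'   `or_scale`.
#' @export
meta_random_effects <- function(estimates) {
  if (!is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(beta = e$beta, se = e$se)))
  }
  k <- nrow(estimates)
  assert_that(k >= 1, "no estimates to pool")
  assert_that(all(estimates$se > 0), "all standard errors must be positive")
  b <- estimates$beta; se <- estimates$se
  w <- 1 / se^2
  b_fixed <- sum(w * b) / sum(w)
  Q <- sum(w * (b - b_fixed)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * b) / sum(wr)
  pooled_se <- sqrt(1 / sum(wr))
  z <- stats::qnorm(0.975)
  structure(list(pooled_beta = pooled, pooled_se = pooled_se,
                 ci_low = pooled - z * pooled_se,
                 ci_high = pooled + z * pooled_se,
                 pval = 2 * stats::pnorm(-abs(pooled / pooled_se)),
                 tau2 = tau2, Q_meta = if (k > 1) Q else NA_real_,
                 Q_pval = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE)
                          else NA_real_,
                 k = k,
                 or_scale = c(or = exp(pooled),
                              ci_low = exp(pooled - z * pooled_se),
                              ci_high = exp(pooled + z * pooled_se))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("random-effects meta (k=%d): OR = %.*f [%.*f, %.*f], tau2 = %.4g, p = %s\n",
              x$k, digits, x$or_scale["or"], digits, x$or_scale["ci_low"],
              digits, x$or_scale["ci_high"], x$tau2,
              format.pval(x$pval, digits = 2)))
  invisible(x)
}

#' Convert printed OR and 95% CI to log-scale beta and SE
#'
#' `beta = ln(or)`, `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)` —
#' the standard back-derivation when per-cohort SEs are not printed.
#'
#' @param or,ci_low,ci_high odds ratio and 95% CI bounds (vectorized).
#' @return data frame with `beta` and `se`.
#' @export
or_to_estimate <- function(or, ci_low, ci_high) {
  data.frame(beta = log(or),
             se = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975)))
}

#' Two-step MR mediation by product of coefficients
#'
#' Decomposes a total causal effect into the indirect path through a mediator
#' and the remaining direct effect: `indirect = beta_em * beta_mo` (exposure
#' to mediator times mediator to outcome), `direct = total - indirect`,
#' `proportion = indirect / total`. A parametric bootstrap (independent
#' normal draws for the three inputs) supplies SEs for the indirect effect
#' and the proportion, and a two-sided normal p-value for the proportion.
#' The proportion point estimate is reported only when total and indirect
#' share sign (a mediated share outside \[0, 1\] is not interpretable).
#'
#' @param total [mr_estimate()] (or list with `beta`, `se`): total effect of
#'   exposure on outcome (log-OR per SD).
#' @param exp_to_med exposure-to-mediator effect (SD per SD).
#' @param med_to_out mediator-to-outcome effect (log-OR per SD).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed bootstrap seed.
#' @return object of class `mediation_result`: `total`, `beta_em`, `beta_mo`,
#'   `indirect`, `direct`, `proportion`, `boot_se_indirect`,
#'   `boot_se_proportion`, `pval_proportion`, `n_boot`, `seed`.
#' @export
two_step_mediation <- function(total, exp_to_med, med_to_out,
                               n_boot = 10000, seed = 1L) {
  tb <- total$beta; ts <- total$se
  ab <- exp_to_med$beta; as_ <- exp_to_med$se
  bb <- med_to_out$beta; bs <- med_to_out$se
  indirect <- ab * bb
  direct <- tb - indirect
  proportion <- if (abs(tb) < 10 * .Machine$double.eps) {
    NA_real_
  } else if (indirect != 0 && sign(indirect) != sign(tb)) {
    NA_real_
  } else indirect / tb

  set.seed(seed)
  tot_b <- stats::rnorm(n_boot, tb, ts)
  a_b <- stats::rnorm(n_boot, ab, as_)
  b_b <- stats::rnorm(n_boot, bb, bs)
  ind_b <- a_b * b_b
  prop_b <- ind_b / tot_b
  boot_se_ind <- stats::sd(ind_b)
  boot_se_prop <- stats::sd(prop_b)
  pval_prop <- if (is.na(proportion)) NA_real_ else
    2 * stats::pnorm(-abs(proportion / boot_se_prop))
  structure(list(total = tb, beta_em = ab, beta_mo = bb,
                 indirect = indirect, direct = direct,
                 proportion = proportion,
                 boot_se_indirect = boot_se_ind,
                 boot_se_proportion = boot_se_prop,
                 pval_proportion = pval_prop,
                 n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat(sprintf(paste0("mediation: total = %.*f, indirect = %.*f (SE %.*f), ",
                     "direct = %.*f, proportion mediated = %s\n"),
              digits, x$total, digits, x$indirect, digits, x$boot_se_indirect,
              digits, x$direct,
              if (is.na(x$proportion)) "n/a"
              else sprintf("%.1f%% (p = %s)", 100 * x$proportion,
                           format.pval(x$pval_proportion, digits = 2))))
  invisible(x)
}

#' Statistical power for MR with a binary outcome
#'
#' Wald-test approximation: the non-centrality is
#' `z = |ln(OR)| * sqrt(n * r2 * K * (1 - K))` for outcome sample size `n`,
#' instrument variance explained `r2`, and case fraction `K`; power is
#' `pnorm(z - z_(1-a/2)) + pnorm(-z - z_(1-a/2))`. With `r2 = 0` or
#' `OR = 1` the power equals `alpha`.
#'
#' @param n outcome GWAS sample size.
#' @param r2_instrument variance in the exposure explained by the instrument.
#' @param case_fraction outcome case proportion.
#' @param or_detect odds ratio to detect (per SD exposure).
#' @param alpha two-sided type-I error (default 0.05).
#' @return object of class `power_result`: `power`, `alpha`, `n`,
#'   `r2_instrument`, `case_fraction`, `or_detect`.
#' @export
mr_power_binary <- function(n, r2_instrument, case_fraction, or_detect,
                            alpha = 0.05) {
  assert_that(n > 0 && r2_instrument >= 0 && r2_instrument < 1 &&
                case_fraction > 0 && case_fraction < 1 && or_detect > 0 &&
                alpha > 0 && alpha < 1, "arguments out of range")
  zc <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or_detect)) *
    sqrt(n * r2_instrument * case_fraction * (1 - case_fraction))
  structure(list(power = stats::pnorm(ncp - zc) + stats::pnorm(-ncp - zc),
                 alpha = alpha, n = n, r2_instrument = r2_instrument,
                 case_fraction = case_fraction, or_detect = or_detect),
            class = "power_result")
}

#' Bonferroni significance report across drug targets
#'
#' @param pvals named numeric vector of per-target p-values.
#' @param m number of tests (default `length(pvals)`); the threshold is
#'   `0.05 / m` with strict inequality.
#' @return data frame `target`, `pval`, `threshold`, `significant`.
#' @export
bonferroni_report <- function(pvals, m = length(pvals)) {
  assert_that(m >= 1, "m must be >= 1")
  thr <- 0.05 / m
  data.frame(target = names(pvals) %||% as.character(seq_along(pvals)),
             pval = unname(pvals), threshold = thr,
             significant = unname(pvals) < thr,
             stringsAsFactors = FALSE)
}

#' Forest-plot data table for pooled cohort estimates
#'
#' @param estimates data frame with `label`, `beta`, `se`.
#' @param meta optional [meta_random_effects()] result appended as a
#'   summary row.
#' @return data frame `label`, `or`, `ci_low`, `ci_high`, `weight_pct`.
#' @export
forest_data <- function(estimates, meta = NULL) {
  z <- stats::qnorm(0.975)
  tau2 <- if (!is.null(meta)) meta$tau2 else 0
  w <- 1 / (estimates$se^2 + tau2)
  out <- data.frame(label = estimates$label,
                    or = exp(estimates$beta),
                    ci_low = exp(estimates$beta - z * estimates$se),
                    ci_high = exp(estimates$beta + z * estimates$se),
                    weight_pct = 100 * w / sum(w),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    out <- rbind(out, data.frame(label = "RE pooled",
                                 or = unname(meta$or_scale["or"]),
                                 ci_low = unname(meta$or_scale["ci_low"]),
                                 ci_high = unname(meta$or_scale["ci_high"]),
                                 weight_pct = NA_real_))
  }
  out
}

#' Minimal forest plot on the odds-ratio scale
#'
#' Base-graphics dot-and-whisker plot of a [forest_data()] table; the x axis
#' is logarithmic with a reference line at OR = 1.
#'
#' @param fd data frame from [forest_data()].
#' @param main plot title.
#' @export
plot_forest <- function(fd, main = "") {
  k <- nrow(fd)
  y <- rev(seq_len(k))
  graphics::plot(fd$or, y, log = "x", pch = 15, yaxt = "n",
                 xlim = range(c(fd$ci_low, fd$ci_high, 1), na.rm = TRUE),
                 xlab = "Odds ratio (95% CI)", ylab = "", main = main)
  graphics::segments(fd$ci_low, y, fd$ci_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = fd$label, las = 1, cex.axis = 0.8)
  invisible(fd)
}
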