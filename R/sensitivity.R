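# leave-one-out IVW slopes for every SNP at once, classical 1/se_y^2 weights
loo_slopes <- function(bx, by, w) {
  Sxx <- sum(w * bx^2)
  Sxy <- sum(w * bx * by)
  (Sxy - w * bx * by) / (Sxx - w * bx^2)
}

#' MR-PRESSO global and outlier test
#'
#' Pleiotropy residual-sum-and-outlier test: the observed RSS sums weighted
#' squared residuals where each variant's residual uses the IVW slope fitted
#' without it (leave-one-out prediction). The null distribution is built by
#' parametric simulation under the fitted no-pleiotropy model (`bx* ~ N(bx,
#' se_x)`, `by* ~ N(slope_loo * bx, se_y)`), applying the identical
#' leave-one-out procedure to each simulated dataset. The global p-value is
#' `(1 + #(RSS_sim >= RSS_obs)) / (n_sim + 1)`. Per-variant outlier p-values
#' compare each observed squared residual with its simulated distribution;
#' outliers are declared at Bonferroni 0.05 / k, and when any are found the
#' IVW estimate is recomputed without them. Weights are the classical
#' `1/se_y^2` (the procedure assumes approximately independent instruments).
#'
#' @param pairs `harmonized_pairs` with at least 4 instruments.
#' @param n_sim simulated datasets (default 1000; the attainable p-value
#'   granularity is `1/(n_sim+1)`).
#' @param seed simulation seed (recorded in the result).
#' @return object of class `presso_result`: `rss_obs`, `global_p`,
#'   `per_snp_p` (named), `outliers` (ids), `corrected_estimate`
#'   ([mr_estimate()] or NULL), `n_sim`, `seed`. With fewer than 4
#'   instruments, `list(applicable = FALSE)`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1L) {
  k <- length(pairs$beta_x)
  if (k < 4) return(list(applicable = FALSE, reason = "fewer than 4 instruments"))
  bx <- pairs$beta_x; by <- pairs$beta_y
  sx <- pairs$se_x; sy <- pairs$se_y
  w <- 1 / sy^2

  sl <- loo_slopes(bx, by, w)
  res_obs <- by - sl * bx
  rss_j_obs <- w * res_obs^2
  rss_obs <- sum(rss_j_obs)

  set.seed(seed)
  # k x n_sim matrices of simulated effects under the no-pleiotropy model
  bxs <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
  bys <- matrix(stats::rnorm(k * n_sim, sl * bx, sy), nrow = k)
  Sxx <- colSums(w * bxs^2)
  Sxy <- colSums(w * bxs * bys)
  sls <- (rep(Sxy, each = k) - w * bxs * bys) /
    (rep(Sxx, each = k) - w * bxs^2)
  ress <- bys - sls * bxs
  rss_j_sim <- w * ress^2           # k x n_sim
  rss_sim <- colSums(rss_j_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + rowSums(rss_j_sim >= rss_j_obs)) / (n_sim + 1)
  names(per_snp_p) <- pairs$snp_ids
  outliers <- pairs$snp_ids[per_snp_p < 0.05 / k]

  corrected <- NULL
  if (length(outliers) > 0 && length(outliers) < k - 1) {
    keep <- !(pairs$snp_ids %in% outliers)
    corrected <- ivw_correlated(subset_pairs(pairs, keep))$estimate
    corrected$method <- "ivw_presso_corrected"
  }
  structure(list(applicable = TRUE, rss_obs = rss_obs, global_p = global_p,
                 per_snp_p = per_snp_p, outliers = outliers,
                 corrected_estimate = corrected, n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.3f, global p = %.4g, %d outlier(s)\n",
              x$rss_obs, x$global_p, length(x$outliers)))
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. On the per-SD quantitative scale,
#' `r2_x = sum 2 p (1-p) bx^2`; for a binary outcome the observed-scale
#' approximation `r2_y = sum 2 p (1-p) by^2 * K (1-K)` is used (for a
#' quantitative outcome, omit `case_fraction`). The causal direction
#' exposure -> outcome is supported when `r2_x > r2_y`; the p-value is a
#' two-sample z test on Fisher-transformed correlations.
#'
#' @param pairs `harmonized_pairs` carrying `eaf` (exposure-side EAF).
#' @param n_exposure,n_outcome GWAS sample sizes (taken from `pairs` when
#'   present).
#' @param case_fraction outcome case proportion; `NULL` treats the outcome as
#'   quantitative.
#' @return object of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction_correct`, `pval`. Missing EAF gives
#'   `list(applicable = FALSE)` with a message.
#' @export
steiger_test <- function(pairs, n_exposure = NULL, n_outcome = NULL,
                         case_fraction = NULL) {
  if (is.null(pairs$eaf) || all(is.na(pairs$eaf))) {
    message("steiger_test: effect-allele frequencies unavailable; not applicable")
    return(list(applicable = FALSE, reason = "missing eaf"))
  }
  n_exposure <- n_exposure %||% unique(pairs$n_x)[1]
  n_outcome <- n_outcome %||% unique(pairs$n_y)[1]
  assert_that(is.finite(n_exposure) && is.finite(n_outcome),
              "sample sizes required for the Steiger test")
  p <- pairs$eaf
  r2x <- sum(2 * p * (1 - p) * pairs$beta_x^2)
  r2y <- sum(2 * p * (1 - p) * pairs$beta_y^2)
  if (!is.null(case_fraction)) r2y <- r2y * case_fraction * (1 - case_fraction)
  r2x <- min(r2x, 1 - 1e-12)
  r2y <- min(r2y, 1 - 1e-12)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(list(applicable = TRUE, r2_exposure = r2x, r2_outcome = r2y,
                 direction_correct = r2x > r2y,
                 pval = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the correlation-adjusted IVW estimate k times, omitting one
#' instrument at a time, and flags exclusions that change the estimate's sign
#' or move it outside the full-set 95% CI — the signature of a single variant
#' driving the association.
#'
#' @param pairs `harmonized_pairs` with at least 2 instruments.
#' @param ... passed to [ivw_correlated()].
#' @return data frame with one row per omitted variant: `snp_omitted`,
#'   `beta`, `se`, `pval`, `sign_change`, `outside_full_ci`.
#' @export
leave_one_out <- function(pairs, ...) {
  k <- length(pairs$beta_x)
  assert_that(k >= 2, "leave-one-out needs at least 2 instruments")
  full <- ivw_correlated(pairs, ...)$estimate
  rows <- lapply(seq_len(k), function(j) {
    est <- ivw_correlated(subset_pairs(pairs, setdiff(seq_len(k), j)), ...)$estimate
    data.frame(snp_omitted = pairs$snp_ids[j], beta = est$beta, se = est$se,
               pval = est$pval,
               sign_change = sign(est$beta) != sign(full$beta),
               outside_full_ci = est$beta < full$ci_low | est$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_estimate") <- full
  out
}

#' Screen instruments against a local confounder-annotation table
#'
#' Reports instruments (and their proxies at r-squared > 0.8) annotated to a
#' potential confounder trait at genome-wide significance. Advisory only: no
#' variant is removed automatically.
#'
#' @param snp_ids instrument variant ids.
#' @param annotation_table data frame with columns `snp`, `trait`, `p` (and
#'   optionally `source`).
#' @param p_threshold association threshold (default 5e-8, strict `<`).
#' @param proxy_table optional proxy table as in [substitute_proxies()];
#'   proxies at r2 > 0.8 extend the screen and hits are reported against the
#'   index variant.
#' @return data frame `snp`, `via` (the annotated variant), `trait`, `p`.
#' @export
screen_confounders <- function(snp_ids, annotation_table, p_threshold = 5e-8,
                               proxy_table = NULL) {
  empty <- data.frame(snp = character(), via = character(),
                      trait = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(annotation_table) || nrow(annotation_table) == 0) {
    warning("empty annotation table: confounder screen is vacuous", call. = FALSE)
    return(empty)
  }
  lookup <- data.frame(snp = snp_ids, via = snp_ids, stringsAsFactors = FALSE)
  if (!is.null(proxy_table)) {
    px <- proxy_table[proxy_table$index_snp %in% snp_ids & proxy_table$r2 > 0.8, ]
    if (nrow(px) > 0)
      lookup <- rbind(lookup, data.frame(snp = px$index_snp, via = px$proxy_snp,
                                         stringsAsFactors = FALSE))
  }
  hits <- merge(lookup, annotation_table[annotation_table$p < p_threshold, ],
                by.x = "via", by.y = "snp")
  if (nrow(hits) == 0) return(empty)
  out <- hits[order(hits$snp, hits$p), c("snp", "via", "trait", "p")]
  rownames(out) <- NULL
  out
}
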