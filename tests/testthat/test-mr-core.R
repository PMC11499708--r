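random_pairs <- function(k, seed, rho = 0) {
  set.seed(seed)
  harmonized_pairs(beta_x = rnorm(k, 0.1, 0.03), se_x = runif(k, 0.005, 0.02),
                   beta_y = rnorm(k, -0.1, 0.05), se_y = runif(k, 0.02, 0.08),
                   ld = block_cor_test(k, rho))
}

block_cor_test <- function(k, rho) {
  R <- matrix(rho, k, k)
  diag(R) <- 1
  R
}

test_that("identity-LD IVW equals the classical closed form", {
  for (seed in 1:20) {
    p <- random_pairs(5, seed)
    got <- ivw_correlated(p, random_effects = FALSE)$estimate
    oracle <- ivw_closed_form(p$beta_x, p$beta_y, p$se_y)
    expect_equal(got$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(got$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("correlated-LD IVW matches a brute-force GLS oracle", {
  for (seed in 1:10) {
    p <- random_pairs(6, seed, rho = 0.35)
    got <- ivw_correlated(p, random_effects = FALSE)$estimate
    oracle <- gls_origin_oracle(p$beta_x, p$beta_y, p$se_y, p$ld)
    expect_equal(got$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(got$se, oracle$se_fixed, tolerance = 1e-10)
  }
})

test_that("a single instrument reduces to the first-order Wald ratio", {
  p <- harmonized_pairs(beta_x = 0.08, se_x = 0.01, beta_y = -0.12, se_y = 0.03)
  got <- ivw_correlated(p)
  expect_equal(got$estimate$method, "wald_ratio")
  expect_equal(got$estimate$beta, -0.12 / 0.08)
  expect_equal(got$estimate$se, 0.03 / 0.08)
  expect_null(got$heterogeneity)
})

test_that("Q is zero when outcome effects are an exact multiple of exposure", {
  p <- harmonized_pairs(beta_x = c(0.05, 0.1, 0.15), se_x = rep(0.01, 3),
                        beta_y = -2 * c(0.05, 0.1, 0.15), se_y = rep(0.03, 3))
  got <- ivw_correlated(p)
  expect_equal(got$estimate$beta, -2)
  expect_equal(got$heterogeneity$Q, 0, tolerance = 1e-20)
  expect_equal(got$heterogeneity$df, 2)
})

test_that("random-effects inflation never shrinks the fixed-effect SE", {
  for (seed in 1:10) {
    p <- random_pairs(8, seed)
    fe <- ivw_correlated(p, random_effects = FALSE)$estimate$se
    re <- ivw_correlated(p, random_effects = TRUE)$estimate$se
    expect_gte(re, fe - 1e-15)
  }
})

test_that("ignoring real LD understates the IVW standard error", {
  mean_se <- function(use_ld) {
    mean(vapply(1:100, function(r) {
      p <- sim_pairs(sim_config(n_snps = 10, ld_block_rho = 0.25,
                                theta = -1.5, seed = 6000 + r))
      ivw_correlated(p, random_effects = FALSE, use_ld = use_ld)$estimate$se
    }, numeric(1)))
  }
  expect_lt(mean_se(use_ld = FALSE), mean_se(use_ld = TRUE))
})

test_that("LD-adjusted IVW recovers the causal effect under block LD", {
  est <- vapply(1:200, function(r) {
    p <- sim_pairs(sim_config(n_snps = 10, ld_block_rho = 0.25, theta = -1.5,
                              seed = 6500 + r))
    ivw_correlated(p)$estimate$beta
  }, numeric(1))
  expect_lt(abs(mean(est) + 1.5), 0.02)
})

test_that("Egger recovers slope and intercept exactly on noiseless data", {
  bx <- c(0.05, 0.08, 0.1, 0.14)
  theta <- -1.2; c0 <- 0.03
  p <- harmonized_pairs(beta_x = bx, se_x = rep(0.01, 4),
                        beta_y = c0 + theta * bx, se_y = rep(0.03, 4))
  got <- mr_egger(p)
  expect_equal(got$slope$beta, theta, tolerance = 1e-10)
  expect_equal(got$intercept$beta, c0, tolerance = 1e-10)
  expect_equal(got$heterogeneity$Q, 0, tolerance = 1e-16)
})

test_that("Egger needs three instruments and reports not-applicable below", {
  p <- harmonized_pairs(beta_x = c(0.1, 0.2), se_x = rep(0.01, 2),
                        beta_y = c(0.1, 0.2), se_y = rep(0.03, 2))
  got <- mr_egger(p)
  expect_false(got$applicable)
})

test_that("under directional pleiotropy Egger is less biased than IVW", {
  bias <- vapply(1:200, function(r) {
    p <- sim_pairs(sim_config(n_snps = 12, theta = -0.5, prop_invalid = 1,
                              pleiotropy_mean = 0.05, pleiotropy_sd = 0.005,
                              seed = 9000 + r))
    c(ivw_correlated(p)$estimate$beta, mr_egger(p)$slope$beta)
  }, numeric(2))
  expect_lt(abs(mean(bias[2, ]) + 0.5), abs(mean(bias[1, ]) + 0.5))
})

test_that("weighted median resists a minority outlier", {
  # equal weights, ratios {1, 2, 100}: the median ignores the outlier
  p <- harmonized_pairs(beta_x = c(0.1, 0.1, 0.1), se_x = rep(0.01, 3),
                        beta_y = c(0.1, 0.2, 10), se_y = rep(0.05, 3))
  got <- weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(got$beta, 2)
})

test_that("degenerate weights return the dominant variant's ratio", {
  # nearly all weight on the middle variant
  p <- harmonized_pairs(beta_x = c(0.01, 0.5, 0.01), se_x = rep(0.01, 3),
                        beta_y = c(0.05, -0.6, 0.01), se_y = c(1, 0.001, 1))
  got <- weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(got$beta, -0.6 / 0.5)
})

test_that("with many invalid instruments the median is less biased than IVW", {
  bias <- vapply(1:300, function(r) {
    p <- sim_pairs(sim_config(n_snps = 10, theta = -0.5, prop_invalid = 0.3,
                              pleiotropy_mean = 0.15, pleiotropy_sd = 0.02,
                              seed = 10000 + r))
    c(ivw_correlated(p)$estimate$beta,
      weighted_median(p, n_boot = 2, seed = r)$beta)
  }, numeric(2))
  expect_lt(abs(mean(bias[2, ]) + 0.5), abs(mean(bias[1, ]) + 0.5))
})

test_that("identical ratios give that ratio as the mode with vanishing SE", {
  p <- harmonized_pairs(beta_x = c(0.05, 0.1, 0.2), se_x = rep(1e-6, 3),
                        beta_y = 1.5 * c(0.05, 0.1, 0.2), se_y = rep(1e-6, 3))
  got <- mode_estimators(p, n_boot = 100, seed = 1)
  expect_equal(got$simple_mode$beta, 1.5, tolerance = 1e-4)
  expect_lt(got$simple_mode$se, 1e-3)
})

test_that("the simple mode picks the plurality cluster", {
  p <- harmonized_pairs(beta_x = rep(0.1, 5), se_x = rep(0.01, 5),
                        beta_y = c(0, 0, 0, 0.5, 0.5), se_y = rep(0.05, 5))
  got <- mode_estimators(p, n_boot = 50, seed = 1)
  expect_lt(abs(got$simple_mode$beta), 1)  # nearer 0 than 5
})

test_that("the mode recovers the effect when a majority cluster is valid", {
  est <- vapply(1:100, function(r) {
    p <- sim_pairs(sim_config(n_snps = 12, theta = -1.5, prop_invalid = 0.25,
                              pleiotropy_mean = 0.3, pleiotropy_sd = 0.05,
                              seed = 11000 + r))
    mode_estimators(p, n_boot = 2, seed = r)$weighted_mode$beta
  }, numeric(1))
  expect_lt(abs(median(est) + 1.5), 0.15)
})

test_that("estimators are scale-equivariant in the exposure", {
  p <- random_pairs(6, 3)
  cc <- 2.5
  p2 <- p
  p2$beta_x <- p$beta_x * cc
  p2$se_x <- p$se_x * cc
  expect_equal(ivw_correlated(p2)$estimate$beta,
               ivw_correlated(p)$estimate$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(p2)$slope$beta, mr_egger(p)$slope$beta / cc,
               tolerance = 1e-12)
  expect_equal(weighted_median(p2, n_boot = 2, seed = 1)$beta,
               weighted_median(p, n_boot = 2, seed = 1)$beta / cc,
               tolerance = 1e-12)
  expect_equal(mode_estimators(p2, n_boot = 2, seed = 1)$simple_mode$beta,
               mode_estimators(p, n_boot = 2, seed = 1)$simple_mode$beta / cc,
               tolerance = 1e-6)
})

test_that("estimators are sign-equivariant in the exposure orientation", {
  p <- random_pairs(6, 4)
  p2 <- p
  p2$beta_x <- -p$beta_x
  ivw1 <- ivw_correlated(p)$estimate
  ivw2 <- ivw_correlated(p2)$estimate
  expect_equal(ivw2$beta, -ivw1$beta, tolerance = 1e-12)
  expect_equal(ivw2$se, ivw1$se, tolerance = 1e-12)
  e1 <- mr_egger(p)$slope
  e2 <- mr_egger(p2)$slope
  expect_equal(e2$beta, -e1$beta, tolerance = 1e-12)
  expect_equal(e2$se, e1$se, tolerance = 1e-12)
  expect_equal(weighted_median(p2, n_boot = 2, seed = 1)$beta,
               -weighted_median(p, n_boot = 2, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("the method suite returns one tidy row per applicable method", {
  p <- random_pairs(6, 5)
  tab <- mr_all_methods(p, n_boot = 50, seed = 1)
  expect_setequal(tab$method,
                  c("ivw_correlated", "mr_egger", "mr_egger_intercept",
                    "weighted_median", "simple_mode", "weighted_mode"))
  expect_true(all(tab$n_snp == 6))
  p1 <- harmonized_pairs(0.1, 0.01, -0.15, 0.04)
  tab1 <- mr_all_methods(p1)
  expect_equal(tab1$method, "wald_ratio")
})
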