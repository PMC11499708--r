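# shared fixture builders: everything is generated in code at test time

# one simulated region as aligned pairs (no allele bookkeeping)
sim_pairs <- function(cfg) {
  s <- simulate_region(cfg)
  harmonized_pairs(s$exposure$beta, s$exposure$se,
                   s$outcome$beta, s$outcome$se,
                   ld = s$ld, snp_ids = s$exposure$snp,
                   eaf = s$exposure$eaf,
                   n_x = cfg$n_exposure, n_y = cfg$n_outcome)
}

# hand-built summary records with controllable alleles
make_records <- function(snp, ea, oa, eaf, beta, se = 0.01,
                         chrom = "11", pos = NULL, n = 1e5) {
  k <- length(snp)
  if (is.null(pos)) pos <- 17400000 + seq_len(k) * 1000
  data.frame(snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = rep_len(se, k),
             pval = 2 * pnorm(-abs(beta / rep_len(se, k))), n = n,
             stringsAsFactors = FALSE)
}

# classical (identity-LD) IVW closed form, independent of the package path
ivw_closed_form <- function(bx, by, sy) {
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se = sqrt(1 / sum(w * bx^2)))
}

# brute-force GLS oracle using explicit matrix inversion
gls_origin_oracle <- function(bx, by, sy, rho) {
  Omega <- outer(sy, sy) * rho
  Oi <- solve(Omega)
  denom <- drop(t(bx) %*% Oi %*% bx)
  beta <- drop(t(bx) %*% Oi %*% by) / denom
  list(beta = beta, se_fixed = sqrt(1 / denom))
}

# brute-force DerSimonian-Laird oracle
dl_oracle <- function(b, se) {
  w <- 1 / se^2
  bf <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bf)^2)
  k <- length(b)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(beta = sum(wr * b) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# per-cohort ABCC8 estimates as printed (OR with 95% CI), discovery +
# two replication cohorts
abcc8_cohort_estimates <- function() {
  or_to_estimate(or = c(0.152, 0.332, 0.189),
                 ci_low = c(0.075, 0.154, 0.071),
                 ci_high = c(0.308, 0.716, 0.500))
}
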