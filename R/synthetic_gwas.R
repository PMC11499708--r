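#' Simulation configuration for a cis-region summary-statistics study
#'
#' Describes one synthetic drug-target region: a block of `n_snps` variants in
#' exchangeable LD (`ld_block_rho`) that affect a standardized quantitative
#' exposure (an HbA1c-like trait, per-SD scale), a binary outcome (a
#' glaucoma-like disease, log-OR scale) with total causal effect `theta`, and a
#' quantitative mediator (an intraocular-pressure-like trait) sitting on the
#' causal path with exposure-to-mediator effect `mediator_a` (SD/SD) and
#' mediator-to-outcome effect `mediator_b` (log-OR per SD).
#'
#' A fraction `prop_invalid` of variants carry horizontal pleiotropy: a direct
#' outcome effect drawn from Normal(`pleiotropy_mean`, `pleiotropy_sd`).
#' `pleiotropy_mean != 0` gives directional pleiotropy; `pleiotropy_mean == 0`
#' with `pleiotropy_sd > 0` gives balanced pleiotropy.
#'
#' Per-SD exposure effect magnitudes are drawn as |Normal(`beta_x_mean`,
#' `beta_x_sd`)|, giving strong cis instruments comparable to common variants
#' at a glycaemic locus in a biobank-scale GWAS.
#'
#' @param n_snps number of variants in the region.
#' @param n_exposure exposure (and mediator) GWAS sample size.
#' @param n_outcome outcome GWAS sample size.
#' @param maf_range length-2 numeric, minor-allele-frequency range in (0, 0.5].
#' @param ld_block_rho exchangeable LD correlation in \[0, 1).
#' @param theta total causal effect, log-OR of outcome per 1 SD exposure.
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters of per-SNP direct
#'   outcome effects (log-OR) for invalid instruments.
#' @param prop_invalid fraction of SNPs receiving pleiotropy, in \[0, 1\].
#' @param mediator_a effect of exposure on mediator (SD per SD).
#' @param mediator_b effect of mediator on outcome (log-OR per SD).
#' @param case_fraction outcome case proportion in (0, 1).
#' @param beta_x_mean,beta_x_sd magnitude distribution of per-SD exposure
#'   effects.
#' @param seed integer seed; identical config + seed gives bit-identical draws.
#' @return an object of class `sim_config`.
#' @seealso [simulate_region()]
#' @export
sim_config <- function(n_snps = 10,
                       n_exposure = 100000,
                       n_outcome = 100000,
                       maf_range = c(0.05, 0.5),
                       ld_block_rho = 0,
                       theta = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       prop_invalid = 0,
                       mediator_a = 0,
                       mediator_b = 0,
                       case_fraction = 0.024,
                       beta_x_mean = 0.08,
                       beta_x_sd = 0.02,
                       seed = 1L) {
  assert_that(length(maf_range) == 2 && all(maf_range > 0) && all(maf_range <= 0.5) &&
                maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  assert_that(ld_block_rho >= 0 && ld_block_rho < 1,
              "ld_block_rho must be in [0, 1): rho >= 1 gives a non-positive-definite LD matrix")
  assert_that(prop_invalid >= 0 && prop_invalid <= 1, "prop_invalid must be in [0, 1]")
  assert_that(case_fraction > 0 && case_fraction < 1, "case_fraction must be in (0, 1)")
  assert_that(n_snps >= 1 && n_exposure > 2 && n_outcome > 2, "sample sizes too small")
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
              n_outcome = n_outcome, maf_range = maf_range,
              ld_block_rho = ld_block_rho, theta = theta,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              prop_invalid = prop_invalid, mediator_a = mediator_a,
              mediator_b = mediator_b, case_fraction = case_fraction,
              beta_x_mean = beta_x_mean, beta_x_sd = beta_x_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate GWAS summary statistics for one cis region
#'
#' Generates marginal association statistics for exposure, outcome, and
#' mediator over a block of variants in exchangeable LD, mirroring the
#' two-sample summary-data setting: true joint per-SD exposure effects are
#' drawn per SNP, marginal effects are the LD-smeared joint effects, and
#' estimated effects add sampling noise whose cross-SNP correlation equals the
#' LD matrix.
#'
#' Standard errors follow the per-SD quantitative model
#' `se = 1/sqrt(2 p (1-p) n)` for exposure and mediator, and the binary-trait
#' approximation `se = 1/sqrt(n K (1-K) 2 p (1-p))` with case fraction `K` for
#' the outcome. The outcome's true marginal effect is
#' `theta * beta_x + alpha_j`, with `alpha_j` the per-SNP pleiotropy (zero for
#' valid instruments).
#'
#' @param config a [sim_config()].
#' @return a list with elements `exposure`, `outcome`, `mediator` (summary
#'   statistic data frames with columns snp, chrom, pos, ea, oa, eaf, beta,
#'   se, pval, n), `ld` (the block correlation matrix with SNP dimnames), and
#'   `truth` (class `sim_truth`: `theta`, `per_snp_pleiotropy`,
#'   `indirect_effect = mediator_a * mediator_b`, `proportion_mediated =
#'   indirect/theta`).
#' @examples
#' sim <- simulate_region(sim_config(n_snps = 5, theta = -1.5, seed = 7))
#' head(sim$exposure)
#' sim$truth$theta
#' @export
simulate_region <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be built by sim_config()")
  set.seed(config$seed)
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  R <- block_cor(m, config$ld_block_rho)
  cR <- chol(R)

  # joint per-SD effects, positive = exposure-lowering allele coded as effect
  gamma <- abs(stats::rnorm(m, config$beta_x_mean, config$beta_x_sd))
  bx_true <- drop(R %*% gamma)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  bx_hat <- mvn_draw(bx_true, se_x, cR)

  # pleiotropy on a fixed fraction of SNPs
  n_invalid <- round(config$prop_invalid * m)
  alpha <- numeric(m)
  if (n_invalid > 0) {
    idx <- sample.int(m, n_invalid)
    alpha[idx] <- stats::rnorm(n_invalid, config$pleiotropy_mean, config$pleiotropy_sd)
  }

  K <- config$case_fraction
  se_y <- 1 / sqrt(config$n_outcome * K * (1 - K) * 2 * maf * (1 - maf))
  by_true <- config$theta * bx_true + alpha
  by_hat <- mvn_draw(by_true, se_y, cR)

  se_m <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  bm_true <- config$mediator_a * bx_true
  bm_hat <- mvn_draw(bm_true, se_m, cR)

  snp <- sprintf("rs%06d", seq_len(m))
  pos <- as.numeric(sort(sample.int(1000000L, m)) + 17000000L)
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T", "A", "T", "C", "G"),
                  ncol = 2, byrow = TRUE)
  ai <- sample.int(nrow(pairs), m, replace = TRUE)
  ea <- pairs[ai, 1]
  oa <- pairs[ai, 2]

  rec <- function(beta, se, n) {
    data.frame(snp = snp, chrom = "11", pos = pos, ea = ea, oa = oa,
               eaf = maf, beta = beta, se = se,
               pval = 2 * stats::pnorm(-abs(beta / se)), n = n,
               stringsAsFactors = FALSE)
  }
  dimnames(R) <- list(snp, snp)

  truth <- list(theta = config$theta,
                per_snp_pleiotropy = alpha,
                indirect_effect = config$mediator_a * config$mediator_b,
                proportion_mediated =
                  if (config$theta != 0)
                    (config$mediator_a * config$mediator_b) / config$theta
                  else NA_real_)
  class(truth) <- "sim_truth"

  list(exposure = rec(bx_hat, se_x, config$n_exposure),
       outcome = rec(by_hat, se_y, config$n_outcome),
       mediator = rec(bm_hat, se_m, config$n_exposure),
       ld = R,
       truth = truth)
}

#' Write summary statistics to a tab-delimited file
#'
#' Columns are SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N; the file
#' round-trips losslessly through [read_sumstats()].
#'
#' @param records summary-statistics data frame as produced by
#'   [simulate_region()] or [read_sumstats()].
#' @param path output path (a `.gz` suffix writes gzip).
#' @return the path, invisibly.
#' @export
write_sumstats <- function(records, path) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data frame")
  need <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  assert_that(all(need %in% names(records)),
              paste("records missing columns:",
                    paste(setdiff(need, names(records)), collapse = ", ")))
  out <- records[need]
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD correlation matrix as TSV with SNP-ID header row and column
#'
#' @param ld square correlation matrix with SNP IDs as dimnames.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  assert_that(is.matrix(ld) && nrow(ld) == ncol(ld) && !is.null(rownames(ld)),
              "ld must be a square matrix with SNP dimnames")
  df <- data.frame(SNP = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an LD correlation matrix written by [write_ld_matrix()]
#'
#' @param path input path (gzip accepted).
#' @return square numeric matrix with SNP dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
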