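#!/usr/bin/env Rscript
# Build the synthetic multi-cohort study used by the rest of the workflow:
# one drug-target region with a protective causal effect on a binary outcome
# (log-OR -1.5 per SD of the exposure biomarker, mediated in part through a
# quantitative mediator), one null target region, three outcome cohorts
# (discovery + two replications), a mediator GWAS, and a positive-control
# outcome. Everything is written as summary-statistics TSVs under
# results/study_inputs/ together with the study YAML config.

suppressPackageStartupMessages(library(targetmr))

dir <- "results/study_inputs"
dir.create(dir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026

cfg <- sim_config(n_snps = 12, theta = -1.5, ld_block_rho = 0.2,
                  mediator_a = -0.7, mediator_b = 1.5, seed = seed)
s <- simulate_region(cfg)

null_snps <- data.frame(
  snp = paste0("nl", 1:4), chrom = "3", pos = 12350000 + (1:4) * 1000,
  ea = "A", oa = "G", eaf = 0.3, beta = c(0.001, -0.002, 0.001, 0.0005),
  se = 0.005, n = 1e5)
null_snps$pval <- 2 * pnorm(-abs(null_snps$beta / null_snps$se))

exposure <- rbind(s$exposure, null_snps)
ld <- diag(nrow(exposure))
ld[1:12, 1:12] <- s$ld
dimnames(ld) <- list(exposure$snp, exposure$snp)

set.seed(seed + 1)
cohort <- function(jitter) {
  out <- rbind(s$outcome, transform(null_snps, beta = 0, se = 0.05))
  out$beta <- out$beta + rnorm(nrow(out), 0, jitter * out$se)
  out$pval <- 2 * pnorm(-abs(out$beta / out$se))
  out
}
med <- rbind(s$mediator, transform(null_snps, beta = 0, se = 0.05))
med$pval <- 2 * pnorm(-abs(med$beta / med$se))
ctl <- s$exposure
ctl$beta <- 2 * s$exposure$beta + rnorm(12, 0, 0.01)   # weight-gain-like control
ctl <- rbind(ctl, transform(null_snps, beta = 0, se = 0.05))
ctl$pval <- 2 * pnorm(-abs(ctl$beta / ctl$se))

write_sumstats(exposure, file.path(dir, "exposure.tsv"))
write_sumstats(cohort(0.3), file.path(dir, "outcome_discovery.tsv"))
write_sumstats(cohort(0.5), file.path(dir, "outcome_rep1.tsv"))
write_sumstats(cohort(0.4), file.path(dir, "outcome_rep2.tsv"))
write_sumstats(med, file.path(dir, "mediator.tsv"))
write_sumstats(ctl, file.path(dir, "control.tsv"))
write_ld_matrix(ld, file.path(dir, "ld.tsv"))
write.table(data.frame(name = c("TGT1", "NULLTGT"), chrom = c("11", "3"),
                       start = c(17400000, 12350000),
                       end = c(17500000, 12360000), flank = 500000),
            file.path(dir, "targets.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

study <- list(
  ancestry = "EUR",
  exposure = list(path = file.path(dir, "exposure.tsv"), n = 1e5),
  outcomes = list(
    discovery = list(path = file.path(dir, "outcome_discovery.tsv"),
                     role = "discovery", meta = TRUE, case_fraction = 0.024),
    rep1 = list(path = file.path(dir, "outcome_rep1.tsv"),
                role = "replication", meta = TRUE, case_fraction = 0.024),
    rep2 = list(path = file.path(dir, "outcome_rep2.tsv"),
                role = "replication", meta = TRUE, case_fraction = 0.024)),
  mediators = list(IOP = list(path = file.path(dir, "mediator.tsv"), n = 1e5)),
  controls = list(control_up = list(path = file.path(dir, "control.tsv"),
                                    expected_direction = 1)),
  targets = file.path(dir, "targets.tsv"),
  ld_path = file.path(dir, "ld.tsv"),
  mediation = list(list(target = "TGT1", mediator = "IOP",
                        med_to_out = list(beta = 1.5, se = 0.06),
                        n_boot = 10000)),
  seed = seed, output_dir = "results/study_outputs")
yaml::write_yaml(study, file.path(dir, "config.yaml"))

cat("Simulated study written to", dir, "\n")
cat("  true total effect (log-OR/SD):", cfg$theta, "\n")
cat("  true mediated proportion:", s$truth$proportion_mediated, "\n")
cat("  variants:", nrow(exposure), "(12 causal-region, 4 null-target)\n")
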