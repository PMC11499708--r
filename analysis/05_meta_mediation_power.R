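#!/usr/bin/env Rscript
# Recompute the published quantities that depend only on printed inputs:
# (i) the pooled European sulfonylurea-receptor (ABCC8) estimate from the
# three per-cohort ORs/CIs, (ii) the proportion of that effect mediated
# through intraocular pressure by product of coefficients, and (iii) the
# power profile of a cis-instrument MR at discovery-cohort scale.
# Writes results/published_recomputation.tsv.

suppressPackageStartupMessages(library(targetmr))

cohorts <- cbind(label = c("IGGC", "GBMI", "FinnGen"),
                 or_to_estimate(or = c(0.152, 0.332, 0.189),
                                ci_low = c(0.075, 0.154, 0.071),
                                ci_high = c(0.308, 0.716, 0.500)))
pooled <- meta_random_effects(cohorts)
cat("Per-cohort ABCC8 estimates pooled by DerSimonian-Laird:\n")
print(forest_data(cohorts, pooled), row.names = FALSE, digits = 3)
print(pooled)

med <- two_step_mediation(
  total = as.list(or_to_estimate(0.211, 0.133, 0.333)),
  exp_to_med = as.list(or_to_estimate(0.474, 0.314, 0.714)),
  med_to_out = as.list(or_to_estimate(4.126, 3.685, 4.620)),
  n_boot = 10000, seed = 1)
cat("\nTwo-step mediation through intraocular pressure:\n")
print(med)

cat("\nPower at discovery scale (n = 216,257, K = 0.077, instrument r2 = 0.5%):\n")
ors <- c(0.15, 0.20, 0.30, 0.50, 0.70)
pw <- vapply(ors, function(o) mr_power_binary(216257, 0.005, 0.077, o)$power,
             numeric(1))
print(data.frame(or_detect = ors, power = round(pw, 3)), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
out <- rbind(
  data.frame(quantity = "pooled_or", value = unname(pooled$or_scale["or"])),
  data.frame(quantity = "pooled_ci_low", value = unname(pooled$or_scale["ci_low"])),
  data.frame(quantity = "pooled_ci_high", value = unname(pooled$or_scale["ci_high"])),
  data.frame(quantity = "tau2", value = pooled$tau2),
  data.frame(quantity = "mediation_proportion", value = med$proportion),
  data.frame(quantity = "mediation_boot_se", value = med$boot_se_proportion),
  data.frame(quantity = "mediation_p", value = med$pval_proportion),
  data.frame(quantity = "bonferroni_threshold",
             value = unique(bonferroni_report(rep(1, 4))$threshold)))
write.table(out, "results/published_recomputation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nTable written to results/published_recomputation.tsv\n")
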