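#' Load a study configuration
#'
#' Reads a YAML study configuration (or accepts an equivalent named list) and
#' validates it. The configuration names the exposure GWAS, one or more
#' outcome GWAS (each with a role label such as discovery/replication and, if
#' marked `meta: true`, pooled across cohorts), optional mediator GWAS and
#' control outcomes, the target-gene table, selection thresholds, and paths
#' to the LD matrix, proxy table, and confounder-annotation table.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list (class `study_config`).
#' @export
study_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  defaults <- list(ancestry = "EUR", p_threshold = 5e-8, r2_prune = 0.30,
                   flank = 500000, palindromic_eaf_window = 0.08,
                   n_boot = 5000, n_sim_presso = 1000, seed = 1L,
                   sign_convention = "per_sd_reduction",
                   output_dir = "results")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  assert_that(!is.null(config$exposure), "config$exposure (path + n) required")
  assert_that(!is.null(config$outcomes) && length(config$outcomes) > 0,
              "config$outcomes required")
  assert_that(!is.null(config$targets), "config$targets required")
  assert_that(config$p_threshold > 0 && config$r2_prune > 0,
              "thresholds must be positive")
  for (p in c(config$exposure$path, vapply(config$outcomes, `[[`, "", "path")))
    assert_that(file.exists(p), paste("configured file missing:", p))
  class(config) <- c("study_config", "list")
  config
}

# run instrument construction for one target; NULL when no instruments
build_instruments <- function(exposure, ld_full, target, p_threshold, r2_max) {
  cand <- select_cis_snps(exposure, target, p_threshold)
  if (attr(cand, "no_instruments")) return(NULL)
  idx <- match(cand$snp, rownames(ld_full))
  assert_that(!anyNA(idx), "LD matrix does not cover all candidate SNPs")
  prune_ld(cand, ld_full[idx, idx, drop = FALSE], r2_max)
}

# harmonize + full estimator/diagnostic suite for one target x outcome cell
analyse_cell <- function(iset, outcome, cfg, case_fraction = NULL) {
  pairs <- harmonize(iset$records, outcome, iset$ld,
                     palindromic_eaf_window = cfg$palindromic_eaf_window,
                     proxy_table = cfg$.proxy_table)
  k <- length(pairs$snp_ids)
  if (k == 0) return(list(pairs = pairs, estimates = NULL))
  ests <- mr_all_methods(pairs, n_boot = cfg$n_boot, seed = cfg$seed)
  diag <- list(
    presso = mr_presso(pairs, n_sim = cfg$n_sim_presso, seed = cfg$seed),
    steiger = steiger_test(pairs, case_fraction = case_fraction),
    loo = if (k >= 2) leave_one_out(pairs) else NULL)
  list(pairs = pairs, estimates = ests, diagnostics = diag)
}

#' Run the full drug-target MR study from a configuration
#'
#' For each target gene: cis instruments are selected from the exposure GWAS
#' and LD-pruned; for each outcome cohort the pairs are harmonized (proxies
#' substituted where configured) and the full estimator and diagnostic suite
#' is run; cohorts marked `meta: true` are pooled by random-effects
#' meta-analysis; Bonferroni correction is applied across targets on the
#' primary (pooled where available, otherwise first-outcome) IVW p-values;
#' mediation triples named in `config$mediation` are decomposed by two-step
#' MR. Targets with no qualifying cis variants are skipped with a logged
#' reason. All tables are written under `config$output_dir` together with a
#' run manifest (config hash, package version, per-stage row counts, seeds,
#' output checksums).
#'
#' @param config a [study_config()] (list or YAML path).
#' @return invisibly, a list with `estimates`, `meta`, `bonferroni`,
#'   `mediation`, `diagnostics`, `skipped`, `manifest`.
#' @export
run_study <- function(config) {
  cfg <- study_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  exposure <- read_sumstats(cfg$exposure$path)
  ld_full <- read_ld_matrix(cfg$ld_path)
  cfg$.proxy_table <- if (!is.null(cfg$proxy_table_path))
    read_tsv(cfg$proxy_table_path) else NULL
  annotation <- if (!is.null(cfg$annotation_path))
    read_tsv(cfg$annotation_path) else NULL
  targets <- if (is.character(cfg$targets)) read_gene_targets(cfg$targets)
             else lapply(cfg$targets, function(t)
               gene_target(t$name, t$chrom, t$start, t$end,
                           t$flank %||% cfg$flank))
  names(targets) <- vapply(targets, `[[`, "", "name")
  outcomes <- lapply(cfg$outcomes, function(o) {
    o$records <- read_sumstats(o$path); o
  })

  all_rows <- list(); meta_results <- list(); diagnostics <- list()
  skipped <- data.frame(target = character(), reason = character(),
                        stringsAsFactors = FALSE)
  counts <- list()
  primary_p <- c()

  for (tg in names(targets)) {
    iset <- build_instruments(exposure, ld_full, targets[[tg]],
                              cfg$p_threshold, cfg$r2_prune)
    if (is.null(iset)) {
      message("target ", tg, " skipped: no instruments at p < ", cfg$p_threshold)
      skipped <- rbind(skipped, data.frame(target = tg, reason = "no_instruments"))
      next
    }
    strength <- instrument_strength(iset$records, cfg$exposure$n)
    per_cohort <- list()
    for (oc in names(outcomes)) {
      cell <- tryCatch(
        analyse_cell(iset, outcomes[[oc]]$records, cfg,
                     case_fraction = outcomes[[oc]]$case_fraction),
        error = function(e) {
          message("target ", tg, " x ", oc, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(cell) || is.null(cell$estimates)) next
      counts[[paste(tg, oc, sep = ":")]] <- data.frame(
        target = tg, outcome = oc,
        selected = nrow(iset$records) + length(iset$pruned_away),
        pruned = nrow(iset$records),
        harmonized = length(cell$pairs$snp_ids),
        proxied = sum(!is.na(cell$pairs$proxied)),
        dropped = nrow(cell$pairs$dropped))
      est <- cbind(target = tg, ancestry = cfg$ancestry, cohort = oc,
                   role = outcomes[[oc]]$role %||% "primary",
                   cell$estimates,
                   total_r2 = strength$total_r2,
                   aggregate_F = strength$aggregate_F)
      all_rows[[paste(tg, oc, sep = ":")]] <- est
      diagnostics[[paste(tg, oc, sep = ":")]] <- cell$diagnostics
      if (isTRUE(outcomes[[oc]]$meta)) {
        ivw_row <- est[est$method %in% c("ivw_correlated", "wald_ratio"), ][1, ]
        per_cohort[[oc]] <- data.frame(label = oc, beta = ivw_row$beta,
                                       se = ivw_row$se)
      }
    }
    if (length(per_cohort) >= 1) {
      mi <- do.call(rbind, per_cohort)
      mres <- meta_random_effects(mi)
      meta_results[[tg]] <- mres
      primary_p[tg] <- mres$pval
    } else if (length(all_rows) > 0) {
      last <- all_rows[[length(all_rows)]]
      primary_p[tg] <- last$pval[last$method %in% c("ivw_correlated", "wald_ratio")][1]
    }
    if (!is.null(annotation)) {
      diagnostics[[paste0(tg, ":confounders")]] <-
        screen_confounders(iset$records$snp, annotation,
                           proxy_table = cfg$.proxy_table)
    }
  }

  estimates <- if (length(all_rows)) do.call(rbind, all_rows) else NULL
  if (!is.null(estimates)) rownames(estimates) <- NULL
  bonf <- if (length(primary_p)) bonferroni_report(primary_p) else NULL

  mediation <- list()
  for (md in cfg$mediation %||% list()) {
    tg <- md$target
    if (!(tg %in% names(meta_results))) next
    iset <- build_instruments(exposure, ld_full, targets[[tg]],
                              cfg$p_threshold, cfg$r2_prune)
    medrec <- read_sumstats(cfg$mediators[[md$mediator]]$path)
    mpairs <- harmonize(iset$records, medrec, iset$ld,
                        palindromic_eaf_window = cfg$palindromic_eaf_window)
    a_est <- ivw_correlated(mpairs)$estimate
    b_est <- if (!is.null(md$med_to_out$or))
      as.list(or_to_estimate(md$med_to_out$or, md$med_to_out$ci_low,
                             md$med_to_out$ci_high))
    else md$med_to_out
    total <- list(beta = meta_results[[tg]]$pooled_beta,
                  se = meta_results[[tg]]$pooled_se)
    mediation[[paste(tg, md$mediator, sep = ":")]] <-
      two_step_mediation(total, a_est, b_est,
                         n_boot = md$n_boot %||% 10000, seed = cfg$seed)
  }

  # write outputs + manifest
  paths <- character()
  if (!is.null(estimates))
    paths["estimates"] <- write_tsv(estimates, file.path(cfg$output_dir, "mr_estimates.tsv"))
  if (length(meta_results)) {
    mdf <- do.call(rbind, lapply(names(meta_results), function(tg) {
      m <- meta_results[[tg]]
      data.frame(target = tg, pooled_beta = m$pooled_beta,
                 pooled_se = m$pooled_se, or = unname(m$or_scale["or"]),
                 ci_low = unname(m$or_scale["ci_low"]),
                 ci_high = unname(m$or_scale["ci_high"]), pval = m$pval,
                 tau2 = m$tau2, Q = m$Q_meta, k = m$k)
    }))
    paths["meta"] <- write_tsv(mdf, file.path(cfg$output_dir, "meta_pooled.tsv"))
  }
  if (!is.null(bonf))
    paths["bonferroni"] <- write_tsv(bonf, file.path(cfg$output_dir, "bonferroni.tsv"))
  if (length(mediation)) {
    mdf <- do.call(rbind, lapply(names(mediation), function(nm) {
      m <- mediation[[nm]]
      data.frame(pathway = nm, total = m$total, indirect = m$indirect,
                 direct = m$direct, proportion = m$proportion,
                 boot_se_indirect = m$boot_se_indirect,
                 boot_se_proportion = m$boot_se_proportion,
                 pval_proportion = m$pval_proportion)
    }))
    paths["mediation"] <- write_tsv(mdf, file.path(cfg$output_dir, "mediation.tsv"))
  }
  if (nrow(skipped))
    paths["skipped"] <- write_tsv(skipped, file.path(cfg$output_dir, "skipped_targets.tsv"))
  json_path <- file.path(cfg$output_dir, "summary.json")
  jsonlite::write_json(
    list(bonferroni = bonf,
         meta = lapply(meta_results, function(m)
           list(or = unname(m$or_scale["or"]),
                ci_low = unname(m$or_scale["ci_low"]),
                ci_high = unname(m$or_scale["ci_high"]),
                pval = m$pval, tau2 = m$tau2, k = m$k)),
         mediation = lapply(mediation, function(m)
           list(proportion = m$proportion, indirect = m$indirect,
                pval_proportion = m$pval_proportion)),
         skipped = skipped$target),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  paths["summary_json"] <- json_path
  count_df <- if (length(counts)) do.call(rbind, counts) else NULL
  if (!is.null(count_df))
    paths["counts"] <- write_tsv(count_df, file.path(cfg$output_dir, "stage_counts.tsv"))

  manifest <- c(
    paste("package_version:", as.character(utils::packageVersion("targetmr"))),
    paste("config_hash:", config_hash(cfg)),
    paste("seed:", cfg$seed),
    paste("sign_convention:", cfg$sign_convention),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "outputs:",
    vapply(paths, function(p)
      paste0("  ", basename(p), "  md5=", unname(tools::md5sum(p))), ""))
  writeLines(manifest, file.path(cfg$output_dir, "MANIFEST.txt"))

  invisible(list(estimates = estimates, meta = meta_results,
                 bonferroni = bonf, mediation = mediation,
                 diagnostics = diagnostics, skipped = skipped,
                 counts = count_df, manifest = manifest))
}

# stable hash of the configuration (paths + thresholds + seeds)
config_hash <- function(cfg) {
  cfg$.proxy_table <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate instruments against positive-control outcomes
#'
#' Runs the primary IVW estimator of each target's instrument against each
#' configured control outcome (an endpoint with a known pharmacological
#' response direction) and reports PASS when the estimated direction matches
#' the configured expectation with p < 0.05, FLAG otherwise.
#'
#' @param config a [study_config()] whose `controls` entry is a named list of
#'   `path`, `expected_direction` (+1/-1) per control outcome.
#' @return data frame `target`, `control`, `beta`, `pval`,
#'   `expected_direction`, `status`.
#' @export
validate_instruments <- function(config) {
  cfg <- study_config(config)
  if (is.null(cfg$controls) || length(cfg$controls) == 0) {
    message("no control outcomes configured: instruments not validated")
    return(data.frame(target = character(), control = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  exposure <- read_sumstats(cfg$exposure$path)
  ld_full <- read_ld_matrix(cfg$ld_path)
  targets <- if (is.character(cfg$targets)) read_gene_targets(cfg$targets)
             else lapply(cfg$targets, function(t)
               gene_target(t$name, t$chrom, t$start, t$end,
                           t$flank %||% cfg$flank))
  names(targets) <- vapply(targets, `[[`, "", "name")
  rows <- list()
  for (tg in names(targets)) {
    iset <- build_instruments(exposure, ld_full, targets[[tg]],
                              cfg$p_threshold, cfg$r2_prune)
    if (is.null(iset)) next
    for (ctl in names(cfg$controls)) {
      crec <- read_sumstats(cfg$controls[[ctl]]$path)
      pairs <- harmonize(iset$records, crec, iset$ld,
                         palindromic_eaf_window = cfg$palindromic_eaf_window)
      if (length(pairs$snp_ids) == 0) next
      est <- ivw_correlated(pairs)$estimate
      expd <- cfg$controls[[ctl]]$expected_direction
      status <- if (est$pval >= 0.05) "FLAG (direction indeterminate)"
                else if (sign(est$beta) == sign(expd)) "PASS"
                else "FLAG"
      rows[[paste(tg, ctl)]] <- data.frame(
        target = tg, control = ctl, beta = est$beta, pval = est$pval,
        expected_direction = expd, status = status, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(), control = character(),
               status = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
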