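#' Define a drug-target gene region
#'
#' @param name gene symbol.
#' @param chrom chromosome label (character, no "chr" prefix expected).
#' @param start,end 1-based inclusive gene coordinates (GRCh37).
#' @param flank flanking window in bp added to both sides (default 500 kb).
#' @return object of class `gene_target`.
#' @export
gene_target <- function(name, chrom, start, end, flank = 500000) {
  assert_that(start <= end, "start must be <= end")
  assert_that(flank >= 0, "flank must be >= 0")
  structure(list(name = name, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 flank = as.numeric(flank)),
            class = "gene_target")
}

#' Read gene targets from a TSV (columns name, chrom, start, end[, flank])
#'
#' @param path TSV path.
#' @param flank default flank used where the file has no flank column.
#' @return list of [gene_target()] objects.
#' @export
read_gene_targets <- function(path, flank = 500000) {
  df <- read_tsv(path)
  lapply(seq_len(nrow(df)), function(i) {
    gene_target(df$name[i], df$chrom[i], df$start[i], df$end[i],
                if ("flank" %in% names(df)) df$flank[i] else flank)
  })
}

#' Select cis variants for a target gene
#'
#' Keeps variants on the target chromosome, positioned within
#' `[start - flank, end + flank]` (clamped at position 1), with p-value
#' strictly below `p_threshold`. An empty result is a valid outcome: the
#' returned (empty) data frame carries attribute `no_instruments = TRUE`,
#' mirroring targets that must be skipped for lack of significant cis signal.
#'
#' @param records summary-statistics data frame.
#' @param target a [gene_target()].
#' @param p_threshold association p-value threshold (strict `<`); genome-wide
#'   significance 5e-8 is conventional for large European GWAS, 5e-5 is a
#'   relaxed threshold used for smaller East Asian GWAS.
#' @return subset of `records`, idempotent under re-application.
#' @export
select_cis_snps <- function(records, target, p_threshold = 5e-8) {
  assert_that(inherits(target, "gene_target"), "target must be a gene_target")
  lo <- max(1, target$start - target$flank)
  hi <- target$end + target$flank
  keep <- records$chrom == target$chrom &
    records$pos >= lo & records$pos <= hi &
    records$pval < p_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_instruments") <- nrow(out) == 0
  attr(out, "target") <- target$name
  out
}

#' Prune variants to weak linkage disequilibrium
#'
#' Greedy clumping: variants are ranked by ascending p-value; each is accepted
#' iff its squared correlation with every previously accepted variant is
#' strictly below `r2_max`. The retained pairwise correlation matrix travels
#' with the result so downstream estimators can adjust for the residual LD
#' that this deliberately permissive threshold leaves in place (weak LD is
#' allowed to increase the variance explained by the instrument).
#'
#' @param candidates summary-statistics data frame.
#' @param ld correlation (r, not r-squared) matrix aligned to `candidates`.
#' @param r2_max maximum squared pairwise correlation (default 0.30).
#' @return object of class `instrument_set`: list with `records`, `ld`
#'   (retained correlations), and `pruned_away` (ids removed).
#' @export
prune_ld <- function(candidates, ld, r2_max = 0.30) {
  m <- nrow(candidates)
  assert_that(nrow(ld) == m && ncol(ld) == m, "ld must be aligned to candidates")
  ord <- order(candidates$pval, candidates$snp)
  accepted <- integer()
  for (i in ord) {
    if (all(ld[i, accepted]^2 < r2_max)) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  rec <- candidates[accepted, , drop = FALSE]
  rownames(rec) <- NULL
  ldk <- ld[accepted, accepted, drop = FALSE]
  dimnames(ldk) <- list(rec$snp, rec$snp)
  structure(list(records = rec, ld = ldk,
                 pruned_away = candidates$snp[-accepted],
                 r2_max = r2_max),
            class = "instrument_set")
}

#' Instrument strength: variance explained and F statistics
#'
#' Per-variant variance explained on a variance-1 (per-SD) trait scale is
#' `r2_j = 2 p_j (1 - p_j) beta_j^2`; the corresponding F statistic is
#' `F_j = r2_j (n - 2) / (1 - r2_j)`. The aggregate over k variants uses
#' `F = (R2 / k) ((n - k - 1) / (1 - R2))` with `R2 = sum r2_j`. F of at
#' least 10 conventionally indicates minimal weak-instrument bias. Both
#' per-variant and aggregate values are reported: single-variant instruments
#' make aggregate-only reporting uninformative.
#'
#' @param instruments an `instrument_set` or summary-statistics data frame
#'   with `eaf` and `beta` columns (per-SD scale).
#' @param n exposure GWAS sample size.
#' @return list with `per_snp_r2`, `per_snp_F`, `total_r2`, `aggregate_F`,
#'   `k`, `n`.
#' @export
instrument_strength <- function(instruments, n) {
  rec <- if (inherits(instruments, "instrument_set")) instruments$records else instruments
  k <- nrow(rec)
  assert_that(k >= 1, "no instruments")
  assert_that(n > k + 1, "sample size must exceed k + 1")
  r2 <- 2 * rec$eaf * (1 - rec$eaf) * rec$beta^2
  total <- sum(r2)
  assert_that(total < 1, "total variance explained must be < 1")
  list(per_snp_r2 = stats::setNames(r2, rec$snp),
       per_snp_F = stats::setNames(r2 * (n - 2) / (1 - r2), rec$snp),
       total_r2 = total,
       aggregate_F = (total / k) * ((n - k - 1) / (1 - total)),
       k = k, n = n)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("instrument_set:", nrow(x$records), "variant(s) at pairwise r2 <",
      x$r2_max, "\n")
  invisible(x)
}
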