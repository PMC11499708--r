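#' Read and validate GWAS summary statistics
#'
#' Reads a delimited summary-statistics file, maps columns to the canonical
#' schema, and validates per-row invariants. Rows failing a hard invariant
#' (non-positive SE, EAF outside (0,1), identical alleles, missing required
#' fields) are dropped; the drop reasons and counts are attached as the
#' `"dropped"` attribute and reported via `message()`. Reported p-values that
#' disagree with the two-sided normal `2*pnorm(-|beta/se|)` beyond 2
#' significant figures raise a warning, not an error.
#'
#' @param path file path; `.gz` files are read transparently.
#' @param column_map named character vector mapping canonical names
#'   (`snp, chrom, pos, ea, oa, eaf, beta, se, pval, n`) to the file's header
#'   names. Defaults to the header written by [write_sumstats()].
#' @return validated summary-statistics data frame (canonical columns).
#' @export
read_sumstats <- function(path,
                          column_map = c(snp = "SNP", chrom = "CHR", pos = "POS",
                                         ea = "EA", oa = "OA", eaf = "EAF",
                                         beta = "BETA", se = "SE", pval = "P",
                                         n = "N")) {
  assert_that(file.exists(path), paste("file not found:", path))
  raw <- read_tsv(path)
  assert_that(nrow(raw) > 0, paste("empty summary-statistics file:", path))
  need <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(need, names(column_map))
  assert_that(length(missing_cols) == 0,
              paste("column_map missing entries for:", paste(missing_cols, collapse = ", ")))
  absent <- setdiff(unname(column_map[need]), names(raw))
  assert_that(length(absent) == 0,
              paste("required columns absent from file:", paste(absent, collapse = ", ")))
  rec <- raw[unname(column_map[need])]
  names(rec) <- need
  rec$chrom <- as.character(rec$chrom)
  rec$ea <- toupper(as.character(rec$ea))
  rec$oa <- toupper(as.character(rec$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- as.numeric(rec[[col]])

  reason <- rep(NA_character_, nrow(rec))
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- mark(!is.finite(rec$beta) | !is.finite(rec$se), "missing_stats")
  reason <- mark(rec$se <= 0, "nonpositive_se")
  reason <- mark(!is.finite(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1, "eaf_out_of_range")
  reason <- mark(rec$ea == rec$oa, "identical_alleles")
  reason <- mark(!(rec$ea %in% c("A", "C", "G", "T")) |
                   !(rec$oa %in% c("A", "C", "G", "T")), "non_acgt_allele")

  dropped <- data.frame(snp = rec$snp[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0) {
    tab <- table(dropped$reason)
    message("read_sumstats: dropped ", nrow(dropped), " row(s) [",
            paste(names(tab), tab, sep = "=", collapse = ", "), "]")
  }
  rec <- rec[is.na(reason), , drop = FALSE]
  rownames(rec) <- NULL

  ok <- is.finite(rec$pval) & rec$pval > 0
  implied <- 2 * stats::pnorm(-abs(rec$beta / rec$se))
  bad_p <- ok & implied > 0 &
    abs(signif(rec$pval, 2) - signif(implied, 2)) > 0.5 * 10^(floor(log10(pmax(implied, 1e-300))) - 1)
  if (any(bad_p))
    warning(sum(bad_p), " row(s) have p-values inconsistent with |beta/se| ",
            "(2 significant figures); kept as read", call. = FALSE)
  attr(rec, "dropped") <- dropped
  rec
}

# classify the allele configuration of an outcome record relative to the
# exposure record: "same", "swap", "strand", "strand_swap" or NA
allele_config <- function(ea_x, oa_x, ea_y, oa_y) {
  if (ea_y == ea_x && oa_y == oa_x) return("same")
  if (ea_y == oa_x && oa_y == ea_x) return("swap")
  cey <- complement_allele(ea_y); coy <- complement_allele(oa_y)
  if (cey == ea_x && coy == oa_x) return("strand")
  if (cey == oa_x && coy == ea_x) return("strand_swap")
  NA_character_
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect-allele orientation. When
#' outcome alleles are swapped relative to the exposure, the outcome beta sign
#' and EAF are flipped. Palindromic variants (A/T, C/G), whose strand cannot be
#' resolved from alleles alone, are resolved by allele frequency: the
#' strand/swap configuration minimizing `|eaf_x - eaf_y|` is taken, but only
#' when both traits are informative (`|eaf - 0.5| > palindromic_eaf_window` on
#' both sides); otherwise the variant is dropped with reason
#' `"palindromic_ambiguous"`. Exposure variants absent from the outcome are
#' replaced by their best proxy when a `proxy_table` provides one at
#' r-squared > 0.8 (see [substitute_proxies()]); otherwise dropped with reason
#' `"missing_no_proxy"`.
#'
#' @param exposure,outcome summary-statistics data frames (canonical columns).
#' @param ld LD correlation matrix aligned to `exposure` SNP order (dimnames
#'   required if proxies may reorder); defaults to identity.
#' @param palindromic_eaf_window frequency window around 0.5 inside which a
#'   palindromic variant is considered ambiguous (default 0.08).
#' @param proxy_table optional proxy table (columns `index_snp, proxy_snp, r2,
#'   phase`, phase `"same"` or `"opposite"`, optionally `distance`).
#' @return an object of class `harmonized_pairs`: list with `snp_ids`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf`, `n_x`, `n_y`, `ld`, `flips`
#'   (outcome allele flipped), `proxied` (proxy SNP id or NA), `dropped`
#'   (data frame of snp, reason), and `outcome_records` (the outcome rows
#'   rewritten in exposure orientation, for idempotence checks).
#' @export
harmonize <- function(exposure, outcome, ld = NULL,
                      palindromic_eaf_window = 0.08,
                      proxy_table = NULL) {
  assert_that(is.data.frame(exposure) && nrow(exposure) > 0, "empty exposure records")
  m <- nrow(exposure)
  if (is.null(ld)) {
    ld <- diag(m)
    dimnames(ld) <- list(exposure$snp, exposure$snp)
  }
  assert_that(nrow(ld) == m, "ld must be aligned to exposure SNP order")

  oidx <- match(exposure$snp, outcome$snp)
  proxied <- rep(NA_character_, m)
  if (any(is.na(oidx)) && !is.null(proxy_table)) {
    subs <- substitute_proxies(exposure$snp[is.na(oidx)], proxy_table,
                               outcome_snps = outcome$snp)
    for (k in seq_len(nrow(subs$substitutions))) {
      s <- subs$substitutions[k, ]
      i <- which(exposure$snp == s$index_snp)
      j <- which(outcome$snp == s$proxy_snp)
      oidx[i] <- j
      proxied[i] <- s$proxy_snp
    }
  }

  keep <- logical(m)
  flips <- logical(m)
  reason <- rep(NA_character_, m)
  by <- se_y <- eaf_y <- n_y <- rep(NA_real_, m)
  out_rec <- exposure[0, ]

  for (i in seq_len(m)) {
    j <- oidx[i]
    if (is.na(j)) { reason[i] <- "missing_no_proxy"; next }
    o <- outcome[j, ]
    ex <- exposure[i, ]
    pal <- is_palindromic(ex$ea, ex$oa)
    if (!is.na(proxied[i])) {
      # proxy substitution: phase from the proxy table decides orientation
      ph <- attr_phase(proxy_table, ex$snp, o$snp)
      flip <- identical(ph, "opposite")
      cfg_ok <- TRUE
    } else if (pal) {
      if (abs(ex$eaf - 0.5) <= palindromic_eaf_window ||
          abs(o$eaf - 0.5) <= palindromic_eaf_window) {
        reason[i] <- "palindromic_ambiguous"; next
      }
      # both strand interpretations collapse to: do the frequencies agree
      # as-is, or after flipping? pick the closer match
      flip <- abs(ex$eaf - o$eaf) > abs(ex$eaf - (1 - o$eaf))
      cfg_ok <- TRUE
    } else {
      cfg <- allele_config(ex$ea, ex$oa, o$ea, o$oa)
      if (is.na(cfg)) { reason[i] <- "allele_mismatch"; next }
      flip <- cfg %in% c("swap", "strand_swap")
      cfg_ok <- TRUE
    }
    keep[i] <- cfg_ok
    flips[i] <- flip
    by[i] <- if (flip) -o$beta else o$beta
    se_y[i] <- o$se
    eaf_y[i] <- if (flip) 1 - o$eaf else o$eaf
    n_y[i] <- o$n
    harm <- o
    harm$snp <- ex$snp
    harm$ea <- ex$ea; harm$oa <- ex$oa
    harm$beta <- by[i]; harm$eaf <- eaf_y[i]
    out_rec <- rbind(out_rec, harm)
  }

  dropped <- data.frame(snp = exposure$snp[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  ids <- exposure$snp[keep]
  ldk <- ld[keep, keep, drop = FALSE]
  if (length(ids) > 0)
    ldk <- ensure_pd(ldk, label = "harmonized LD matrix")
  dimnames(ldk) <- list(ids, ids)

  res <- list(snp_ids = ids,
              beta_x = exposure$beta[keep],
              se_x = exposure$se[keep],
              beta_y = by[keep],
              se_y = se_y[keep],
              eaf = exposure$eaf[keep],
              eaf_y = eaf_y[keep],
              n_x = exposure$n[keep],
              n_y = n_y[keep],
              ld = ldk,
              flips = flips[keep],
              proxied = proxied[keep],
              dropped = dropped,
              outcome_records = out_rec)
  class(res) <- "harmonized_pairs"
  res
}

# phase of a (index, proxy) pair in a proxy table
attr_phase <- function(proxy_table, index_snp, proxy_snp) {
  r <- proxy_table[proxy_table$index_snp == index_snp &
                     proxy_table$proxy_snp == proxy_snp, ]
  if (nrow(r) == 0) "same" else r$phase[1]
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  cat("harmonized_pairs:", length(x$snp_ids), "variant(s)")
  if (any(x$flips)) cat(";", sum(x$flips), "allele-flipped")
  if (any(!is.na(x$proxied))) cat(";", sum(!is.na(x$proxied)), "proxied")
  if (nrow(x$dropped) > 0) cat(";", nrow(x$dropped), "dropped")
  cat("\n")
  invisible(x)
}

#' Build a harmonized-pairs object directly from vectors
#'
#' Convenience constructor for already-aligned effect vectors (no allele
#' bookkeeping), used by the estimators' tests and by callers holding
#' pre-harmonized data.
#'
#' @param beta_x,se_x,beta_y,se_y aligned effect and SE vectors.
#' @param ld LD correlation matrix (default identity).
#' @param snp_ids optional variant ids.
#' @param eaf,n_x,n_y optional effect-allele frequencies and sample sizes
#'   (needed by [steiger_test()]).
#' @return `harmonized_pairs` object.
#' @export
harmonized_pairs <- function(beta_x, se_x, beta_y, se_y, ld = NULL,
                             snp_ids = NULL, eaf = NULL, n_x = NULL, n_y = NULL) {
  m <- length(beta_x)
  assert_that(length(se_x) == m && length(beta_y) == m && length(se_y) == m,
              "effect vectors must share length")
  assert_that(all(se_x > 0) && all(se_y > 0), "standard errors must be positive")
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(m))
  if (is.null(ld)) ld <- diag(m)
  ld <- ensure_pd(ld)
  dimnames(ld) <- list(snp_ids, snp_ids)
  res <- list(snp_ids = snp_ids, beta_x = beta_x, se_x = se_x,
              beta_y = beta_y, se_y = se_y,
              eaf = eaf, eaf_y = eaf, n_x = n_x, n_y = n_y, ld = ld,
              flips = rep(FALSE, m), proxied = rep(NA_character_, m),
              dropped = data.frame(snp = character(), reason = character()),
              outcome_records = NULL)
  class(res) <- "harmonized_pairs"
  res
}

# subset a harmonized_pairs object by logical or integer index
subset_pairs <- function(pairs, idx) {
  if (is.logical(idx)) idx <- which(idx)
  res <- pairs
  for (f in c("snp_ids", "beta_x", "se_x", "beta_y", "se_y",
              "eaf", "eaf_y", "n_x", "n_y", "flips", "proxied"))
    if (!is.null(res[[f]])) res[[f]] <- res[[f]][idx]
  res$ld <- pairs$ld[idx, idx, drop = FALSE]
  res
}

#' Substitute proxy variants for SNPs missing from an outcome GWAS
#'
#' For each missing variant, the highest-r-squared proxy exceeding `r2_min`
#' that is present among `outcome_snps` is substituted; its phase (allele
#' alignment relative to the index variant) travels with the substitution.
#' Ties in r-squared are broken by smaller genomic distance (if a `distance`
#' column exists), then lexicographic proxy id. Variants with no qualifying
#' proxy are reported, not errored.
#'
#' @param missing_snps character vector of index variant ids.
#' @param proxy_table data frame with columns `index_snp, proxy_snp, r2,
#'   phase` and optionally `distance`.
#' @param r2_min minimum squared LD correlation (default 0.80, strict `>`).
#' @param outcome_snps ids available in the outcome; `NULL` accepts any proxy.
#' @return list with `substitutions` (data frame index_snp, proxy_snp, r2,
#'   phase) and `unresolved` (character vector).
#' @export
substitute_proxies <- function(missing_snps, proxy_table, r2_min = 0.80,
                               outcome_snps = NULL) {
  need <- c("index_snp", "proxy_snp", "r2", "phase")
  assert_that(all(need %in% names(proxy_table)),
              paste("proxy_table must have columns:", paste(need, collapse = ", ")))
  subs <- proxy_table[0, need]
  unresolved <- character()
  for (s in missing_snps) {
    cand <- proxy_table[proxy_table$index_snp == s & proxy_table$r2 > r2_min, ]
    if (!is.null(outcome_snps))
      cand <- cand[cand$proxy_snp %in% outcome_snps, ]
    if (nrow(cand) == 0) { unresolved <- c(unresolved, s); next }
    dist <- if ("distance" %in% names(cand)) cand$distance else rep(0, nrow(cand))
    o <- order(-cand$r2, dist, cand$proxy_snp)
    subs <- rbind(subs, cand[o[1], need])
  }
  rownames(subs) <- NULL
  list(substitutions = subs, unresolved = unresolved)
}
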