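test_that("read_sumstats validates rows and reports drop reasons", {
  rec <- make_records(paste0("rs", 1:4), ea = c("A", "C", "G", "A"),
                      oa = c("G", "T", "G", "C"), eaf = c(0.3, 0.2, 0.4, 1.5),
                      beta = c(0.1, 0.2, 0.1, 0.1))
  rec$se[2] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  # write by hand: write_sumstats would refuse invalid rows is not its job,
  # but the reader must catch them
  out <- rec
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(back <- read_sumstats(path), "dropped 3")
  expect_equal(back$snp, "rs1")
  dropped <- attr(back, "dropped")
  expect_setequal(dropped$reason[dropped$snp == "rs2"], "nonpositive_se")
  expect_setequal(dropped$reason[dropped$snp == "rs3"], "identical_alleles")
  expect_setequal(dropped$reason[dropped$snp == "rs4"], "eaf_out_of_range")
})

test_that("alternate header names via column_map give identical records", {
  rec <- make_records(paste0("rs", 1:5), ea = rep("A", 5), oa = rep("G", 5),
                      eaf = seq(0.1, 0.5, 0.1), beta = rnorm(5, 0, 0.05))
  canonical <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(rec, canonical)
  alt <- read_sumstats(canonical)
  names_alt <- c("rsid", "chromosome", "base_pair", "allele1", "allele2",
                 "freq1", "effect", "stderr", "pvalue", "samplesize")
  df <- alt
  names(df) <- names_alt
  alt_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, alt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sumstats(alt_path,
                       column_map = c(snp = "rsid", chrom = "chromosome",
                                      pos = "base_pair", ea = "allele1",
                                      oa = "allele2", eaf = "freq1",
                                      beta = "effect", se = "stderr",
                                      pval = "pvalue", n = "samplesize"))
  expect_equal(got, alt, ignore_attr = TRUE)
})

test_that("reader errors on empty files and missing columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tBETA", p)
  expect_error(read_sumstats(p), "empty|absent")
  rec <- make_records("rs1", "A", "G", 0.2, 0.1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(rec, p2)
  expect_error(read_sumstats(p2, column_map = c(snp = "SNP")), "column_map")
})

test_that("inconsistent p-values warn but are kept", {
  rec <- make_records("rs1", "A", "G", 0.2, 0.05, se = 0.01)
  rec$pval <- 0.9  # z = 5 implies p ~ 6e-7
  out <- rec
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(back <- read_sumstats(p), "inconsistent")
  expect_equal(back$pval, 0.9)
})

test_that("identical allele coding harmonizes as the identity", {
  ex <- make_records(paste0("rs", 1:3), ea = c("A", "C", "G"),
                     oa = c("G", "T", "A"), eaf = c(0.2, 0.3, 0.4),
                     beta = c(0.1, -0.2, 0.15))
  out <- ex
  out$beta <- c(0.05, 0.07, -0.02)
  h <- harmonize(ex, out)
  expect_false(any(h$flips))
  expect_equal(h$beta_y, out$beta)
  expect_equal(h$beta_x, ex$beta)
  expect_identical(nrow(h$dropped), 0L)
})

test_that("swapped outcome alleles flip beta sign and mirror EAF", {
  ex <- make_records("rs1", "A", "G", eaf = 0.2, beta = 0.1)
  out <- make_records("rs1", "G", "A", eaf = 0.8, beta = 0.3)
  h <- harmonize(ex, out)
  expect_true(h$flips)
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$eaf_y, 0.2)
})

test_that("strand-flipped records harmonize without a sign flip", {
  ex <- make_records("rs1", "A", "G", eaf = 0.2, beta = 0.1)
  out <- make_records("rs1", "T", "C", eaf = 0.2, beta = 0.3)  # complement
  h <- harmonize(ex, out)
  expect_false(h$flips)
  expect_equal(h$beta_y, 0.3)
})

test_that("palindromic variants resolve by frequency or drop", {
  # informative frequencies on both sides: 0.9 vs 0.12 implies a flip
  ex <- make_records("rs1", "A", "T", eaf = 0.9, beta = 0.1)
  out <- make_records("rs1", "A", "T", eaf = 0.12, beta = 0.3)
  h <- harmonize(ex, out)
  expect_true(h$flips)
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$eaf_y, 0.88)

  # ambiguous frequency near 0.5 drops the variant
  ex2 <- make_records("rs1", "A", "T", eaf = 0.52, beta = 0.1)
  h2 <- harmonize(ex2, out)
  expect_identical(length(h2$snp_ids), 0L)
  expect_equal(h2$dropped$reason, "palindromic_ambiguous")
})

test_that("harmonization is idempotent", {
  ex <- make_records(paste0("rs", 1:4), ea = c("A", "A", "C", "A"),
                     oa = c("G", "T", "G", "C"), eaf = c(0.2, 0.85, 0.3, 0.4),
                     beta = c(0.1, 0.12, -0.2, 0.15))
  out <- make_records(paste0("rs", 1:4), ea = c("G", "T", "C", "A"),
                      oa = c("A", "A", "G", "C"), eaf = c(0.8, 0.15, 0.3, 0.4),
                      beta = c(0.05, 0.07, -0.02, 0.2))
  h1 <- harmonize(ex, out)
  h2 <- harmonize(ex, h1$outcome_records)
  expect_false(any(h2$flips))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$eaf_y, h1$eaf_y)
  expect_equal(h2$ld, h1$ld)
})

test_that("harmonization is invariant to wholesale outcome allele flips", {
  ex <- make_records(paste0("rs", 1:4), ea = c("A", "A", "C", "G"),
                     oa = c("G", "T", "G", "T"), eaf = c(0.2, 0.85, 0.3, 0.4),
                     beta = c(0.1, 0.12, -0.2, 0.15))
  out <- make_records(paste0("rs", 1:4), ea = c("A", "A", "C", "G"),
                      oa = c("G", "T", "G", "T"), eaf = c(0.22, 0.83, 0.33, 0.38),
                      beta = c(0.05, 0.07, -0.02, 0.2))
  flipped <- out
  flipped$ea <- out$oa
  flipped$oa <- out$ea
  flipped$beta <- -out$beta
  flipped$eaf <- 1 - out$eaf
  h1 <- harmonize(ex, out)
  h2 <- harmonize(ex, flipped)
  expect_equal(h1$beta_y, h2$beta_y)
  expect_equal(h1$eaf_y, h2$eaf_y)
  expect_equal(h1$snp_ids, h2$snp_ids)
})

test_that("proxy substitution picks the best qualifying proxy", {
  ptab <- data.frame(index_snp = c("rs1", "rs1", "rs2", "rs3"),
                     proxy_snp = c("rsA", "rsB", "rsC", "rsD"),
                     r2 = c(0.95, 0.85, 0.75, 0.95),
                     phase = c("same", "same", "same", "opposite"),
                     stringsAsFactors = FALSE)
  got <- substitute_proxies(c("rs1", "rs2", "rs3"), ptab,
                            outcome_snps = c("rsA", "rsB", "rsC", "rsD"))
  expect_equal(got$substitutions$proxy_snp[got$substitutions$index_snp == "rs1"], "rsA")
  expect_true("rs2" %in% got$unresolved)  # best proxy below 0.80
  expect_equal(got$substitutions$phase[got$substitutions$index_snp == "rs3"], "opposite")
})

test_that("proxy ties break by distance then lexicographic id", {
  ptab <- data.frame(index_snp = "rs1", proxy_snp = c("rsZ", "rsA", "rsB"),
                     r2 = c(0.9, 0.9, 0.9), phase = "same",
                     distance = c(100, 500, 100), stringsAsFactors = FALSE)
  got <- substitute_proxies("rs1", ptab)
  expect_equal(got$substitutions$proxy_snp, "rsB")  # min distance, then id
})

test_that("a missing variant with an opposite-phase proxy harmonizes with a sign flip", {
  ex <- make_records(c("rs1", "rs2"), ea = c("A", "C"), oa = c("G", "G"),
                     eaf = c(0.2, 0.3), beta = c(0.1, 0.2))
  # outcome lacks rs2 but carries its proxy rsP
  out <- make_records(c("rs1", "rsP"), ea = c("A", "A"), oa = c("G", "C"),
                      eaf = c(0.2, 0.7), beta = c(0.05, 0.4),
                      pos = c(17401000, 17402100))
  ptab <- data.frame(index_snp = "rs2", proxy_snp = "rsP", r2 = 0.9,
                     phase = "opposite", stringsAsFactors = FALSE)
  h <- harmonize(ex, out, proxy_table = ptab)
  expect_equal(h$snp_ids, c("rs1", "rs2"))
  expect_equal(h$proxied, c(NA, "rsP"))
  expect_equal(h$beta_y, c(0.05, -0.4))

  # without the proxy table the variant is dropped with a reason
  h0 <- harmonize(ex, out)
  expect_equal(h0$dropped$reason, "missing_no_proxy")
})
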