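test_that("read_summary_stats parses rows, skips invalid ones, errors usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t100\ta\tg\t0.2\t0.1\t0.01\t1e-9\t1000",
    "rs2\t1\t200\tC\tT\t0.4\t-0.2\t0.02\t1e-8\t1000",
    "rs3\t1\t300\tG\tA\t0.5\t0.05\t0.005\t1e-7\t1000"
  ), path)
  x <- read_summary_stats(path)
  expect_s3_class(x, "variant_assoc")
  expect_equal(nrow(x), 3L)
  expect_equal(attr(x, "n_skipped"), 0L)
  expect_equal(x$effect_allele[1], "A")  # uppercased

  # se = 0 and an unparseable beta are skipped and counted
  writeLines(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t100\tA\tG\t0.2\t0.1\t0\t1e-9\t1000",
    "rs2\t1\t200\tC\tT\t0.4\tnot_a_number\t0.02\t1e-8\t1000",
    "rs3\t1\t300\tG\tA\t0.5\t0.05\t0.005\t1e-7\t1000"
  ), path)
  expect_message(x <- read_summary_stats(path), "skipped 2")
  expect_equal(nrow(x), 1L)
  expect_equal(attr(x, "n_skipped"), 2L)

  # missing mandatory column is named in the error
  writeLines(c("SNP\tEA\tOA\tBETA\tP", "rs1\tA\tG\t0.1\t1e-9"), path)
  expect_error(read_summary_stats(path), "SE")

  writeLines("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN", path)
  expect_error(read_summary_stats(path), "no data rows")
})

test_that("summary stats round-trip bit-exactly through write/read", {
  x <- load_instrument_fixture("PCSK9")
  x$f_printed <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  y <- read_summary_stats(path)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    expect_identical(y[[col]], x[[col]], label = col)
  }
  expect_identical(y$snp, x$snp)
})

test_that("packaged instrument fixtures match the published table", {
  pcsk9 <- load_instrument_fixture("PCSK9")
  hmgcr <- load_instrument_fixture("HMGCR")
  npc1l1 <- load_instrument_fixture("NPC1L1")
  expect_equal(nrow(pcsk9), 33L)
  expect_equal(nrow(hmgcr), 19L)
  expect_equal(nrow(npc1l1), 6L)
  expect_equal(nrow(pcsk9) + nrow(hmgcr) + nrow(npc1l1), 58L)

  r <- pcsk9[pcsk9$snp == "rs11591147", ]
  expect_equal(r$beta, -0.348456)
  expect_equal(r$se, 0.00793088)
  expect_equal(r$effect_allele, "T")
  expect_equal(npc1l1$eaf[npc1l1$snp == "rs2073547"], 0.184007)
  expect_true(all(pcsk9$n == 440546))

  expect_error(load_instrument_fixture("ABCA1"), "PCSK9, HMGCR, NPC1L1")
})

test_that("LD matrix IO validates and round-trips", {
  m <- make_ld(c("rs1", "rs2", "rs3"), list(list("rs1", "rs2", 0.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(m, path)
  expect_equal(read_ld_matrix(path), m)

  bad <- m
  bad[1, 2] <- 1.5
  expect_error(validate_ld_matrix(bad), "\\[0, 1\\]")
  bad <- m
  bad[1, 2] <- 0.9  # asymmetric
  expect_error(validate_ld_matrix(bad), "symmetric")
  bad <- m
  diag(bad) <- 0.5
  expect_error(validate_ld_matrix(bad), "diagonal")
})

test_that("harmonize aligns, flips, and drops as specified", {
  expo <- make_variants("rs1", beta = 0.2, se = 0.01, ea = "T", oa = "G")
  outc <- make_variants("rs1", beta = 0.5, se = 0.05, ea = "G", oa = "T")
  h <- harmonize(expo, outc)
  expect_equal(h$action, "flipped")
  expect_equal(h$outcome_beta, -0.5)
  expect_equal(h$outcome_eaf, 0.7)

  # identical coding: kept, untouched
  h2 <- harmonize(expo, make_variants("rs1", 0.5, 0.05, ea = "T", oa = "G"))
  expect_equal(h2$action, "kept")
  expect_equal(h2$outcome_beta, 0.5)

  # palindromic inside the ambiguity window is dropped
  expo_pal <- make_variants("rs9", 0.2, 0.01, eaf = 0.49, ea = "A", oa = "T")
  outc_pal <- make_variants("rs9", 0.5, 0.05, eaf = 0.49, ea = "A", oa = "T")
  h3 <- harmonize(expo_pal, outc_pal, palindromic_eaf_window = 0.08)
  expect_equal(h3$action, "dropped_palindromic")

  # palindromic with concordant extreme EAFs survives
  expo_pal$eaf <- 0.1; outc_pal$eaf <- 0.12
  h4 <- harmonize(expo_pal, outc_pal, palindromic_eaf_window = 0.08)
  expect_equal(h4$action, "kept")

  # allele set matching neither orientation
  h5 <- harmonize(expo, make_variants("rs1", 0.5, 0.05, ea = "C", oa = "A"))
  expect_equal(h5$action, "dropped_mismatch")

  # duplicate ids are an ambiguous join
  dup <- rbind(as.data.frame(expo), as.data.frame(expo))
  class(dup) <- class(as.data.frame(expo))
  expect_error(harmonize(dup, outc), "duplicate")
})

test_that("harmonize is idempotent and flipping is an involution", {
  set.seed(101)
  alleles <- list(c("A", "G"), c("G", "A"), c("T", "C"), c("C", "T"))
  n <- 20
  pick <- sample(4, n, replace = TRUE)
  expo <- make_variants(sprintf("rs%d", 1:n), beta = rnorm(n, 0, 0.05),
                        se = runif(n, 0.005, 0.02), eaf = runif(n, 0.1, 0.9),
                        ea = vapply(pick, function(i) alleles[[i]][1], ""),
                        oa = vapply(pick, function(i) alleles[[i]][2], ""))
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  outc <- expo
  outc$beta <- rnorm(n, 0, 0.05)
  outc$se <- runif(n, 0.01, 0.05)
  tmp <- outc$effect_allele[swap]
  outc$effect_allele[swap] <- outc$other_allele[swap]
  outc$other_allele[swap] <- tmp
  outc$eaf[swap] <- 1 - outc$eaf[swap]

  h <- harmonize(expo, outc)
  expect_true(all(h$action %in% c("kept", "flipped")))
  # flipped records carry the negated beta and complemented eaf
  expect_equal(h$outcome_beta, ifelse(swap, -outc$beta, outc$beta))
  expect_equal(h$outcome_eaf, ifelse(swap, 1 - outc$eaf, outc$eaf))

  # idempotence: re-harmonizing the harmonized outcome changes nothing
  out2 <- make_variants(h$snp, beta = h$outcome_beta, se = h$outcome_se,
                        eaf = h$outcome_eaf, ea = h$effect_allele,
                        oa = h$other_allele)
  h2 <- harmonize(expo, out2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$outcome_beta, h$outcome_beta)
  expect_equal(h2$outcome_eaf, h$outcome_eaf)
})
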