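test_that("per-SNP chi-square prefers b/se and inverts p-values correctly", {
  expect_equal(snp_chisq(beta = 0.1, se = 0.05), 4)
  expect_equal(snp_chisq(p = 0.0455003), 4, tolerance = 1e-3)
  expect_equal(snp_chisq(p = 1), 0)
  # b/se wins over p by default; the flag flips the preference
  expect_equal(snp_chisq(beta = 0.1, se = 0.05, p = 0.5), 4)
  expect_equal(snp_chisq(beta = 0.1, se = 0.05, p = 0.5, prefer = "p"),
               qchisq(0.5, 1, lower.tail = FALSE))
  expect_error(snp_chisq(p = 0), "supply beta")
  expect_error(snp_chisq(beta = 0.1), "needs")
})

test_that("gene windows include boundary SNPs and match brute force", {
  genes <- tibble::tibble(gene = "G", chr = "1",
                          start = 100000L, end = 120000L)
  pos <- tibble::tibble(snp = c("in_edge", "out_edge", "inside", "wrong_chr"),
                        chr = c("1", "1", "1", "2"),
                        pos = c(50000L, 49999L, 110000L, 110000L))
  sets <- assemble_gene_sets(pos, genes, window_kb = 50)
  expect_equal(sets$snps[[1]], c("in_edge", "inside"))

  # randomised membership vs a direct per-(SNP, gene) interval check
  set.seed(31)
  genes3 <- tibble::tibble(
    gene = c("A", "B", "C"), chr = "1",
    start = c(1000L, 4000L, 9000L), end = c(3000L, 8000L, 12000L)
  )
  pos10 <- tibble::tibble(snp = sprintf("s%02d", 1:10), chr = "1",
                          pos = sort(sample.int(15000, 10)))
  w <- 1000
  sets3 <- suppressMessages(
    assemble_gene_sets(pos10, genes3, window_kb = w / 1000)
  )
  for (i in seq_len(nrow(sets3))) {
    g <- genes3[genes3$gene == sets3$set_id[i], ]
    manual <- pos10$snp[pos10$pos >= g$start - w & pos10$pos <= g$end + w]
    expect_equal(sets3$snps[[i]], manual)
  }
})

test_that("single-SNP set degenerates to the single-SNP test", {
  panel <- simulate_unlinked_genotypes(1000, 1, seed = 1)
  summ <- make_summary(panel_snps(panel), p = 0.0455)
  res <- run_fastbat(panel_snps(panel), summ, panel)
  expect_equal(res$p_fastbat, 0.0455, tolerance = 1e-3)
  expect_equal(res$n_snps_raw, 1L)
  expect_equal(res$top_snp_id, panel_snps(panel))
})

test_that("perfect-LD duplication leaves the unpruned p-value unchanged", {
  panel <- simulate_unlinked_genotypes(2000, 1, seed = 2)
  dup <- add_perfect_ld_snp(panel, panel_snps(panel)[1], "copy")
  summ <- make_summary(c(panel_snps(panel)[1], "copy"),
                       beta = 0.1, se = 0.05)
  res <- run_fastbat(c(panel_snps(panel)[1], "copy"), summ, dup,
                     r2_prune = NULL)
  # z^2 = 4 twice, lambdas = {2}: p = P(chi^2_1 > 4), duplication is inert
  expect_equal(res$chisq_obs, 8)
  expect_equal(res$p_fastbat, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("allele mismatches are dropped and top SNP precedes pruning", {
  panel <- simulate_unlinked_genotypes(800, 4, seed = 3)
  ids <- panel_snps(panel)
  summ <- make_summary(ids, beta = c(0.02, 0.3, 0.02, 0.02),
                       se = 0.05, a1 = c("A", "A", "T", "A"),
                       a2 = c("G", "G", "C", "G"))
  expect_message(
    res <- run_fastbat(ids, summ, panel, r2_prune = NULL),
    "mismatched alleles"
  )
  expect_equal(res$n_snps_raw, 3L)        # the T/C SNP is dropped
  expect_equal(res$top_snp_id, ids[2])    # smallest p among summary SNPs

  dup <- add_perfect_ld_snp(panel, ids[2], "copy2")
  summ2 <- dplyr::bind_rows(
    make_summary(ids, beta = c(0.02, 0.3, 0.02, 0.02), se = 0.05),
    make_summary("copy2", beta = 0.3, se = 0.05)
  )
  res2 <- run_fastbat(c(ids, "copy2"), summ2, dup, r2_prune = 0.9)
  # pruning removed one of the perfect pair but the report keeps the top SNP
  expect_equal(res2$n_snps_pruned, res2$n_snps_raw - 1L)
  expect_true(res2$top_snp_id %in% c(ids[2], "copy2"))
})

test_that("genome-wide driver sorts, skips bad sets, and reports threshold", {
  panel <- simulate_unlinked_genotypes(1500, 30, seed = 4)
  cohort <- simulate_phenotype(panel, panel_snps(panel)[1], 0.02, seed = 4)
  summ <- marginal_scan(cohort)
  sets <- split(panel_snps(panel), rep(1:6, each = 5))
  names(sets) <- sprintf("SET%d", 1:6)
  sets$BAD <- c("absent1", "absent2")
  res <- fastbat(summ, panel, sets = sets)
  expect_s3_class(res, "fastbat_result")
  expect_equal(nrow(res), 6)
  expect_false(is.unsorted(res$p_fastbat))
  expect_equal(attr(res, "skipped")$set_id, "BAD")
  expect_equal(attr(res, "threshold"), 0.05 / 6)
  g <- glance(res)
  expect_equal(g$n_sets, 6L)
  expect_equal(g$n_skipped, 1L)
  td <- tidy(res)
  expect_true(is.logical(td$significant))
})

test_that("identity-reference fastbat equals the chi-square closed form", {
  # orthogonal (unlinked, large n) reference: -log10 p matches chi^2_m
  panel <- simulate_unlinked_genotypes(5000, 8, seed = 6)
  ids <- panel_snps(panel)
  summ <- make_summary(ids, beta = 0.03, se = 0.02)
  res <- run_fastbat(ids, summ, panel, r2_prune = NULL)
  ld <- compute_ld(panel)
  expect_equal(res$chisq_obs, 8 * 2.25)
  expect_equal(res$p_fastbat,
               quadform_pvalue(res$chisq_obs, spectral_weights(ld)))
  # threshold 1.0 with no perfect pairs is identical to the unpruned run
  res_pr <- run_fastbat(ids, summ, panel, r2_prune = 1)
  expect_equal(res_pr$p_fastbat, res$p_fastbat)
  expect_equal(res_pr$n_snps_pruned, res_pr$n_snps_raw)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(significance_threshold(25000), 2e-6)
  expect_equal(significance_threshold(1), 0.05)
  expect_equal(significance_threshold(10, alpha = 0.1), 0.01)
})
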