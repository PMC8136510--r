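test_that("gene pooling is additive and order invariant", {
  snps <- data.frame(
    gene_id = "g1", replicate_id = "r1",
    maternal_count = c(10, 20), paternal_count = c(2, 8),
    stringsAsFactors = FALSE
  )
  out <- pool_gene_counts(snps)
  expect_equal(out$maternal, 30)
  expect_equal(out$paternal, 10)
  expect_equal(out$n_snps, 2L)

  single <- pool_gene_counts(snps[1, ])
  expect_equal(single$maternal, 10)
  expect_equal(single$paternal, 2)

  expect_equal(pool_gene_counts(snps[2:1, ]), out)
})

test_that("inclusion filter applies the single-SNP depth rescue and TPM rule", {
  pooled <- rbind(
    data.frame(gene_id = "single_deep", replicate_id = c("r1", "r2"),
               maternal = c(40, 45), paternal = c(20, 15), n_snps = 1L),
    data.frame(gene_id = "single_shallow", replicate_id = c("r1", "r2"),
               maternal = c(25, 25), paternal = c(15, 15), n_snps = 1L),
    data.frame(gene_id = "multi_low_tpm", replicate_id = c("r1", "r2"),
               maternal = c(100, 100), paternal = c(100, 100), n_snps = 3L),
    data.frame(gene_id = "multi_ok", replicate_id = c("r1", "r2"),
               maternal = c(100, 100), paternal = c(100, 100), n_snps = 3L)
  )
  tpm <- data.frame(gene_id = c("single_deep", "single_shallow",
                                "multi_low_tpm", "multi_ok"),
                    tpm = c(5, 5, 0.5, 2))
  out <- gene_inclusion_filter(pooled, tpm)
  # 120 pooled reads rescue the single-SNP gene; 80 do not; TPM < 1 removes
  expect_setequal(unique(out$gene_id), c("single_deep", "multi_ok"))

  expect_message(
    out2 <- gene_inclusion_filter(pooled, tpm[-4, ]),
    "no TPM")
  expect_setequal(unique(out2$gene_id), "single_deep")
})

test_that("exact binomial test matches hand-derived and reference values", {
  expect_equal(exact_binomial_test(5, 10), 1.0)
  expect_equal(exact_binomial_test(10, 10), 2 / 1024)
  expect_equal(exact_binomial_test(8, 10), 2 * 56 / 1024)
  expect_error(exact_binomial_test(1, 0), "total = 0")
  expect_error(exact_binomial_test(5, 4))

  # spot agreement with the stock two-sided test at the symmetric null
  for (n in c(7, 12, 19)) for (m in c(0, 3, n %/% 2, n)) {
    expect_equal(exact_binomial_test(m, n),
                 stats::binom.test(m, n, 0.5)$p.value, tolerance = 1e-12)
  }
  # vectorized
  expect_equal(exact_binomial_test(c(5, 10), c(10, 10)), c(1, 2 / 1024))
})

test_that("ASE categories follow the thresholds with B precedence", {
  expect_equal(classify_ase(0.50, FALSE), "B")
  expect_equal(classify_ase(0.97, TRUE), "M")
  expect_equal(classify_ase(0.80, TRUE), "MB")
  expect_equal(classify_ase(0.02, TRUE), "P")
  expect_equal(classify_ase(0.20, TRUE), "PB")
  # the biparental rule wins even at extreme p_m when the null is not rejected
  expect_equal(classify_ase(0.99, FALSE), "B")
  # closed B interval and closed M/P boundaries
  expect_equal(classify_ase(c(0.35, 0.65), c(TRUE, TRUE)), c("B", "B"))
  expect_equal(classify_ase(c(0.95, 0.05), c(TRUE, TRUE)), c("M", "P"))

  # partition of [0,1] under rejection: every value gets exactly one category
  grid <- seq(0, 1, by = 0.001)
  cats <- classify_ase(grid, rep(TRUE, length(grid)))
  expect_true(all(nchar(cats) > 0))
  expect_setequal(unique(cats), c("M", "MB", "B", "PB", "P"))
})

test_that("replicate homogeneity G-test matches hand computations", {
  same <- replicate_homogeneity(c(90, 45), c(10, 5))
  expect_equal(same$G, 0)
  expect_equal(same$df, 1L)

  opposite <- replicate_homogeneity(c(10, 0), c(0, 10))
  expect_equal(opposite$G, 40 * log(2), tolerance = 1e-12)
  expect_equal(opposite$df, 1L)

  # a replicate duplicated k times is perfectly homogeneous
  for (k in c(2, 5)) {
    dup <- replicate_homogeneity(rep(30, k), rep(10, k))
    expect_equal(dup$G, 0)
  }
  expect_message(z <- replicate_homogeneity(c(10, 10, 0), c(5, 5, 0)),
                 "zero total")
  expect_equal(z$df, 1L)
})

test_that("G-test of independence handles margins and permutations", {
  flat <- g_test_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$G, 0)
  expect_equal(flat$df, 1L)

  diag2 <- g_test_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$G, 40 * log(2), tolerance = 1e-12)

  set.seed(41)
  tab <- matrix(rpois(12, 30), 3, 4)
  base <- g_test_independence(tab)
  perm <- g_test_independence(tab[sample(3), sample(4)])
  expect_equal(perm$G, base$G, tolerance = 1e-12)
  expect_equal(perm$df, base$df)
  expect_true(base$p >= 0 && base$p <= 1)
  expect_equal(base$df, 6L)

  withzero <- rbind(tab, 0)
  expect_message(dropped <- g_test_independence(withzero), "empty row")
  expect_equal(dropped$G, base$G)
  expect_equal(dropped$df, base$df)

  expect_error(g_test_independence(matrix(c(5, 5), 1)), "at least 2 x 2")
})

test_that("replicate validation keeps homogeneous or fully concordant genes", {
  tpm <- data.frame(gene_id = c("hom", "het_agree", "het_disagree"),
                    tpm = c(10, 10, 10))
  # hom: identical strong maternal bias in all replicates
  hom <- gene_counts("hom", m = c(900, 900, 900), p = c(100, 100, 100))
  # het_agree: heterogeneous counts but same category (MB) and all rejected
  het_agree <- gene_counts("het_agree", m = c(900, 700, 800), p = c(100, 300, 200))
  # het_disagree: replicates span M / B-ish / PB patterns
  het_disagree <- gene_counts("het_disagree",
                              m = c(980, 500, 200), p = c(20, 500, 800))
  out <- classify_gene_ase(rbind(hom, het_agree, het_disagree), tpm)
  expect_true("hom" %in% out$gene_id)
  expect_true("het_agree" %in% out$gene_id)
  expect_false("het_disagree" %in% out$gene_id)
  expect_equal(out$category[out$gene_id == "hom"], "MB")
  expect_equal(out$p_m[out$gene_id == "hom"], 0.9)
  # pooled p_m is count weighted: pooling counts then dividing
  expect_equal(out$p_m[out$gene_id == "het_agree"], 2400 / 3000)
  audit <- attr(out, "audit")
  expect_equal(unname(audit["genes_included"]), 3)
  expect_equal(unname(audit["genes_validated"]), 2)
})

test_that("scaffolds map to chromosomes by unique majority only", {
  counts <- data.frame(
    scaffold = c("s1", "s1", "s2", "s2", "s3"),
    chromosome = c("chr1", "chr2", "chr1", "chr2", "chr1"),
    n = c(5, 1, 3, 3, 0)
  )
  out <- assign_scaffolds_to_chromosomes(counts)
  expect_equal(out$chromosome[out$scaffold == "s1"], "chr1")
  expect_true(is.na(out$chromosome[out$scaffold == "s2"]))  # tie
  expect_true(is.na(out$chromosome[out$scaffold == "s3"]))  # no evidence
  expect_error(assign_scaffolds_to_chromosomes(transform(counts, n = -n - 1)))
})
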