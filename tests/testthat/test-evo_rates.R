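test_that("codon degeneracy matches hand-enumerated cases", {
  expect_equal(annotate_degeneracy("ATG"), c(0, 0, 0))          # Met: unique codon
  expect_equal(annotate_degeneracy("TTT"), c(0, 0, 1 / 3))      # only TTC stays Phe
  expect_equal(annotate_degeneracy("GGG"), c(0, 0, 1))          # 4-fold Gly
  expect_error(annotate_degeneracy("TAA"), "stop")
  amb <- annotate_degeneracy("ANG")
  expect_equal(as.numeric(amb), c(0, 0, 0))
  expect_true(attr(amb, "ambiguous"))
})

test_that("site counting follows the toy gene arithmetic and strand symmetry", {
  genome <- Biostrings::DNAStringSet(c(ctg = "ATGTTTGGGTAA"))
  cds <- data.frame(gene_id = "g", contig = "ctg", strand = "+",
                    start = 1L, end = 12L, phase = 0L)
  sc <- count_sites(cds, genome)
  expect_true(sc$valid)
  expect_equal(sc$s_sites, 4 / 3, tolerance = 1e-12)
  expect_equal(sc$n_sites, 23 / 3, tolerance = 1e-12)
  expect_equal(sc$n_sites + sc$s_sites, 3 * sc$n_codons)

  # minus-strand gene built from the reverse complement gives identical counts
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGTTTGGGTAA")))
  genome_m <- Biostrings::DNAStringSet(c(ctg = rc))
  cds_m <- transform(cds, strand = "-")
  sc_m <- count_sites(cds_m, genome_m)
  expect_equal(sc_m$s_sites, sc$s_sites)
  expect_equal(sc_m$n_sites, sc$n_sites)

  # internal stop flags the gene instead of crashing
  genome_stop <- Biostrings::DNAStringSet(c(ctg = "ATGTAAGGGTAA"))
  sc_bad <- count_sites(cds, genome_stop)
  expect_false(sc_bad$valid)
  expect_match(sc_bad$reason, "internal stop")

  expect_error(count_sites(transform(cds, start = 5L, end = 4L), genome))
})

test_that("the site sum rule holds across a simulated gene set", {
  toy <- simulate_toy_genome(n_genes = 8, codons_per_gene = 30,
                             n_variants = 10, seed = 7)
  for (g in unique(toy$cds$gene_id)) {
    sc <- count_sites(toy$cds[toy$cds$gene_id == g, ], toy$genome)
    expect_true(sc$valid)
    expect_equal(sc$n_sites + sc$s_sites, 3 * sc$n_codons, tolerance = 1e-9)
    expect_equal(sc$n_codons, 31L)  # start + 30 body codons, stop excluded
  }
})

test_that("substitutions classify by codon effect with strand awareness", {
  genome <- Biostrings::DNAStringSet(c(ctg = "ATGTTTGGGTAA"))
  cds <- data.frame(gene_id = "g", contig = "ctg", strand = "+",
                    start = 1L, end = 12L, phase = 0L)
  snps <- data.frame(contig = "ctg", pos = c(6L, 7L), ref = c("T", "G"),
                     alt = c("C", "A"), stringsAsFactors = FALSE)
  out <- classify_substitution(snps, cds, genome)
  expect_equal(out$effect, c("synonymous", "nonsynonymous"))  # TTT->TTC; GGG->AGG
  expect_equal(out$gene_id, c("g", "g"))

  # minus-strand gene: plus-strand CAT holds codon ATG; the plus-strand T->C
  # at the codon's 5' genomic end turns the coding codon into GTG (Val)
  genome_m <- Biostrings::DNAStringSet(c(ctg = "CAT"))
  cds_m <- data.frame(gene_id = "gm", contig = "ctg", strand = "-",
                      start = 1L, end = 3L, phase = 0L)
  snp_m <- data.frame(contig = "ctg", pos = 3L, ref = "T", alt = "C")
  expect_equal(classify_substitution(snp_m, cds_m, genome_m)$effect,
               "nonsynonymous")

  # intronic and intergenic SNPs are noncoding
  genome2 <- Biostrings::DNAStringSet(c(ctg = "ATGTTTAAAAAGGGTAAACGT"))
  cds2 <- data.frame(gene_id = "g2", contig = "ctg", strand = "+",
                     start = c(1L, 11L), end = c(6L, 16L), phase = 0L)
  noncod <- classify_substitution(
    data.frame(contig = "ctg", pos = c(8L, 20L), ref = c("A", "G"),
               alt = c("C", "A")), cds2, genome2)
  expect_equal(noncod$effect, c("noncoding", "noncoding"))

  expect_error(
    classify_substitution(
      data.frame(contig = "ctg", pos = 6L, ref = "A", alt = "C"), cds, genome),
    "reference mismatch")
})

test_that("minus-strand classification equals its plus-strand construction", {
  # planted truth is recorded at construction time, independently of the
  # classifier, for genes on both strands with and without introns
  toy <- simulate_toy_genome(n_genes = 20, codons_per_gene = 25,
                             n_variants = 100, seed = 13)
  eff <- classify_substitution(toy$variants, toy$cds, toy$genome)
  expect_equal(eff$effect, toy$variants$truth_effect)
  expect_equal(eff$gene_id, toy$variants$gene_id)
  minus <- toy$cds$strand[match(toy$variants$gene_id, toy$cds$gene_id)] == "-"
  expect_gt(sum(minus), 0)  # both strands exercised
})

test_that("dN/dS arithmetic handles the defined and undefined cases", {
  expect_equal(compute_dnds(1, 1, 23 / 3, 4 / 3), 12 / 69, tolerance = 1e-12)
  expect_equal(compute_dnds(0, 3, 10, 5), 0)
  expect_true(is.na(compute_dnds(2, 0, 10, 5)))     # no synonymous changes
  expect_true(is.na(compute_dnds(2, 1, 0, 5)))      # zero site count
  expect_equal(compute_dnds(c(1, 0), c(1, 2), c(23 / 3, 9), c(4 / 3, 3)),
               c(12 / 69, 0))
})

test_that("Kruskal-Wallis and Nemenyi behave on toy configurations", {
  kw <- kruskal_wallis(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)

  flat <- kruskal_wallis(rep(c(5, 5), 5), rep(c("a", "b"), 5))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)

  # group relabelling leaves H unchanged
  set.seed(71)
  x <- rnorm(60); g <- rep(c("a", "b", "c"), 20)
  perm <- c(a = "c", b = "a", c = "b")[g]
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(x, perm)$H,
               tolerance = 1e-12)

  nem <- nemenyi_posthoc(c(1, 2, 3, 7, 8, 9, 4, 5, 6),
                         rep(c("A", "B", "C"), each = 3))
  expect_true(isSymmetric(nem))
  expect_equal(diag(nem), c(A = 1, B = 1, C = 1))
  expect_lt(nem["A", "B"], nem["A", "C"])  # larger rank separation

  ident <- nemenyi_posthoc(rep(1, 10), rep(c("A", "B"), 5))
  expect_equal(ident["A", "B"], 1)
  expect_error(nemenyi_posthoc(c(1, 2), factor(c("A", "A"), levels = c("A", "B"))),
               "empty group")
})
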