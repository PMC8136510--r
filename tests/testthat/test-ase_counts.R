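counter_row <- function(contig = "c1", position = 100L, refAllele = "A",
                        altAllele = "G", refCount = 90, altCount = 10,
                        totalCount = refCount + altCount) {
  data.frame(contig = contig, position = position, refAllele = refAllele,
             altAllele = altAllele, refCount = refCount, altCount = altCount,
             totalCount = totalCount, stringsAsFactors = FALSE)
}

test_that("allele counts are relabelled by cross orientation", {
  row <- counter_row(refCount = 90, altCount = 10, totalCount = 100)
  mat_ref <- read_allele_counts(row, maternal = "ref")
  expect_equal(mat_ref$maternal_count, 90)
  expect_equal(mat_ref$paternal_count, 10)
  expect_equal(mat_ref$other_count, 0)

  mat_alt <- read_allele_counts(row, maternal = "alt")
  expect_equal(mat_alt$maternal_count, 10)
  expect_equal(mat_alt$paternal_count, 90)

  extra <- read_allele_counts(counter_row(totalCount = 105))
  expect_equal(extra$other_count, 5)
  expect_equal(extra$total_depth, 105)

  expect_error(read_allele_counts(counter_row(refCount = -1)), "negative")
})

test_that("rows outside the panel are dropped with a logged count", {
  rows <- rbind(counter_row(position = 100L), counter_row(position = 200L))
  panel <- data.frame(contig = "c1", pos = 100L)
  expect_message(out <- read_allele_counts(rows, panel = panel), "not in panel")
  expect_equal(out$pos, 100L)
})

test_that("SNP filter cascade enforces depth and unique-fraction per replicate", {
  design <- cross_design("citri", "ficus", c("r1", "r2", "r3"), min_depth = 30)
  counts <- rbind(
    # s1: depth 25 in one replicate -> removed (hybrid minimum is 30x)
    make_count(pos = 1L, replicate_id = "r1", maternal = 20, paternal = 5),
    make_count(pos = 1L, replicate_id = "r2", maternal = 30, paternal = 10),
    make_count(pos = 1L, replicate_id = "r3", maternal = 30, paternal = 10),
    # s2: 85/100 parental reads in r2 -> removed (<90% uniquely mapped)
    make_count(pos = 2L, replicate_id = "r1", maternal = 80, paternal = 20),
    make_count(pos = 2L, replicate_id = "r2", maternal = 60, paternal = 25, other = 15),
    make_count(pos = 2L, replicate_id = "r3", maternal = 80, paternal = 20),
    # s3: exactly at both boundaries in all replicates -> kept
    make_count(pos = 3L, replicate_id = "r1", maternal = 20, paternal = 10),
    make_count(pos = 3L, replicate_id = "r2", maternal = 15, paternal = 15),
    make_count(pos = 3L, replicate_id = "r3", maternal = 25, paternal = 5),
    # s4: absent from r3 -> removed
    make_count(pos = 4L, replicate_id = "r1", maternal = 50, paternal = 50),
    make_count(pos = 4L, replicate_id = "r2", maternal = 50, paternal = 50)
  )
  out <- filter_snp_counts(counts, design)
  expect_setequal(unique(out$pos), 3L)
  expect_true(all(out$total_depth >= design$min_depth))
  audit <- attr(out, "audit")
  expect_equal(unname(audit["removed_missing_replicate"]), 1)
  expect_equal(unname(audit["removed_depth"]), 1)
  expect_equal(unname(audit["removed_unique_frac"]), 1)

  # replicate input order never changes the outcome
  shuffled <- counts[sample.int(nrow(counts)), ]
  out2 <- filter_snp_counts(shuffled, design)
  expect_setequal(paste(out2$pos, out2$replicate_id),
                  paste(out$pos, out$replicate_id))

  expect_error(
    filter_snp_counts(counts[counts$replicate_id != "r3", ], design),
    "absent from counts")
})

test_that("purity filter removes exactly the planted impure sites", {
  set.seed(31)
  n <- 40
  impure <- sample(c(TRUE, FALSE), n, replace = TRUE)
  pure_frac <- ifelse(impure, runif(n, 0.5, 0.949), runif(n, 0.95, 1))
  pure <- do.call(rbind, lapply(seq_len(n), function(i) {
    tot <- 200
    make_count(pos = i, replicate_id = "pure",
               maternal = round(tot * pure_frac[i]),
               paternal = tot - round(tot * pure_frac[i]))
  }))
  hybrid <- do.call(rbind, lapply(seq_len(n), function(i)
    make_count(pos = i, replicate_id = "r1", maternal = 60, paternal = 40)))

  out <- suppressMessages(purity_filter(hybrid, pure))
  removed <- setdiff(hybrid$pos, out$pos)
  expect_setequal(removed, which(round(200 * pure_frac) / 200 < 0.95))
  expect_true(all(out$pure_line_checked))

  # sites absent from the pure-line control are kept but flagged
  extra <- make_count(pos = 999L, replicate_id = "r1")
  out2 <- suppressMessages(purity_filter(rbind(hybrid, extra), pure))
  expect_true(999L %in% out2$pos)
  expect_false(out2$pure_line_checked[out2$pos == 999L])

  expect_warning(unchanged <- purity_filter(hybrid, pure[0, ]), "empty")
  expect_equal(unchanged$pos, hybrid$pos)
})

test_that("SNPs are assigned to exactly one feature class", {
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    contig = c("c1", "c1", "c1"),
    start = c(100L, 300L, 600L),
    end = c(200L, 400L, 700L),
    stringsAsFactors = FALSE
  )
  snps <- data.frame(contig = c("c1", "c1", "c1", "c2"),
                     pos = c(150L, 250L, 500L, 10L),
                     stringsAsFactors = FALSE)
  out <- annotate_snp_features(snps, exons)
  expect_equal(out$feature[out$pos == 150], "exonic")
  expect_equal(out$gene_id[out$pos == 150], "g1")
  expect_equal(out$feature[out$pos == 250], "intronic")  # inside span, no exon
  expect_equal(out$feature[out$pos == 500], "intergenic")
  expect_equal(out$feature[out$pos == 10], "orphan")     # contig unannotated
  # partition: one class per SNP
  classes_per_snp <- tapply(out$feature, paste(out$contig, out$pos),
                            function(x) length(unique(x)))
  expect_true(all(classes_per_snp == 1L))
  expect_equal(length(classes_per_snp), 4L)
})

test_that("a SNP in exons of two genes is duplicated and flagged", {
  exons <- data.frame(gene_id = c("g1", "g2"), contig = "c1",
                      start = c(100L, 140L), end = c(200L, 240L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(contig = "c1", pos = 150L)
  out <- annotate_snp_features(snps, exons)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_true(all(out$multi_gene))
})
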