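#' Pool exonic SNP counts per gene and replicate
#'
#' @param snp_counts data.frame of exonic SNP counts with columns `gene_id`,
#'   `replicate_id`, `maternal_count`, `paternal_count` (one row per SNP per
#'   replicate).
#' @return data.frame with one row per gene x replicate: `gene_id`,
#'   `replicate_id`, `maternal`, `paternal`, `n_snps`.
#' @export
pool_gene_counts <- function(snp_counts) {
  stopifnot(all(c("gene_id", "replicate_id", "maternal_count", "paternal_count")
                %in% names(snp_counts)))
  snp_counts <- snp_counts[!is.na(snp_counts$gene_id), , drop = FALSE]
  if (nrow(snp_counts) == 0L)
    return(data.frame(gene_id = character(), replicate_id = character(),
                      maternal = numeric(), paternal = numeric(),
                      n_snps = integer()))
  key <- paste(snp_counts$gene_id, snp_counts$replicate_id, sep = "\r")
  maternal <- rowsum(snp_counts$maternal_count, key)
  paternal <- rowsum(snp_counts$paternal_count, key)
  n_snps <- rowsum(rep(1L, nrow(snp_counts)), key)
  parts <- strsplit(rownames(maternal), "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    replicate_id = vapply(parts, `[`, "", 2L),
    maternal = as.numeric(maternal),
    paternal = as.numeric(paternal),
    n_snps = as.integer(n_snps),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene inclusion filter: SNP coverage and expression level
#'
#' A gene is kept iff it is covered by at least two SNPs in every replicate,
#' or — when covered by a single SNP — its maternal+paternal read depth pooled
#' across replicates is at least `single_snp_min_depth`; and its mean TPM
#' across replicates is at least `min_tpm`.
#'
#' @param pooled output of [pool_gene_counts()].
#' @param tpm data.frame with `gene_id` and `tpm` (mean TPM across
#'   replicates); genes missing from it are excluded with a message.
#' @param single_snp_min_depth pooled-depth rescue threshold for single-SNP
#'   genes.
#' @param min_tpm minimum mean TPM.
#' @return the rows of `pooled` for included genes, with `mean_tpm` attached.
#' @export
gene_inclusion_filter <- function(pooled, tpm, single_snp_min_depth = 100,
                                  min_tpm = 1) {
  stopifnot(all(c("gene_id", "tpm") %in% names(tpm)))
  min_snps <- tapply(pooled$n_snps, pooled$gene_id, min)
  depth <- tapply(pooled$maternal + pooled$paternal, pooled$gene_id, sum)
  snp_ok <- min_snps >= 2L | depth >= single_snp_min_depth

  tpm_map <- stats::setNames(tpm$tpm, tpm$gene_id)
  gene_tpm <- tpm_map[names(min_snps)]
  no_tpm <- is.na(gene_tpm)
  if (any(no_tpm))
    message(sum(no_tpm), " gene(s) excluded: no TPM value")
  keep_genes <- names(min_snps)[snp_ok & !no_tpm & gene_tpm >= min_tpm]

  out <- pooled[pooled$gene_id %in% keep_genes, , drop = FALSE]
  out$mean_tpm <- tpm_map[out$gene_id]
  rownames(out) <- NULL
  out
}

#' Two-sided exact binomial test against a null maternal fraction
#'
#' Computes the tail-doubled two-sided p-value
#' `min(1, 2 * min(P(X <= m), P(X >= m)))` for `X ~ Binomial(total, null_p)`.
#' At `null_p = 0.5` this equals the minimum-likelihood two-sided p-value by
#' symmetry. Vectorized over `maternal` and `total`.
#'
#' @param maternal maternal read count(s).
#' @param total total (maternal + paternal) read count(s); must be >= 1.
#' @param null_p null maternal fraction (0.5 = Mendelian expression).
#' @return numeric vector of p-values in \[0, 1\].
#' @export
exact_binomial_test <- function(maternal, total, null_p = 0.5) {
  if (any(total < 1)) stop("exact_binomial_test undefined for total = 0")
  if (any(maternal < 0 | maternal > total))
    stop("maternal count must lie in [0, total]")
  lower <- stats::pbinom(maternal, total, null_p)
  upper <- stats::pbinom(maternal - 1, total, null_p, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Classify a gene into an allele-specific expression category
#'
#' Categories: biparental (`B`) when the Mendelian null was not rejected
#' and/or `0.35 <= p_m <= 0.65`; otherwise exclusively maternal (`M`,
#' `p_m >= 0.95`), maternally biased (`MB`, `0.65 < p_m < 0.95`), paternally
#' biased (`PB`, `0.05 < p_m < 0.35`) or exclusively paternal (`P`,
#' `p_m <= 0.05`). The biparental rule takes precedence: an unrejected gene
#' is `B` regardless of `p_m`.
#'
#' @param p_m maternal expression fraction(s) in \[0, 1\].
#' @param rejected logical: was the exact binomial null rejected (after
#'   Bonferroni correction)?
#' @return character vector of categories.
#' @export
classify_ase <- function(p_m, rejected) {
  stopifnot(all(p_m >= 0 & p_m <= 1))
  out <- character(length(p_m))
  b <- !rejected | (p_m >= 0.35 & p_m <= 0.65)
  out[b] <- "B"
  out[!b & p_m >= 0.95] <- "M"
  out[!b & p_m > 0.65 & p_m < 0.95] <- "MB"
  out[!b & p_m > 0.05 & p_m < 0.35] <- "PB"
  out[!b & p_m <= 0.05] <- "P"
  out
}

#' G-test of homogeneity of allelic bias across replicates
#'
#' Builds the 2 x k allele-by-replicate table and computes the log-likelihood
#' ratio statistic `G = 2 * sum(O * ln(O/E))` with expectations from the
#' marginals (`0 * ln 0 = 0`), `df = k - 1`, and a chi-square upper-tail
#' p-value. Replicates with zero total are excluded.
#'
#' @param maternal,paternal per-replicate counts.
#' @return list with `G`, `df`, `p`.
#' @export
replicate_homogeneity <- function(maternal, paternal) {
  tot <- maternal + paternal
  keep <- tot > 0
  if (sum(!keep) > 0L)
    message(sum(!keep), " replicate(s) excluded from homogeneity test: zero total")
  maternal <- maternal[keep]; paternal <- paternal[keep]
  if (length(maternal) < 2L)
    stop("replicate_homogeneity needs >= 2 replicates with positive totals")
  # one allele absent from every replicate: proportions are identical, G = 0
  if (sum(maternal) == 0 || sum(paternal) == 0)
    return(list(G = 0, df = length(maternal) - 1L, p = 1))
  g_test_independence(rbind(maternal, paternal))
}

#' G-test of independence on a contingency table
#'
#' `G = 2 * sum(O * ln(O/E))` with `E` from the row/column marginals,
#' `df = (r-1)(c-1)`, chi-square upper-tail p-value. No Williams or Yates
#' correction is applied. Rows or columns with a zero marginal are dropped
#' (with a message) and the degrees of freedom adjusted.
#'
#' @param tab numeric matrix of non-negative counts, at least 2 x 2 after
#'   dropping empty margins.
#' @return list with `G`, `df`, `p`.
#' @export
g_test_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts in contingency table")
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    message("dropping ", sum(empty_r), " empty row(s) and ",
            sum(empty_c), " empty column(s)")
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2 with positive marginals")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Classify genes into ASE categories with replicate validation
#'
#' The full gene-level classifier for one cross direction:
#' \enumerate{
#'   \item pool exonic SNP counts per gene and replicate
#'     ([pool_gene_counts()]);
#'   \item apply the SNP-coverage and TPM inclusion filter
#'     ([gene_inclusion_filter()]); the number of included genes is the
#'     Bonferroni family size;
#'   \item per replicate, run the exact binomial test against `p_m = 0.5` and
#'     classify ([classify_ase()]);
#'   \item test replicate homogeneity with a Bonferroni-corrected G-test;
#'     homogeneous genes are validated immediately, heterogeneous genes only
#'     if all replicates agree on category and rejection status;
#'   \item for validated genes, pool counts across replicates, run a final
#'     exact binomial test, and assign the final category from the pooled
#'     `p_m` and pooled-test rejection.
#' }
#'
#' @param snp_counts exonic SNP counts (`gene_id`, `replicate_id`,
#'   `maternal_count`, `paternal_count`).
#' @param tpm data.frame `gene_id`, `tpm` (mean TPM across replicates).
#' @param alpha family-wise significance level.
#' @param single_snp_min_depth,min_tpm passed to [gene_inclusion_filter()].
#' @return data.frame of validated genes: `gene_id`, `n_snps`,
#'   `pooled_maternal`, `pooled_paternal`, `p_m`, `binomial_p`,
#'   `bonferroni_significant`, `homogeneity_G`, `homogeneity_p`, `category`,
#'   `mean_tpm`. The `audit` attribute records genes in/validated and the
#'   Bonferroni family size.
#' @export
classify_gene_ase <- function(snp_counts, tpm, alpha = 0.05,
                              single_snp_min_depth = 100, min_tpm = 1) {
  pooled <- pool_gene_counts(snp_counts)
  inc <- gene_inclusion_filter(pooled, tpm,
                               single_snp_min_depth = single_snp_min_depth,
                               min_tpm = min_tpm)
  genes <- unique(inc$gene_id)
  n_tests <- length(genes)
  if (n_tests == 0L)
    return(empty_gene_table())
  per_gene <- split(inc, inc$gene_id)

  rows <- lapply(per_gene, function(g) {
    tot <- g$maternal + g$paternal
    p_rep <- exact_binomial_test(g$maternal, tot)
    rej_rep <- p_rep < alpha / n_tests
    cat_rep <- classify_ase(g$maternal / tot, rej_rep)
    hom <- if (nrow(g) >= 2L) replicate_homogeneity(g$maternal, g$paternal)
           else list(G = 0, df = 0L, p = 1)
    hom_p_corr <- min(1, hom$p * n_tests)
    validated <- hom_p_corr >= alpha ||
      (length(unique(cat_rep)) == 1L && length(unique(rej_rep)) == 1L)
    pm_sum <- sum(g$maternal); pp_sum <- sum(g$paternal)
    p_pool <- exact_binomial_test(pm_sum, pm_sum + pp_sum)
    rej_pool <- p_pool < alpha / n_tests
    data.frame(
      gene_id = g$gene_id[1],
      n_snps = max(g$n_snps),
      pooled_maternal = pm_sum,
      pooled_paternal = pp_sum,
      p_m = pm_sum / (pm_sum + pp_sum),
      binomial_p = p_pool,
      bonferroni_significant = rej_pool,
      homogeneity_G = hom$G,
      homogeneity_p = hom$p,
      validated = validated,
      category = classify_ase(pm_sum / (pm_sum + pp_sum), rej_pool),
      mean_tpm = g$mean_tpm[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  res <- out[out$validated, setdiff(names(out), "validated"), drop = FALSE]
  rownames(res) <- NULL
  attr(res, "audit") <- c(genes_included = n_tests,
                          genes_validated = nrow(res),
                          bonferroni_family = n_tests)
  res
}

empty_gene_table <- function() {
  structure(
    data.frame(gene_id = character(), n_snps = integer(),
               pooled_maternal = numeric(), pooled_paternal = numeric(),
               p_m = numeric(), binomial_p = numeric(),
               bonferroni_significant = logical(), homogeneity_G = numeric(),
               homogeneity_p = numeric(), category = character(),
               mean_tpm = numeric(), stringsAsFactors = FALSE),
    audit = c(genes_included = 0L, genes_validated = 0L, bonferroni_family = 0L))
}

#' Assign scaffolds to chromosomes by majority of alignments
#'
#' A scaffold is assigned to the chromosome it aligns to most often; ties
#' between two or more chromosomes, or all-zero counts, leave it unassigned
#' (`NA`).
#'
#' @param alignment_counts data.frame with `scaffold`, `chromosome`, `n`
#'   (alignment counts, >= 0).
#' @return data.frame `scaffold`, `chromosome` (`NA` when unassigned).
#' @export
assign_scaffolds_to_chromosomes <- function(alignment_counts) {
  stopifnot(all(c("scaffold", "chromosome", "n") %in% names(alignment_counts)))
  if (any(alignment_counts$n < 0)) stop("alignment counts must be >= 0")
  per <- split(alignment_counts, alignment_counts$scaffold)
  assigned <- vapply(per, function(d) {
    if (all(d$n == 0)) return(NA_character_)
    top <- d$chromosome[d$n == max(d$n)]
    if (length(top) > 1L) NA_character_ else as.character(top)
  }, character(1))
  data.frame(scaffold = names(assigned), chromosome = unname(assigned),
             stringsAsFactors = FALSE)
}
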