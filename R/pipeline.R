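#' Run the full parent-of-origin ASE pipeline on a reciprocal design
#'
#' Orchestrates the stages for one reciprocal cross pair: SNP-level filtering
#' ([filter_snp_counts()]) in each direction, gene-level pooling and
#' classification ([classify_gene_ase()]), reciprocal pairing and
#' parent-of-origin classification ([pair_reciprocal()], [classify_poe()]).
#' Deterministic: identical inputs and thresholds reproduce identical
#' outputs.
#'
#' @param counts_dir1,counts_dir2 SNP count tables for the two cross
#'   directions (columns as produced by [read_allele_counts()] or
#'   [simulate_cross()], with `gene_id`).
#' @param tpm data.frame `gene_id`, `tpm` (mean TPM across replicates).
#' @param design1,design2 [cross_design()] objects; defaults are built from
#'   the replicates present in each table with `min_depth`.
#' @param min_depth per-SNP minimum depth used when designs are defaulted
#'   (20 = intraspecific setting).
#' @param alpha family-wise significance level.
#' @param unique_frac_min minimum uniquely-mapped parental read fraction.
#' @param cross_pair label for the pair.
#' @return list with `genes_dir1`, `genes_dir2` (validated gene tables),
#'   `poe` (the [classify_poe()] table) and `manifest` (thresholds and
#'   per-stage record counts).
#' @export
run_ase_pipeline <- function(counts_dir1, counts_dir2, tpm,
                             design1 = NULL, design2 = NULL,
                             min_depth = 20, alpha = 0.05,
                             unique_frac_min = 0.90, cross_pair = "pair1") {
  default_design <- function(counts, dir) {
    cross_design(maternal_line = paste0("line_m_", dir),
                 paternal_line = paste0("line_p_", dir),
                 replicate_ids = unique(counts$replicate_id),
                 min_depth = min_depth)
  }
  if (is.null(design1)) design1 <- default_design(counts_dir1, 1)
  if (is.null(design2)) design2 <- default_design(counts_dir2, 2)

  f1 <- filter_snp_counts(counts_dir1, design1, unique_frac_min)
  f2 <- filter_snp_counts(counts_dir2, design2, unique_frac_min)
  g1 <- classify_gene_ase(f1, tpm, alpha = alpha)
  g2 <- classify_gene_ase(f2, tpm, alpha = alpha)
  pairs <- pair_reciprocal(g1, g2)
  poe <- classify_poe(pairs, alpha = alpha, cross_pair = cross_pair)

  manifest <- list(
    thresholds = list(min_depth1 = design1$min_depth,
                      min_depth2 = design2$min_depth,
                      unique_frac_min = unique_frac_min, alpha = alpha,
                      p_m_cutpoints = c(0.05, 0.35, 0.65, 0.95)),
    counts = c(snps_in_dir1 = length(unique(paste(counts_dir1$contig, counts_dir1$pos))),
               snps_kept_dir1 = length(unique(paste(f1$contig, f1$pos))),
               snps_in_dir2 = length(unique(paste(counts_dir2$contig, counts_dir2$pos))),
               snps_kept_dir2 = length(unique(paste(f2$contig, f2$pos))),
               genes_dir1 = nrow(g1), genes_dir2 = nrow(g2),
               genes_paired = nrow(pairs)),
    audit_dir1 = attr(g1, "audit"), audit_dir2 = attr(g2, "audit")
  )
  list(genes_dir1 = g1, genes_dir2 = g2, poe = poe, manifest = manifest)
}

#' Summarize ASE category counts and percentages
#'
#' Tabulates gene categories in the fixed order M, MB, B, PB, P (plus
#' `no_poe_bias` when present) with percentages reported to one decimal
#' place. The denominator defaults to the sum of the counts but can be
#' overridden when a stated dataset total differs from the tabulated sum.
#'
#' @param categories character vector of per-gene categories, or a named
#'   numeric vector of pre-tabulated counts.
#' @param total percentage denominator; defaults to `sum` of the counts.
#' @return data.frame `category`, `n`, `pct` (one decimal).
#' @export
summarize_categories <- function(categories, total = NULL) {
  order_cats <- c("B", "MB", "M", "PB", "P", "no_poe_bias")
  if (is.numeric(categories)) {
    counts <- categories
  } else {
    counts <- table(categories)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  present <- intersect(order_cats, names(counts))
  extra <- setdiff(names(counts), order_cats)
  counts <- counts[c(present, extra)]
  if (is.null(total)) total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 1) else rep(0, length(counts))
  data.frame(category = names(counts), n = as.numeric(counts),
             pct = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Build a category contingency table across data sets
#'
#' Stacks per-dataset category counts into the k x c table consumed by
#' [g_test_independence()], using the union of categories (absent categories
#' count 0).
#'
#' @param ... named numeric vectors of category counts (one per data set), or
#'   a single named list of them.
#' @return integer matrix with data sets as rows and categories as columns.
#' @export
category_contingency <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  if (length(sets) < 2L) stop("need at least two data sets")
  cats <- unique(unlist(lapply(sets, names)))
  tab <- t(vapply(sets, function(s) {
    out <- stats::setNames(numeric(length(cats)), cats)
    out[names(s)] <- s
    out
  }, numeric(length(cats))))
  if (is.null(rownames(tab))) rownames(tab) <- paste0("set", seq_len(nrow(tab)))
  tab
}
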