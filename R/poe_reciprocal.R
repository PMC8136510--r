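#' Pair gene-level ASE calls from reciprocal cross directions
#'
#' Inner join on `gene_id`: only genes with validated ASE information in both
#' cross directions are retained, since parent-of-origin effects can only be
#' asserted when both directions are observed.
#'
#' @param dir1,dir2 gene tables from [classify_gene_ase()] for the two
#'   reciprocal directions.
#' @return data.frame with per-direction columns suffixed `_dir1` / `_dir2`.
#' @export
pair_reciprocal <- function(dir1, dir2) {
  for (d in list(dir1, dir2))
    if (anyDuplicated(d$gene_id))
      stop("duplicate gene_id within a cross direction")
  common <- intersect(dir1$gene_id, dir2$gene_id)
  n_drop <- (nrow(dir1) - length(common)) + (nrow(dir2) - length(common))
  if (n_drop > 0L)
    message(n_drop, " unpaired gene record(s) dropped")
  cols <- c("p_m", "category", "pooled_maternal", "pooled_paternal")
  a <- dir1[match(common, dir1$gene_id), cols, drop = FALSE]
  b <- dir2[match(common, dir2$gene_id), cols, drop = FALSE]
  names(a) <- paste0(cols, "_dir1")
  names(b) <- paste0(cols, "_dir2")
  out <- cbind(data.frame(gene_id = common, stringsAsFactors = FALSE), a, b)
  rownames(out) <- NULL
  out
}

#' Classify parent-of-origin effects from a reciprocal pair
#'
#' Computes, for each paired gene, the reciprocal average
#' `p_m_mean = (p_m_dir1 + p_m_dir2) / 2` and a final category from
#' [classify_ase()] with rejection taken from an exact binomial test on
#' counts pooled over both directions. Genes whose two directions disagree in
#' ASE category *and* whose reciprocal `p_m` difference exceeds the mean
#' absolute difference `D` across all paired genes (computed before any
#' flagging) are flagged `no_poe_bias`: their bias follows the parental line,
#' not the parental sex.
#'
#' @param pairs output of [pair_reciprocal()].
#' @param alpha family-wise significance level; the Bonferroni family is the
#'   number of paired genes.
#' @param cross_pair label recorded in the output.
#' @return data.frame with `gene_id`, `p_m_dir1`, `p_m_dir2`, `p_m_mean`,
#'   `category_dir1`, `category_dir2`, `poe_category` (an ASE category or
#'   `"no_poe_bias"`) and `cross_pair`; `pooled_maternal`/`pooled_paternal`
#'   sum both directions. The mean absolute reciprocal difference is attached
#'   as attribute `D`.
#' @export
classify_poe <- function(pairs, alpha = 0.05, cross_pair = "pair1") {
  stopifnot(nrow(pairs) >= 1L)
  diff <- abs(pairs$p_m_dir1 - pairs$p_m_dir2)
  D <- mean(diff)
  p_m_mean <- (pairs$p_m_dir1 + pairs$p_m_dir2) / 2

  m_pool <- pairs$pooled_maternal_dir1 + pairs$pooled_maternal_dir2
  p_pool <- pairs$pooled_paternal_dir1 + pairs$pooled_paternal_dir2
  n_tests <- nrow(pairs)
  p_val <- exact_binomial_test(m_pool, m_pool + p_pool)
  rejected <- p_val < alpha / n_tests

  category <- classify_ase(p_m_mean, rejected)
  discordant <- pairs$category_dir1 != pairs$category_dir2 & diff > D
  poe_category <- ifelse(discordant, "no_poe_bias", category)

  out <- data.frame(
    gene_id = pairs$gene_id,
    p_m_dir1 = pairs$p_m_dir1, p_m_dir2 = pairs$p_m_dir2,
    p_m_mean = p_m_mean,
    category_dir1 = pairs$category_dir1, category_dir2 = pairs$category_dir2,
    pooled_maternal = m_pool, pooled_paternal = p_pool,
    poe_category = poe_category,
    cross_pair = cross_pair,
    stringsAsFactors = FALSE
  )
  attr(out, "D") <- D
  out
}

#' Combine parent-of-origin calls across cross pairs
#'
#' Takes the union of genes over all reciprocal cross pairs. A gene observed
#' in several pairs receives the unweighted mean of its per-pair `p_m_mean`
#' values and a category from [classify_ase()] on that mean, with rejection
#' from an exact binomial test on counts pooled over all pairs. A gene
#' flagged `no_poe_bias` in any pair keeps that flag (the conservative
#' conflict rule).
#'
#' @param poe_sets list of per-pair tables from [classify_poe()].
#' @param alpha family-wise significance level (family = combined gene count).
#' @return data.frame `gene_id`, `p_m`, `n_pairs`, `poe_category`.
#' @export
combine_cross_pairs <- function(poe_sets, alpha = 0.05) {
  stopifnot(is.list(poe_sets), length(poe_sets) >= 1L)
  all_poe <- do.call(rbind, poe_sets)
  genes <- unique(all_poe$gene_id)
  n_tests <- length(genes)
  per <- split(all_poe, all_poe$gene_id)
  rows <- lapply(per, function(g) {
    p_m <- mean(g$p_m_mean)
    m <- sum(g$pooled_maternal); p <- sum(g$pooled_paternal)
    rejected <- exact_binomial_test(m, m + p) < alpha / n_tests
    flagged <- any(g$poe_category == "no_poe_bias")
    data.frame(
      gene_id = g$gene_id[1],
      p_m = p_m,
      n_pairs = nrow(g),
      poe_category = if (flagged) "no_poe_bias" else classify_ase(p_m, rejected),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
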