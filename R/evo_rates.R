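# Codon machinery uses the standard nuclear genetic code throughout; mutations
# creating a stop are counted as nonsynonymous and the terminal stop codon is
# excluded from site counts.

.bases <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Per-position synonymous fraction of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-nucleotide changes that preserve the encoded amino acid. Changes
#' creating a stop codon count as nonsynonymous. Stop codons are not valid
#' input; codons containing an ambiguous base contribute `(0, 0, 0)` and are
#' flagged via the `"ambiguous"` attribute.
#'
#' @param codon a 3-letter nucleotide string over A/C/G/T.
#' @return numeric vector of length 3 of synonymous fractions in \[0, 1\].
#' @export
annotate_degeneracy <- function(codon) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  nts <- strsplit(codon, "")[[1]]
  if (!all(nts %in% .bases)) {
    out <- c(0, 0, 0)
    attr(out, "ambiguous") <- TRUE
    return(out)
  }
  aa <- translate_codon(codon)
  if (aa == "*") stop("annotate_degeneracy is undefined for stop codons: ", codon)
  vapply(1:3, function(pos) {
    alt <- setdiff(.bases, nts[pos])
    syn <- vapply(alt, function(b) {
      mut <- nts; mut[pos] <- b
      aa2 <- translate_codon(paste(mut, collapse = ""))
      identical(aa2, aa) # stop ('*') never equals aa, so it counts nonsynonymous
    }, logical(1))
    sum(syn) / 3
  }, numeric(1))
}

# lookup of per-codon synonymous-site totals, built once per session
degeneracy_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      codons <- names(Biostrings::GENETIC_CODE)
      non_stop <- codons[Biostrings::GENETIC_CODE != "*"]
      cache <<- vapply(non_stop, function(cd) sum(annotate_degeneracy(cd)),
                       numeric(1))
    }
    cache
  }
})

# extract the spliced CDS of one gene in translation order
extract_cds <- function(cds, genome) {
  ctg <- cds$contig[1]
  if (!ctg %in% names(genome)) stop("contig not in genome: ", ctg)
  ivs <- cds[order(cds$start), , drop = FALSE]
  seqs <- lapply(seq_len(nrow(ivs)), function(i)
    Biostrings::subseq(genome[[ctg]], ivs$start[i], ivs$end[i]))
  s <- do.call(Biostrings::xscat, seqs)
  strand <- cds$strand[1]
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  phase <- if ("phase" %in% names(cds)) {
    if (strand == "-") cds$phase[which.max(cds$end)] else cds$phase[which.min(cds$start)]
  } else 0L
  if (is.na(phase)) phase <- 0L
  if (phase > 0L) s <- Biostrings::subseq(s, phase + 1L)
  s
}

#' Count synonymous and nonsynonymous sites of a coding gene
#'
#' Sums the per-position synonymous fractions over all non-stop codons of the
#' spliced CDS: `s_sites` is that sum and `n_sites = 3 * codons - s_sites`,
#' so the two always add up to three times the codon count. A terminal stop
#' codon is excluded; an internal stop flags the gene as invalid.
#'
#' @param cds data.frame of CDS intervals for one gene: `contig`, `strand`,
#'   `start`, `end` (1-based inclusive, and optional `phase` of the first
#'   interval in translation order).
#' @param genome a `DNAStringSet`.
#' @return list with `n_sites`, `s_sites`, `n_codons` and `valid` (FALSE with
#'   a `reason` when the CDS contains an internal stop or its length is not a
#'   multiple of 3).
#' @export
count_sites <- function(cds, genome) {
  stopifnot(nrow(cds) >= 1L)
  s <- extract_cds(cds, genome)
  if (length(s) == 0L) stop("zero-length CDS")
  if (length(s) %% 3L != 0L)
    return(list(n_sites = NA_real_, s_sites = NA_real_, n_codons = NA_integer_,
                valid = FALSE, reason = "length not a multiple of 3"))
  codons <- substring(as.character(s), seq(1, length(s), 3), seq(3, length(s), 3))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aas))
    return(list(n_sites = NA_real_, s_sites = NA_real_, n_codons = NA_integer_,
                valid = FALSE, reason = "ambiguous base in CDS"))
  # drop a terminal stop; an internal stop invalidates the gene
  if (aas[length(aas)] == "*") {
    codons <- codons[-length(codons)]
    aas <- aas[-length(aas)]
  }
  if (any(aas == "*"))
    return(list(n_sites = NA_real_, s_sites = NA_real_, n_codons = NA_integer_,
                valid = FALSE, reason = "internal stop codon"))
  s_sites <- sum(degeneracy_table()[codons])
  n_codons <- length(codons)
  list(n_sites = 3 * n_codons - s_sites, s_sites = s_sites,
       n_codons = n_codons, valid = TRUE, reason = NA_character_)
}

#' Classify substitutions as synonymous, nonsynonymous or noncoding
#'
#' For each SNP (given on the plus strand), finds the CDS codon containing
#' it, substitutes the alternate base (reverse-complementing for minus-strand
#' genes) and compares the encoded amino acids. SNPs outside every CDS are
#' `noncoding`.
#'
#' @param snps data.frame with `contig`, `pos`, `ref`, `alt` (plus-strand
#'   alleles; `ref` must match the genome).
#' @param cds data.frame of CDS intervals for all genes: `gene_id`, `contig`,
#'   `strand`, `start`, `end`.
#' @param genome a `DNAStringSet`.
#' @return data.frame: `contig`, `pos`, `gene_id` (`NA` for noncoding) and
#'   `effect` in `{"synonymous", "nonsynonymous", "noncoding"}`.
#' @export
classify_substitution <- function(snps, cds, genome) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(snps)))
  snp_gr <- GenomicRanges::GRanges(snps$contig, IRanges::IRanges(snps$pos, snps$pos))
  cds_gr <- GenomicRanges::GRanges(cds$contig, IRanges::IRanges(cds$start, cds$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, cds_gr, ignore.strand = TRUE)

  out <- data.frame(contig = snps$contig, pos = snps$pos,
                    gene_id = NA_character_, effect = "noncoding",
                    stringsAsFactors = FALSE)
  if (length(hits) == 0L) return(out)

  cds_by_gene <- split(cds, cds$gene_id)
  spliced <- lapply(cds_by_gene, extract_cds, genome = genome)

  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    gene <- cds$gene_id[S4Vectors::subjectHits(hits)[h]]
    g <- cds_by_gene[[gene]]
    strand <- g$strand[1]
    ref_base <- as.character(Biostrings::subseq(genome[[snps$contig[i]]],
                                                snps$pos[i], snps$pos[i]))
    if (ref_base != snps$ref[i])
      stop("reference mismatch at ", snps$contig[i], ":", snps$pos[i],
           " (genome ", ref_base, ", variant ", snps$ref[i], ")")
    # position within the spliced CDS, in translation order
    ivs <- g[order(g$start), , drop = FALSE]
    offs <- cumsum(c(0, ivs$end - ivs$start + 1))
    k <- which(snps$pos[i] >= ivs$start & snps$pos[i] <= ivs$end)[1]
    cds_pos_plus <- offs[k] + (snps$pos[i] - ivs$start[k] + 1)
    total <- offs[length(offs)]
    cds_seq <- spliced[[gene]]
    if (strand == "-") {
      cds_pos <- total - cds_pos_plus + 1
      alt_base <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(snps$alt[i])))
    } else {
      cds_pos <- cds_pos_plus
      alt_base <- snps$alt[i]
    }
    codon_idx <- (cds_pos - 1) %/% 3
    codon_start <- codon_idx * 3 + 1
    if (codon_start + 2 > length(cds_seq)) next  # truncated trailing codon
    codon <- as.character(Biostrings::subseq(cds_seq, codon_start, codon_start + 2))
    mut <- codon
    substr(mut, cds_pos - codon_start + 1, cds_pos - codon_start + 1) <- alt_base
    aa1 <- translate_codon(codon); aa2 <- translate_codon(mut)
    out$gene_id[i] <- gene
    out$effect[i] <- if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
  }
  out
}

#' dN/dS from site and change counts
#'
#' `dnds = (n_changes / n_sites) / (s_changes / s_sites)`; undefined (`NA`)
#' when there are no synonymous changes or any site count is zero — such
#' genes are excluded from rate comparisons rather than padded.
#'
#' @param n_changes,s_changes nonsynonymous / synonymous change counts.
#' @param n_sites,s_sites nonsynonymous / synonymous site counts.
#' @return numeric vector of dN/dS ratios (`NA` where undefined).
#' @export
compute_dnds <- function(n_changes, s_changes, n_sites, s_sites) {
  out <- (n_changes / n_sites) / (s_changes / s_sites)
  undef <- s_changes == 0 | !is.finite(n_sites) | !is.finite(s_sites) |
    n_sites == 0 | s_sites == 0
  out[undef] <- NA_real_
  out
}

#' Per-gene dN/dS table from a variant panel
#'
#' Combines [count_sites()] and [classify_substitution()] over all genes:
#' counts synonymous/nonsynonymous sites from the CDS and synonymous/
#' nonsynonymous changes from the panel SNPs falling in each gene's CDS.
#'
#' @param snps variant table (`contig`, `pos`, `ref`, `alt`).
#' @param cds CDS interval table (`gene_id`, `contig`, `strand`, `start`,
#'   `end`).
#' @param genome a `DNAStringSet`.
#' @return data.frame with `gene_id`, `n_sites`, `s_sites`, `n_changes`,
#'   `s_changes`, `dnds` (`NA` where undefined or the gene is invalid).
#' @export
dnds_table <- function(snps, cds, genome) {
  effects <- classify_substitution(snps, cds, genome)
  genes <- unique(cds$gene_id)
  rows <- lapply(genes, function(g) {
    sc <- count_sites(cds[cds$gene_id == g, , drop = FALSE], genome)
    if (!sc$valid) {
      message("gene ", g, " excluded from dN/dS: ", sc$reason)
      return(data.frame(gene_id = g, n_sites = NA_real_, s_sites = NA_real_,
                        n_changes = NA_integer_, s_changes = NA_integer_,
                        dnds = NA_real_, stringsAsFactors = FALSE))
    }
    ev <- effects[!is.na(effects$gene_id) & effects$gene_id == g, , drop = FALSE]
    nd <- sum(ev$effect == "nonsynonymous")
    sd <- sum(ev$effect == "synonymous")
    data.frame(gene_id = g, n_sites = sc$n_sites, s_sites = sc$s_sites,
               n_changes = nd, s_changes = sd,
               dnds = compute_dnds(nd, sd, sc$n_sites, sc$s_sites),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across expression categories
#'
#' Wrapper over the standard rank-based test with tie correction; used to
#' compare dN/dS distributions across ASE categories.
#'
#' @param values numeric values (e.g. per-gene dN/dS).
#' @param groups group labels, same length as `values`.
#' @return list with `H` (the chi-square approximated statistic), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- is.finite(values)
  values <- values[keep]; groups <- factor(groups[keep])
  stopifnot(length(values) >= 3L, nlevels(groups) >= 2L)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Nemenyi all-pairs post hoc test (chi-square approximation)
#'
#' After a significant Kruskal-Wallis result, compares mean ranks of all
#' group pairs. The chi-square approximation
#' `chi = (Rbar_i - Rbar_j)^2 / (N(N+1)/12 * (1/n_i + 1/n_j))`, divided by
#' the tie-correction factor and referred to `df = k - 1`, is valid for
#' unequal group sizes (ASE categories differ markedly in size).
#'
#' @param values numeric values.
#' @param groups group labels.
#' @return symmetric matrix of pairwise p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(values, groups) {
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  if (is.factor(groups) && any(table(groups) == 0L))
    stop("empty group in nemenyi_posthoc")
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("nemenyi_posthoc needs >= 2 groups")
  n_i <- table(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  p <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- rbar[i] - rbar[j]
    if (d == 0) { p[i, j] <- p[j, i] <- 1; next }
    denom <- (N * (N + 1) / 12) * (1 / n_i[i] + 1 / n_i[j])
    chi <- (d^2 / denom) / C
    p[i, j] <- p[j, i] <- stats::pchisq(chi, df = k - 1, lower.tail = FALSE)
  }
  p
}
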