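#' Read a per-replicate allele-count table
#'
#' Parses the standard allele-counter TSV dialect (columns `contig`,
#' `position`, `refAllele`, `altAllele`, `refCount`, `altCount`, `totalCount`)
#' and relabels counts as maternal/paternal according to the cross
#' orientation: the reference allele is maternal when the maternal line is the
#' reference line, paternal otherwise. Rows at positions absent from the
#' panel are dropped with a logged count.
#'
#' @param path TSV path, or a data.frame already in the counter dialect.
#' @param panel discriminant-SNP panel (`contig`, `pos` columns) or `NULL` to
#'   keep all rows.
#' @param maternal `"ref"` or `"alt"`: which allele belongs to the maternal
#'   line.
#' @param replicate_id label recorded in the `replicate_id` column.
#' @return data.frame with columns `contig`, `pos`, `replicate_id`,
#'   `maternal_count`, `paternal_count`, `other_count`, `total_depth`.
#' @export
read_allele_counts <- function(path, panel = NULL, maternal = c("ref", "alt"),
                               replicate_id = "rep1") {
  maternal <- match.arg(maternal)
  tab <- if (is.data.frame(path)) path else utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("contig", "position", "refCount", "altCount", "totalCount")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop("allele-count table missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(tab$refCount) | !is.finite(tab$altCount) |
                 !is.finite(tab$totalCount))
  if (length(bad) > 0L)
    stop("malformed allele-count row at line ", bad[1] + 1L)
  if (any(tab$refCount < 0 | tab$altCount < 0 | tab$totalCount < 0))
    stop("negative counts in allele-count table")

  out <- data.frame(
    contig = tab$contig,
    pos = as.integer(tab$position),
    replicate_id = replicate_id,
    maternal_count = if (maternal == "ref") tab$refCount else tab$altCount,
    paternal_count = if (maternal == "ref") tab$altCount else tab$refCount,
    stringsAsFactors = FALSE
  )
  out$other_count <- tab$totalCount - tab$refCount - tab$altCount
  out$total_depth <- tab$totalCount
  if (any(out$other_count < 0))
    stop("totalCount smaller than refCount + altCount")
  if (!is.null(panel)) {
    keep <- paste(out$contig, out$pos) %in% paste(panel$contig, panel$pos)
    if (any(!keep))
      message(sum(!keep), " row(s) dropped: position not in panel")
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Define a cross design
#'
#' @param maternal_line,paternal_line line identifiers.
#' @param replicate_ids character vector of biological replicate labels.
#' @param min_depth per-SNP minimum total read depth required in every
#'   replicate: 30 for hybrid crosses, 20 for intraspecific crosses (fewer
#'   discriminant SNPs warrant the lower bound).
#' @return a list of class `cross_design`.
#' @export
cross_design <- function(maternal_line, paternal_line, replicate_ids,
                         min_depth = 30) {
  stopifnot(length(replicate_ids) >= 1L, min_depth > 0)
  structure(list(maternal_line = maternal_line, paternal_line = paternal_line,
                 replicate_ids = as.character(replicate_ids),
                 min_depth = min_depth),
            class = "cross_design")
}

#' SNP-level filter cascade over replicates
#'
#' A SNP survives iff it is observed with `total_depth >= design$min_depth` in
#' every replicate of the design, and uniquely mapped parental reads
#' (maternal + paternal) make up at least `unique_frac_min` of the total depth
#' in every replicate.
#'
#' @param counts data.frame of per-SNP counts (rows from
#'   [read_allele_counts()], all replicates together).
#' @param design a [cross_design()].
#' @param unique_frac_min minimum (maternal+paternal)/total fraction.
#' @return the rows of `counts` belonging to surviving SNPs, with an
#'   `audit` attribute recording counts removed per rule.
#' @export
filter_snp_counts <- function(counts, design, unique_frac_min = 0.90) {
  stopifnot(inherits(design, "cross_design"))
  reps <- design$replicate_ids
  absent <- setdiff(reps, unique(counts$replicate_id))
  if (length(absent) > 0L)
    stop("replicate(s) in design but absent from counts: ",
         paste(absent, collapse = ", "))
  counts <- counts[counts$replicate_id %in% reps, , drop = FALSE]
  key <- paste(counts$contig, counts$pos)

  n_rep <- tapply(counts$replicate_id, key, function(x) length(unique(x)))
  present_all <- names(n_rep)[n_rep == length(reps)]

  ok_depth <- counts$total_depth >= design$min_depth
  frac <- ifelse(counts$total_depth > 0,
                 (counts$maternal_count + counts$paternal_count) / counts$total_depth, 0)
  ok_frac <- frac >= unique_frac_min

  depth_all <- tapply(ok_depth, key, all)
  frac_all <- tapply(ok_frac, key, all)

  keys <- names(depth_all)
  survive <- keys[keys %in% present_all & depth_all & frac_all]
  out <- counts[key %in% survive, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- c(
    snps_in = length(keys),
    removed_missing_replicate = sum(!(keys %in% present_all)),
    removed_depth = sum(keys %in% present_all & !depth_all),
    removed_unique_frac = sum(keys %in% present_all & depth_all & !frac_all),
    snps_out = length(survive)
  )
  out
}

#' Remove within-line polymorphic sites using a pure-line control
#'
#' SNPs where the pure maternal-line sample shows a reference (maternal)
#' allele fraction below `ref_frac_min` are removed: such sites are
#' polymorphic within the maternal line and would contaminate parental
#' assignment. SNPs absent from the pure-line table are kept and flagged
#' (`pure_line_checked = FALSE`) since only observed impurity removes a site.
#'
#' @param counts filtered SNP count rows.
#' @param pure_counts pure-line counts oriented so `maternal_count` is the
#'   reference (maternal-line) allele; multiple rows per SNP are pooled.
#' @param ref_frac_min minimum pure-line reference-allele fraction.
#' @return `counts` without impure SNPs, with a `pure_line_checked` column.
#' @export
purity_filter <- function(counts, pure_counts, ref_frac_min = 0.95) {
  if (is.null(pure_counts) || nrow(pure_counts) == 0L) {
    warning("pure-line table empty; purity filter not applied")
    counts$pure_line_checked <- rep(FALSE, nrow(counts))
    return(counts)
  }
  pkey <- paste(pure_counts$contig, pure_counts$pos)
  ref <- tapply(pure_counts$maternal_count, pkey, sum)
  tot <- tapply(pure_counts$maternal_count + pure_counts$paternal_count, pkey, sum)
  frac <- ref / tot
  impure <- names(frac)[!is.na(frac) & frac < ref_frac_min]

  key <- paste(counts$contig, counts$pos)
  out <- counts[!(key %in% impure), , drop = FALSE]
  out$pure_line_checked <- paste(out$contig, out$pos) %in% names(frac)
  n_removed <- length(unique(key[key %in% impure]))
  if (n_removed > 0L)
    message(n_removed, " SNP(s) removed by pure-line purity filter")
  rownames(out) <- NULL
  out
}

#' Assign SNPs to annotation features
#'
#' Each SNP is classified as `exonic` (inside an exon, with the gene id),
#' `intronic` (inside a gene span — min exon start to max exon end — but no
#' exon), `intergenic` (on an annotated contig, outside all genes) or `orphan`
#' (on a contig with no annotation). A SNP overlapping exons of two genes is
#' assigned to both (duplicated row) and flagged `multi_gene`.
#'
#' @param snps data.frame with `contig`, `pos` columns.
#' @param exons data.frame of exon intervals: `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive).
#' @param annotated_contigs contigs considered annotated; defaults to those
#'   appearing in `exons`.
#' @return `snps` with `feature`, `gene_id` and `multi_gene` columns; exonic
#'   SNPs in several genes appear once per gene.
#' @export
annotate_snp_features <- function(snps, exons, annotated_contigs = NULL) {
  stopifnot(all(c("contig", "pos") %in% names(snps)),
            all(c("gene_id", "contig", "start", "end") %in% names(exons)))
  if (is.null(annotated_contigs)) annotated_contigs <- unique(exons$contig)

  snp_gr <- GenomicRanges::GRanges(snps$contig, IRanges::IRanges(snps$pos, snps$pos))
  exon_gr <- GenomicRanges::GRanges(exons$contig, IRanges::IRanges(exons$start, exons$end),
                                    gene_id = exons$gene_id)
  span <- data.frame(
    gene_id = tapply(exons$gene_id, exons$gene_id, `[`, 1),
    contig = tapply(exons$contig, exons$gene_id, `[`, 1),
    start = tapply(exons$start, exons$gene_id, min),
    end = tapply(exons$end, exons$gene_id, max)
  )
  span_gr <- GenomicRanges::GRanges(span$contig, IRanges::IRanges(span$start, span$end),
                                    gene_id = span$gene_id)

  hits_exon <- GenomicRanges::findOverlaps(snp_gr, exon_gr, ignore.strand = TRUE)
  exon_map <- unique(data.frame(
    snp = S4Vectors::queryHits(hits_exon),
    gene_id = exon_gr$gene_id[S4Vectors::subjectHits(hits_exon)],
    stringsAsFactors = FALSE
  ))
  hits_span <- GenomicRanges::findOverlaps(snp_gr, span_gr, ignore.strand = TRUE)
  in_span <- unique(S4Vectors::queryHits(hits_span))

  n <- nrow(snps)
  exonic_idx <- unique(exon_map$snp)
  feature <- rep("intergenic", n)
  feature[!(snps$contig %in% annotated_contigs)] <- "orphan"
  feature[setdiff(in_span, exonic_idx)] <- "intronic"
  feature[exonic_idx] <- "exonic"

  n_genes <- table(factor(exon_map$snp, levels = seq_len(n)))
  base <- snps
  base$feature <- feature
  base$gene_id <- NA_character_
  base$multi_gene <- as.integer(n_genes) > 1L

  non_exonic <- base[feature != "exonic", , drop = FALSE]
  exonic <- base[exon_map$snp, , drop = FALSE]
  exonic$gene_id <- exon_map$gene_id
  out <- rbind(exonic, non_exonic)
  out <- out[order(match(paste(out$contig, out$pos),
                         paste(snps$contig, snps$pos))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from a GFF3/GTF file
#'
#' Thin wrapper over `rtracklayer::import` returning the exon and CDS tables
#' consumed by [annotate_snp_features()] and [count_sites()].
#'
#' @param path GFF3 or GTF file.
#' @return list with `exons` (`gene_id`, `contig`, `start`, `end`) and `cds`
#'   (`gene_id`, `contig`, `strand`, `start`, `end`, `phase`) data.frames.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_annotation requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(md)) md$gene_id else md$ID
  get_tab <- function(type) {
    sel <- md$type %in% type
    data.frame(
      gene_id = as.character(gene_id[sel]),
      contig = as.character(GenomicRanges::seqnames(gr[sel])),
      strand = as.character(GenomicRanges::strand(gr[sel])),
      start = GenomicRanges::start(gr[sel]),
      end = GenomicRanges::end(gr[sel]),
      phase = if ("phase" %in% names(md)) as.integer(as.character(md$phase[sel])) else 0L,
      stringsAsFactors = FALSE
    )
  }
  exons <- get_tab(c("exon"))
  cds <- get_tab(c("CDS"))
  if (nrow(exons) == 0L) exons <- get_tab("CDS")
  list(exons = exons[, c("gene_id", "contig", "start", "end")], cds = cds)
}
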