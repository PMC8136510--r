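#' Filter variant sites on sequencing-quality annotations
#'
#' Applies the strict quality cascade used to build discriminant-SNP panels:
#' total depth (DP), alternate observations on each strand (SAF, SAR) and
#' alternate reads to each side of the variant (RPR, RPL) must all strictly
#' exceed their thresholds, and only single-nucleotide biallelic sites are
#' retained.
#'
#' @param sites data.frame of variant sites with columns `contig`, `pos`,
#'   `ref`, `alt`, `dp`, `ao`, `saf`, `sar`, `rpr`, `rpl` (additional columns
#'   are carried through).
#' @param dp_min,saf_min,sar_min,rpr_min,rpl_min strict lower bounds; a site is
#'   kept only if the corresponding field exceeds the bound.
#' @return The subset of `sites` passing all filters, input order preserved.
#'   Sites with a missing quality field are rejected with a message, never an
#'   error.
#' @export
filter_variant_quality <- function(sites, dp_min = 10, saf_min = 2,
                                   sar_min = 2, rpr_min = 1, rpl_min = 1) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) return(sites)
  needed <- c("contig", "pos", "ref", "alt", "dp", "ao", "saf", "sar", "rpr", "rpl")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0L)
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))

  is_snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T") &
    sites$ref != sites$alt

  qual <- cbind(sites$dp, sites$saf, sites$sar, sites$rpr, sites$rpl)
  has_all <- stats::complete.cases(qual)
  if (any(!has_all))
    message(sum(!has_all), " site(s) rejected: missing quality field")

  pass <- is_snp & has_all
  pass[has_all] <- pass[has_all] &
    sites$dp[has_all] > dp_min & sites$saf[has_all] > saf_min &
    sites$sar[has_all] > sar_min & sites$rpr[has_all] > rpr_min &
    sites$rpl[has_all] > rpl_min
  pass[is.na(pass)] <- FALSE
  sites[pass, , drop = FALSE]
}

#' Select SNPs that discriminate two parental lines
#'
#' A site is discriminant when line A is homozygous for the reference allele
#' and line B is homozygous for a single alternate allele, i.e. the difference
#' is fixed between the lines. In `"interline"` mode (intraspecific isofemale
#' lines) read depth > 10 is additionally required in both lines.
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `gt_a`, `gt_b` (diploid genotypes such as `"0/0"`, `"1/1"`; `"."` or `NA`
#'   for missing) and, for interline mode, `dp_a`, `dp_b`. Quality columns
#'   `ao`/`dp`, if present, are carried through for [confidence_filter()].
#' @param mode `"interspecific"` (between species; no per-line depth rule) or
#'   `"interline"` (between conspecific lines; DP > 10 in both lines).
#' @param maternal which line is the maternal line; determines the
#'   maternal/paternal allele labels of the panel.
#' @return data.frame panel with columns `contig`, `pos`, `maternal_allele`,
#'   `paternal_allele` plus any `ao`/`dp` columns present in the input.
#' @export
select_discriminant_snps <- function(sites,
                                     mode = c("interspecific", "interline"),
                                     maternal = c("a", "b")) {
  mode <- match.arg(mode)
  maternal <- match.arg(maternal)
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      maternal_allele = character(), paternal_allele = character()))
  }
  hom <- function(gt, allele) {
    gt <- gsub("\\|", "/", as.character(gt))
    !is.na(gt) & gt == paste0(allele, "/", allele)
  }
  keep <- hom(sites$gt_a, 0L) & hom(sites$gt_b, 1L)
  if (mode == "interline") {
    if (!all(c("dp_a", "dp_b") %in% names(sites)))
      stop("interline mode requires per-line depths dp_a and dp_b")
    keep <- keep & !is.na(sites$dp_a) & !is.na(sites$dp_b) &
      sites$dp_a > 10 & sites$dp_b > 10
  }
  keep[is.na(keep)] <- FALSE
  out <- sites[keep, , drop = FALSE]
  # line A is homozygous reference, line B homozygous alternate
  allele_a <- out$ref
  allele_b <- out$alt
  panel <- data.frame(
    contig = out$contig, pos = out$pos,
    maternal_allele = if (maternal == "a") allele_a else allele_b,
    paternal_allele = if (maternal == "a") allele_b else allele_a,
    stringsAsFactors = FALSE
  )
  for (col in intersect(c("ao", "dp"), names(out))) panel[[col]] <- out[[col]]
  if (anyDuplicated(paste(panel$contig, panel$pos)))
    stop("duplicate positions in discriminant panel")
  rownames(panel) <- NULL
  panel
}

#' High-confidence filter on a discriminant-SNP panel
#'
#' Keeps only sites where the alternate allele is observed at least `ao_min`
#' times and makes up at least `ao_dp_min` of the total read depth; either
#' failing condition removes the site.
#'
#' @param panel data.frame from [select_discriminant_snps()] carrying `ao` and
#'   `dp` columns.
#' @param ao_min minimum alternate-observation count (kept iff AO >= ao_min).
#' @param ao_dp_min minimum AO/DP fraction (kept iff AO/DP >= ao_dp_min).
#' @return the filtered panel with a `passed_confidence` column set to `TRUE`.
#' @export
confidence_filter <- function(panel, ao_min = 20, ao_dp_min = 0.99) {
  stopifnot(is.data.frame(panel), all(c("ao", "dp") %in% names(panel)))
  if (nrow(panel) == 0L) {
    panel$passed_confidence <- logical(0)
    return(panel)
  }
  zero_dp <- !is.na(panel$dp) & panel$dp == 0
  if (any(zero_dp)) message(sum(zero_dp), " site(s) removed: zero depth")
  keep <- !is.na(panel$ao) & !is.na(panel$dp) & !zero_dp &
    panel$ao >= ao_min & (panel$ao / panel$dp) >= ao_dp_min
  out <- panel[keep, , drop = FALSE]
  out$passed_confidence <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Hard-mask discriminant SNPs into a pseudogenome
#'
#' Replaces the base at every panel position with `N`, removing reference-
#' allele mapping bias at discriminant sites. Sequence lengths and contig
#' count are unchanged.
#'
#' @param reference a [Biostrings::DNAStringSet] (names are contig ids).
#' @param panel data.frame with `contig` and `pos` (1-based) columns.
#' @return a `DNAStringSet` identical to `reference` except for the masked
#'   positions.
#' @export
mask_pseudogenome <- function(reference, panel) {
  stopifnot(methods::is(reference, "DNAStringSet"), is.data.frame(panel))
  if (nrow(panel) == 0L) return(reference)
  unknown <- setdiff(unique(panel$contig), names(reference))
  if (length(unknown) > 0L)
    stop("panel contig(s) absent from reference: ", paste(unknown, collapse = ", "))
  out <- reference
  for (ctg in unique(panel$contig)) {
    pos <- panel$pos[panel$contig == ctg]
    len <- Biostrings::width(out[ctg])
    bad <- pos < 1L | pos > len
    if (any(bad))
      stop("panel position beyond contig length: ", ctg, ":",
           paste(pos[bad], collapse = ","), " (length ", len, ")")
    out[[ctg]] <- Biostrings::replaceLetterAt(
      out[[ctg]], at = pos, letter = strrep("N", length(pos)))
  }
  out
}

#' Write a masked pseudogenome as FASTA (60-column lines)
#'
#' @param genome a `DNAStringSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pseudogenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 60L)
  invisible(path)
}

#' Read/write a discriminant-SNP panel as 4-column TSV
#'
#' The panel dialect is `contig`, `pos`, `maternal_allele`, `paternal_allele`,
#' tab-separated with a header.
#'
#' @param panel data.frame panel.
#' @param path file path.
#' @return `read_snp_panel` returns the panel data.frame; `write_snp_panel`
#'   returns `path` invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  cols <- c("contig", "pos", "maternal_allele", "paternal_allele")
  stopifnot(all(cols %in% names(panel)))
  utils::write.table(panel[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("contig", "pos", "maternal_allele", "paternal_allele")
  if (!all(cols %in% names(panel)))
    stop("panel file must have columns: ", paste(cols, collapse = ", "))
  panel$pos <- as.integer(panel$pos)
  panel
}

#' Read variant sites from a joint two-sample VCF
#'
#' Extracts the fields needed by [filter_variant_quality()] and
#' [select_discriminant_snps()] from a FreeBayes-style VCF with both parental
#' lines as samples. Multi-allelic records are decomposed into biallelic
#' records; indels and MNPs are dropped at parse time.
#'
#' @param path VCF path (may be gzipped).
#' @param sample_a,sample_b sample names of lines A and B; default the first
#'   two samples.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `gt_a`,
#'   `gt_b`, `dp_a`, `dp_b`, `dp`, `ao`, `saf`, `sar`, `rpr`, `rpl`.
#' @export
read_variant_vcf <- function(path, sample_a = NULL, sample_b = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variant_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(sample_a)) sample_a <- samples[1]
  if (is.null(sample_b)) sample_b <- samples[2]
  if (!all(c(sample_a, sample_b) %in% samples))
    stop("samples not found in VCF: ", sample_a, ", ", sample_b)

  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    x
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp_fmt <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))

  dp   <- suppressWarnings(as.numeric(info_num("DP")))
  ao   <- info_num("AO")
  saf  <- info_num("SAF")
  sar  <- info_num("SAR")
  rpr  <- info_num("RPR")
  rpl  <- info_num("RPL")

  # decompose multi-allelic records: per-alt INFO fields are comma separated
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  which_alt <- sequence(n_alt)
  pick <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
    vapply(seq_along(idx), function(i) {
      p <- parts[[idx[i]]]
      if (length(p) >= which_alt[i]) suppressWarnings(as.numeric(p[which_alt[i]])) else NA_real_
    }, numeric(1))
  }
  out <- data.frame(
    contig = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    gt_a = unname(gt[idx, sample_a]),
    gt_b = unname(gt[idx, sample_b]),
    dp_a = unname(dp_fmt[idx, sample_a]),
    dp_b = unname(dp_fmt[idx, sample_b]),
    dp = dp[idx],
    ao = pick(ao), saf = pick(saf), sar = pick(sar),
    rpr = pick(rpr), rpl = pick(rpl),
    stringsAsFactors = FALSE
  )
  # genotypes refer to the original allele indexing; after decomposition keep
  # only records whose genotypes are expressible with ref (0) and this alt
  out$gt_a <- remap_genotype(out$gt_a, which_alt)
  out$gt_b <- remap_genotype(out$gt_b, which_alt)
  snp <- nchar(out$ref) == 1L & nchar(out$alt) == 1L
  out[snp, , drop = FALSE]
}

# remap a genotype to the decomposed biallelic record for alt index k:
# alleles equal to k become 1, 0 stays 0, anything else -> NA (dropped later)
remap_genotype <- function(gt, k) {
  gt <- gsub("\\|", "/", gt)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(seq_along(parts), function(i) {
    p <- suppressWarnings(as.integer(parts[[i]]))
    if (length(p) != 2L || anyNA(p)) return(NA_character_)
    p2 <- ifelse(p == 0L, 0L, ifelse(p == k[i], 1L, NA_integer_))
    if (anyNA(p2)) return(NA_character_)
    paste(p2, collapse = "/")
  }, character(1))
}
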