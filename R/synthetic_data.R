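#' Configuration for a simulated reciprocal cross
#'
#' Defines the study conditions a simulated experiment emulates: a mixture of
#' true ASE categories, a fraction of genes whose bias follows the parental
#' *line* rather than the parental sex, multiple SNPs per gene, and
#' overdispersed (beta-binomial) per-replicate allele counts.
#'
#' Defaults mirror the intraspecific reciprocal-cross setting downscaled:
#' 2,000 genes, ~7 SNPs per gene, 3 biological replicates per direction,
#' mean per-SNP depth 500 with mild overdispersion (rho = 0.01), a category
#' mixture dominated by maternally biased and completely maternal genes, and
#' 7% line-of-origin genes.
#'
#' @param n_genes number of genes.
#' @param category_proportions named fractions over `M`, `MB`, `B`, `PB`, `P`
#'   summing to 1.
#' @param line_effect_fraction fraction of genes with line-of-origin (not
#'   parent-of-origin) bias.
#' @param snps_per_gene_mean mean of the (zero-truncated Poisson) SNPs-per-
#'   gene distribution.
#' @param depth_mean,depth_dispersion mean and negative-binomial size of the
#'   per-SNP total depth.
#' @param overdispersion_rho beta-binomial intra-class correlation in
#'   \[0, 1); 0 gives plain binomial sampling.
#' @param replicates_per_direction biological replicates per cross direction.
#' @param seed integer seed governing the whole scenario.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       category_proportions = c(M = 0.17, MB = 0.72, B = 0.07,
                                                PB = 0.02, P = 0.02),
                       line_effect_fraction = 0.07,
                       snps_per_gene_mean = 7,
                       depth_mean = 500, depth_dispersion = 10,
                       overdispersion_rho = 0.01,
                       replicates_per_direction = 3,
                       seed = 42) {
  stopifnot(n_genes >= 1, replicates_per_direction >= 1,
            overdispersion_rho >= 0, overdispersion_rho < 1,
            line_effect_fraction >= 0, line_effect_fraction <= 1)
  cats <- c("M", "MB", "B", "PB", "P")
  if (!setequal(names(category_proportions), cats))
    stop("category_proportions must be named M, MB, B, PB, P")
  if (abs(sum(category_proportions) - 1) > 1e-9)
    stop("category_proportions must sum to 1")
  structure(list(
    n_genes = as.integer(n_genes),
    category_proportions = category_proportions[cats],
    line_effect_fraction = line_effect_fraction,
    snps_per_gene_mean = snps_per_gene_mean,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    overdispersion_rho = overdispersion_rho,
    replicates_per_direction = as.integer(replicates_per_direction),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# closed p_m intervals from which true maternal fractions are drawn;
# boundaries match the classifier thresholds
.category_intervals <- list(
  M = c(0.95, 1), MB = c(0.65, 0.95), B = c(0.35, 0.65),
  PB = c(0.05, 0.35), P = c(0, 0.05)
)

#' Draw the per-gene ground truth of a simulated scenario
#'
#' Assigns each gene a true ASE category from the configured mixture, a true
#' maternal fraction `theta` drawn uniformly within that category's `p_m`
#' interval, an effect type (`parent_of_origin` or `line_of_origin`), a SNP
#' count and a mean TPM. Shared between the two directions of a reciprocal
#' design so that line-of-origin genes flip while parent-of-origin genes do
#' not.
#'
#' @param config a [sim_config()]. The configured seed is set here.
#' @return data.frame with `gene_id`, `contig`, `theta`, `effect_type`,
#'   `true_category`, `n_snps`, `tpm`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cats <- sample(names(config$category_proportions), n, replace = TRUE,
                 prob = config$category_proportions)
  theta <- vapply(cats, function(cc) {
    iv <- .category_intervals[[cc]]
    stats::runif(1, iv[1], iv[2])
  }, numeric(1))
  effect <- ifelse(stats::runif(n) < config$line_effect_fraction,
                   "line_of_origin", "parent_of_origin")
  n_snps <- pmax(1L, stats::rpois(n, config$snps_per_gene_mean))
  tpm <- stats::rlnorm(n, meanlog = log(50), sdlog = 1.5)
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    contig = sprintf("ctg%04d", seq_len(n)),
    theta = unname(theta),
    effect_type = effect,
    true_category = cats,
    n_snps = n_snps,
    tpm = tpm,
    stringsAsFactors = FALSE
  )
}

# beta-binomial sampler: rho = 0 degenerates to binomial; theta 0/1 are exact
rbetabinom <- function(n, size, theta, rho) {
  if (rho == 0) return(stats::rbinom(n, size, theta))
  out <- integer(n)
  deg0 <- theta <= 0; deg1 <- theta >= 1
  mid <- !deg0 & !deg1
  out[deg1] <- size[deg1]
  if (any(mid)) {
    a <- theta[mid] * (1 - rho) / rho
    b <- (1 - theta[mid]) * (1 - rho) / rho
    p <- stats::rbeta(sum(mid), a, b)
    out[mid] <- stats::rbinom(sum(mid), size[mid], p)
  }
  out
}

#' Simulate per-SNP allele counts for one cross direction
#'
#' For each gene, SNP and replicate, draws a total depth from a negative
#' binomial and a maternal count from a beta-binomial at the gene's true
#' maternal fraction. For `line_of_origin` genes the biased allele follows
#' the *line*, so the maternal fraction flips to `1 - theta` in direction 2;
#' `parent_of_origin` genes keep `theta` in both directions. Deterministic
#' given the config seed and direction.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()] (generated from `config` if
#'   omitted, so a reciprocal pair should pass the same `truth`).
#' @param direction 1 or 2 (which line is the mother).
#' @return data.frame of SNP counts: `contig`, `pos`, `gene_id`,
#'   `replicate_id`, `maternal_count`, `paternal_count`, `other_count`,
#'   `total_depth`.
#' @export
simulate_cross <- function(config, truth = simulate_truth(config), direction = 1) {
  stopifnot(inherits(config, "sim_config"), direction %in% c(1, 2))
  set.seed(config$seed + direction)
  reps <- paste0("d", direction, "_rep", seq_len(config$replicates_per_direction))

  theta <- ifelse(truth$effect_type == "line_of_origin" & direction == 2,
                  1 - truth$theta, truth$theta)
  gene_idx <- rep(seq_len(nrow(truth)), truth$n_snps)
  snp_pos <- unlist(lapply(truth$n_snps, function(k) seq(100, by = 100, length.out = k)))

  per_rep <- lapply(reps, function(r) {
    depth <- stats::rnbinom(length(gene_idx), mu = config$depth_mean,
                            size = config$depth_dispersion)
    depth <- pmax(depth, 1L)
    m <- rbetabinom(length(gene_idx), depth, theta[gene_idx],
                    config$overdispersion_rho)
    data.frame(
      contig = truth$contig[gene_idx],
      pos = snp_pos,
      gene_id = truth$gene_id[gene_idx],
      replicate_id = r,
      maternal_count = m,
      paternal_count = depth - m,
      other_count = 0L,
      total_depth = depth,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_rep)
  rownames(out) <- NULL
  out
}

#' Simulate a full reciprocal design
#'
#' Convenience wrapper drawing one ground truth and both cross directions
#' from it, plus the per-gene TPM table consumed by the gene filter.
#'
#' @param config a [sim_config()].
#' @return list with `truth`, `dir1`, `dir2` (SNP count tables) and `tpm`
#'   (`gene_id`, `tpm`).
#' @export
simulate_reciprocal <- function(config) {
  truth <- simulate_truth(config)
  list(
    truth = truth,
    dir1 = simulate_cross(config, truth, direction = 1),
    dir2 = simulate_cross(config, truth, direction = 2),
    tpm = truth[, c("gene_id", "tpm")]
  )
}

#' Simulate a toy genome with planted coding variants
#'
#' Builds random protein-coding genes (start codon, random non-stop codons,
#' terminal stop) on both strands, optionally split by a short intron, and
#' plants single-nucleotide variants in coding sequence. The synonymous or
#' nonsynonymous status of each variant is recorded at construction time by
#' mutating the known codon directly — independently of the pipeline's own
#' substitution classifier — so the codon-degeneracy machinery can be
#' validated end to end. The emitted genome, gene models and variant panel
#' are mutually consistent.
#'
#' @param n_genes number of genes.
#' @param codons_per_gene coding codons per gene (excluding start/stop).
#' @param n_variants planted variants across all genes.
#' @param seed integer seed.
#' @param intron_every every k-th gene gets a 30-bp intron splitting its CDS
#'   (0 = no introns).
#' @return list with `genome` (`DNAStringSet`), `cds` (interval table),
#'   `variants` (`contig`, `pos`, `ref`, `alt`, `gene_id`, `truth_effect`).
#' @export
simulate_toy_genome <- function(n_genes = 10, codons_per_gene = 50,
                                n_variants = 30, seed = 1, intron_every = 2) {
  set.seed(seed)
  stop_codons <- c("TAA", "TAG", "TGA")
  all_codons <- names(Biostrings::GENETIC_CODE)
  coding_codons <- setdiff(all_codons, stop_codons)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  seqs <- character(n_genes)
  cds_rows <- list()
  tx_maps <- list()  # per gene: coding sequence + genomic position of each coding base
  flank <- 50L
  for (i in seq_len(n_genes)) {
    body <- paste(sample(coding_codons, codons_per_gene, replace = TRUE),
                  collapse = "")
    cds_seq <- paste0("ATG", body, "TAA")
    L <- nchar(cds_seq)
    strand <- if (i %% 2 == 0) "-" else "+"
    cds_tx <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    } else cds_seq
    has_intron <- intron_every > 0 && i %% intron_every == 0
    left <- paste(sample(.bases, flank, replace = TRUE), collapse = "")
    right <- paste(sample(.bases, flank, replace = TRUE), collapse = "")
    ctg <- sprintf("toyctg%02d", i)
    gid <- sprintf("toygene%02d", i)
    if (has_intron) {
      cut <- 3 * (codons_per_gene %/% 2)  # genomic split at a codon boundary
      intron <- paste(sample(.bases, 30, replace = TRUE), collapse = "")
      part1 <- substr(cds_tx, 1, cut)
      part2 <- substr(cds_tx, cut + 1, L)
      seqs[i] <- paste0(left, part1, intron, part2, right)
      s1 <- flank + 1L; e1 <- flank + cut
      s2 <- e1 + 31L; e2 <- s2 + nchar(part2) - 1L
      cds_rows[[i]] <- data.frame(gene_id = gid, contig = ctg, strand = strand,
                                  start = c(s1, s2), end = c(e1, e2),
                                  phase = 0L, stringsAsFactors = FALSE)
      genomic <- c(seq(s1, e1), seq(s2, e2))  # ascending genomic coords of coding bases
    } else {
      seqs[i] <- paste0(left, cds_tx, right)
      cds_rows[[i]] <- data.frame(gene_id = gid, contig = ctg, strand = strand,
                                  start = flank + 1L, end = flank + L,
                                  phase = 0L, stringsAsFactors = FALSE)
      genomic <- seq(flank + 1L, flank + L)
    }
    # coding index c (1..L along cds_seq) -> genomic position
    tx_maps[[gid]] <- list(
      cds_seq = cds_seq, strand = strand, contig = ctg,
      pos_of = if (strand == "-") rev(genomic) else genomic
    )
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, sprintf("toyctg%02d", seq_len(n_genes))))
  cds <- do.call(rbind, cds_rows)

  # plant variants at random distinct coding indices, deriving truth by
  # mutating the constructed codon string directly
  slots <- do.call(rbind, lapply(names(tx_maps), function(gid)
    data.frame(gene_id = gid, cds_idx = seq_len(nchar(tx_maps[[gid]]$cds_seq)),
               stringsAsFactors = FALSE)))
  if (n_variants > nrow(slots))
    stop("cannot place ", n_variants, " variants in ", nrow(slots),
         " coding positions")
  picked <- slots[sample.int(nrow(slots), n_variants), , drop = FALSE]
  variants <- do.call(rbind, lapply(seq_len(nrow(picked)), function(j) {
    gid <- picked$gene_id[j]; cidx <- picked$cds_idx[j]
    mp <- tx_maps[[gid]]
    pos <- mp$pos_of[cidx]
    coding_ref <- substr(mp$cds_seq, cidx, cidx)
    coding_alt <- sample(setdiff(.bases, coding_ref), 1)
    codon_start <- ((cidx - 1L) %/% 3L) * 3L + 1L
    codon <- substr(mp$cds_seq, codon_start, codon_start + 2L)
    mut <- codon
    substr(mut, cidx - codon_start + 1L, cidx - codon_start + 1L) <- coding_alt
    effect <- if (identical(Biostrings::GENETIC_CODE[[codon]],
                            Biostrings::GENETIC_CODE[[mut]]))
      "synonymous" else "nonsynonymous"
    ref <- if (mp$strand == "-") comp[[coding_ref]] else coding_ref
    alt <- if (mp$strand == "-") comp[[coding_alt]] else coding_alt
    data.frame(contig = mp$contig, pos = pos, ref = ref, alt = alt,
               gene_id = gid, truth_effect = effect, stringsAsFactors = FALSE)
  }))
  variants <- variants[order(variants$contig, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(genome = genome, cds = cds, variants = variants)
}

#' Simulate male/female expression tables
#'
#' Draws genes from three components: male-specific (female TPM 0),
#' female-specific (male TPM 0) and shared (both sexes drawn independently
#' from the same lognormal, giving mean SPM 0.5 by symmetry). Emulates the
#' extreme bimodal distribution of sex-biased expression seen in highly
#' dimorphic insects.
#'
#' @param n_genes number of genes.
#' @param weights named mixture weights over `male`, `female`, `shared`,
#'   summing to 1.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `male_tpm`, `female_tpm`, `component`.
#' @export
simulate_sex_expression <- function(n_genes = 2000,
                                    weights = c(male = 0.4, female = 0.4,
                                                shared = 0.2),
                                    seed = 1) {
  if (!setequal(names(weights), c("male", "female", "shared")))
    stop("weights must be named male, female, shared")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  set.seed(seed)
  comp <- sample(names(weights), n_genes, replace = TRUE, prob = weights)
  expr <- function(n) stats::rlnorm(n, meanlog = log(30), sdlog = 1)
  male <- ifelse(comp == "female", 0, expr(n_genes))
  female <- ifelse(comp == "male", 0, expr(n_genes))
  data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    male_tpm = male, female_tpm = female, component = comp,
    stringsAsFactors = FALSE
  )
}
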