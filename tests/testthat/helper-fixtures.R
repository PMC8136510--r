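# In-code fixtures shared across test files.

# a variant-site row with passing defaults; override any field
make_site <- function(contig = "ctg1", pos = 100L, ref = "A", alt = "G",
                      gt_a = "0/0", gt_b = "1/1", dp_a = 15, dp_b = 15,
                      dp = 15, ao = 25, saf = 5, sar = 5, rpr = 3, rpl = 3) {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             gt_a = gt_a, gt_b = gt_b, dp_a = dp_a, dp_b = dp_b,
             dp = dp, ao = ao, saf = saf, sar = sar, rpr = rpr, rpl = rpl,
             stringsAsFactors = FALSE)
}

make_sites <- function(...) do.call(rbind, list(...))

# SNP-count rows in the shape read_allele_counts() produces
make_count <- function(contig = "ctg1", pos = 100L, replicate_id = "rep1",
                       maternal = 50, paternal = 50, other = 0) {
  data.frame(contig = contig, pos = pos, replicate_id = replicate_id,
             maternal_count = maternal, paternal_count = paternal,
             other_count = other, total_depth = maternal + paternal + other,
             stringsAsFactors = FALSE)
}

# gene-level SNP counts: one gene, k replicates with given maternal/paternal
gene_counts <- function(gene_id, m, p, n_snps = 2) {
  do.call(rbind, lapply(seq_along(m), function(i) {
    data.frame(gene_id = gene_id, replicate_id = paste0("rep", i),
               maternal_count = rep(m[i] / n_snps, n_snps),
               paternal_count = rep(p[i] / n_snps, n_snps),
               stringsAsFactors = FALSE)
  }))
}

# classifier p_m intervals, used to check theta-inside-category conditions
category_interval <- function(category) {
  switch(category,
         M = c(0.95, 1), MB = c(0.65, 0.95), B = c(0.35, 0.65),
         PB = c(0.05, 0.35), P = c(0, 0.05))
}

theta_inside <- function(theta, category, margin = 0.02) {
  iv <- category_interval(category)
  theta >= iv[1] + margin & theta <= iv[2] - margin
}

# independent enumeration oracle for the two-sided exact binomial p at 0.5:
# sum the probabilities of all outcomes no more likely than the observed one
enumerate_binom_p <- function(m, n, p0 = 0.5) {
  mass <- dbinom(0:n, n, p0)
  sum(mass[mass <= mass[m + 1] * (1 + 1e-12)])
}
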