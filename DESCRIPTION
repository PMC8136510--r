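Package: poeASE
Title: Parent-of-Origin Allele-Specific Expression Analysis for Paternal Genome Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying parent-of-origin allele-specific
    expression (ASE) in species with paternal genome elimination, such as
    mealybugs. Builds panels of SNPs that discriminate two parental genomes
    and hard-masks them into a pseudogenome; ingests per-replicate allele
    count tables and applies depth, uniqueness and pure-line purity filters;
    pools exonic SNP counts per gene and classifies genes into maternal,
    maternally biased, biparental, paternally biased and paternal categories
    using exact binomial tests with Bonferroni correction and G-test
    replicate-homogeneity validation; separates true parent-of-origin effects
    from line-of-origin effects using reciprocal crosses; models
    sex-specificity (SPM) against maternal bias; and compares dN/dS across
    expression categories via codon-degeneracy site counting with
    Kruskal-Wallis and Nemenyi tests. Includes a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    seqinr
Config/testthat/edition: 3
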