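---
title: "Methods: quantifying parent-of-origin allele-specific expression under paternal genome elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying parent-of-origin allele-specific expression under paternal genome elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poeASE)
```

## The biological problem

Under paternal genome elimination (PGE) — the reproductive system of
mealybugs and several other arthropod clades — males are diploid but
transmit only maternally inherited chromosomes; the paternal haploid set is
excluded from sperm and, in mealybugs, heterochromatinized early in
development. Whether that paternal set is transcriptionally inert is a
question about genome-wide genomic imprinting, and it can be answered by
allele-specific expression (ASE): if reads at sites that distinguish the two
parental haplotypes come overwhelmingly from the maternal allele, the
paternal genome is silenced; any paternal contribution marks genes that
escape silencing.

poeASE implements the full analysis: building a panel of discriminant SNPs
between parental lines, removing reference-mapping bias, filtering
allele-count tables, classifying genes by their maternal expression fraction,
using reciprocal crosses to separate parent-of-origin from line-of-origin
effects, and relating the resulting categories to sex-specificity and rates
of protein evolution.

## Discriminant SNPs and the pseudogenome

A *discriminant SNP* is a site fixed for different alleles in the two
parental lines, so every RNA-seq read covering it can be assigned a parent
of origin. Panels are built from variant calls by requiring line A to be
homozygous reference and line B homozygous for one alternate allele
(`select_discriminant_snps()`). Two filter layers precede this:

* **Call quality** (`filter_variant_quality()`): depth DP > 10, alternate
  observations on both strands SAF > 2 and SAR > 2, and alternate reads on
  both sides of the site RPR > 1 and RPL > 1, all strict. Only biallelic
  single-nucleotide records survive; multi-allelic records are decomposed
  first and indels/MNPs dropped at parse time.
* **Confidence** (`confidence_filter()`): a site is kept only if AO ≥ 20
  *and* AO/DP ≥ 0.99. Either failing condition removes it — the goal is a
  small, near-certain panel rather than a complete one, because every false
  discriminant site injects systematic noise into all downstream counts.

For conspecific isofemale lines (`mode = "interline"`) a per-line depth
> 10 is additionally required, since line-level coverage replaces the
species-level evidence.

Reads are then mapped not to the reference but to a *pseudogenome*
(`mask_pseudogenome()`): the reference with every panel position hard-masked
to `N`. Without masking, reads carrying the alternate allele mismatch the
reference and map at lower rates, inflating the apparent reference
(maternal) fraction. Masking makes both alleles equally penalized at
discriminant sites. Masking never changes sequence lengths or contig
counts, and output FASTA is wrapped at 60 columns.

## SNP-level filtering of allele counts

Allele-count tables (one per biological replicate, in the standard
counter dialect: `contig, position, refAllele, altAllele, refCount,
altCount, totalCount`) are relabelled maternal/paternal by cross
orientation (`read_allele_counts()`) and then filtered
(`filter_snp_counts()`):

* present with total depth ≥ `min_depth` in **every** replicate — default
  30× for hybrid crosses, 20× for intraspecific crosses, where far fewer
  discriminant SNPs are available and the stricter bound would discard most
  of the signal;
* uniquely mapped parental reads (maternal + paternal) ≥ 90% of total depth
  in every replicate — sites where many reads carry neither parental allele
  indicate mapping or paralogy artefacts.

The depth rule applies to the *total* depth at the site, so the 90% rule
retains independent effect. A third, optional filter (`purity_filter()`)
uses a pure maternal-line sample: any site where that sample shows < 95%
reference (maternal-line) alleles is an undetected within-line polymorphism
and is removed. Sites absent from the pure-line control are retained but
flagged (`pure_line_checked = FALSE`): the rule removes observed impurity,
not missing evidence — dropping unobserved sites would discard most of the
panel whenever the control library is shallower than the cross libraries.

SNPs are then assigned to annotation features (`annotate_snp_features()`):
exonic (inside an exon, with its gene id), intronic (inside the gene span,
defined as min exon start to max exon end, but not in an exon), intergenic,
or orphan (on a contig with no annotation). Only exonic SNPs feed the gene
classifier. A SNP inside exons of two overlapping genes is assigned to both
and flagged `multi_gene` — the choice is deliberately conservative in the
opposite direction from dropping: downstream users can exclude flagged
SNPs, but silently dropped signal cannot be recovered.

## Gene-level classification

`classify_gene_ase()` pools maternal and paternal counts over all exonic
SNPs of a gene, per replicate, and estimates the maternal expression
fraction

$$p_m = \frac{\text{maternal reads}}{\text{maternal} + \text{paternal reads}}.$$

**Inclusion.** A gene enters the analysis if covered by ≥ 2 SNPs in every
replicate, or by a single SNP whose pooled (across replicates) parental
depth is ≥ 100; and if its mean TPM across replicates is ≥ 1. The
single-SNP rescue is inclusive (≥ 100) on pooled counts.

**Testing.** Each replicate gets a two-sided exact binomial test of
$p_m = 0.5$ (Mendelian expression). The two-sided p-value is computed by
tail doubling, $\min(1,\, 2\min(P(X \le m), P(X \ge m)))$, which at the
symmetric null equals minimum-likelihood summation. Bonferroni correction
uses the number of included genes as family size at α = 0.05.

**Categories.** With `rejected` the Bonferroni-corrected test outcome:

| category | rule |
|---|---|
| B (biparental) | not rejected, **or** 0.35 ≤ p_m ≤ 0.65 |
| M (maternal) | rejected and p_m ≥ 0.95 |
| MB (maternally biased) | rejected and 0.65 < p_m < 0.95 |
| PB (paternally biased) | rejected and 0.05 < p_m < 0.35 |
| P (paternal) | rejected and p_m ≤ 0.05 |

The B rule is evaluated first, so an unrejected gene is B regardless of
p_m; the central interval is closed at both ends and M/P are closed at
0.95/0.05, making the categories exhaustive over [0, 1]. Where different
readings of the interval notation were possible we chose the one that makes
the partition total and matches the "and/or" phrasing of the rule.

**Validation.** A 2×k G-test of homogeneity (allele × replicate,
`replicate_homogeneity()`) guards against genes whose bias is an artefact
of one replicate. $G = 2\sum O \ln(O/E)$ with df = k − 1; no Williams or
Yates correction is applied anywhere in the package. Genes that are not
significantly heterogeneous (Bonferroni-corrected p ≥ α) are validated
immediately; heterogeneous genes are kept only when every replicate agrees
on both category and rejection status. Validated genes receive a final
pooled p_m (counts pooled, then divided — count-weighted, not a mean of
fractions) and a final exact binomial test that determines the reported
category. A gene whose one allele is absent from every replicate is
perfectly homogeneous (G = 0) by construction.

## Reciprocal crosses: parent of origin vs line of origin

A maternal bias observed in a single cross cannot distinguish imprinting
from line-specific expression (e.g. a cis-regulatory difference between the
parental lines). The reciprocal design resolves this: a true
parent-of-origin gene is maternally biased in **both** directions, while a
line-of-origin gene flips its bias when the lines swap roles.

`pair_reciprocal()` keeps genes validated in both directions.
`classify_poe()` computes the reciprocal mean $\bar p_m = (p_m^{(1)} +
p_m^{(2)})/2$ and flags a gene `no_poe_bias` only when *both* hold:

1. the two directions assign different ASE categories, and
2. the reciprocal difference $|p_m^{(1)} - p_m^{(2)}|$ exceeds $D$, the mean
   absolute reciprocal difference over all validated paired genes of that
   cross pair, computed before any flagging.

The conjunction matters: replicate noise alone can push a gene across a
category boundary, and a large but category-consistent shift can reflect
depth imbalance; requiring both keeps either alone from triggering the
flag. Unflagged genes are classified on $\bar p_m$ with rejection from a
binomial test on counts pooled over both directions.

`combine_cross_pairs()` merges several reciprocal pairs: the union of
genes, an unweighted mean of per-pair $\bar p_m$ for genes seen more than
once, and `no_poe_bias` propagating from any pair. Propagation is the
conservative choice for a conflict the single-pair logic cannot arbitrate:
a gene that any pair shows to follow the line is not safely imprinted.

## Sex-specificity and expression-level models

`compute_spm()` maps male/female expression to [0, 1] (0 = fully male, 1 =
fully female). The default is the squared form $f^2/(m^2+f^2)$ — the
standard specificity metric, which spreads intermediate values away from
0.5 — with the simple proportion $f/(m+f)$ available by flag; both satisfy
the endpoint conventions, and the choice only reshapes the scale between
the endpoints.

Two regressions relate maternal bias to expression:

* `fit_log_tpm_model()`: ordinary least squares of log-TPM (natural log;
  TPM = 0 genes excluded rather than offset, since an arbitrary offset
  would manufacture curvature at the low end) on $p_m + p_m^2$.
* `fit_spm_glm()`: quasibinomial GLM (logit link, variance
  $\phi\,\mu(1-\mu)$) of SPM on $p_m + p_m^2$, with sequential (type-I)
  per-term F tests from the analysis of deviance scaled by the estimated
  dispersion — the term order ($p_m$, then $p_m^2$) is part of the model
  definition. An optional TPM filter refits on well-expressed genes to
  check that curvature is not driven by background expression.

## Rates of molecular evolution

`annotate_degeneracy()` gives, for each codon position, the fraction of the
three possible single-nucleotide changes that preserve the amino acid
(standard nuclear code; changes creating a stop count as nonsynonymous).
Summing over all non-stop codons of a gene's spliced CDS yields synonymous
site counts $S$, with nonsynonymous sites $N = 3 \times \text{codons} - S$
(`count_sites()`); the terminal stop is excluded and an internal stop flags
the gene out of the analysis. Equal mutation weights are used — no
transition/transversion weighting — which keeps the site definition exactly
dual to the change counting. One transcript per gene is assumed; callers
with multi-isoform annotations should supply their chosen (e.g. longest)
CDS per gene.

`classify_substitution()` types each panel SNP falling in a CDS as
synonymous or nonsynonymous by substituting the alternate base into its
codon (reverse-complementing for minus-strand genes), and

$$dN/dS = \frac{N_d / N}{S_d / S}$$

is left undefined — not padded — when $S_d = 0$ or any site count is zero;
such genes are excluded from comparisons (a pseudo-count would be a plotting
convenience, not a rate).

Rates are compared across ASE categories with the Kruskal–Wallis rank test
(tie-corrected, delegated to the standard implementation) and an all-pairs
Nemenyi post hoc test using the chi-square approximation, which is valid
for the unequal group sizes that ASE categories always have. The Nemenyi
statistic for groups $i, j$ is
$(\bar R_i - \bar R_j)^2 / \left[\tfrac{N(N+1)}{12}(1/n_i + 1/n_j)\right]$,
divided by the tie-correction factor and referred to $\chi^2_{k-1}$.

## The synthetic-data generator

Because the pipeline's ground truth cannot be known for real sequencing
data, `simulate_reciprocal()` generates complete inputs with known truth:

* per-gene true maternal fractions θ drawn uniformly within the p_m
  interval of a category sampled from a configurable mixture — the default
  (M 0.17, MB 0.72, B 0.07, PB 0.02, P 0.02) mirrors the maternally
  dominated landscape of PGE males, where most genes are maternally biased,
  a minority fully maternal, and predominantly paternal genes are rare;
* a configurable fraction of *line-of-origin* genes (default 0.07, matching
  the 6–8% of reciprocally inconsistent genes a PGE experiment typically
  shows) whose maternal fraction flips to 1 − θ in the second cross
  direction;
* ~7 SNPs per gene (zero-truncated Poisson), 3 replicates per direction,
  per-SNP depths from a negative binomial with mean 500, and maternal
  counts from a beta-binomial with intra-class correlation ρ = 0.01 —
  real ASE counts are overdispersed relative to binomial, and a classifier
  whose validation logic only works at ρ = 0 would be fragile;
* per-gene TPM from a lognormal (median 50), so the TPM ≥ 1 filter removes
  a realistic sliver of genes.

One seed (default 42) governs an entire scenario; the same truth table
drives both directions, which is what makes the reciprocal logic testable.

What the generator does **not** emulate: mapping bias (counts are generated
downstream of alignment), correlated SNPs within a gene beyond the shared
θ, contamination between samples, technical replicates (assumed merged
upstream), and hybrid-incompatibility mortality. Passing the recovery tests
therefore shows the statistical machinery is correct under the stated noise
model — not that a real experiment's upstream artefacts are handled.

`simulate_toy_genome()` builds random coding genes on both strands (half
split by a short intron) and plants variants whose synonymous status is
recorded at construction time by mutating the known codon directly — an
oracle independent of the classifier under test. `simulate_sex_expression()`
draws genes from male-specific, female-specific and shared components to
reproduce the extreme bimodal sex-specificity of dimorphic insects.

## Numerical choices and degenerate inputs

* Binomial p-values by tail doubling, capped at 1; `total = 0` is a hard
  error rather than a silent NA.
* G-tests: $0 \ln 0 = 0$; rows/columns with zero marginals are dropped with
  a message and df adjusted; tables smaller than 2×2 after dropping are an
  error.
* Homogeneity with one allele entirely absent: G = 0 (identical
  proportions), not an error.
* `classify_ase` is total on [0, 1]; boundary values are assigned by the
  closure rules above.
* Scaffold-to-chromosome assignment: unique argmax of alignment counts;
  ties and all-zero rows stay unassigned.
* All simulations take explicit integer seeds; the pipeline itself is
  deterministic given its inputs.

## Problem sizes used by the test suite

The recovery checks run one reciprocal scenario of 2,000 genes at depth
mean 500, ρ = 0.01, 3 replicates per direction (~84,000 SNP-replicate
rows per direction), chosen to match the generator's default scale; the
rank-test calibration uses 2,000 simulated data sets of three groups of 15.
These sizes give binomial standard errors comfortably below the tolerances
being asserted while keeping a full run of the suite under a minute.

## Known limitations

* dN/dS uses raw per-site proportions without multiple-hit correction, so
  it is a divergence-scale contrast between gene classes, not a
  substitution-model estimate.
* The Bonferroni family is the gene count of the data set under test;
  joint analyses across tissues should be corrected by the caller.
* Genes overlapping on opposite strands share their exonic SNPs (flagged);
  there is no read-level disambiguation.
* The purity filter requires the pure-line sample to be oriented to the
  maternal line; no automatic orientation check is performed.
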