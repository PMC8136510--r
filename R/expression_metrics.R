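#' Sex-specificity metric (SPM)
#'
#' Maps a gene's male and female expression to \[0, 1\]: 0 means 100% of
#' expression in males, 0.5 unbiased expression, 1 means 100% in females.
#' The default `"squared"` method is the standard specificity metric
#' `f^2 / (m^2 + f^2)`; `"proportion"` gives the simple share `f / (m + f)`.
#' Both satisfy the endpoint conventions. Genes with zero expression in both
#' sexes are undefined and return `NA` (callers should exclude them).
#'
#' @param male_tpm,female_tpm non-negative expression values (vectorized).
#' @param method `"squared"` or `"proportion"`.
#' @return numeric vector of SPM values in \[0, 1\] (`NA` where undefined).
#' @export
compute_spm <- function(male_tpm, female_tpm, method = c("squared", "proportion")) {
  method <- match.arg(method)
  stopifnot(all(male_tpm >= 0, na.rm = TRUE), all(female_tpm >= 0, na.rm = TRUE))
  both_zero <- male_tpm == 0 & female_tpm == 0
  if (any(both_zero, na.rm = TRUE))
    message(sum(both_zero, na.rm = TRUE),
            " gene(s) with zero expression in both sexes: SPM undefined")
  out <- if (method == "squared") {
    female_tpm^2 / (male_tpm^2 + female_tpm^2)
  } else {
    female_tpm / (male_tpm + female_tpm)
  }
  out[both_zero] <- NA_real_
  out
}

#' Linear model of expression level on maternal bias
#'
#' Ordinary least squares of `log(TPM)` (natural logarithm) on the maternal
#' fraction `p_m` and its square, testing whether expression level varies
#' with (and curves in) the degree of maternal bias. Genes with TPM = 0 are
#' excluded.
#'
#' @param tpm per-gene expression values (> 0 for inclusion).
#' @param p_m per-gene maternal fractions.
#' @return list with `coefficients` (intercept, p_m, p_m^2), `r2_adjusted`,
#'   `f_statistic` (overall F, df_num, df_den, p) and the underlying `fit`.
#' @export
fit_log_tpm_model <- function(tpm, p_m) {
  stopifnot(length(tpm) == length(p_m))
  keep <- is.finite(tpm) & tpm > 0 & is.finite(p_m)
  if (sum(!keep) > 0L)
    message(sum(!keep), " gene(s) excluded from TPM model (zero/missing values)")
  tpm <- tpm[keep]; p_m <- p_m[keep]
  if (length(tpm) < 4L) stop("fit_log_tpm_model needs >= 4 genes")
  if (length(unique(p_m)) < 3L)
    stop("collinear design: p_m has fewer than 3 distinct values")
  fit <- stats::lm(log(tpm) ~ p_m + I(p_m^2))
  s <- summary(fit)
  fs <- s$fstatistic
  list(
    coefficients = stats::setNames(stats::coef(fit),
                                   c("intercept", "p_m", "p_m2")),
    r2_adjusted = s$adj.r.squared,
    f_statistic = list(F = unname(fs[1]), df_num = unname(fs[2]),
                       df_den = unname(fs[3]),
                       p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    fit = fit
  )
}

#' Quasibinomial GLM of sex-specificity on maternal bias
#'
#' Fits `SPM ~ p_m + p_m^2` with a logit link and quasibinomial variance
#' `phi * mu * (1 - mu)` via iteratively reweighted least squares, and
#' reports sequential (type-I) per-term F tests from the analysis of
#' deviance scaled by the estimated dispersion. An optional TPM filter
#' removes low-expressed genes before fitting, to guard against background
#' expression driving the curvature.
#'
#' @param spm per-gene SPM values in \[0, 1\].
#' @param p_m per-gene maternal fractions.
#' @param tpm optional per-gene expression used only for filtering.
#' @param min_tpm genes with `tpm < min_tpm` are excluded (0 = no filter).
#' @return list with `coefficients`, `dispersion`, `f_tests` (data.frame:
#'   term, F, df, p), `n` and the underlying `fit`.
#' @export
fit_spm_glm <- function(spm, p_m, tpm = NULL, min_tpm = 0) {
  stopifnot(length(spm) == length(p_m))
  keep <- is.finite(spm) & is.finite(p_m) & spm >= 0 & spm <= 1
  if (!is.null(tpm) && min_tpm > 0) keep <- keep & is.finite(tpm) & tpm >= min_tpm
  spm <- spm[keep]; p_m <- p_m[keep]
  fit <- stats::glm(spm ~ p_m + I(p_m^2), family = stats::quasibinomial())
  if (!fit$converged) stop("quasibinomial GLM did not converge")
  an <- stats::anova(fit, test = "F")
  terms <- rownames(an)[-1]
  f_tests <- data.frame(
    term = c("p_m", "p_m2")[seq_along(terms)],
    F = an$F[-1],
    df = an$Df[-1],
    p = an$`Pr(>F)`[-1],
    stringsAsFactors = FALSE
  )
  list(
    coefficients = stats::setNames(stats::coef(fit),
                                   c("intercept", "p_m", "p_m2")),
    dispersion = summary(fit)$dispersion,
    f_tests = f_tests,
    n = length(spm),
    fit = fit
  )
}
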