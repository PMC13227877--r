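#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table (the classical two-sided convention). The
#' point odds ratio is the sample estimate \eqn{ad / bc} (not the
#' conditional MLE).
#'
#' @param a,b,c_,d Nonnegative integer cell counts; rows are the condition
#'   (e.g. hub / non-hub), columns the outcome (e.g. driver / background).
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be nonnegative integers")
  }
  if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) {
    abort("zero margin in 2x2 table")
  }
  ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  list(odds_ratio = or, p = unname(ft$p.value))
}

#' Odds ratio with Wald log-scale confidence interval
#'
#' \eqn{OR = ad / bc} with
#' \eqn{CI = \exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. Zero cells
#' receive the Haldane-Anscombe +0.5 correction to all four cells, flagged
#' in the output. An OR above 2 is conventionally read as meaningful
#' enrichment. The Fisher exact p-value for the same table and the
#' Bonferroni-corrected alpha for the named test family are included.
#'
#' @param a,b,c_,d Nonnegative integer cell counts.
#' @param z Normal quantile for the interval (default 1.96, i.e. 95%).
#' @param family Optional test-family name for multiplicity bookkeeping.
#' @param m Family size for the Bonferroni-corrected alpha (default 1).
#' @return One-row `enrichment_result` tibble: cells, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `family`, `m`, `corrected_alpha`,
#'   `haldane_corrected`.
#' @export
odds_ratio_ci <- function(a, b, c_, d, z = 1.96, family = NA_character_,
                          m = 1) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0)) abort("cell counts must be nonnegative")
  corrected <- any(cells == 0)
  p_exact <- tryCatch(fisher_exact(a, b, c_, d)$p, error = function(e) NA_real_)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  out <- tibble::tibble(
    a = a, b = b, c = c_, d = d,
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p = p_exact,
    family = family, m = m,
    corrected_alpha = bonferroni_alpha(0.05, m),
    haldane_corrected = corrected
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' U from rank sums with tie correction; the p-value is exact (permutation
#' distribution) for small untied samples (`n1 + n2 <= 12`) and the
#' tie-corrected normal approximation otherwise. Cohen's d (pooled SD) is
#' reported alongside as the effect-size currency.
#'
#' @param x_values,y_values Numeric group samples (both non-empty).
#' @param alternative Passed to the test (default two-sided).
#' @return One-row `comparison_result` tibble: group summaries, `U`, `p`,
#'   `method`, `d`, `interpretation`.
#' @export
mann_whitney <- function(x_values, y_values,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x_values) == 0 || length(y_values) == 0) {
    abort("both groups must be non-empty")
  }
  n1 <- length(x_values)
  n2 <- length(y_values)
  r <- rank(c(x_values, y_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x_values, y_values)) > 0
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x_values, y_values, exact = exact,
                       correct = !exact, alternative = alternative)
  )
  d <- tryCatch(
    cohens_d(n1, mean(x_values), sd(x_values),
             n2, mean(y_values), sd(y_values)),
    error = function(e) NA_real_
  )
  out <- tibble::tibble(
    n1 = n1, mean1 = mean(x_values), sd1 = sd(x_values),
    n2 = n2, mean2 = mean(y_values), sd2 = sd(y_values),
    U = unname(u), p = unname(wt$p.value),
    method = if (exact) "exact" else "normal",
    d = d, interpretation = interpret_d(d)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Cohen's d from group summaries
#'
#' Standardised mean difference with pooled standard deviation,
#' \eqn{d = (\mu_1 - \mu_2) / s_p},
#' \eqn{s_p^2 = ((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)}.
#' Bands: |d| < 0.2 negligible, < 0.5 small, < 0.8 medium, else large.
#'
#' @param n1,mean1,sd1 First group size, mean, sample SD.
#' @param n2,mean2,sd2 Second group size, mean, sample SD.
#' @return The effect size d (scalar; sign follows `mean1 - mean2`).
#' @examples
#' cohens_d(3, 10, 2, 3, 7, 2) # 1.5
#' @export
cohens_d <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) abort("each group needs n >= 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) abort("zero pooled standard deviation")
  (mean1 - mean2) / sp
}

interpret_d <- function(d) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad < 0.2) "negligible" else if (ad < 0.5) "small"
  else if (ad < 0.8) "medium" else "large"
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests in the family.
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 45)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1) {
  if (m < 1) abort("family size m must be >= 1")
  alpha / m
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' \eqn{CI = \tanh(\mathrm{atanh}(r) \pm z / \sqrt{n - 3})}.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param z Normal quantile (default 1.96).
#' @return One-row tibble with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_with_fisher_z <- function(x, y, z = 1.96) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) abort("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(tibble::tibble(r = r, ci_low = r, ci_high = r, n = n))
  }
  zr <- atanh(r)
  half <- z / sqrt(n - 3)
  tibble::tibble(
    r = r, ci_low = tanh(zr - half), ci_high = tanh(zr + half), n = n
  )
}
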