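# Inferential statistics used throughout the pipeline: Wilcoxon rank-sum
# with exact small-sample p values, Benjamini-Hochberg FDR, Spearman
# correlation, and multiple linear regression of features on clinical
# predictors.

#' Wilcoxon rank-sum test between two groups
#'
#' Exact two-sided p value (distribution of the rank-sum statistic) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @return List with `statistic` (Mann-Whitney U for `group_a`), `p`, and
#'   `method`.
#' @export
ranksum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop_arg("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: with ordered p values p(1) <= ... <= p(m), rejects
#' the hypotheses 1..k for the largest k with p(k) <= k q / m. Adjusted
#' p values are the usual monotone BH values.
#'
#' @param p_values Numeric vector of p values in `[0, 1]` (NAs allowed,
#'   passed through).
#' @param q FDR level for the rejection mask (default 0.05).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  pv <- p_values[!is.na(p_values)]
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    stop_arg("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The p value is exact for n <= 9 without
#' ties, otherwise the t approximation on r x sqrt((n-2)/(1-r^2)).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `r`, `p`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_arg("`x` and `y` must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("zero variance input")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(r = unname(ct$estimate), p = ct$p.value,
       method = if (exact) "exact" else "t approximation")
}

#' Multiple linear regression of a feature on clinical predictors
#'
#' Ordinary least squares with intercept, e.g. feature ~ age at epilepsy
#' onset + patient age + number of ASMs + epilepsy duration + epilepsy
#' subtype, with the subtype encoded as a binary indicator. Rank-deficient
#' designs are refused with the offending (aliased) columns named.
#'
#' @param feature Numeric response vector.
#' @param predictors data.frame of predictors (factors/characters become
#'   indicator variables).
#' @return data.frame with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `t`, `p`.
#' @export
multiple_regression <- function(feature, predictors) {
  predictors <- as.data.frame(predictors)
  if (length(feature) != nrow(predictors))
    stop_arg("`feature` and `predictors` must have matching length")
  if (length(feature) <= ncol(predictors) + 1)
    stop_arg("need n > number of predictors + 1")
  df <- cbind(.y = feature, predictors)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_arg("rank-deficient design; aliased column(s): ",
             paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL)
}
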