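# Group tests and covariate regressions.

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test via [stats::wilcox.test()]: exact for small
#' tie-free samples, normal approximation with tie and continuity
#' corrections otherwise.
#'
#' @param x,y Numeric samples for the two groups.
#' @return List with `statistic` (U for `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("each group needs at least 1 value")
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Univariate association (Pearson correlation)
#'
#' @param metric,covariate Numeric vectors.
#' @return Pearson correlation coefficient.
#' @export
univariate_assoc <- function(metric, covariate) {
  stats::cor(metric, covariate, use = "complete.obs")
}

#' Multivariate ordinary least squares
#'
#' OLS of `y` on the columns of `X` (intercept added), with the usual
#' unbiased-variance standard errors. Rank-deficient designs error, naming
#' the aliased columns.
#'
#' @param y Response vector.
#' @param X Numeric predictor matrix with column names.
#' @return Tibble: `term`, `estimate`, `std_error`, `p_value`.
#' @export
multivariate_lm <- function(y, X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1) stop("need n > p + 1 observations")
  fit <- stats::lm(y ~ X)
  if (anyNA(stats::coef(fit))) {
    bad <- sub("^X", "", names(stats::coef(fit))[is.na(stats::coef(fit))])
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  tibble::tibble(term = sub("^X", "", rownames(sm)),
                 estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
                 p_value = unname(sm[, 4]))
}
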