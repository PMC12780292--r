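# Two-class linear discriminant analysis, cross-validated AUC, the DeLong
# test for correlated ROC curves, VIF pruning, combined z-scores and power.

#' Fit a pooled-covariance two-class linear discriminant
#'
#' Weights proportional to `solve(Sigma_pooled) %*% (mu1 - mu0)`; the
#' intercept places the decision boundary using class-frequency priors. A
#' ridge jitter of `1e-8 * trace/p` is added only when the pooled covariance
#' is singular. The discriminant score `w'x + b` (not the class label) is
#' what downstream ROC analysis consumes.
#'
#' @param X Numeric feature matrix (rows = cases) with column names.
#' @param y Two-level class vector; the second level (or `TRUE`/1) is the
#'   positive class.
#' @return An object of class `"lda_model"`: `weights`, `intercept`,
#'   `means` (class means), `pooled_cov`, `features`, `levels`.
#' @export
fit_lda <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("features must be finite")
  yl <- as_two_level(y)
  n0 <- sum(yl == levels(yl)[1]); n1 <- sum(yl == levels(yl)[2])
  if (nlevels(yl) != 2L || min(n0, n1) < 2) {
    stop("need exactly two classes with at least 2 cases each")
  }
  mu0 <- colMeans(X[yl == levels(yl)[1], , drop = FALSE])
  mu1 <- colMeans(X[yl == levels(yl)[2], , drop = FALSE])
  S0 <- stats::cov(X[yl == levels(yl)[1], , drop = FALSE])
  S1 <- stats::cov(X[yl == levels(yl)[2], , drop = FALSE])
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  w <- tryCatch(solve(Sp, mu1 - mu0), error = function(e) {
    ridge <- 1e-8 * sum(diag(Sp)) / ncol(X)
    solve(Sp + diag(ridge, ncol(X)), mu1 - mu0)
  })
  prior0 <- n0 / (n0 + n1); prior1 <- n1 / (n0 + n1)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(prior1 / prior0)
  structure(list(weights = stats::setNames(as.vector(w), colnames(X)),
                 intercept = b,
                 means = rbind(mu0, mu1),
                 pooled_cov = Sp,
                 features = colnames(X),
                 levels = levels(yl)),
            class = "lda_model")
}

as_two_level <- function(y) {
  if (is.logical(y)) factor(y, levels = c(FALSE, TRUE)) else factor(y)
}

#' @rdname fit_lda
#' @param object A fitted `lda_model`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
#' @return Numeric discriminant scores.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$features))
  }
  as.vector(newdata %*% object$weights) + object$intercept
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Ties count one half. Equals the probability a random positive scores
#' above a random negative.
#'
#' @param scores Numeric scores, higher = more disease-like.
#' @param y Two-level class vector (second level positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, y) {
  yl <- as_two_level(y)
  pos <- yl == levels(yl)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validated AUC
#'
#' Stratified fold assignment (every fold contains both classes), LDA fit
#' on each training split, out-of-fold discriminant scores pooled into a
#' single ROC. Deterministic given the seed.
#'
#' @param X Feature matrix.
#' @param y Two-level class vector (second level positive).
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold assignment.
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1:k`), e.g. to share folds between two compared models.
#' @return List: `auc`, `scores` (pooled out-of-fold), `folds`.
#' @export
cv_auc <- function(X, y, k = 5, seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  yl <- as_two_level(y)
  if (min(table(yl)) < k) {
    stop("minority class has fewer cases (", min(table(yl)),
         ") than folds (", k, "); use a smaller k")
  }
  if (is.null(folds)) folds <- make_stratified_folds(yl, k, seed)
  scores <- numeric(length(yl))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_lda(X[!test, , drop = FALSE], yl[!test])
    scores[test] <- predict(fit, X[test, , drop = FALSE])
  }
  list(auc = auc_mann_whitney(scores, yl), scores = scores, folds = folds)
}

#' @rdname cv_auc
#' @export
make_stratified_folds <- function(y, k = 5, seed = 1L) {
  yl <- as_two_level(y)
  folds <- integer(length(yl))
  with_rng(seed, {
    for (lv in levels(yl)) {
      idx <- which(yl == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' DeLong test comparing two correlated ROC AUCs
#'
#' Structural-components estimate of `var(AUC_a - AUC_b)` accounting for
#' the correlation induced by scoring the same cases, with a two-sided
#' normal p-value. Scores are typically the pooled out-of-fold discriminant
#' scores of two models evaluated on the same cohort.
#'
#' @param scores_a,scores_b Score vectors over the same cases.
#' @param y Two-level class vector (second level positive).
#' @return List: `z`, `p`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, y) {
  yl <- as_two_level(y)
  pos <- yl == levels(yl)[2]
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")
  comp <- function(s) delong_components(s[pos], s[!pos])
  ca <- comp(scores_a)
  cb <- comp(scores_b)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  z <- if (var_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}

# Midrank-based structural components (positive scores xs, negative ys).
delong_components <- function(xs, ys) {
  m <- length(xs); n <- length(ys)
  all_r <- rank(c(xs, ys))
  rx <- rank(xs)
  ry <- rank(ys)
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' @rdname delong_compare
#' @param scores Single-model scores.
#' @return `delong_auc_variance()`: list with `auc` and `var`.
#' @export
delong_auc_variance <- function(scores, y) {
  yl <- as_two_level(y)
  pos <- yl == levels(yl)[2]
  cc <- delong_components(scores[pos], scores[!pos])
  list(auc = cc$auc,
       var = stats::var(cc$v10) / sum(pos) + stats::var(cc$v01) / sum(!pos))
}

#' Iterative variance-inflation-factor pruning
#'
#' Computes each column's VIF (`1 / (1 - R^2)` of regressing it on the
#' others) and removes one variable at a time until all VIFs fall below the
#' threshold. When both an LV and an RV volume measure exceed the
#' threshold, the RV measure is removed first (the paired rule); otherwise
#' the single largest-VIF variable goes, with ties broken by column order.
#' Perfectly collinear columns have infinite VIF and are removed first.
#'
#' @param X Numeric matrix with column names.
#' @param names Feature names (default `colnames(X)`).
#' @param threshold VIF threshold (default 5).
#' @param volume_pair_rule Apply the LV/RV paired rule.
#' @return Character vector of retained names, with the removed ones in
#'   attribute `"removed"`.
#' @export
vif_prune <- function(X, names = colnames(X), threshold = 5,
                      volume_pair_rule = TRUE) {
  X <- as.matrix(X)
  colnames(X) <- names
  if (nrow(X) <= ncol(X) + 1) stop("need n > p + 1 observations")
  lv_vol <- c("LVEDV", "LVESV")
  rv_vol <- c("RVEDV", "RVESV")
  removed <- character()
  repeat {
    if (ncol(X) < 2) break
    v <- vif_values(X)
    over <- which(v > threshold)
    if (length(over) == 0) break
    drop_name <- NULL
    if (volume_pair_rule) {
      over_names <- colnames(X)[over]
      if (any(over_names %in% lv_vol) && any(over_names %in% rv_vol)) {
        rv_over <- over_names[over_names %in% rv_vol]
        drop_name <- rv_over[which.max(v[rv_over])]
      }
    }
    if (is.null(drop_name)) drop_name <- colnames(X)[which.max(v)]
    removed <- c(removed, drop_name)
    X <- X[, colnames(X) != drop_name, drop = FALSE]
  }
  structure(colnames(X), removed = removed)
}

vif_values <- function(X) {
  p <- ncol(X)
  v <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    v[j] <- if (ssr <= sst * 1e-12) Inf else 1 / (ssr / sst)
  }
  v
}

#' Combined z-score from a discriminant model
#'
#' Projects cases on the discriminant weights and standardizes by the
#' reference-subset mean and SD, so the reference cohort sits at mean 0,
#' SD 1 by construction; the sign is oriented so the non-reference group
#' mean is positive.
#'
#' @param lda A fitted [fit_lda()] model.
#' @param X Feature matrix for all cases.
#' @param reference_mask Logical vector marking the standardization
#'   (reference) subset.
#' @return Numeric z-score per case.
#' @export
combined_zscore <- function(lda, X, reference_mask) {
  if (!any(reference_mask)) stop("reference subset is empty")
  s <- predict(lda, X)
  mu <- mean(s[reference_mask])
  sd_ <- stats::sd(s[reference_mask])
  if (sd_ == 0) stop("zero variance in the reference subset")
  z <- (s - mu) / sd_
  if (any(!reference_mask) && mean(z[!reference_mask]) < 0) z <- -z
  z
}

#' Two-sample power calculation (normal approximation)
#'
#' `n_per_group = 2 * (z_{1-alpha/2} + z_{power})^2 / d^2`, rounded to the
#' nearest integer. The effect size convention is the disease-group mean
#' combined z-score with the reference standardized to mean 0, SD 1.
#'
#' @param d Effect size (standardized mean difference).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return List: `n_per_group`, `n_total`.
#' @export
power_two_sample <- function(d, alpha = 0.05, power = 0.80) {
  if (any(d <= 0)) stop("effect size must be positive")
  n_per <- round(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2)
  list(n_per_group = n_per, n_total = 2 * n_per)
}
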