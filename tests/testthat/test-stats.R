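# Statistical layer: rank tests, regressions, LDA, AUC, DeLong, VIF,
# z-scores, power.

test_that("Wilcoxon matches exact enumeration and handles degenerate input", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 0.1)     # 2/20 orderings, exact two-sided
  expect_equal(wilcoxon_rank_sum(rep(1, 5), rep(1, 5))$p, 1)
  # power: 1 SD shift at n = 30/30; analytic power at alpha = 0.01 is ~0.88
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    if (wilcoxon_rank_sum(rnorm(30), rnorm(30, 1))$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.75)
})

test_that("regressions match closed forms and flag rank deficiency", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(univariate_assoc(2 * x, x), 1)
  set.seed(9)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5) + rnorm(5, 0, 0.1)
  # brute-force normal equations oracle
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_error(multivariate_lm(y[1:4], X[1:4, ]), "n > p")
  X8 <- rbind(X, matrix(rnorm(9), 3, 3, dimnames = list(NULL, colnames(X))))
  y8 <- X8 %*% c(1, -2, 0.5) + rnorm(8, 0, 0.1)
  beta8 <- solve(t(cbind(1, X8)) %*% cbind(1, X8), t(cbind(1, X8)) %*% y8)
  fit <- multivariate_lm(y8, X8)
  expect_equal(fit$estimate, as.vector(beta8), tolerance = 1e-10)
  # aliased column named in the error
  Xal <- cbind(X8, d = X8[, "a"])
  expect_error(multivariate_lm(y8, Xal), "d")
  # null association stays small
  set.seed(10)
  r <- replicate(40, univariate_assoc(rnorm(1000), rnorm(1000)))
  expect_gte(mean(abs(r) < 0.1), 0.95)
})

test_that("LDA weights equal the closed form and align with MASS::lda", {
  set.seed(12)
  n <- 200
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(1, 0.5), `+`))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = n)
  fit <- fit_lda(X, y)
  # closed form via explicit 2x2 inversion
  S0 <- cov(X[1:n, ]); S1 <- cov(X[n + 1:n, ])
  Sp <- (S0 + S1) / 2
  dmu <- colMeans(X[n + 1:n, ]) - colMeans(X[1:n, ])
  inv <- matrix(c(Sp[2, 2], -Sp[1, 2], -Sp[2, 1], Sp[1, 1]), 2) /
    (Sp[1, 1] * Sp[2, 2] - Sp[1, 2] * Sp[2, 1])
  expect_equal(unname(fit$weights), as.vector(inv %*% dmu),
               tolerance = 1e-10)
  # independent cross-check: MASS::lda scaling is proportional
  skip_if_not_installed("MASS")
  m <- MASS::lda(X, grouping = y)
  ratio <- fit$weights / as.vector(m$scaling)
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
  # degenerate inputs
  expect_error(fit_lda(X, rep(TRUE, 2 * n)), "two classes")
  # 1-D sanity: weight points toward the larger class mean
  f1 <- fit_lda(matrix(c(rnorm(50), rnorm(50, 1)), ncol = 1),
                rep(c(FALSE, TRUE), each = 50))
  expect_gt(f1$weights[1], 0)
})

test_that("cross-validated AUC: separation, null, and Gaussian closed form", {
  set.seed(20)
  # perfectly separated classes
  Xs <- matrix(c(rnorm(40, -10), rnorm(40, 10)), ncol = 1)
  ys <- rep(c(FALSE, TRUE), each = 40)
  expect_equal(cv_auc(Xs, ys, k = 5, seed = 3)$auc, 1.0)

  # shuffled labels stay near 0.5
  near_half <- 0
  for (s in 1:20) {
    set.seed(s)
    X0 <- matrix(rnorm(1000), ncol = 1)
    y0 <- sample(rep(c(FALSE, TRUE), each = 500))
    a <- cv_auc(X0, y0, k = 5, seed = s)$auc
    if (a > 0.45 && a < 0.55) near_half <- near_half + 1
  }
  expect_gte(near_half / 20, 0.9)

  # Gaussian closed form: AUC = Phi(Delta / sqrt(2)) for two classes with
  # common covariance and Mahalanobis separation Delta
  set.seed(21)
  n <- 2000
  delta <- 1.2
  X <- rbind(matrix(rnorm(3 * n), n, 3),
             sweep(matrix(rnorm(3 * n), n, 3), 2, c(delta, 0, 0), `+`))
  y <- rep(c(FALSE, TRUE), each = n)
  expect_lt(abs(cv_auc(X, y, k = 5, seed = 7)$auc - pnorm(delta / sqrt(2))),
            0.02)

  # pooled-score AUC equals brute-force pairwise comparison
  set.seed(22)
  sc <- rnorm(60)
  yy <- rep(c(FALSE, TRUE), 30)
  brute <- mean(outer(sc[yy], sc[!yy], function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_mann_whitney(sc, yy), brute, tolerance = 1e-12)

  expect_error(cv_auc(Xs[1:41, , drop = FALSE], c(ys[1:40], TRUE), k = 5),
               "smaller k")
})

test_that("DeLong test: identity, variance oracles, pROC agreement", {
  set.seed(30)
  n <- 100
  y <- rep(c(FALSE, TRUE), each = n)
  sig <- c(rnorm(n), rnorm(n, 1))
  sa <- sig + rnorm(2 * n, 0, 0.5)
  # identical scores -> z = 0, p = 1
  dl0 <- delong_compare(sa, sa, y)
  expect_equal(dl0$z, 0)
  expect_equal(dl0$p, 1)

  # single-AUC variance vs bootstrap on a 200-case toy
  dv <- delong_auc_variance(sa, y)
  set.seed(31)
  boots <- replicate(2000, {
    i <- sample(which(y), replace = TRUE)
    j <- sample(which(!y), replace = TRUE)
    auc_mann_whitney(c(sa[i], sa[j]), c(y[i], y[j]))
  })
  expect_lt(abs(dv$var / var(boots) - 1), 0.15)

  # Hanley-McNeil closed form on tie-free exponential scores
  set.seed(32)
  se_ <- rexp(150); sn <- rexp(150, 2)
  scores <- c(sn, se_)
  yy <- rep(c(FALSE, TRUE), each = 150)
  a <- auc_mann_whitney(scores, yy)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  hm <- (a * (1 - a) + 149 * (q1 - a^2) + 149 * (q2 - a^2)) / (150 * 150)
  expect_equal(delong_auc_variance(scores, yy)$var, hm, tolerance = 0.20)

  # agreement with pROC's DeLong implementation
  skip_if_not_installed("pROC")
  sb <- sig + rnorm(2 * n, 0, 0.5)
  dl <- delong_compare(sa, sb, y)
  pr <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                       pROC::roc(y, sb, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p, pr$p.value, tolerance = 1e-8)
  expect_equal(abs(dl$z), abs(unname(pr$statistic)), tolerance = 1e-8)
})

test_that("VIF pruning removes collinearity with the RV-first rule", {
  set.seed(40)
  n <- 2000
  # independent columns survive
  Xi <- matrix(rnorm(5 * n), n, 5,
               dimnames = list(NULL, paste0("v", 1:5)))
  kept <- vif_prune(Xi)
  expect_equal(as.character(kept), paste0("v", 1:5))

  # duplicated column: infinite VIF, duplicate removed
  Xd <- cbind(Xi, v1b = Xi[, "v1"])
  kept2 <- vif_prune(Xd)
  expect_length(attr(kept2, "removed"), 1)
  expect_true(all(is.finite(bivatlas:::vif_values(
    Xd[, as.character(kept2), drop = FALSE]))))

  # correlated LV/RV volumes: the RV measure goes first
  lv <- rnorm(n)
  rv <- 0.98 * lv + rnorm(n, 0, sqrt(1 - 0.98^2))
  Xv <- cbind(LVEDV = lv, RVEDV = rv, a = rnorm(n), b = rnorm(n))
  kept3 <- vif_prune(Xv, threshold = 5)
  expect_equal(attr(kept3, "removed")[1], "RVEDV")
  expect_true("LVEDV" %in% as.character(kept3))
})

test_that("combined z-scores standardize the reference and orient disease", {
  set.seed(50)
  n <- 300
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * 100), 100, 2), 2, c(-1, 0), `+`))
  colnames(X) <- c("a", "b")
  y <- c(rep(FALSE, n), rep(TRUE, 100))
  fit <- fit_lda(X, y)
  z <- combined_zscore(fit, X, reference_mask = !y)
  expect_equal(mean(z[!y]), 0, tolerance = 1e-9)
  expect_equal(sd(z[!y]), 1, tolerance = 1e-9)
  expect_gt(mean(z[y]), 0)     # sign convention: disease positive
  expect_error(combined_zscore(fit, X, rep(FALSE, nrow(X))), "empty")
})

test_that("power calculation reproduces its printed convention", {
  expect_equal(power_two_sample(0.99)$n_total, 32)
  expect_equal(power_two_sample(0.99)$n_per_group, 16)
  expect_equal(power_two_sample(0.68)$n_total, 68)
  expect_equal(power_two_sample(0.68)$n_per_group, 34)
  # inverse-square law
  expect_equal(power_two_sample(0.4)$n_per_group /
                 power_two_sample(0.8)$n_per_group, 4, tolerance = 0.05)
  expect_error(power_two_sample(0), "positive")
})
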