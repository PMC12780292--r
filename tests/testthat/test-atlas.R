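# Procrustes alignment and the PCA atlas.

test_that("rigid alignment exactly undoes a known rigid motion", {
  tmpl <- coarse_template()
  R <- random_rotation(21)
  moved <- transform_shape(tmpl, R, c(15, -30, 8))
  back <- rigid_align(moved, tmpl$ed$vertices)
  expect_lt(max(abs(back$ed$vertices - tmpl$ed$vertices)), 1e-8)
  expect_lt(max(abs(back$es$vertices - tmpl$es$vertices)), 1e-8)
})

test_that("alignment residual is invariant to rigid pre-transforms", {
  tmpl <- coarse_template()
  set.seed(2)
  jit <- tmpl
  jit$ed <- new_mesh(tmpl$ed$vertices + matrix(rnorm(length(tmpl$ed$vertices)),
                                               ncol = 3),
                     tmpl$ed$faces, validate = FALSE)
  resid <- function(s) {
    a <- rigid_align(s, tmpl$ed$vertices)
    sqrt(mean((a$ed$vertices - tmpl$ed$vertices)^2))
  }
  r0 <- resid(jit)
  r1 <- resid(transform_shape(jit, random_rotation(3), c(4, 4, -9)))
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("reflection is never chosen even when it would fit better", {
  tmpl <- coarse_template()
  mirrored <- tmpl$ed$vertices
  mirrored[, 1] <- -mirrored[, 1]
  aligned <- rigid_align(tmpl, mirrored)
  # brute-force unconstrained orthogonal solution would fit a reflection
  # exactly; the proper-rotation solution must leave a residual
  expect_gt(sqrt(mean((aligned$ed$vertices - mirrored)^2)), 1)
  tf <- bivatlas:::kabsch(tmpl$ed$vertices, mirrored)
  expect_equal(det(tf$R), 1, tolerance = 1e-9)
})

test_that("generalized Procrustes collapses rigid scatter to consensus", {
  tmpl <- coarse_template()
  set.seed(31)
  shapes <- lapply(1:6, function(i) {
    transform_shape(tmpl, random_rotation(), rnorm(3, 0, 20))
  })
  gpa <- generalized_procrustes(shapes)
  ref <- gpa$shapes[[1]]$ed$vertices
  for (s in gpa$shapes[-1]) {
    expect_lt(sqrt(mean((s$ed$vertices - ref)^2)), 1e-6)
  }
})

test_that("consensus is independent of input order (up to global pose)", {
  sim <- coarse_cohort(n = 10)
  g1 <- generalized_procrustes(sim$shapes)
  g2 <- generalized_procrustes(rev(sim$shapes))
  # align the two consensus means rigidly; they must then agree
  tf <- bivatlas:::kabsch(g2$mean_ed, g1$mean_ed)
  m2 <- sweep(g2$mean_ed %*% tf$R, 2, tf$t, `+`)
  expect_lt(max(abs(m2 - g1$mean_ed)), 1e-4)
})

test_that("concatenated shape vectors round-trip", {
  tmpl <- coarse_template()
  v <- concat_vector(tmpl)
  expect_length(v, 2 * 3 * nrow(tmpl$ed$vertices))
  back <- unconcat_vector(v, tmpl)
  expect_equal(back$ed$vertices, tmpl$ed$vertices)
  expect_equal(back$es$vertices, tmpl$es$vertices)
  # ED-only edits leave the ES half unchanged
  v2 <- v
  v2[1:9] <- v2[1:9] + 5
  back2 <- unconcat_vector(v2, tmpl)
  expect_equal(back2$es$vertices, tmpl$es$vertices)
  expect_false(isTRUE(all.equal(back2$ed$vertices, tmpl$ed$vertices)))
})

test_that("fit_atlas equals a brute-force covariance eigendecomposition", {
  set.seed(42)
  X <- matrix(rnorm(24), 4, 6)
  atlas <- fit_atlas(X, n_components = 3)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(atlas$variances, ev$values[1:3], tolerance = 1e-10)
  for (j in 1:3) {
    # same axis up to sign
    expect_equal(abs(sum(atlas$modes[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
    # sign convention: largest-magnitude loading positive
    expect_gt(atlas$modes[which.max(abs(atlas$modes[, j])), j], 0)
  }
  # total variance conservation
  expect_equal(sum(fit_atlas(X)$variances), sum(diag(stats::cov(X))),
               tolerance = 1e-8)
})

test_that("rank and component-count rules behave", {
  # 3 points in a plane span exactly 2 directions
  set.seed(1)
  B <- matrix(rnorm(20), 2, 10)
  X <- rbind(rnorm(2) %*% B, rnorm(2) %*% B, rnorm(2) %*% B)
  atlas <- fit_atlas(X)
  expect_length(atlas$variances, 2)

  fake <- structure(list(variances = c(9, 1)), class = "shape_atlas")
  expect_equal(n_components_for_variance(fake, 0.9), 1)
  expect_equal(n_components_for_variance(fake, 1.0), 2)
  expect_error(n_components_for_variance(fake, 1.5), "fraction")
  expect_warning(fit_atlas(matrix(rnorm(40), 4, 10), n_components = 10),
                 "capped")
})

test_that("projection, reconstruction and distances obey their algebra", {
  sim <- coarse_cohort(n = 25)
  gpa <- generalized_procrustes(sim$shapes)
  X <- do.call(rbind, lapply(gpa$shapes, concat_vector))
  atlas <- fit_atlas(X, n_components = 10)

  expect_equal(project(atlas, atlas$mean_vector), rep(0, 10),
               tolerance = 1e-8)
  # mean + 2 sd along PC1 scores exactly (2 sd, 0, ...)
  v <- atlas$mean_vector + 2 * sqrt(atlas$variances[1]) * atlas$modes[, 1]
  sc <- project(atlas, v)
  expect_equal(sc[1], 2 * sqrt(atlas$variances[1]), tolerance = 1e-8)
  expect_lt(max(abs(sc[-1])), 1e-8)
  # training vector with all components retained reconstructs exactly
  k_all <- length(atlas$variances)
  scf <- project(atlas, X[3, ], n_components = k_all)
  expect_lt(max(abs(reconstruct(atlas, scf) - X[3, ])), 1e-8)
  # projection error: mean + c * PC_{k+1} has RMS error |c|/sqrt(d)
  k <- 5
  cc <- 7.5
  v2 <- atlas$mean_vector + cc * atlas$modes[, k + 1]
  expect_equal(projection_error(atlas, v2, k),
               cc / sqrt(length(atlas$mean_vector)), tolerance = 1e-8)
  # non-increasing in k
  e <- vapply(1:10, function(kk) projection_error(atlas, X[1, ], kk),
              numeric(1))
  expect_true(all(diff(e) <= 1e-12))

  # Mahalanobis: zero scores -> 0; scores = sqrt(variances) -> sqrt(k)
  expect_equal(mahalanobis_distance(atlas, rep(0, 10)), 0)
  expect_equal(mahalanobis_distance(atlas, sqrt(atlas$variances[1:10])),
               sqrt(10), tolerance = 1e-10)
})

test_that("scores are pose-invariant and uncorrelated on training data", {
  sim <- coarse_cohort(n = 40)
  gpa <- generalized_procrustes(sim$shapes)
  X <- do.call(rbind, lapply(gpa$shapes, concat_vector))
  atlas <- fit_atlas(X, n_components = 4)
  S <- project(atlas, X)
  C <- stats::cor(S)
  expect_lt(max(abs(C[upper.tri(C)])), 0.02)

  # random rigid motions of every input shape leave scores unchanged
  set.seed(8)
  moved <- lapply(sim$shapes, function(s) {
    transform_shape(s, random_rotation(), rnorm(3, 0, 30))
  })
  gpa2 <- generalized_procrustes(moved, reference = gpa$mean_ed)
  S2 <- project(atlas, do.call(rbind, lapply(gpa2$shapes, concat_vector)))
  expect_lt(max(abs(S2 - S)), 1e-6)
})

test_that("atlas archives round-trip", {
  sim <- coarse_cohort(n = 10)
  X <- do.call(rbind, lapply(sim$shapes, concat_vector))
  atlas <- fit_atlas(X)
  path <- file.path(withr::local_tempdir(), "atlas.rds")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(back$modes, atlas$modes)
  expect_equal(back$variances, atlas$variances)
})
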