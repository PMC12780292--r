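# Procrustes co-registration and the concatenated ED/ES PCA shape atlas.

#' Rigid Procrustes alignment (no scaling) of one shape to a target
#'
#' Least-squares rotation and translation (Kabsch solution with the
#' determinant correction, so reflections are never chosen) computed on the
#' ED vertices only, then applied to both frames. Applying the ED transform
#' to ES preserves the systolic-motion information that the concatenated
#' shape vector is meant to carry.
#'
#' @param shape A [new_shape()] object.
#' @param target_ed Vertex matrix (same count/order as the shape's ED frame).
#' @return The aligned shape (a transformed copy).
#' @export
rigid_align <- function(shape, target_ed) {
  P <- shape$ed$vertices
  if (nrow(P) != nrow(target_ed)) stop("vertex count mismatch with target")
  tf <- kabsch(P, target_ed)
  apply_rigid(shape, tf$R, tf$t)
}

# Rotation R and translation t minimizing || (P - cP) R - (Q - cQ) ||_F,
# aligned = P R + t. det(R) = +1 enforced.
kabsch <- function(P, Q) {
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP)
  Qc <- sweep(Q, 2, cQ)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("degenerate point configuration: alignment undefined")
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = cQ - as.vector(cP %*% R))
}

apply_rigid <- function(shape, R, t) {
  tr <- function(m) new_mesh(sweep(m$vertices %*% R, 2, t, `+`), m$faces,
                             validate = FALSE)
  shape$ed <- tr(shape$ed)
  shape$es <- tr(shape$es)
  shape
}

#' Generalized Procrustes alignment of a shape population
#'
#' Iteratively aligns every shape's ED frame to the evolving ED mean until
#' the mean moves less than `tol` (RMS mm) or `max_iter` iterations. Each
#' shape's ES frame follows its ED transform. Deterministic.
#'
#' @param shapes List of [new_shape()] objects with shared topology.
#' @param tol Convergence tolerance on the RMS movement of the mean, mm.
#' @param max_iter Iteration cap.
#' @param reference Optional fixed ED vertex matrix; when supplied, a single
#'   pass aligning every shape to it is performed (fixed-reference mode)
#'   instead of the iterative consensus.
#' @return List with `shapes` (aligned) and `mean_ed` (consensus vertex
#'   matrix).
#' @export
generalized_procrustes <- function(shapes, tol = 1e-6, max_iter = 100,
                                   reference = NULL) {
  if (length(shapes) < 2 && is.null(reference)) {
    stop("need at least 2 shapes for a consensus alignment")
  }
  if (!is.null(reference)) {
    aligned <- lapply(shapes, rigid_align, target_ed = reference)
    return(list(shapes = aligned, mean_ed = reference, iterations = 1L))
  }
  mean_ed <- Reduce(`+`, lapply(shapes, function(s) s$ed$vertices)) /
    length(shapes)
  aligned <- shapes
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, rigid_align, target_ed = mean_ed)
    new_mean <- Reduce(`+`, lapply(aligned, function(s) s$ed$vertices)) /
      length(aligned)
    move <- sqrt(mean((new_mean - mean_ed)^2))
    mean_ed <- new_mean
    if (move < tol) {
      return(list(shapes = aligned, mean_ed = mean_ed, iterations = it))
    }
  }
  stop("generalized Procrustes did not converge in ", max_iter,
       " iterations (last mean movement ", signif(move, 3), " mm)")
}

#' Concatenated ED+ES shape vector
#'
#' Flattens the ED vertex coordinates (x, y, z per vertex, in vertex order)
#' followed by the ES coordinates, giving a vector of length `2 * 3 * V`.
#'
#' @param shape A [new_shape()] object.
#' @return Numeric vector of length `2 * 3 * V`.
#' @export
concat_vector <- function(shape) {
  c(as.vector(t(shape$ed$vertices)), as.vector(t(shape$es$vertices)))
}

#' @rdname concat_vector
#' @param vec Concatenated shape vector.
#' @param template Shape providing topology and labels for the rebuild.
#' @param id Identifier for the rebuilt shape.
#' @export
unconcat_vector <- function(vec, template, id = template$id) {
  V <- nrow(template$ed$vertices)
  stopifnot(length(vec) == 2 * 3 * V)
  ed <- matrix(vec[seq_len(3 * V)], ncol = 3, byrow = TRUE)
  es <- matrix(vec[3 * V + seq_len(3 * V)], ncol = 3, byrow = TRUE)
  new_shape(id, new_mesh(ed, template$ed$faces, validate = FALSE),
            new_mesh(es, template$es$faces, validate = FALSE),
            template$labels)
}

#' Fit a PCA shape atlas from concatenated shape vectors
#'
#' Mean-centers the stacked shape vectors and takes the right singular
#' vectors of the centered data matrix; this equals the eigendecomposition
#' of the sample covariance (1/(n-1) normalization) without forming the
#' large covariance explicitly. PC signs follow the
#' largest-magnitude-loading-positive convention so scores are reproducible.
#'
#' @param vectors Matrix with one row per shape (n x 2*3*V), or a list of
#'   vectors.
#' @param n_components Components to retain; default
#'   `min(25, components for 90% variance)`.
#' @param variance_fraction Fraction of total variance the retained
#'   components must reach when `n_components` is `NULL`.
#' @param max_components Cap applied to the variance-fraction rule.
#' @param reference_mean_ed Optional consensus ED vertex matrix stored for
#'   aligning new shapes.
#' @return An object of class `"shape_atlas"`: `mean_vector`, `modes`
#'   (columns are unit PCs, descending variance), `variances` (eigenvalues,
#'   mm^2), `n_components`, `n_samples`, `reference_mean_ed`.
#' @export
fit_atlas <- function(vectors, n_components = NULL, variance_fraction = 0.90,
                      max_components = 25, reference_mean_ed = NULL) {
  X <- if (is.list(vectors)) do.call(rbind, vectors) else as.matrix(vectors)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 shapes to fit an atlas")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  variances <- s$d^2 / (n - 1)
  keep <- variances > max(variances[1], .Machine$double.eps) * 1e-12
  variances <- variances[keep]
  modes <- s$v[, keep, drop = FALSE]
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  atlas <- structure(list(mean_vector = mu, modes = modes,
                          variances = variances,
                          n_components = length(variances),
                          n_samples = n,
                          reference_mean_ed = reference_mean_ed),
                     class = "shape_atlas")
  k <- if (is.null(n_components)) {
    min(max_components, n_components_for_variance(atlas, variance_fraction))
  } else {
    if (n_components > length(variances)) {
      warning("requested ", n_components, " components but only ",
              length(variances), " available; capped")
      length(variances)
    } else n_components
  }
  atlas$n_components <- as.integer(k)
  atlas
}

#' @export
print.shape_atlas <- function(x, ...) {
  cat("<shape_atlas> ", x$n_samples, " shapes, dim ", length(x$mean_vector),
      ", ", length(x$variances), " modes (", x$n_components, " retained, ",
      sprintf("%.1f%%", 100 * sum(x$variances[seq_len(x$n_components)]) /
                sum(x$variances)), " of variance)\n", sep = "")
  invisible(x)
}

#' Number of components reaching a variance fraction
#'
#' @param atlas A fitted [fit_atlas()] object.
#' @param fraction Target cumulative variance fraction in (0, 1].
#' @return Smallest k whose cumulative variance fraction reaches `fraction`.
#' @export
n_components_for_variance <- function(atlas, fraction = 0.90) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  cum <- cumsum(atlas$variances) / sum(atlas$variances)
  which(cum >= fraction - 1e-12)[1]
}

#' Project shapes into atlas score space and reconstruct
#'
#' Scores are the coordinates of a centered shape vector in the retained PC
#' basis; reconstruction inverts the projection within that span.
#'
#' @param atlas A fitted [fit_atlas()] object.
#' @param vector Concatenated shape vector (or matrix of row vectors).
#' @param n_components Number of leading PCs; default the atlas's retained
#'   count.
#' @return `project()`: numeric score vector (or matrix); `reconstruct()`:
#'   shape vector(s).
#' @export
project <- function(atlas, vector, n_components = atlas$n_components) {
  M <- atlas$modes[, seq_len(n_components), drop = FALSE]
  if (is.matrix(vector)) {
    sweep(vector, 2, atlas$mean_vector) %*% M
  } else {
    as.vector((vector - atlas$mean_vector) %*% M)
  }
}

#' @rdname project
#' @param scores Score vector (or matrix of row score vectors).
#' @export
reconstruct <- function(atlas, scores, n_components = NULL) {
  if (is.null(n_components)) {
    n_components <- if (is.matrix(scores)) ncol(scores) else length(scores)
  }
  M <- atlas$modes[, seq_len(n_components), drop = FALSE]
  if (is.matrix(scores)) {
    sweep(scores %*% t(M), 2, atlas$mean_vector, `+`)
  } else {
    atlas$mean_vector + as.vector(M %*% scores)
  }
}

#' RMS projection error of a shape vector at rank k
#'
#' Root-mean-square per-coordinate residual between a shape vector and its
#' rank-k atlas reconstruction; the quality-control gate for shapes the
#' atlas cannot represent.
#'
#' @inheritParams project
#' @param k Number of components in the reconstruction.
#' @return RMS residual, mm.
#' @export
projection_error <- function(atlas, vector, k = atlas$n_components) {
  sc <- project(atlas, vector, k)
  if (is.matrix(vector)) {
    res <- vector - reconstruct(atlas, sc, k)
    sqrt(rowMeans(res^2))
  } else {
    sqrt(mean((vector - reconstruct(atlas, sc, k))^2))
  }
}

#' Mahalanobis distance in atlas score space
#'
#' `sqrt(sum(score_i^2 / variance_i))` over the retained components; the
#' variance-normalized distance used as the outlier gate.
#'
#' @param atlas A fitted [fit_atlas()] object.
#' @param scores Score vector (or matrix of row score vectors).
#' @return Dimensionless distance (vector if `scores` is a matrix).
#' @export
mahalanobis_distance <- function(atlas, scores) {
  k <- if (is.matrix(scores)) ncol(scores) else length(scores)
  v <- atlas$variances[seq_len(k)]
  if (any(v <= 0)) stop("zero variance among retained components")
  if (is.matrix(scores)) {
    sqrt(as.vector(scores^2 %*% (1 / v)))
  } else {
    sqrt(sum(scores^2 / v))
  }
}

#' Score a cohort of shapes against an atlas
#'
#' @param atlas A fitted [fit_atlas()] object.
#' @param shapes List of aligned [new_shape()] objects.
#' @return A tibble: `id`, `pc1` ... `pck`.
#' @export
score_table <- function(atlas, shapes) {
  X <- do.call(rbind, lapply(shapes, concat_vector))
  S <- project(atlas, X)
  colnames(S) <- paste0("pc", seq_len(ncol(S)))
  tibble::tibble(id = vapply(shapes, function(s) as.character(s$id),
                             character(1))) |>
    dplyr::bind_cols(tibble::as_tibble(S))
}

#' Save / load a shape atlas archive
#'
#' Serializes the mean, modes, variances and metadata as a single RDS
#' archive.
#'
#' @param atlas A fitted [fit_atlas()] object.
#' @param path File path (conventionally `.rds`).
#' @export
write_atlas <- function(atlas, path) {
  saveRDS(unclass(atlas), path)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  structure(readRDS(path), class = "shape_atlas")
}
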