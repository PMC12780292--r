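#' Create a triangulated surface mesh
#'
#' A mesh is a list of vertex coordinates (millimetres) and triangular faces.
#' Faces index vertices 1-based, following R convention; on-disk label
#' sidecars use 0-based indices and are converted at the I/O boundary.
#'
#' @param vertices Numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces Integer matrix, one row per triangle, three vertex indices.
#' @param validate Check invariants (finite coordinates, index range,
#'   non-degenerate faces). Disable only in tight inner loops on meshes
#'   already known valid.
#' @return An object of class `"biv_mesh"`.
#' @export
new_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "biv_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(f) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen)) {
      stop(sum(degen), " degenerate face(s) with repeated vertices")
    }
  }
  invisible(mesh)
}

#' @export
print.biv_mesh <- function(x, ...) {
  cat("<biv_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

# Faces whose three vertices all belong to `surface` (a vertex index set).
surface_faces <- function(mesh, surface) {
  keep <- matrix(mesh$faces %in% surface, ncol = 3L)
  mesh$faces[rowSums(keep) == 3L, , drop = FALSE]
}

# Count boundary (non-manifold) edges: edges not shared by exactly two faces
# with opposite winding. Returns 0 for a closed, consistently oriented surface.
open_edge_count <- function(faces) {
  if (nrow(faces) == 0L) return(NA_integer_)
  a <- c(faces[, 1], faces[, 2], faces[, 3])
  b <- c(faces[, 2], faces[, 3], faces[, 1])
  base <- max(a, b) + 1
  key_dir <- a * base + b
  # opposite winding: each directed edge appears exactly once
  if (anyDuplicated(key_dir)) {
    return(sum(duplicated(key_dir)) + 1L)
  }
  key_und <- sort(pmin(a, b) * base + pmax(a, b))
  n <- length(key_und)
  paired <- n %% 2L == 0L &&
    all(key_und[seq(1L, n, by = 2L)] == key_und[seq(2L, n, by = 2L)])
  if (paired) return(0L)
  sum(rle(key_und)$lengths != 2L)
}

#' Volume enclosed by a closed surface
#'
#' Signed divergence-theorem sum of tetrahedron volumes spanned by the origin
#' and each triangle, `sum(det[v0, v1, v2]) / 6`. The result is
#' translation- and rotation-invariant for a closed surface. Outward
#' orientation gives a positive sum; an inward-oriented surface is accepted,
#' flipped internally and reported with a warning.
#'
#' @param mesh A [new_mesh()] object.
#' @param surface Optional vertex index set restricting the computation to the
#'   faces lying entirely within it (e.g. one anatomical surface of a
#'   combined mesh). Default: all faces.
#' @return Enclosed volume in millilitres (mm^3 / 1000).
#' @examples
#' cube <- unit_cube_mesh(edge = 10)   # 10 mm cube
#' surface_volume(cube)                # 1 mL
#' @export
surface_volume <- function(mesh, surface = NULL) {
  f <- if (is.null(surface)) mesh$faces else surface_faces(mesh, surface)
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  n_open <- open_edge_count(f)
  if (is.na(n_open) || n_open > 0L) {
    stop("surface is not closed/consistently oriented: ",
         if (is.na(n_open)) "no faces" else paste(n_open, "open edge(s)"))
  }
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
          a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det6) / 6
  if (vol < 0) {
    warning("surface orientation is inward; sign flipped")
    vol <- -vol
  }
  vol / 1000
}

#' Area-weighted outward vertex normals
#'
#' Each vertex normal is the normalised sum of incident face normals weighted
#' by face area (the cross product magnitude carries the weighting).
#'
#' @inheritParams surface_volume
#' @return Matrix of unit normals, one row per vertex; rows for vertices with
#'   no incident face are NA.
#' @export
vertex_normals <- function(mesh, surface = NULL) {
  f <- if (is.null(surface)) mesh$faces else surface_faces(mesh, surface)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    nrm[, 1] <- nrm[, 1] + rowsum_vec(fn[, 1], f[, k], nrow(v))
    nrm[, 2] <- nrm[, 2] + rowsum_vec(fn[, 2], f[, k], nrow(v))
    nrm[, 3] <- nrm[, 3] + rowsum_vec(fn[, 3], f[, k], nrow(v))
  }
  len <- sqrt(rowSums(nrm^2))
  touched <- tabulate(f, nbins = nrow(v)) > 0L
  nrm <- nrm / ifelse(len > 0, len, 1)
  nrm[!touched, ] <- NA_real_
  if (any(touched & len == 0)) {
    stop("zero-magnitude normal at vertex ",
         paste(which(touched & len == 0)[1:min(5, sum(touched & len == 0))],
               collapse = ", "))
  }
  nrm
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Offset a surface along its outward normals
#'
#' Displaces the vertices in `which_vertices` outward along their
#' area-weighted vertex normals, emulating the construction of a thin
#' epicardial shell around an endocardial surface (the right-ventricular wall
#' is conventionally approximated by a fixed 3 mm outward offset). The
#' topology is unchanged.
#'
#' @param mesh A [new_mesh()] object.
#' @param which_vertices Vertex index set to displace (e.g. the RV endocardial
#'   set). Default: all vertices of `surface`.
#' @param offset Offset distance along the outward normal, mm.
#' @param surface Vertex index set defining the closed surface used to compute
#'   normals. Default: all faces.
#' @return A new mesh with displaced vertices.
#' @export
impute_rv_epicardium <- function(mesh, which_vertices = NULL, offset = 3,
                                 surface = NULL) {
  if (offset == 0) return(mesh)
  nrm <- vertex_normals(mesh, surface)
  if (is.null(which_vertices)) {
    which_vertices <- which(!is.na(nrm[, 1]))
  }
  if (anyNA(nrm[which_vertices, ])) {
    stop("normals undefined for some requested vertices")
  }
  v <- mesh$vertices
  v[which_vertices, ] <- v[which_vertices, , drop = FALSE] +
    offset * nrm[which_vertices, , drop = FALSE]
  new_mesh(v, mesh$faces, validate = FALSE)
}

#' Arc length along a ring or line of vertices
#'
#' Sum of consecutive Euclidean segment lengths; a ring closes last-to-first.
#' These arc lengths are the `EDL`/`ESL` quantities in the geometric strain
#' definition.
#'
#' @param mesh A [new_mesh()] object.
#' @param ring,line Ordered vertex index vector (cyclic for `ring_arc_length`,
#'   open for `line_arc_length`).
#' @return Length in mm.
#' @export
ring_arc_length <- function(mesh, ring) {
  if (length(ring) < 3L) stop("a ring needs at least 3 vertices")
  path_length(mesh$vertices, c(ring, ring[1]))
}

#' @rdname ring_arc_length
#' @export
line_arc_length <- function(mesh, line) {
  if (length(line) < 2L) stop("a line needs at least 2 vertices")
  path_length(mesh$vertices, line)
}

path_length <- function(vertices, idx) {
  if (any(idx[-1] == idx[-length(idx)])) {
    stop("repeated consecutive vertex index in path")
  }
  p <- vertices[idx, , drop = FALSE]
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Axis-aligned cube mesh (test phantom)
#'
#' @param edge Edge length, mm.
#' @param origin Minimum corner.
#' @return A closed, outward-oriented 12-triangle mesh.
#' @export
unit_cube_mesh <- function(edge = 10, origin = c(0, 0, 0)) {
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  v <- sweep(as.matrix(g) * edge, 2, origin, `+`)
  # vertex order from expand.grid: index = 1 + x + 2y + 4z
  idx <- function(x, y, z) 1L + x + 2L * y + 4L * z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(idx(0,0,0), idx(0,1,0), idx(1,1,0), idx(1,0,0)),  # z = 0, normal -z
    quad(idx(0,0,1), idx(1,0,1), idx(1,1,1), idx(0,1,1)),  # z = 1, normal +z
    quad(idx(0,0,0), idx(1,0,0), idx(1,0,1), idx(0,0,1)),  # y = 0
    quad(idx(0,1,0), idx(0,1,1), idx(1,1,1), idx(1,1,0)),  # y = 1
    quad(idx(0,0,0), idx(0,0,1), idx(0,1,1), idx(0,1,0)),  # x = 0
    quad(idx(1,0,0), idx(1,1,0), idx(1,1,1), idx(1,0,1))   # x = 1
  )
  new_mesh(v, f)
}

#' Refined icosphere / ellipsoid mesh (test phantom)
#'
#' Starts from a regular icosahedron, subdivides each triangle 4-ways
#' `subdivisions` times projecting onto the unit sphere, then scales by the
#' given semi-axes.
#'
#' @param semi_axes Length-3 semi-axes (mm).
#' @param subdivisions Number of 4-way refinement passes (4 gives 5120 faces).
#' @param center Center of the ellipsoid.
#' @return A closed, outward-oriented mesh.
#' @export
icosphere_mesh <- function(semi_axes = c(1, 1, 1), subdivisions = 3,
                           center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      m <- nrow(verts)
      edge_mid[[key]] <- m
      m
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v <- sweep(sweep(v, 2, semi_axes, `*`), 2, center, `+`)
  new_mesh(v, f)
}

# Apply a rigid transform (rotation matrix R, translation t) to all vertices.
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  new_mesh(sweep(mesh$vertices %*% R, 2, t, `+`), mesh$faces,
           validate = FALSE)
}

#' Voxelisation volume estimate (brute-force cross-check)
#'
#' Counts regular-grid voxel centers inside the closed surface by parity of
#' ray-triangle crossings along +z. Slow; intended as an independent oracle
#' for [surface_volume()] on small phantoms.
#'
#' @inheritParams surface_volume
#' @param resolution Voxels along the largest bounding-box side.
#' @return Volume in mL.
#' @export
voxel_volume <- function(mesh, surface = NULL, resolution = 40) {
  f <- if (is.null(surface)) mesh$faces else surface_faces(mesh, surface)
  v <- mesh$vertices
  used <- sort(unique(as.vector(f)))
  lo <- apply(v[used, ], 2, min)
  hi <- apply(v[used, ], 2, max)
  h <- max(hi - lo) / resolution
  xs <- seq(lo[1] + h / 2, hi[1], by = h)
  ys <- seq(lo[2] + h / 2, hi[2], by = h)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  inside_count <- 0L
  for (x in xs) for (y in ys) {
    # 2D point-in-triangle test in xy; collect z crossings
    d1 <- (b[, 1] - a[, 1]) * (y - a[, 2]) - (b[, 2] - a[, 2]) * (x - a[, 1])
    d2 <- (c_[, 1] - b[, 1]) * (y - b[, 2]) - (c_[, 2] - b[, 2]) * (x - b[, 1])
    d3 <- (a[, 1] - c_[, 1]) * (y - c_[, 2]) - (a[, 2] - c_[, 2]) * (x - c_[, 1])
    hit <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    if (!any(hit)) next
    ah <- a[hit, , drop = FALSE]; bh <- b[hit, , drop = FALSE]
    ch <- c_[hit, , drop = FALSE]
    det <- (bh[, 1] - ah[, 1]) * (ch[, 2] - ah[, 2]) -
           (ch[, 1] - ah[, 1]) * (bh[, 2] - ah[, 2])
    ok <- abs(det) > 1e-12
    if (!any(ok)) next
    w1 <- ((bh[, 1] - x) * (ch[, 2] - y) - (ch[, 1] - x) * (bh[, 2] - y)) / det
    w2 <- ((ch[, 1] - x) * (ah[, 2] - y) - (ah[, 1] - x) * (ch[, 2] - y)) / det
    w3 <- 1 - w1 - w2
    zc <- (w1 * ah[, 3] + w2 * bh[, 3] + w3 * ch[, 3])[ok]
    zs <- sort(zc)
    if (length(zs) >= 2L) {
      # voxel centers along z sit at lo[3] + h/2 + k*h
      n_below <- function(z) max(0, floor((z - lo[3]) / h + 0.5))
      for (i in seq(1L, length(zs) - 1L, by = 2L)) {
        inside_count <- inside_count + n_below(zs[i + 1]) - n_below(zs[i])
      }
    }
  }
  inside_count * h^3 / 1000
}
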