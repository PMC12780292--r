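# Analytic biventricular template: truncated prolate spheroids for the LV
# endo/epicardium, a laterally attached crescent-section shell for the RV
# endocardium, and a fixed 3 mm normal-offset RV epicardium. Each surface is
# closed (basal cap + apex fan) so divergence-theorem volumes are defined,
# and carries ring / long-line labels for arc-length strain.

# Build one closed surface of stacked rings. `ring_xyz` is an R-list of P x 3
# matrices ordered base -> apex; `base_center` and `apex` are 3-vectors.
# Vertex order: base_center, rings (base->apex, each P vertices), apex.
ring_surface <- function(ring_xyz, base_center, apex) {
  n_r <- length(ring_xyz)
  P <- nrow(ring_xyz[[1]])
  v <- rbind(base_center, do.call(rbind, ring_xyz), apex)
  i_base <- 1L
  i_apex <- nrow(v)
  ring_idx <- function(k) 1L + (k - 1L) * P + seq_len(P)
  nxt <- function(j) j %% P + 1L
  faces <- vector("list", n_r + 1L)
  r1 <- ring_idx(1)
  faces[[1]] <- cbind(i_base, r1, r1[nxt(seq_len(P))])          # base cap
  for (k in seq_len(n_r - 1L)) {
    a <- ring_idx(k); b <- ring_idx(k + 1L)
    j <- seq_len(P); jn <- nxt(j)
    faces[[k + 1L]] <- rbind(cbind(a[j], b[j], b[jn]),
                             cbind(a[j], b[jn], a[jn]))
  }
  rk <- ring_idx(n_r)
  faces[[n_r + 1L]] <- cbind(i_apex, rk[nxt(seq_len(P))], rk)   # apex fan
  f <- do.call(rbind, faces)
  mesh <- new_mesh(v, f)
  # fix orientation deterministically (no reliance on winding bookkeeping)
  if (signed_volume6(mesh) < 0) mesh <- new_mesh(v, f[, c(1, 3, 2)])
  list(mesh = mesh, rings = lapply(seq_len(n_r), ring_idx),
       base_center = i_base, apex = i_apex)
}

signed_volume6 <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))
}

# Truncated prolate spheroid rings: semi-axes (a, a, c), apex at z = -c,
# base plane at z = f_base * c. Crescent factor w modulates ring radius with
# angle, r(theta) = a sin(phi) (1 + w cos theta), giving the RV's
# kidney-shaped cross-section when w > 0.
spheroid_rings <- function(a, c_ax, f_base, n_rings, p_ring, center = c(0, 0, 0),
                           crescent = 0) {
  phi_b <- acos(f_base)
  phi <- phi_b + (seq_len(n_rings) - 1L) / n_rings * (pi - phi_b)
  th <- 2 * pi * (seq_len(p_ring) - 1L) / p_ring
  rings <- lapply(phi, function(p) {
    r <- a * sin(p) * (1 + crescent * cos(th))
    cbind(center[1] + r * cos(th), center[2] + r * sin(th),
          center[3] + c_ax * cos(p))
  })
  list(rings = rings,
       base_center = center + c(0, 0, c_ax * f_base),
       apex = center + c(0, 0, -c_ax))
}

# Closed-form volume of the truncated spheroid (cap cut at z = f*c).
spheroid_truncated_volume <- function(a, c_ax, f_base, crescent = 0) {
  pi * a^2 * (1 + crescent^2 / 2) * c_ax * (f_base - f_base^3 / 3 + 2 / 3) / 1000
}

#' Build the analytic biventricular template shape
#'
#' Constructs a synthetic, fully labeled biventricular anatomy: LV endo- and
#' epicardial surfaces as truncated prolate spheroids sharing the long axis,
#' an RV endocardial shell with a crescent cross-section attached laterally,
#' and an RV epicardium obtained by a 3 mm outward normal offset. The ES
#' frame applies per-surface circumferential contraction about the long axis
#' plus a basal descent that carries the valve rings toward the apex, with a
#' linear apex-to-base weighting. Default dimensions are calibrated so the
#' template's metrics sit near healthy mid-life reference values
#' (LVEDV ~146 mL, LVEF ~54%, LV mass ~123 g, MAPSE ~12 mm, GCS ~27%).
#'
#' @param rings_per_surface Number of short-axis rings per surface (>= 6).
#' @param points_per_ring Vertices per ring (>= 16).
#' @param lv_radii LV endocardial short and long semi-axes (a, c), mm.
#' @param wall_thickness LV wall thickness, mm.
#' @param rv_params List: `r0` (short semi-axis), `c` (long semi-axis),
#'   `crescent` (cross-section modulation), `x0` (lateral offset of the RV
#'   axis), `f_base` (base truncation fraction), `epi_offset` (mm).
#' @param es_contraction Named fractional inward contraction at ES per
#'   surface (`lv_endo`, `lv_epi`, `rv_endo`, `rv_epi`).
#' @param es_basal_descent Named basal descent at ES, mm (`lv`, `rv`).
#' @param f_base LV base truncation fraction (z_base = f_base * c).
#' @param n_long_lines Long-axis lines kept per surface.
#' @return A [new_shape()] with fully populated labels.
#' @export
build_template <- function(rings_per_surface = 12,
                           points_per_ring = 28,
                           lv_radii = c(26, 55),
                           wall_thickness = 7.5,
                           rv_params = list(r0 = 24, c = 60, crescent = 0.45,
                                            x0 = 42, f_base = 0.7,
                                            epi_offset = 3),
                           es_contraction = c(lv_endo = 0.27, lv_epi = 0.12,
                                              rv_endo = 0.238, rv_epi = 0.12),
                           es_basal_descent = c(lv = 11.1, rv = 17.1),
                           f_base = 0.7,
                           n_long_lines = 8) {
  if (rings_per_surface < 6) stop("need at least 6 rings per surface")
  if (points_per_ring < 16) stop("need at least 16 points per ring")
  if (wall_thickness <= 0) stop("wall thickness must be positive")
  a <- lv_radii[1]; c_ax <- lv_radii[2]
  z_base <- f_base * c_ax

  mk <- function(a_, c_, center = c(0, 0, 0), crescent = 0, f_ = NULL) {
    fb <- if (is.null(f_)) (z_base - center[3]) / c_ else f_
    sr <- spheroid_rings(a_, c_, fb, rings_per_surface, points_per_ring,
                         center, crescent)
    ring_surface(sr$rings, sr$base_center, sr$apex)
  }
  lv_endo <- mk(a, c_ax)
  lv_epi <- mk(a + wall_thickness, c_ax + wall_thickness)
  rv_center <- c(rv_params$x0, 0,
                 z_base - rv_params$f_base * rv_params$c)
  rv_endo <- mk(rv_params$r0, rv_params$c, rv_center, rv_params$crescent,
                f_ = rv_params$f_base)
  rv_epi_mesh <- impute_rv_epicardium(rv_endo$mesh, offset = rv_params$epi_offset)
  rv_epi <- rv_endo
  rv_epi$mesh <- rv_epi_mesh

  parts <- list(lv_endo = lv_endo, lv_epi = lv_epi,
                rv_endo = rv_endo, rv_epi = rv_epi)
  offs <- cumsum(c(0, vapply(parts, function(p) nrow(p$mesh$vertices),
                             numeric(1))))[1:4]
  names(offs) <- names(parts)
  verts <- do.call(rbind, lapply(parts, function(p) p$mesh$vertices))
  faces <- do.call(rbind, Map(function(p, o) p$mesh$faces + as.integer(o),
                              parts, offs))
  rownames(verts) <- NULL

  surf_idx <- Map(function(p, o) seq_len(nrow(p$mesh$vertices)) + as.integer(o),
                  parts, offs)
  rings <- Map(function(p, o) lapply(p$rings, function(r) r + as.integer(o)),
               parts, offs)
  line_angles <- unique(round(seq(1, points_per_ring,
                                  length.out = n_long_lines + 1)))[seq_len(n_long_lines)]
  long_lines <- Map(function(p, o) {
    lapply(line_angles, function(j) {
      c(vapply(p$rings, function(r) r[j], integer(1)), p$apex) + as.integer(o)
    })
  }, parts, offs)

  labels <- new_labels(
    surfaces = surf_idx,
    valves = list(mitral = rings$lv_endo[[1]],
                  tricuspid = rings$rv_endo[[1]],
                  aortic = rings$lv_epi[[1]]),
    apex = lv_endo$apex + as.integer(offs["lv_endo"]),
    rings = rings,
    long_lines = long_lines)

  ed <- new_mesh(verts, faces)
  es_verts <- verts
  axis_x <- c(lv_endo = 0, lv_epi = 0, rv_endo = rv_params$x0,
              rv_epi = rv_params$x0)
  descent <- c(lv_endo = es_basal_descent[["lv"]],
               lv_epi = es_basal_descent[["lv"]],
               rv_endo = es_basal_descent[["rv"]],
               rv_epi = es_basal_descent[["rv"]])
  for (s in names(parts)) {
    idx <- surf_idx[[s]]
    p <- verts[idx, , drop = FALSE]
    kappa <- es_contraction[[s]]
    p[, 1] <- axis_x[[s]] + (1 - kappa) * (p[, 1] - axis_x[[s]])
    p[, 2] <- (1 - kappa) * p[, 2]
    zr <- range(verts[idx, 3])
    w <- (p[, 3] - zr[1]) / (zr[2] - zr[1])
    p[, 3] <- p[, 3] - descent[[s]] * w
    es_verts[idx, ] <- p
  }
  es <- new_mesh(es_verts, faces, validate = FALSE)

  shape <- new_shape("template", ed, es, labels)
  if (any(es_contraction != 0) || any(es_basal_descent > 0)) {
    edv <- surface_volume(ed, labels$surfaces$lv_endo)
    esv <- surface_volume(es, labels$surfaces$lv_endo)
    if (esv >= edv) stop("template ES LV volume >= ED volume despite ",
                         "requested contraction; invalid parameters")
  }
  shape
}
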