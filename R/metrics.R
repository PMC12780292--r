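# Standard functional metrics computed from the shape models: cavity
# volumes and EF, LV mass, geometric arc-length strain, MAPSE/TAPSE,
# Arts-formula afterload. All are pose-invariant and computed in native
# (pre-alignment) coordinates.

#' Geometric shortening strain
#'
#' Percent change in arc length between end-diastole and end-systole,
#' `((EDL - ESL) / EDL) * 100`; positive for contraction.
#'
#' @param edl,esl Arc lengths at ED and ES, mm.
#' @return Strain in % shortening.
#' @export
geometric_strain <- function(edl, esl) {
  if (any(edl <= 0)) stop("ED arc length must be positive")
  (edl - esl) / edl * 100
}

# Ring whose cumulative base-to-apex position is closest to 50%.
mid_ring_index <- function(shape, surface) {
  rings <- shape$labels$rings[[surface]]
  if (length(rings) < 3) stop("need at least 3 rings for a mid-ring strain")
  centers <- vapply(rings, function(r) mean(shape$ed$vertices[r, 3]),
                    numeric(1))
  pos <- cumsum(c(0, abs(diff(centers))))
  which.min(abs(pos / pos[length(pos)] - 0.5))
}

#' Global circumferential strain at the mid-ventricular ring
#'
#' Strain of the endocardial ring closest to 50% of the cumulative
#' base-to-apex distance; the same ring index is used at ED and ES.
#'
#' @param shape A [new_shape()] object.
#' @param ventricle `"lv"` or `"rv"`.
#' @return Strain in % shortening.
#' @export
gcs_mid <- function(shape, ventricle = c("lv", "rv")) {
  surface <- paste0(match.arg(ventricle), "_endo")
  k <- mid_ring_index(shape, surface)
  ring <- shape$labels$rings[[surface]][[k]]
  geometric_strain(ring_arc_length(shape$ed, ring),
                   ring_arc_length(shape$es, ring))
}

#' Global longitudinal strain
#'
#' Mean over the labeled base-to-apex endocardial lines of each line's
#' geometric strain (per-line averaging, robust to unequal line lengths;
#' the pooled-length variant is available via `pooled = TRUE`).
#'
#' @inheritParams gcs_mid
#' @param pooled Use strain of the summed lengths instead of the mean of
#'   per-line strains.
#' @return Strain in % shortening.
#' @export
gls <- function(shape, ventricle = c("lv", "rv"), pooled = FALSE) {
  surface <- paste0(match.arg(ventricle), "_endo")
  lines <- shape$labels$long_lines[[surface]]
  if (length(lines) == 0) stop("no longitudinal lines labeled for ", surface)
  edl <- vapply(lines, function(l) line_arc_length(shape$ed, l), numeric(1))
  esl <- vapply(lines, function(l) line_arc_length(shape$es, l), numeric(1))
  if (pooled) geometric_strain(sum(edl), sum(esl)) else
    mean(geometric_strain(edl, esl))
}

#' Valve annular plane systolic excursion (MAPSE / TAPSE)
#'
#' Mean 3D displacement of the valve-ring vertices from ED to ES, in native
#' coordinates (excursion is a physical motion, so it is computed before
#' any atlas alignment). Point-wise displacement magnitudes are averaged.
#'
#' @param shape A [new_shape()] object.
#' @param ring `"mitral"` or `"tricuspid"`.
#' @return Excursion in mm.
#' @export
valve_excursion <- function(shape, ring = c("mitral", "tricuspid")) {
  idx <- shape$labels$valves[[match.arg(ring)]]
  if (length(idx) == 0) stop("empty valve ring")
  d <- shape$es$vertices[idx, , drop = FALSE] -
       shape$ed$vertices[idx, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Arts-formula afterload index
#'
#' End-systolic myocyte stress estimate from adjusted systolic blood
#' pressure, LV end-systolic cavity volume and LV wall volume at ED. The
#' default is the product form `SBP * (1 + 3 * LVESV / LVWallVolume)`; the
#' logarithmic fiber-stress variant `3 * SBP / log(1 + 3 * LVESV /
#' LVWallVolume)` is selectable.
#'
#' @param sbp_adjusted Medication-adjusted SBP, mmHg.
#' @param lvesv LV end-systolic volume, mL.
#' @param lv_wall_volume LV wall volume at ED, mL.
#' @param variant `"product"` (default) or `"arts-log"`.
#' @return Stress index (mmHg-scaled).
#' @export
afterload <- function(sbp_adjusted, lvesv, lv_wall_volume,
                      variant = c("product", "arts-log")) {
  variant <- match.arg(variant)
  if (any(lv_wall_volume <= 0)) stop("LV wall volume must be positive")
  if (any(lvesv < 0)) stop("LVESV must be non-negative")
  ratio <- 3 * lvesv / lv_wall_volume
  if (variant == "product") {
    sbp_adjusted * (1 + ratio)
  } else {
    if (any(ratio <= 0)) stop("arts-log variant requires LVESV > 0")
    3 * sbp_adjusted / log(1 + ratio)
  }
}

metric_one_shape <- function(shape, density = 1.05,
                             afterload_variant = "product",
                             sbp_adjusted = NA_real_) {
  lab <- shape$labels$surfaces
  lvedv <- surface_volume(shape$ed, lab$lv_endo)
  lvesv <- surface_volume(shape$es, lab$lv_endo)
  rvedv <- surface_volume(shape$ed, lab$rv_endo)
  rvesv <- surface_volume(shape$es, lab$rv_endo)
  wall <- lv_wall_volume(shape, "ed")
  tibble::tibble(
    id = as.character(shape$id),
    LVEDV = lvedv, LVESV = lvesv, RVEDV = rvedv, RVESV = rvesv,
    LVM = wall * density,
    LVEF = 100 * (lvedv - lvesv) / lvedv,
    RVEF = 100 * (rvedv - rvesv) / rvedv,
    LV_GCS_mid = gcs_mid(shape, "lv"),
    LV_GLS = gls(shape, "lv"),
    RV_GCS_mid = gcs_mid(shape, "rv"),
    RV_GLS = gls(shape, "rv"),
    MAPSE = valve_excursion(shape, "mitral"),
    TAPSE = valve_excursion(shape, "tricuspid"),
    afterload = if (is.na(sbp_adjusted)) NA_real_ else
      afterload(sbp_adjusted, lvesv, wall, afterload_variant))
}

#' Compute the standard metric table for a cohort
#'
#' One row per participant: cavity volumes (mL), LV mass (g), ejection
#' fractions (%), mid-ventricular GCS and GLS (% shortening), MAPSE/TAPSE
#' (mm) and the afterload index. Per-shape failures are caught, flagged in
#' the `ok`/`note` columns and never silently dropped.
#'
#' @param shapes List of [new_shape()] objects (native coordinates).
#' @param records Optional participant tibble with `id`, `sbp_raw`,
#'   `bp_medication` (for the afterload column).
#' @param density Myocardial density, g/mL.
#' @param afterload_variant Passed to [afterload()].
#' @return A tibble of metrics, one row per shape.
#' @export
compute_metric_table <- function(shapes, records = NULL, density = 1.05,
                                 afterload_variant = "product") {
  sbp <- rep(NA_real_, length(shapes))
  if (!is.null(records)) {
    adj <- adjust_sbp(records$sbp_raw, records$bp_medication)
    m <- match(vapply(shapes, function(s) as.character(s$id), character(1)),
               records$id)
    sbp <- adj[m]
  }
  rows <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    rows[[i]] <- tryCatch({
      r <- metric_one_shape(shapes[[i]], density, afterload_variant, sbp[i])
      r$ok <- TRUE
      r$note <- NA_character_
      r
    }, error = function(e) {
      tibble::tibble(id = as.character(shapes[[i]]$id),
                     LVEDV = NA_real_, LVESV = NA_real_, RVEDV = NA_real_,
                     RVESV = NA_real_, LVM = NA_real_, LVEF = NA_real_,
                     RVEF = NA_real_, LV_GCS_mid = NA_real_, LV_GLS = NA_real_,
                     RV_GCS_mid = NA_real_, RV_GLS = NA_real_,
                     MAPSE = NA_real_, TAPSE = NA_real_, afterload = NA_real_,
                     ok = FALSE, note = conditionMessage(e))
    })
  }
  dplyr::bind_rows(rows)
}
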