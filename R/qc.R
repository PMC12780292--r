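# Quality-control gates: model-fit sanity, Mahalanobis score outliers,
# atlas projection error, volume consistency against an independent
# estimate. Gates are pure functions; the report counts per-criterion and
# union rejections (cases commonly fail several criteria at once).

#' Model-fit quality gate
#'
#' Fails on non-finite coordinates, non-positive cavity or wall volumes,
#' ESV >= EDV in either ventricle, or open labeled surfaces.
#'
#' @param shape A [new_shape()] object.
#' @return List with `ok` (flag) and `reasons` (character).
#' @export
qc_fit <- function(shape) {
  reasons <- character()
  if (!all(is.finite(shape$ed$vertices)) || !all(is.finite(shape$es$vertices))) {
    return(list(ok = FALSE, reasons = "non-finite coordinates"))
  }
  lab <- shape$labels$surfaces
  vols <- tryCatch({
    list(lvedv = surface_volume(shape$ed, lab$lv_endo),
         lvesv = surface_volume(shape$es, lab$lv_endo),
         rvedv = surface_volume(shape$ed, lab$rv_endo),
         rvesv = surface_volume(shape$es, lab$rv_endo),
         epi = surface_volume(shape$ed, lab$lv_epi))
  }, error = function(e) e)
  if (inherits(vols, "error")) {
    return(list(ok = FALSE, reasons = paste("open surface:",
                                            conditionMessage(vols))))
  }
  if (vols$lvedv <= 0 || vols$rvedv <= 0) reasons <- c(reasons, "non-positive cavity volume")
  if (vols$epi - vols$lvedv <= 0) reasons <- c(reasons, "non-positive wall volume")
  if (vols$lvesv >= vols$lvedv) reasons <- c(reasons, "LV ESV>=EDV")
  if (vols$rvesv >= vols$rvedv) reasons <- c(reasons, "RV ESV>=EDV")
  list(ok = length(reasons) == 0, reasons = reasons)
}

#' Mahalanobis-distance quality gate
#'
#' Fails when the squared score-space distance exceeds the chi-square
#' upper-`alpha` quantile with k (retained components) degrees of freedom.
#'
#' @param scores Score vector or matrix (rows = cases) of retained PCs.
#' @param atlas A fitted [fit_atlas()] object.
#' @param alpha Upper tail probability (default 0.001).
#' @return Logical pass flag(s).
#' @export
qc_mahalanobis <- function(scores, atlas, alpha = 0.001) {
  k <- if (is.matrix(scores)) ncol(scores) else length(scores)
  d2 <- mahalanobis_distance(atlas, scores)^2
  d2 <= stats::qchisq(1 - alpha, df = k)
}

#' Projection-error quality gate
#'
#' Fails when the rank-k RMS projection error exceeds `threshold_mm`. The
#' default threshold is calibrated from the training cohort as
#' `median + 5 * MAD` of its projection errors (see
#' [qc_projection_threshold()]).
#'
#' @param vectors Shape vector or matrix of row vectors.
#' @param atlas A fitted [fit_atlas()] object.
#' @param k Components in the reconstruction.
#' @param threshold_mm Rejection threshold, mm.
#' @return Logical pass flag(s).
#' @export
qc_projection <- function(vectors, atlas, k = atlas$n_components,
                          threshold_mm) {
  projection_error(atlas, vectors, k) <= threshold_mm
}

#' @rdname qc_projection
#' @param training_vectors Matrix of training-cohort shape vectors.
#' @export
qc_projection_threshold <- function(atlas, training_vectors,
                                    k = atlas$n_components) {
  e <- projection_error(atlas, training_vectors, k)
  stats::median(e) + 5 * stats::mad(e)
}

#' Volume-consistency quality gate
#'
#' Fails when the model LVEDV differs from an independent estimate by more
#' than `rel_tol` (relative). In the synthetic pipeline the independent
#' value is the generator's ground truth; with real data it would be an
#' independent (e.g. slice-summation) measurement. Boundary cases exactly
#' at tolerance pass.
#'
#' @param model_lvedv,independent_lvedv Volumes, mL (vectorized).
#' @param rel_tol Relative tolerance (default 0.20).
#' @return Logical pass flag(s).
#' @export
qc_volume_consistency <- function(model_lvedv, independent_lvedv,
                                  rel_tol = 0.20) {
  if (any(independent_lvedv <= 0)) stop("independent volume must be positive")
  abs(model_lvedv - independent_lvedv) / independent_lvedv <= rel_tol
}

#' Multi-criteria QC report
#'
#' @param flags Tibble/data frame with `id` and logical pass columns
#'   `fit_ok`, `mahalanobis_ok`, `projection_ok`, `volume_ok` (any subset).
#' @param thresholds Optional named list echoed into the report.
#' @return An object of class `"qc_report"`: the flag table, per-criterion
#'   rejection counts, and the union rejection count (always <= the sum,
#'   since cases may fail several criteria).
#' @export
qc_report <- function(flags, thresholds = list()) {
  flags <- tibble::as_tibble(flags)
  crit <- setdiff(names(flags), "id")
  per <- vapply(crit, function(cn) sum(!flags[[cn]], na.rm = TRUE), integer(1))
  any_fail <- rowSums(!as.matrix(flags[crit]), na.rm = TRUE) > 0
  structure(list(flags = flags,
                 per_criterion = per,
                 n_rejected = sum(any_fail),
                 n_total = nrow(flags),
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_total, " cases, ", x$n_rejected,
      " rejected by >=1 criterion\n", sep = "")
  for (cn in names(x$per_criterion)) {
    cat("  ", cn, ": ", x$per_criterion[[cn]], " rejected\n", sep = "")
  }
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes `qc_report.json` (counts + thresholds) and `qc_flags.csv`.
#'
#' @param report A [qc_report()] object.
#' @param dir Output directory.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(n_total = report$n_total, n_rejected = report$n_rejected,
         per_criterion = as.list(report$per_criterion),
         thresholds = report$thresholds),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$flags, file.path(dir, "qc_flags.csv"),
                   row.names = FALSE)
  invisible(dir)
}
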