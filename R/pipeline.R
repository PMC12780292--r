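# Configuration-driven end-to-end orchestration. Each stage reads its
# upstream artifacts from the output directory, is idempotent given the
# same config and seed, and logs a QC funnel.

#' Load and validate a pipeline configuration
#'
#' YAML with sections `cohort` (passed to [cohort_spec()]), `atlas`
#' (`variance_fraction`, `max_components`, `alignment` = consensus |
#' reference), `qc` (`mahalanobis_alpha`, `projection_mad_mult`,
#' `volume_rel_tol`), `metrics` (`density`, `afterload_variant`) and
#' `discrimination` (`folds`, `seed`, `vif_threshold`). Unknown keys are
#' rejected.
#'
#' @param path YAML file path, or a list already in config form.
#' @param seed Optional override of the cohort seed.
#' @return Validated config list of class `"pipeline_config"`.
#' @export
load_config <- function(path, seed = NULL) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("cohort", "atlas", "qc", "metrics", "discrimination", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults <- list(
    cohort = list(),
    atlas = list(variance_fraction = 0.90, max_components = 25,
                 alignment = "consensus"),
    qc = list(mahalanobis_alpha = 0.001, projection_mad_mult = 5,
              volume_rel_tol = 0.20),
    metrics = list(density = 1.05, afterload_variant = "product"),
    discrimination = list(folds = 5, seed = 1, vif_threshold = 5),
    out_dir = "bivatlas_out")
  for (sec in names(defaults)) {
    if (sec == "out_dir") next
    extra <- setdiff(names(cfg[[sec]]),
                     unique(c(names(defaults[[sec]]),
                              names(formals(cohort_spec)))))
    if (length(extra)) stop("unknown key(s) in '", sec, "': ",
                            paste(extra, collapse = ", "))
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  if (!is.null(cfg$out_dir)) defaults$out_dir <- cfg$out_dir
  if (!is.null(seed)) defaults$cohort$seed <- as.integer(seed)
  structure(defaults, class = "pipeline_config")
}

pipeline_log <- function(...) message("[bivatlas] ", ...)

cohort_from_config <- function(config) {
  sp <- config$cohort
  sp$n_disease <- unlist(sp$n_disease)
  sp$disease_shift <- lapply(sp$disease_shift, unlist)
  do.call(cohort_spec, sp[lengths(sp) > 0 | names(sp) == "mode_variances"])
}

#' Pipeline stages
#'
#' `cmd_simulate()` writes the synthetic cohort (per-participant PLY + JSON
#' shapes, `participants.csv`, manifest); `cmd_atlas()` aligns, fits and
#' serializes the atlas plus `scores.csv`; `cmd_metrics()` writes
#' `metrics.csv`; `cmd_qc()` writes the QC report; `cmd_discriminate()`
#' writes the discrimination report; `cmd_all()` chains all stages.
#'
#' @param config A [load_config()] object (or a path / list accepted by it).
#' @return Each stage invisibly returns its main artifact.
#' @export
cmd_simulate <- function(config) {
  config <- as_config(config)
  out <- config$out_dir
  dir.create(file.path(out, "shapes"), recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_from_config(config)
  template <- build_template()
  modes <- build_mode_bank(template)
  sim <- simulate_cohort(template, modes, spec)
  pipeline_log("simulated ", length(sim$shapes), " shapes (seed ",
               spec$seed, ")")
  for (s in sim$shapes) write_shape(s, file.path(out, "shapes", s$id))
  utils::write.csv(sim$records, file.path(out, "participants.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = spec$seed, n = length(sim$shapes),
                            noise_sd = spec$noise_sd,
                            groups = as.list(table(sim$records$group))),
                       file.path(out, "cohort_manifest.json"),
                       auto_unbox = TRUE)
  invisible(sim)
}

as_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else load_config(config)
}

read_cohort <- function(out) {
  csv <- file.path(out, "participants.csv")
  if (!file.exists(csv)) {
    stop("missing participants.csv in ", out, "; run cmd_simulate first")
  }
  records <- tibble::as_tibble(utils::read.csv(csv))
  shapes <- lapply(records$id, function(id) {
    read_shape(file.path(out, "shapes", id), id = id)
  })
  list(shapes = shapes, records = records)
}

#' @rdname cmd_simulate
#' @export
cmd_atlas <- function(config) {
  config <- as_config(config)
  out <- config$out_dir
  co <- read_cohort(out)
  fit_ok <- vapply(co$shapes, function(s) qc_fit(s)$ok, logical(1))
  pipeline_log("fit QC: ", sum(!fit_ok), " of ", length(fit_ok), " rejected")
  ref <- if (identical(config$atlas$alignment, "reference")) {
    co$shapes[[1]]$ed$vertices
  } else NULL
  gpa <- generalized_procrustes(co$shapes[fit_ok], reference = ref)
  X <- do.call(rbind, lapply(gpa$shapes, concat_vector))
  atlas <- fit_atlas(X, variance_fraction = config$atlas$variance_fraction,
                     max_components = config$atlas$max_components,
                     reference_mean_ed = gpa$mean_ed)
  pipeline_log("atlas: ", atlas$n_components, " components retained")
  write_atlas(atlas, file.path(out, "atlas.rds"))
  sc <- score_table(atlas, gpa$shapes)
  utils::write.csv(sc, file.path(out, "scores.csv"), row.names = FALSE)
  invisible(atlas)
}

#' @rdname cmd_simulate
#' @export
cmd_metrics <- function(config) {
  config <- as_config(config)
  out <- config$out_dir
  co <- read_cohort(out)
  mt <- compute_metric_table(co$shapes, co$records,
                             density = config$metrics$density,
                             afterload_variant = config$metrics$afterload_variant)
  utils::write.csv(mt, file.path(out, "metrics.csv"), row.names = FALSE)
  pipeline_log("metrics: ", sum(!mt$ok), " of ", nrow(mt), " rows flagged")
  invisible(mt)
}

#' @rdname cmd_simulate
#' @export
cmd_qc <- function(config) {
  config <- as_config(config)
  out <- config$out_dir
  co <- read_cohort(out)
  atlas_path <- file.path(out, "atlas.rds")
  if (!file.exists(atlas_path)) stop("missing atlas.rds; run cmd_atlas first")
  atlas <- read_atlas(atlas_path)
  fit_ok <- vapply(co$shapes, function(s) qc_fit(s)$ok, logical(1))
  gpa <- generalized_procrustes(co$shapes,
                                reference = atlas$reference_mean_ed)
  X <- do.call(rbind, lapply(gpa$shapes, concat_vector))
  S <- project(atlas, X)
  maha_ok <- qc_mahalanobis(S, atlas, config$qc$mahalanobis_alpha)
  thr <- qc_projection_threshold(atlas, X)
  proj_ok <- qc_projection(X, atlas, threshold_mm = thr)
  mt_path <- file.path(out, "metrics.csv")
  vol_ok <- if (file.exists(mt_path) && !is.null(co$records$gt_lvedv)) {
    mt <- utils::read.csv(mt_path)
    qc_volume_consistency(mt$LVEDV[match(co$records$id, mt$id)],
                          co$records$gt_lvedv, config$qc$volume_rel_tol)
  } else rep(TRUE, nrow(co$records))
  rep_ <- qc_report(tibble::tibble(id = co$records$id, fit_ok = fit_ok,
                                   mahalanobis_ok = maha_ok,
                                   projection_ok = proj_ok,
                                   volume_ok = vol_ok),
                    thresholds = list(
                      mahalanobis_alpha = config$qc$mahalanobis_alpha,
                      projection_mm = thr,
                      volume_rel_tol = config$qc$volume_rel_tol))
  pipeline_log("QC funnel: fit ", sum(!fit_ok), ", mahalanobis ",
               sum(!maha_ok), ", projection ", sum(!proj_ok), ", volume ",
               sum(!vol_ok), "; union ", rep_$n_rejected)
  write_qc_report(rep_, out)
  invisible(rep_)
}

#' @rdname cmd_simulate
#' @export
cmd_discriminate <- function(config) {
  config <- as_config(config)
  out <- config$out_dir
  need <- file.path(out, c("participants.csv", "scores.csv", "metrics.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing upstream artifact(s): ",
                         paste(basename(miss), collapse = ", "),
                         "; run earlier stages first")
  records <- tibble::as_tibble(utils::read.csv(file.path(out, "participants.csv")))
  scores <- tibble::as_tibble(utils::read.csv(file.path(out, "scores.csv")))
  metrics <- tibble::as_tibble(utils::read.csv(file.path(out, "metrics.csv")))
  res <- run_discrimination(
    scores, metrics,
    dplyr::select(records, "id", "age", "sex", "bmi", "height"),
    dplyr::transmute(records, id = .data$id,
                     group = ifelse(.data$group == "Reference", "Reference",
                                    .data$group)),
    folds = config$discrimination$folds,
    seed = config$discrimination$seed,
    vif_threshold = config$discrimination$vif_threshold)
  write_discrimination_report(res, out)
  pipeline_log("discrimination: ", nrow(res), " model comparisons written")
  invisible(res)
}

#' @rdname cmd_simulate
#' @export
cmd_all <- function(config) {
  config <- as_config(config)
  cmd_simulate(config)
  cmd_atlas(config)
  cmd_metrics(config)
  cmd_qc(config)
  res <- cmd_discriminate(config)
  # echo the config for reproducibility
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config_echo.yaml"))
  invisible(res)
}
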