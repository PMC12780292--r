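# Per-disease discrimination protocol: PC-score vs standard-metric LDA with
# shared-fold cross-validated AUC, DeLong comparison, VIF pruning, combined
# z-scores, per-metric Wilcoxon tests.

standard_metric_names <- function() {
  c("LVEDV", "LVESV", "RVEDV", "RVESV", "LVM", "LVEF", "RVEF",
    "LV_GCS_mid", "LV_GLS", "RV_GCS_mid", "RV_GLS", "MAPSE", "TAPSE")
}

covariate_columns <- function(covariate_table,
                              covariates = c("age", "sex", "bmi", "height",
                                             "afterload")) {
  out <- list()
  for (cv in covariates) {
    if (cv == "sex") {
      out$sex <- as.numeric(covariate_table$sex == "male")
    } else {
      out[[cv]] <- covariate_table[[cv]]
    }
  }
  do.call(cbind, out)
}

#' Compare PC-score and standard-metric disease discrimination
#'
#' For each disease group versus the reference cohort, builds the model
#' comparisons of the discrimination protocol:
#' * `pc_vs_standard` — PC scores vs standard metrics;
#' * `pc_cov_vs_standard_cov` — both models plus covariates (age, sex, BMI,
#'   height, afterload);
#' * `pc_standard_cov_vs_standard_cov` — PCs + standard + covariates vs
#'   standard + covariates, with VIF pruning applied to the combined model.
#'
#' Each comparison fits both LDA models with a shared stratified fold
#' assignment, pools the out-of-fold scores, compares AUCs with the DeLong
#' test, and reports combined z-score summaries (reference standardized to
#' mean 0, SD 1) plus per-metric Wilcoxon p-values.
#'
#' @param scores_table Tibble `id`, `pc1..pck` from [score_table()].
#' @param metric_table Tibble from [compute_metric_table()].
#' @param covariate_table Tibble with `id`, `age`, `sex`, `bmi`, `height`
#'   (afterload is taken from `metric_table`).
#' @param disease_labels Tibble with `id`, `group` (`"Reference"` or a
#'   disease name).
#' @param folds Number of CV folds.
#' @param seed Fold-assignment seed (shared between compared models).
#' @param comparisons Subset of the comparison names above.
#' @param vif_threshold VIF threshold for the combined model pruning.
#' @param apply_vif_standard Also prune the standard model's features
#'   (reported either way).
#' @return An object of class `"discrimination_result"`: a tibble with one
#'   row per disease and comparison (`auc_pc`, `auc_standard`, `delong_z`,
#'   `delong_p`, n's, z-score summaries) plus list-columns with retained
#'   features; Wilcoxon per-metric p-values in `attr(, "wilcoxon")`.
#' @export
run_discrimination <- function(scores_table, metric_table, covariate_table,
                               disease_labels,
                               folds = 5, seed = 1L,
                               comparisons = c("pc_vs_standard",
                                               "pc_cov_vs_standard_cov",
                                               "pc_standard_cov_vs_standard_cov"),
                               vif_threshold = 5,
                               apply_vif_standard = FALSE) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  tab <- dplyr::inner_join(disease_labels, scores_table, by = "id") |>
    dplyr::inner_join(metric_table, by = "id") |>
    dplyr::inner_join(covariate_table, by = "id")
  if (!is.null(tab$ok)) tab <- dplyr::filter(tab, .data$ok)
  pc_cols <- grep("^pc[0-9]+$", names(tab), value = TRUE)
  std_cols <- intersect(standard_metric_names(), names(tab))
  ref <- tab$group == "Reference"
  if (!any(ref)) stop("no reference group in disease_labels")
  diseases <- setdiff(unique(tab$group), "Reference")

  rows <- list()
  wilcox <- list()
  for (dz in diseases) {
    sub <- tab[ref | tab$group == dz, ]
    y <- sub$group == dz
    n_dz <- sum(y)
    if (n_dz < 2 * folds) {
      message("skipping '", dz, "': only ", n_dz,
              " cases (< 2 x ", folds, " folds)")
      next
    }
    X_pc <- as.matrix(sub[pc_cols])
    X_std <- as.matrix(sub[std_cols])
    X_cov <- covariate_columns(sub)
    shared_folds <- make_stratified_folds(y, folds, seed)

    retained_std <- as.character(
      vif_prune(X_std, threshold = vif_threshold))
    if (apply_vif_standard) {
      X_std_used <- X_std[, retained_std, drop = FALSE]
    } else {
      X_std_used <- X_std
    }

    wilcox[[dz]] <- tibble::tibble(
      disease = dz,
      metric = std_cols,
      p = vapply(std_cols, function(mc) {
        wilcoxon_rank_sum(sub[[mc]][y], sub[[mc]][!y])$p
      }, numeric(1)))

    for (cmp in comparisons) {
      feats <- switch(cmp,
        pc_vs_standard = list(a = X_pc, b = X_std_used,
                              retained = retained_std),
        pc_cov_vs_standard_cov = list(a = cbind(X_pc, X_cov),
                                      b = cbind(X_std_used, X_cov),
                                      retained = retained_std),
        pc_standard_cov_vs_standard_cov = {
          comb <- cbind(X_pc, X_std, X_cov)
          kept <- as.character(vif_prune(comb, threshold = vif_threshold))
          list(a = comb[, kept, drop = FALSE],
               b = cbind(X_std_used, X_cov), retained = kept)
        })
      cva <- cv_auc(feats$a, y, k = folds, folds = shared_folds)
      cvb <- cv_auc(feats$b, y, k = folds, folds = shared_folds)
      dl <- delong_compare(cva$scores, cvb$scores, y)

      z_pc <- combined_zscore(fit_lda(feats$a, y), feats$a, !y)
      z_std <- combined_zscore(fit_lda(feats$b, y), feats$b, !y)
      rows[[paste(dz, cmp)]] <- tibble::tibble(
        disease = dz, comparison = cmp,
        n_disease = n_dz, n_reference = sum(!y),
        auc_pc = dl$auc_a, auc_standard = dl$auc_b,
        delong_z = dl$z, delong_p = dl$p,
        z_ref_mean_pc = mean(z_pc[!y]), z_ref_sd_pc = stats::sd(z_pc[!y]),
        z_dz_mean_pc = mean(z_pc[y]), z_dz_sd_pc = stats::sd(z_pc[y]),
        z_ref_mean_std = mean(z_std[!y]), z_ref_sd_std = stats::sd(z_std[!y]),
        z_dz_mean_std = mean(z_std[y]), z_dz_sd_std = stats::sd(z_std[y]),
        retained = list(feats$retained),
        fold_seed = seed)
    }
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "wilcoxon") <- dplyr::bind_rows(wilcox)
  class(res) <- c("discrimination_result", class(res))
  res
}

#' Power table from a discrimination result
#'
#' Applies [power_two_sample()] to each disease's combined z-score effect
#' sizes (disease-group mean z for the PC and standard models).
#'
#' @param result A [run_discrimination()] result.
#' @param comparison Which comparison row to use.
#' @param alpha,power Passed to [power_two_sample()].
#' @return Tibble: disease, effect sizes and required totals per model.
#' @export
power_table <- function(result, comparison = "pc_vs_standard",
                        alpha = 0.05, power = 0.80) {
  res <- dplyr::filter(result, .data$comparison == !!comparison)
  tibble::tibble(
    disease = res$disease,
    d_pc = res$z_dz_mean_pc,
    d_standard = res$z_dz_mean_std,
    n_total_pc = vapply(res$z_dz_mean_pc, function(d)
      power_two_sample(max(d, 1e-9), alpha, power)$n_total, numeric(1)),
    n_total_standard = vapply(res$z_dz_mean_std, function(d)
      power_two_sample(max(d, 1e-9), alpha, power)$n_total, numeric(1)))
}

#' Serialize a discrimination report
#'
#' Writes `discrimination_report.json` and per-disease/model
#' `roc_points.csv` is omitted here (scores are in the result); the JSON
#' carries AUC pairs, DeLong z/p, retained variables, z-score summaries
#' and the power table.
#'
#' @param result A [run_discrimination()] result.
#' @param dir Output directory.
#' @export
write_discrimination_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(seq_len(nrow(result)), function(i) {
    r <- result[i, ]
    list(disease = r$disease, comparison = r$comparison,
         auc_pc = r$auc_pc, auc_standard = r$auc_standard,
         delong_z = r$delong_z, delong_p = r$delong_p,
         retained = r$retained[[1]],
         z_scores = list(pc = c(ref_mean = r$z_ref_mean_pc,
                                ref_sd = r$z_ref_sd_pc,
                                disease_mean = r$z_dz_mean_pc,
                                disease_sd = r$z_dz_sd_pc),
                         standard = c(ref_mean = r$z_ref_mean_std,
                                      ref_sd = r$z_ref_sd_std,
                                      disease_mean = r$z_dz_mean_std,
                                      disease_sd = r$z_dz_sd_std)))
  })
  jsonlite::write_json(list(results = out,
                            power = power_table(result)),
                       file.path(dir, "discrimination_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
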