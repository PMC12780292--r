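# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape atlas
#'
#' One row per principal component: eigenvalue, variance fraction and
#' cumulative fraction.
#'
#' @param x A [fit_atlas()] object.
#' @param ... Unused.
#' @return A tibble: `component`, `variance`, `fraction`, `cumulative`,
#'   `retained`.
#' @export
tidy.shape_atlas <- function(x, ...) {
  fr <- x$variances / sum(x$variances)
  tibble::tibble(component = seq_along(x$variances),
                 variance = x$variances,
                 fraction = fr,
                 cumulative = cumsum(fr),
                 retained = seq_along(fr) <= x$n_components)
}

#' @rdname tidy.shape_atlas
#' @export
glance.shape_atlas <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples,
                 dim = length(x$mean_vector),
                 n_modes = length(x$variances),
                 n_components = x$n_components,
                 variance_retained = sum(x$variances[seq_len(x$n_components)]) /
                   sum(x$variances))
}

#' Tidy a fitted linear discriminant
#'
#' @param x A [fit_lda()] object.
#' @param ... Unused.
#' @return A tibble: `term`, `weight`.
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(term = x$features, weight = unname(x$weights))
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 intercept = x$intercept,
                 positive_level = x$levels[2])
}

#' Tidy a discrimination result
#'
#' @param x A [run_discrimination()] result.
#' @param ... Unused.
#' @return The flat comparison tibble (without list columns).
#' @export
tidy.discrimination_result <- function(x, ...) {
  tibble::as_tibble(x[setdiff(names(x), "retained")])
}

#' @rdname tidy.discrimination_result
#' @export
glance.discrimination_result <- function(x, ...) {
  tibble::tibble(n_diseases = length(unique(x$disease)),
                 n_comparisons = nrow(x),
                 pc_wins = sum(x$auc_pc > x$auc_standard & x$delong_p < 0.05))
}

#' Scree plot of a shape atlas
#'
#' @param object A [fit_atlas()] object.
#' @param n_components Components shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_atlas <- function(object, n_components = 25, ...) {
  td <- tidy(object)
  td <- td[seq_len(min(n_components, nrow(td))), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component,
                                   y = 100 * .data$fraction,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$cumulative),
                       linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$cumulative),
                        size = 1, colour = "grey30") +
    ggplot2::labs(x = "Principal component",
                  y = "Shape variance explained (%)",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}

#' AUC comparison plot of a discrimination result
#'
#' @param object A [run_discrimination()] result.
#' @param ... Unused.
#' @return A ggplot of paired AUCs per disease and comparison.
#' @export
autoplot.discrimination_result <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(cols = c("auc_pc", "auc_standard"),
                        names_to = "model", values_to = "auc") |>
    dplyr::mutate(model = ifelse(.data$model == "auc_pc",
                                 "PC scores", "Standard metrics"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$disease, y = .data$auc,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip(ylim = c(0.5, 1)) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = NULL, y = "Cross-validated AUC", fill = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve from pooled scores
#'
#' @param scores Numeric scores (higher = disease).
#' @param y Two-level class vector (second level positive).
#' @param label Curve label.
#' @return A ggplot.
#' @export
plot_roc <- function(scores, y, label = "model") {
  yl <- as_two_level(y)
  ord <- order(scores, decreasing = TRUE)
  pos <- yl[ord] == levels(yl)[2]
  df <- tibble::tibble(tpr = c(0, cumsum(pos) / sum(pos)),
                       fpr = c(0, cumsum(!pos) / sum(!pos)),
                       model = label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
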