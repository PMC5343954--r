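#' Plot a complexity profile
#'
#' Complexity function values against subword length, with the detected
#' exponentially increasing part shaded and the entropy point marked.
#'
#' @param object A `complexity_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.complexity_profile <- function(object, ...) {
  d <- tibble(n = seq_along(object$p), p = object$p)
  n0 <- entropy_point(object$sequence_length)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$p))
  if (!object$degenerate && !is.na(object$eip_first)) {
    gg <- gg + ggplot2::annotate(
      "rect", xmin = object$eip_first - 0.5, xmax = object$eip_last + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  gg +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = n0, linetype = "dashed") +
    ggplot2::labs(
      x = "subword length n", y = "distinct subwords p(n)",
      title = sprintf("Complexity profile (L = %d)", object$sequence_length),
      subtitle = sprintf("entropy point n0 = %d (dashed); EIP shaded", n0)
    )
}

#' Plot an ROC curve from an evaluation report
#'
#' @param object A `meth_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Plot bootstrap feature importance
#'
#' Top features by mean normalized coefficient, with one-SD error bars,
#' coloured by feature group (DNA composition vs sequence complexity).
#'
#' @param importance Tibble from [feature_importance()].
#' @param top_n Number of top-ranked features to show (default 24).
#' @return A ggplot.
#' @export
plot_importance <- function(importance, top_n = 24L) {
  d <- importance |>
    dplyr::arrange(.data$rank) |>
    utils::head(top_n) |>
    dplyr::mutate(
      group = ifelse(startsWith(.data$feature, "SC"),
                     "sequence complexity", "DNA composition"),
      feature = factor(.data$feature, levels = rev(.data$feature))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$feature,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - .data$sd,
                   xmax = .data$mean + .data$sd),
      height = 0.3
    ) +
    ggplot2::scale_fill_manual(values = c(
      "DNA composition" = "steelblue", "sequence complexity" = "firebrick"
    )) +
    ggplot2::labs(x = "normalized |coefficient|", y = NULL, fill = NULL,
                  title = sprintf("Top %d features", nrow(d)))
}

#' Plot region-level consistency
#'
#' Assayed vs predicted region means per state, as paired violin-style
#' distributions.
#'
#' @param profiles Tibble from [profile_regions()].
#' @return A ggplot.
#' @export
plot_region_profiles <- function(profiles) {
  d <- profiles |>
    tidyr::pivot_longer(c("assayed_mean", "predicted_mean"),
                        names_to = "source", values_to = "mean_beta") |>
    dplyr::mutate(source = sub("_mean$", "", .data$source))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state_label,
                                  y = .data$mean_beta,
                                  fill = .data$source)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         alpha = 0.7, scale = "width") +
    ggplot2::labs(x = NULL, y = "region mean methylation", fill = NULL)
}
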