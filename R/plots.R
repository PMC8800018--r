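#' ROC curve of a score vector against activity labels
#'
#' Plots the empirical ROC (true-positive vs false-positive rate) under the
#' stated orientation, annotated with the rank-method AUC.
#'
#' @inheritParams roc_auc
#' @return a ggplot object.
#' @export
plot_roc <- function(scores, labels, orientation = c("lower_is_active", "higher_is_active")) {
  orientation <- match.arg(orientation)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  s <- if (orientation == "lower_is_active") -scores else scores
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L) / sum(labels == 1L)
  fp <- cumsum(labels[ord] == 0L) / sum(labels == 0L)
  auc <- roc_auc(scores, labels, orientation)
  df <- tibble(fpr = c(0, fp), tpr = c(0, tp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", auc)
    )
}

#' Inhibitor vs decoy docking-score distributions per conformation
#'
#' Mirrors the per-conformation score histograms used to judge screening
#' power by eye: overlapping densities of the two classes, faceted by
#' conformation.
#'
#' @param score_table long tibble with `conformation_id`, `score`, `label`.
#' @return a ggplot object.
#' @export
plot_score_distributions <- function(score_table) {
  df <- filter(as_tibble(score_table), !is.na(.data$score)) %>%
    mutate(class = ifelse(.data$label == 1, "inhibitor", "decoy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::facet_wrap(~conformation_id) +
    ggplot2::labs(x = "docking score (kcal/mol-like, lower = better)",
                  y = "density", fill = NULL)
}

#' Interaction occupancy histogram
#'
#' Bar chart of the fraction of trajectory frames in which each residue
#' contact of each type is present.
#'
#' @param occupancy tibble from [interaction_occupancy()].
#' @return a ggplot object.
#' @export
plot_occupancy <- function(occupancy) {
  df <- mutate(occupancy,
               residue = paste0(.data$residue_name, .data$residue_number))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$occupancy,
                                   fill = .data$itype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "occupancy (fraction of frames)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-atom ligand RMSF profile
#'
#' @param rmsf tibble from [ligand_rmsf()].
#' @return a ggplot object.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$atom, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ligand atom index", y = "RMSF (Å)")
}
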