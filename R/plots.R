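#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a cluster hierarchy: cluster counts and cohesiveness per level
#'
#' @param object A `cluster_hierarchy`.
#' @param ... Unused.
#' @return A ggplot showing, per level, the cluster cohesiveness values
#'   (points) and the cluster count (facet strip labels).
#' @method autoplot cluster_hierarchy
#' @export
autoplot.cluster_hierarchy <- function(object, ...) {
  long <- tidy(object)
  per_cluster <- distinct(long[, c("level", "cluster", "h")])
  per_cluster$level <- factor(per_cluster$level,
                              labels = paste0("L", sort(unique(per_cluster$level))))
  ggplot(per_cluster, aes(x = .data$level, y = .data$h)) +
    geom_point(alpha = 0.7,
               position = ggplot2::position_jitter(width = 0.08, height = 0)) +
    labs(x = "hierarchy level", y = "cluster cohesiveness h",
         title = "Cohesiveness of clusters per hierarchy level") +
    theme_minimal()
}

#' Plot ranked prediction scores
#'
#' @param object A `link_predictions` tibble from [predict_level()].
#' @param ... Unused.
#' @return A ggplot of prediction score versus rank.
#' @method autoplot link_predictions
#' @export
autoplot.link_predictions <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$rank, y = .data$score)) +
    geom_step() +
    labs(x = "rank", y = "aggregated score",
         title = "Ranked candidate ncRNA-disease pairs") +
    theme_minimal()
}

#' Plot a TPR@k curve
#'
#' @param ranked Ranked predictions (tibble `ncrna`, `disease`, `score`).
#' @param positives Tibble of validated pairs.
#' @param k_max Largest cutoff to draw.
#' @param candidates Optional candidate completion (see [tpr_at_k()]).
#' @return A ggplot of TPR@k against k.
#' @export
plot_tpr_curve <- function(ranked, positives, k_max = 5000,
                           candidates = NULL) {
  curve <- tpr_curve(ranked, positives, k_max, candidates)
  ggplot(curve, aes(x = .data$k, y = .data$tpr)) +
    geom_line() +
    labs(x = "k", y = "TPR@k", title = "True-positive rate at rank k") +
    theme_minimal()
}
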