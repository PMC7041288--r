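#' Clusters of a level containing a given pair
#'
#' All clusters at one hierarchy level containing both the ncRNA and the
#' disease, ordered by the cohesiveness ordering (highest cohesiveness
#' first).
#'
#' @param level List of clusters (one element of `hierarchy$levels`).
#' @param ncrna,disease Node IDs.
#' @param rel Extracted relationships (used to order clusters when their
#'   `h` is not yet filled in).
#' @return Ordered list of clusters (possibly empty).
#' @export
clusters_containing_pair <- function(level, ncrna, disease, rel) {
  smap <- rel_score_map(rel)
  hits <- purrr::keep(level, function(C) {
    ncrna %in% C$ncrnas && disease %in% C$diseases
  })
  sort_clusters(hits, smap)
}

#' Aggregate cluster cohesiveness values into one prediction score
#'
#' Combines the cohesiveness values of the clusters containing a pair into
#' a single degree of certainty:
#' * `max`, `min`, `avg` - as named;
#' * `ec` (evidence combination) - the recursion
#'   `ec_1 = h_1`, `ec_m = ec_{m-1} + (1 - ec_{m-1}) * h_m`
#'   over the values in decreasing-cohesiveness order; it rewards pairs
#'   appearing in several cohesive clusters and never falls below `max`.
#'
#' @param hs Non-empty numeric vector of cohesiveness values in `[0, 1]`,
#'   ordered decreasing (the order only matters for `ec`).
#' @param method One of `"max"`, `"min"`, `"avg"`, `"ec"`.
#' @return Aggregated score in `[0, 1]`.
#' @examples
#' aggregate_evidence(c(0.4, 0.3), "max")  # 0.4
#' aggregate_evidence(c(0.4, 0.3), "avg")  # 0.35
#' aggregate_evidence(c(0.4, 0.3), "ec")   # 0.4 + 0.6*0.3 = 0.58
#' @export
aggregate_evidence <- function(hs, method = c("max", "min", "avg", "ec")) {
  method <- match.arg(method)
  if (!length(hs)) abort("`hs` must be non-empty; skip pairs with no cluster")
  if (any(hs < 0 | hs > 1)) abort("cohesiveness values must lie in [0, 1]")
  switch(method,
    max = max(hs),
    min = min(hs),
    avg = mean(hs),
    ec = {
      ec <- hs[1]
      for (h in hs[-1]) ec <- ec + (1 - ec) * h
      ec
    })
}

#' Rank candidate pairs with one hierarchy level
#'
#' Stage 3 of the pipeline: every ncRNA-disease pair co-occurring in at
#' least one cluster of level `w` receives the aggregated cohesiveness of
#' its containing clusters ([aggregate_evidence()]); pairs in no cluster are
#' omitted (evaluation treats them as score 0). With `exclude_known = TRUE`
#' (the default, matching the transductive prediction of *new*
#' relationships) pairs present in `known` are removed from the output.
#'
#' @param hierarchy A `cluster_hierarchy` from [build_hierarchy()].
#' @param w Level index, `1 <= w <= length(hierarchy$levels)`.
#' @param method Aggregation method (see [aggregate_evidence()]).
#' @param known Optional tibble of known pairs (`ncrna`, `disease`) to
#'   exclude, typically [known_target_pairs()] of the training network.
#' @param exclude_known Whether to drop `known` pairs from the table.
#' @return Tibble of class `link_predictions`, columns `ncrna`, `disease`,
#'   `score`, `n_clusters`, `rank`; sorted by decreasing score, ties broken
#'   by (ncrna, disease) lexicographic order.
#' @export
predict_level <- function(hierarchy, w, method = "max", known = NULL,
                          exclude_known = TRUE) {
  stopifnot(inherits(hierarchy, "cluster_hierarchy"))
  if (!is_scalar_number(w) || w < 1 || w > length(hierarchy$levels)) {
    abort(sprintf("`w` must be a level index in 1..%d",
                  length(hierarchy$levels)))
  }
  level <- hierarchy$levels[[w]]
  smap <- rel_score_map(hierarchy$rel)
  level <- sort_clusters(level, smap)
  rows <- list()
  for (C in level) {
    if (!length(C$ncrnas) || !length(C$diseases)) next
    rows[[length(rows) + 1L]] <- tibble(
      ncrna = rep(C$ncrnas, each = length(C$diseases)),
      disease = rep.int(C$diseases, length(C$ncrnas)),
      h = C$h)
  }
  if (!length(rows)) {
    out <- tibble(ncrna = character(), disease = character(),
                  score = double(), n_clusters = integer(), rank = integer())
    class(out) <- c("link_predictions", class(out))
    return(out)
  }
  long <- bind_rows(rows)
  # clusters were appended in cohesiveness order, so each pair's h values
  # are already ordered decreasing (as the EC recursion requires)
  agg <- long |>
    group_by(.data$ncrna, .data$disease) |>
    summarise(score = aggregate_evidence(.data$h, method),
              n_clusters = dplyr::n(), .groups = "drop")
  if (exclude_known && !is.null(known) && nrow(known)) {
    agg <- agg[!(pair_key(agg$ncrna, agg$disease) %in%
                   pair_key(known$ncrna, known$disease)), ]
  }
  agg <- agg[order(-agg$score, agg$ncrna, agg$disease, method = "radix"), ]
  agg$rank <- seq_len(nrow(agg))
  class(agg) <- c("link_predictions", class(agg))
  agg
}

#' Write ranked predictions to a TSV file
#'
#' Columns `ncrna_id`, `disease_id`, `score`, `n_clusters`, `rank`.
#'
#' @param predictions A `link_predictions` tibble from [predict_level()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  out <- tibble(ncrna_id = predictions$ncrna,
                disease_id = predictions$disease,
                score = predictions$score,
                n_clusters = predictions$n_clusters,
                rank = predictions$rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
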