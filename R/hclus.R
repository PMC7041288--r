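#' Filter scored pairs by the score threshold
#'
#' Keeps exactly the ncRNA-disease pairs whose degree of certainty is at
#' least `beta`. These *extracted relationships* feed the clustering stage;
#' directly linked pairs (score 1) always survive. An empty result makes the
#' downstream clustering empty (warning, not an error).
#'
#' @param scores A `pair_scores` tibble from [score_all_pairs()] (columns
#'   `ncrna`, `disease`, `score`).
#' @param beta Threshold in `[0, 1]`.
#' @return Tibble with columns `ncrna`, `disease`, `score`, every score
#'   `>= beta`.
#' @export
filter_pairs <- function(scores, beta) {
  check_prob(beta, "beta")
  out <- scores[scores$score >= beta, c("ncrna", "disease", "score")]
  out <- as_tibble(out)
  if (nrow(out) == 0L) warn("no pair reaches `beta`; clustering will be empty")
  out[order_c(out$ncrna, out$disease), ]
}

new_cluster <- function(ncrnas, diseases, h = NA_real_) {
  list(ncrnas = sort_c(unique(ncrnas)),
       diseases = sort_c(unique(diseases)),
       h = h)
}

cluster_key <- function(C) {
  paste(paste(C$ncrnas, collapse = ","), paste(C$diseases, collapse = ","),
        sep = "|")
}

rel_score_map <- function(rel) {
  stats::setNames(rel$score, pair_key(rel$ncrna, rel$disease))
}

#' Cohesiveness of a multi-type cluster
#'
#' The average degree of certainty over *all possible* ncRNA-disease pairs
#' of the cluster: the sum of the scores of the cluster's pairs present in
#' the extracted relationships (absent pairs contribute 0), divided by
#' `|ncrnas| * |diseases|`.
#'
#' @param cluster A cluster (list with `ncrnas`, `diseases`), e.g. from
#'   [build_hierarchy()] levels or [fixture_prediction_example()].
#' @param rel Extracted relationships from [filter_pairs()].
#' @return Cohesiveness in `[0, 1]`.
#' @examples
#' rel <- tibble::tibble(ncrna = c("n1", "n1", "n1"),
#'                       disease = c("d1", "d2", "d3"),
#'                       score = c(0.7, 0.8, 0.9))
#' C <- list(ncrnas = c("n1", "n2"), diseases = c("d1", "d2", "d3"))
#' cohesiveness(C, rel)  # (0.7+0.8+0.9) / (2*3) = 0.4
#' @export
cohesiveness <- function(cluster, rel) {
  smap <- rel_score_map(rel)
  cohesiveness_impl(cluster, smap)
}

cohesiveness_impl <- function(cluster, smap) {
  n <- length(cluster$ncrnas)
  d <- length(cluster$diseases)
  if (n == 0L || d == 0L) abort("cluster must contain both target types")
  keys <- pair_key(rep(cluster$ncrnas, each = d),
                   rep.int(cluster$diseases, n))
  sum(smap[keys], na.rm = TRUE) / (n * d)
}

# Deterministic total-order sort key for clusters: higher cohesiveness
# first, then fewer possible pairs, then lexicographically smallest member
# set. Returns the clusters sorted, each with `h` filled in.
sort_clusters <- function(clusters, smap) {
  if (!length(clusters)) return(clusters)
  clusters <- lapply(clusters, function(C) {
    C$h <- cohesiveness_impl(C, smap)
    C
  })
  h <- vapply(clusters, `[[`, 0, "h")
  size <- vapply(clusters, function(C)
    length(C$ncrnas) * length(C$diseases), 0)
  keyz <- vapply(clusters, cluster_key, "")
  clusters[order(-h, size, keyz, method = "radix")]
}

#' Compare two clusters under the cohesiveness ordering
#'
#' A cluster precedes another iff its cohesiveness is strictly higher; ties
#' are broken by fewer possible pairs, then by the lexicographically
#' smallest member set, giving a deterministic total order.
#'
#' @param a,b Clusters (lists with `ncrnas`, `diseases`).
#' @param rel Extracted relationships from [filter_pairs()].
#' @return `-1` if `a` precedes `b`, `1` if `b` precedes `a`, `0` if they
#'   are identical.
#' @export
cluster_order <- function(a, b, rel) {
  smap <- rel_score_map(rel)
  ha <- cohesiveness_impl(a, smap); hb <- cohesiveness_impl(b, smap)
  if (ha != hb) return(if (ha > hb) -1L else 1L)
  sa <- length(a$ncrnas) * length(a$diseases)
  sb <- length(b$ncrnas) * length(b$diseases)
  if (sa != sb) return(if (sa < sb) -1L else 1L)
  ka <- cluster_key(a); kb <- cluster_key(b)
  if (ka == kb) return(0L)
  if (order_c(c(ka, kb))[1] == 1L) -1L else 1L
}

#' Initial bicliques: one 1x1 cluster per retained pair
#'
#' @param rel Extracted relationships from [filter_pairs()].
#' @return List of clusters sorted by the cohesiveness ordering (each pair's
#'   cohesiveness is its score).
#' @export
init_bicliques <- function(rel) {
  smap <- rel_score_map(rel)
  clusters <- purrr::map2(rel$ncrna, rel$disease,
                          function(n, d) new_cluster(n, d))
  sort_clusters(clusters, smap)
}

# A merged cluster satisfies the biclique constraint iff every pair of the
# union ncrnas x diseases is a retained relationship.
is_biclique <- function(C, rel_keys) {
  n <- length(C$ncrnas); d <- length(C$diseases)
  keys <- pair_key(rep(C$ncrnas, each = d), rep.int(C$diseases, n))
  all(keys %in% rel_keys)
}

merge_two <- function(a, b) {
  new_cluster(c(a$ncrnas, b$ncrnas), c(a$diseases, b$diseases))
}

dedup_clusters <- function(clusters) {
  keys <- vapply(clusters, cluster_key, "")
  clusters[!duplicated(keys)]
}

#' Greedy biclique merging (first hierarchy level)
#'
#' Scans the cohesiveness-sorted cluster list; each cluster is merged with
#' the first later cluster whose union (union of ncRNA sets x union of
#' disease sets) still satisfies the biclique constraint, i.e. every pair of
#' the union is a retained relationship. After each merge the list is
#' re-sorted and deduplicated; scanning repeats until a full pass performs
#' no merge. The fixpoint is the first hierarchy level.
#'
#' @param clusters Sorted clusters from [init_bicliques()].
#' @param rel Extracted relationships from [filter_pairs()].
#' @return List of clusters (level 1), sorted, each with cohesiveness `h`.
#' @export
merge_bicliques <- function(clusters, rel) {
  smap <- rel_score_map(rel)
  rel_keys <- names(smap)
  clusters <- sort_clusters(clusters, smap)
  repeat {
    merged <- FALSE
    n <- length(clusters)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          cand <- merge_two(clusters[[i]], clusters[[j]])
          if (is_biclique(cand, rel_keys)) {
            clusters <- c(clusters[-c(i, j)], list(cand))
            clusters <- sort_clusters(dedup_clusters(clusters), smap)
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  clusters
}

#' One merging pass above the first level
#'
#' Same greedy scheme as [merge_bicliques()], but a merge is valid when the
#' union's cohesiveness exceeds `alpha` (the biclique constraint is
#' dropped), and a single pass over the sorted list defines one new level:
#' each cluster merges at most once per level, and unmerged clusters carry
#' over unchanged.
#'
#' @param prev Clusters of the previous level.
#' @param rel Extracted relationships from [filter_pairs()].
#' @param alpha Minimum cohesiveness a merged cluster must exceed.
#' @return The next level's clusters (sorted, deduplicated), or the string
#'   `"stop"` if no merge was possible.
#' @export
merge_level <- function(prev, rel, alpha) {
  check_prob(alpha, "alpha")
  smap <- rel_score_map(rel)
  clusters <- sort_clusters(prev, smap)
  n <- length(clusters)
  consumed <- rep(FALSE, n)
  nxt <- list()
  merged_any <- FALSE
  for (i in seq_len(n)) {
    if (consumed[i]) next
    partner <- 0L
    if (i < n) {
      for (j in (i + 1L):n) {
        if (consumed[j]) next
        cand <- merge_two(clusters[[i]], clusters[[j]])
        if (cohesiveness_impl(cand, smap) > alpha) {
          partner <- j
          break
        }
      }
    }
    if (partner > 0L) {
      consumed[i] <- consumed[partner] <- TRUE
      nxt[[length(nxt) + 1L]] <- merge_two(clusters[[i]], clusters[[partner]])
      merged_any <- TRUE
    } else {
      consumed[i] <- TRUE
      nxt[[length(nxt) + 1L]] <- clusters[[i]]
    }
  }
  if (!merged_any) return("stop")
  sort_clusters(dedup_clusters(nxt), smap)
}

#' Build the hierarchy of overlapping multi-type clusters
#'
#' Stage 2 of the pipeline: filter the scored pairs at `beta`, initialize
#' one biclique per retained pair, greedily merge to the biclique fixpoint
#' (level 1), then repeatedly apply cohesiveness-gated merge passes
#' ([merge_level()]) until no merge is possible. Every level-`i+1` cluster
#' contains at least one level-`i` cluster, and level sizes strictly
#' decrease.
#'
#' @param scores A `pair_scores` tibble from [score_all_pairs()].
#' @param alpha Minimum cohesiveness for merged clusters above level 1.
#' @param beta Score threshold for the extracted relationships.
#' @return An object of class `cluster_hierarchy`: list with `levels` (list
#'   of lists of clusters, each cluster carrying `ncrnas`, `diseases`, `h`),
#'   `rel` (the retained pairs), `alpha`, `beta`.
#' @export
build_hierarchy <- function(scores, alpha, beta) {
  check_prob(alpha, "alpha"); check_prob(beta, "beta")
  rel <- filter_pairs(scores, beta)
  levels <- list()
  if (nrow(rel) > 0L) {
    L1 <- merge_bicliques(init_bicliques(rel), rel)
    levels[[1]] <- L1
    repeat {
      nxt <- merge_level(levels[[length(levels)]], rel, alpha)
      if (identical(nxt, "stop")) break
      levels[[length(levels) + 1L]] <- nxt
    }
  } else {
    warn("empty hierarchy: no retained pairs")
  }
  structure(list(levels = levels, rel = rel, alpha = alpha, beta = beta),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat(sprintf("<cluster_hierarchy> %d level(s), alpha=%g, beta=%g\n",
              length(x$levels), x$alpha, x$beta))
  for (i in seq_along(x$levels)) {
    h <- vapply(x$levels[[i]], `[[`, 0, "h")
    cat(sprintf("  L%d: %d cluster(s), mean h=%.3f\n",
                i, length(x$levels[[i]]), mean(h)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster hierarchy into a long membership table
#'
#' @param x A `cluster_hierarchy`.
#' @param ... Unused.
#' @return Tibble with columns `level`, `cluster` (index within level,
#'   cohesiveness order), `h`, `member_type` (`"ncrna"`/`"disease"`),
#'   `member_id`.
#' @method tidy cluster_hierarchy
#' @export
tidy.cluster_hierarchy <- function(x, ...) {
  rows <- list()
  for (w in seq_along(x$levels)) {
    for (ci in seq_along(x$levels[[w]])) {
      C <- x$levels[[w]][[ci]]
      rows[[length(rows) + 1L]] <- tibble(
        level = w, cluster = ci, h = C$h,
        member_type = c(rep("ncrna", length(C$ncrnas)),
                        rep("disease", length(C$diseases))),
        member_id = c(C$ncrnas, C$diseases))
    }
  }
  if (!length(rows)) {
    return(tibble(level = integer(), cluster = integer(), h = double(),
                  member_type = character(), member_id = character()))
  }
  bind_rows(rows)
}

#' One-row summary of a cluster hierarchy
#'
#' @param x A `cluster_hierarchy`.
#' @param ... Unused.
#' @return Tibble with `n_levels`, `n_clusters_l1`, `n_retained_pairs`,
#'   `alpha`, `beta`.
#' @method glance cluster_hierarchy
#' @export
glance.cluster_hierarchy <- function(x, ...) {
  tibble(n_levels = length(x$levels),
         n_clusters_l1 = if (length(x$levels)) length(x$levels[[1]]) else 0L,
         n_retained_pairs = nrow(x$rel),
         alpha = x$alpha, beta = x$beta)
}

#' Write hierarchy levels to TSV + JSON files
#'
#' Emits one `clusters_L<i>.tsv` per level (columns `cluster_id`,
#' `member_type`, `member_id`) and a `hierarchy.json` with level sizes,
#' cohesiveness values and the parameters.
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_hierarchy <- function(hierarchy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- tidy(hierarchy)
  paths <- character()
  for (w in seq_along(hierarchy$levels)) {
    p <- file.path(dir, sprintf("clusters_L%d.tsv", w))
    lw <- long[long$level == w, ]
    readr::write_tsv(tibble(cluster_id = lw$cluster,
                            member_type = lw$member_type,
                            member_id = lw$member_id), p, progress = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    alpha = hierarchy$alpha, beta = hierarchy$beta,
    n_levels = length(hierarchy$levels),
    levels = lapply(seq_along(hierarchy$levels), function(w) {
      lapply(hierarchy$levels[[w]], function(C) {
        list(ncrnas = C$ncrnas, diseases = C$diseases, h = C$h)
      })
    })
  )
  jp <- file.path(dir, "hierarchy.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
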