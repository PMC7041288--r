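#' Split the known positive pairs into cross-validation folds
#'
#' Seeded random partition of the directly linked target pairs into
#' `n_folds` disjoint, exhaustive folds. Each fold's training network is the
#' original network with that fold's direct target-target edges removed;
#' all nodes are retained (the setting is transductive: only links among
#' nodes seen in training are predicted).
#'
#' @param net A `hetnet` with at least `n_folds` known positive pairs.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List of folds, each a list with `fold` (index), `test_pairs`
#'   (tibble `ncrna`, `disease`) and `train_net` (a `hetnet`).
#' @export
make_folds <- function(net, n_folds = 10, seed = 1) {
  pos <- known_target_pairs(net)
  if (nrow(pos) < n_folds) {
    abort(sprintf("need at least %d known positive pairs, have %d",
                  n_folds, nrow(pos)))
  }
  perm <- withr::with_seed(seed, sample.int(nrow(pos)))
  assign <- rep_len(seq_len(n_folds), nrow(pos))[order(perm)]
  lapply(seq_len(n_folds), function(f) {
    test <- pos[assign == f, ]
    list(fold = f, test_pairs = test,
         train_net = drop_target_edges(net, test))
  })
}

# Extend a ranked table to cover all candidate pairs: unranked candidates
# get score 0 and are appended in lexicographic order.
complete_ranking <- function(ranked, candidates = NULL) {
  out <- tibble(ncrna = ranked$ncrna, disease = ranked$disease,
                score = ranked$score)
  if (!is.null(candidates) && nrow(candidates)) {
    extra <- candidates[!(pair_key(candidates$ncrna, candidates$disease) %in%
                            pair_key(out$ncrna, out$disease)), ]
    if (nrow(extra)) {
      extra <- tibble(ncrna = extra$ncrna, disease = extra$disease, score = 0)
      extra <- extra[order_c(extra$ncrna, extra$disease), ]
      out <- bind_rows(out, extra)
    }
  }
  out
}

#' True-positive rate among the top k predictions
#'
#' The fraction of the validated positive pairs appearing in the first `k`
#' rows of the ranking, i.e. `TP / (TP + FN)`. Candidate pairs absent from
#' the ranking are appended with score 0 in lexicographic order, so the
#' measure is defined for any `k`.
#'
#' @param ranked Ranked predictions (tibble with `ncrna`, `disease`, `score`
#'   in rank order), e.g. from [predict_level()].
#' @param positives Tibble of validated pairs (`ncrna`, `disease`).
#' @param k Cutoff rank, `k >= 1`.
#' @param candidates Optional tibble of all candidate pairs for ranking
#'   completion.
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_k <- function(ranked, positives, k, candidates = NULL) {
  stopifnot(k >= 1)
  if (is.null(positives) || nrow(positives) == 0L) {
    abort("`positives` must be non-empty")
  }
  full <- complete_ranking(ranked, candidates)
  top <- full[seq_len(min(k, nrow(full))), ]
  pk <- pair_key(positives$ncrna, positives$disease)
  sum(pair_key(top$ncrna, top$disease) %in% pk) / nrow(positives)
}

tpr_curve <- function(ranked, positives, k_max, candidates = NULL) {
  full <- complete_ranking(ranked, candidates)
  pk <- pair_key(positives$ncrna, positives$disease)
  hit <- pair_key(full$ncrna, full$disease) %in% pk
  cum <- cumsum(hit) / nrow(positives)
  k <- seq_len(k_max)
  tpr <- ifelse(k <= length(cum), cum[pmin(k, length(cum))],
                if (length(cum)) cum[length(cum)] else 0)
  tibble(k = k, tpr = tpr)
}

#' Area under the TPR@k curve
#'
#' Trapezoidal area of TPR@k over `k = 1..k_max`, normalized by
#' `k_max - 1` so that a ranking placing a single positive at rank 1 scores
#' exactly 1. Items below rank `k_max` do not affect the value.
#'
#' @inheritParams tpr_at_k
#' @param k_max Largest cutoff considered (default 5000).
#' @return Normalized area in `[0, 1]`.
#' @export
autpr_at_k <- function(ranked, positives, k_max = 5000, candidates = NULL) {
  stopifnot(k_max >= 1)
  curve <- tpr_curve(ranked, positives, k_max, candidates)
  if (k_max == 1) return(curve$tpr[1])
  pracma::trapz(curve$k, curve$tpr) / (k_max - 1)
}

#' ROC and precision-recall under the unknowns-as-negatives assumption
#'
#' Treats every candidate pair absent from `positives` as a negative and
#' computes ROC and PR curves with their areas. Tied scores are grouped
#' (one step across the tie block), so a constant ranking yields AUROC 0.5.
#' Because unvalidated pairs are not true negatives, these numbers are
#' meaningful for relative comparison only, and the result is labeled
#' accordingly.
#'
#' @param ranked Ranked predictions (tibble `ncrna`, `disease`, `score`).
#' @param positives Tibble of validated pairs (`ncrna`, `disease`).
#' @param candidates Tibble of all candidate pairs; pairs missing from
#'   `ranked` get score 0.
#' @return List with `auroc`, `aupr`, `roc_points` (tibble `fpr`, `tpr`),
#'   `pr_points` (tibble `recall`, `precision`) and `note`.
#' @export
roc_pr_unknown_neg <- function(ranked, positives, candidates = NULL) {
  full <- complete_ranking(ranked, candidates)
  pk <- pair_key(positives$ncrna, positives$disease)
  label <- as.integer(pair_key(full$ncrna, full$disease) %in% pk)
  if (length(unique(label)) < 2L) {
    abort("degenerate input: need both positive and negative pairs")
  }
  roc <- pROC::roc(response = label, predictor = full$score,
                   direction = "<", levels = c(0, 1), quiet = TRUE)
  roc_points <- tibble(fpr = rev(1 - roc$specificities),
                       tpr = rev(roc$sensitivities))
  # PR curve over distinct thresholds, ties grouped
  ord <- order(-full$score, method = "radix")
  lab <- label[ord]
  sc <- full$score[ord]
  n_pos <- sum(lab)
  cum_tp <- cumsum(lab)
  cum_fp <- cumsum(1L - lab)
  last_of_block <- c(diff(sc) != 0, TRUE)
  tp <- cum_tp[last_of_block]
  fp <- cum_fp[last_of_block]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)  # step integral
  list(auroc = as.numeric(pROC::auc(roc)),
       aupr = aupr,
       roc_points = roc_points,
       pr_points = tibble(recall = recall, precision = precision),
       note = "relative comparison only (unknown pairs assumed negative)")
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold from [make_folds()], scores the training network, builds
#' the hierarchy, ranks the candidate pairs with the requested level and
#' aggregator, and measures TPR@k / AUTPR@k against the held-out positives.
#' All pairs absent from the training positive set are candidates; unranked
#' candidates count as score 0.
#'
#' @param net A `hetnet`.
#' @param alpha,beta Hierarchy parameters (see [build_hierarchy()]).
#' @param level Hierarchy level to evaluate (levels beyond a fold's
#'   hierarchy depth fall back to its deepest level).
#' @param method Aggregation method (see [aggregate_evidence()]).
#' @param n_folds,seed Fold parameters (see [make_folds()]).
#' @param k_max AUTPR@k cutoff.
#' @param max_len,depth,seq_cap Scoring parameters (see
#'   [score_all_pairs()]).
#' @return Tibble with one row per fold: `fold`, `n_test`, `autpr`,
#'   `tpr_at_10`.
#' @export
evaluate_cv <- function(net, alpha = 0.2, beta = 0.4, level = 1,
                        method = "max", n_folds = 10, seed = 1,
                        k_max = 5000, max_len = 3, depth = 2,
                        seq_cap = 1000) {
  folds <- make_folds(net, n_folds = n_folds, seed = seed)
  tt <- net$schema$target_types
  all_pairs <- tidyr::expand_grid(ncrna = sort_c(net$nodes[[tt[1]]]$id),
                                  disease = sort_c(net$nodes[[tt[2]]]$id))
  purrr::map_dfr(folds, function(fd) {
    scores <- score_all_pairs(fd$train_net, max_len = max_len,
                              depth = depth, seq_cap = seq_cap)
    hier <- suppressWarnings(build_hierarchy(scores, alpha, beta))
    train_known <- known_target_pairs(fd$train_net)
    candidates <- all_pairs[!(pair_key(all_pairs$ncrna, all_pairs$disease) %in%
                                pair_key(train_known$ncrna,
                                         train_known$disease)), ]
    if (length(hier$levels)) {
      w <- min(level, length(hier$levels))
      ranked <- predict_level(hier, w, method = method, known = train_known)
    } else {
      ranked <- tibble(ncrna = character(), disease = character(),
                       score = double())
    }
    tibble(fold = fd$fold,
           n_test = nrow(fd$test_pairs),
           autpr = autpr_at_k(ranked, fd$test_pairs, k_max = k_max,
                              candidates = candidates),
           tpr_at_10 = tpr_at_k(ranked, fd$test_pairs, k = 10,
                                candidates = candidates))
  })
}
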