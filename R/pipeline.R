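#' Run the full pipeline on a network
#'
#' Orchestrates the three stages end to end: pair scoring
#' ([score_all_pairs()]), hierarchy construction ([build_hierarchy()]),
#' per-level ranked prediction ([predict_level()]) and, optionally, the
#' cross-validated evaluation ([evaluate_cv()]). All outputs are written to
#' `out_dir` together with a `manifest.json` recording parameters, seed and
#' file checksums, so that two runs with identical inputs and parameters
#' produce byte-identical artifacts.
#'
#' @param net A validated `hetnet` (e.g. from [load_network()] or
#'   [generate_network()]).
#' @param out_dir Output directory (created if needed).
#' @param alpha,beta Hierarchy parameters; the defaults match the
#'   configuration grids the method is typically run with.
#' @param depth,max_len,seq_cap Scoring parameters (see
#'   [score_all_pairs()]).
#' @param methods Aggregation methods to emit predictions for.
#' @param evaluate Whether to run the cross-validated evaluation.
#' @param n_folds,seed,k_max Evaluation parameters (see [evaluate_cv()]).
#' @return Invisibly, a list with `scores`, `hierarchy`, `predictions`
#'   (named by `L<level>_<method>`), `metrics` (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(net, out_dir,
                         alpha = 0.2, beta = 0.4,
                         depth = 2, max_len = 3, seq_cap = 1000,
                         methods = c("max", "min", "avg", "ec"),
                         evaluate = FALSE, n_folds = 10, seed = 1,
                         k_max = 5000) {
  stopifnot(inherits(net, "hetnet"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  message("stage 1/3: scoring target pairs")
  scores <- score_all_pairs(net, max_len = max_len, depth = depth,
                            seq_cap = seq_cap)
  write_scores(scores, file.path(out_dir, "scores.tsv"))

  message("stage 2/3: building the cluster hierarchy")
  hierarchy <- build_hierarchy(scores, alpha = alpha, beta = beta)
  write_hierarchy(hierarchy, out_dir)
  for (w in seq_along(hierarchy$levels)) {
    message(sprintf("  level %d: %d cluster(s)", w,
                    length(hierarchy$levels[[w]])))
  }

  message("stage 3/3: ranking candidate pairs")
  known <- known_target_pairs(net)
  predictions <- list()
  for (w in seq_along(hierarchy$levels)) {
    for (m in methods) {
      pred <- predict_level(hierarchy, w, method = m, known = known)
      nm <- sprintf("L%d_%s", w, m)
      predictions[[nm]] <- pred
      write_predictions(pred,
                        file.path(out_dir,
                                  sprintf("predictions_L%d_%s.tsv", w, m)))
    }
  }

  metrics <- NULL
  if (evaluate) {
    message("evaluation: cross-validated ranking metrics")
    metrics <- evaluate_cv(net, alpha = alpha, beta = beta,
                           method = methods[1], n_folds = n_folds,
                           seed = seed, k_max = k_max, max_len = max_len,
                           depth = depth, seq_cap = seq_cap)
    readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"),
                     progress = FALSE)
  }

  files <- sort_c(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    parameters = list(alpha = alpha, beta = beta, depth = depth,
                      max_len = max_len, seq_cap = seq_cap,
                      methods = methods, n_folds = n_folds,
                      k_max = k_max, seed = seed),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, hierarchy = hierarchy,
                 predictions = predictions, metrics = metrics,
                 manifest = manifest))
}
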