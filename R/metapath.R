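#' Enumerate meta-paths between the two target types
#'
#' A meta-path is an ordered sequence of node types, joined by declared edge
#' types, running from the ncRNA-like target type to the disease-like target
#' type. Enumeration is cycle-free at the type level (no node type repeats)
#' and bounded by `max_len` edges; the result is ordered shortest first, then
#' lexicographically by type sequence (then edge-type sequence), so it is
#' deterministic.
#'
#' @param net A `hetnet`.
#' @param max_len Maximum number of edges per meta-path (default 3).
#' @return List of `metapath` objects; empty (with a warning) when the two
#'   target types are not connected at the type level.
#' @export
enumerate_metapaths <- function(net, max_len = 3) {
  stopifnot(inherits(net, "hetnet"), max_len >= 1)
  s <- net$schema
  start <- s$target_types[1]
  goal <- s$target_types[2]
  et <- s$edge_types
  found <- list()
  walk <- function(types, edges) {
    cur <- types[length(types)]
    if (cur == goal && length(edges) >= 1L) {
      found[[length(found) + 1L]] <<- new_metapath(types, edges)
      return(invisible())
    }
    if (length(edges) >= max_len) return(invisible())
    # candidate continuations: any edge type touching `cur`, other endpoint
    # an unvisited type (the goal type is only reachable as the last step)
    cand <- list()
    for (i in seq_len(nrow(et))) {
      if (et$from[i] == cur) cand[[length(cand) + 1L]] <- c(et$name[i], et$to[i])
      if (et$to[i] == cur && et$from[i] != et$to[i])
        cand[[length(cand) + 1L]] <- c(et$name[i], et$from[i])
    }
    for (cd in cand) {
      nxt <- cd[2]
      if (nxt %in% types) next
      walk(c(types, nxt), c(edges, cd[1]))
    }
    invisible()
  }
  walk(start, character())
  if (!length(found)) {
    warn("no meta-path connects the target types within `max_len` edges")
    return(list())
  }
  keys <- vapply(found, function(m) {
    sprintf("%03d|%s|%s", length(m$edge_types),
            paste(m$types, collapse = "."),
            paste(m$edge_types, collapse = "."))
  }, "")
  found[order_c(keys)]
}

new_metapath <- function(types, edge_types) {
  structure(list(types = types, edge_types = edge_types), class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath>", paste(x$types, collapse = " - "), "\n")
  invisible(x)
}

#' @export
format.metapath <- function(x, ...) paste(x$types, collapse = ".")

#' Materialize the node sequences of a meta-path
#'
#' Enumerates every simple path in the network instantiating the meta-path
#' (node *i* of type `types[i]`, consecutive nodes adjacent through the
#' declared edge type). Node types along a meta-path are distinct, so the
#' paths are automatically node-simple. Enumeration is depth-first with
#' neighbors visited in lexicographic ID order; at most `seq_cap` sequences
#' are kept per starting node (deterministic truncation, with a warning).
#'
#' @param net A `hetnet`.
#' @param metapath A `metapath`.
#' @param seq_cap Per-start-node cap on materialized sequences.
#' @return Character matrix, one row per sequence, one column per meta-path
#'   position.
#' @export
path_sequences <- function(net, metapath, seq_cap = Inf) {
  adj <- edge_lookup(net)
  k <- length(metapath$types)
  starts <- sort_c(net$nodes[[metapath$types[1]]]$id)
  rows <- list()
  truncated <- FALSE
  for (s0 in starts) {
    got <- 0L
    dfs <- function(path) {
      if (got >= seq_cap) { truncated <<- TRUE; return(invisible()) }
      pos <- length(path)
      if (pos == k) {
        rows[[length(rows) + 1L]] <<- path
        got <<- got + 1L
        return(invisible())
      }
      e <- metapath$edge_types[pos]
      frm <- node_type_of(net, e, "from")
      key <- if (frm == metapath$types[pos]) paste0("f|", e) else paste0("t|", e)
      nbrs <- adj[[key]][[path[pos]]]
      for (nb in nbrs) {
        if (nb %in% path) next  # defensive; types are distinct anyway
        dfs(c(path, nb))
      }
      invisible()
    }
    dfs(s0)
  }
  if (truncated) {
    warn(sprintf("sequence cap %s reached for meta-path %s; truncating",
                 format(seq_cap), format(metapath)))
  }
  if (!length(rows)) {
    return(matrix(character(), nrow = 0, ncol = k))
  }
  do.call(rbind, rows)
}

# Named list "f|<edge>" / "t|<edge>" -> (node ID -> sorted neighbor IDs),
# following the edge type forward or backward.
edge_lookup <- function(net) {
  out <- list()
  for (e in names(net$edges)) {
    tab <- net$edges[[e]]
    out[[paste0("f|", e)]] <- split(tab$to, tab$from)
    out[[paste0("t|", e)]] <- split(tab$from, tab$to)
    out[[paste0("f|", e)]] <- lapply(out[[paste0("f|", e)]], sort_c)
    out[[paste0("t|", e)]] <- lapply(out[[paste0("t|", e)]], sort_c)
  }
  out
}

#' Global attribute ranges
#'
#' For every numeric attribute of every node type, the observed minimum and
#' maximum over the whole network. These global ranges normalize numeric
#' attribute similarity; they must be recomputed whenever the network (or
#' its enrichment) changes.
#'
#' @param net A `hetnet`.
#' @return Tibble with columns `node_type`, `attribute`, `kind`, `min`, `max`.
#' @export
attribute_stats <- function(net) {
  out <- list()
  for (t in net$schema$node_types) {
    kinds <- schema_kinds(net$schema, t)
    for (a in names(kinds)) {
      v <- net$nodes[[t]][[a]]
      if (kinds[[a]] == "numeric") {
        ok <- !is.na(v)
        out[[length(out) + 1L]] <- tibble(
          node_type = t, attribute = a, kind = "numeric",
          min = if (any(ok)) min(v[ok]) else NA_real_,
          max = if (any(ok)) max(v[ok]) else NA_real_)
      } else {
        out[[length(out) + 1L]] <- tibble(
          node_type = t, attribute = a, kind = "categorical",
          min = NA_real_, max = NA_real_)
      }
    }
  }
  if (!length(out)) {
    return(tibble(node_type = character(), attribute = character(),
                  kind = character(), min = double(), max = double()))
  }
  bind_rows(out)
}

#' Similarity of two attribute values
#'
#' Numeric: `1 - |v1 - v2| / (max_x - min_x)` with the global range from
#' [attribute_stats()]; a constant attribute (`max_x == min_x`) compares as 1
#' when both values are present. Categorical: 1 if equal, else 0. Either
#' value missing gives `NA` (the caller drops such comparisons pairwise).
#'
#' @param v1,v2 Attribute values.
#' @param kind `"numeric"` or `"categorical"`.
#' @param min_x,max_x Global range (numeric attributes only).
#' @return Similarity in `[0, 1]`, or `NA` if either value is missing.
#' @export
attribute_similarity <- function(v1, v2, kind, min_x = NA, max_x = NA) {
  if (is.na(v1) || is.na(v2)) return(NA_real_)
  if (kind == "numeric") {
    rng <- max_x - min_x
    if (!is.finite(rng)) return(NA_real_)
    if (rng == 0) return(1)
    return(max(0, min(1, 1 - abs(v1 - v2) / rng)))
  }
  as.numeric(v1 == v2)
}

# Pairwise sequence-similarity matrix for all sequences of one meta-path.
# Missing comparisons are dropped from numerator and denominator; sequences
# with no comparable attribute pair get similarity 0.
seq_sim_matrix <- function(net, metapath, seqs, stats) {
  m <- nrow(seqs)
  if (m == 0L) return(matrix(numeric(), 0, 0))
  acc <- matrix(0, m, m)
  cnt <- matrix(0L, m, m)
  n_attr <- 0L
  for (pos in seq_along(metapath$types)) {
    t <- metapath$types[pos]
    kinds <- schema_kinds(net$schema, t)
    if (!length(kinds)) next
    tab <- net$nodes[[t]]
    idx <- match(seqs[, pos], tab$id)
    for (a in names(kinds)) {
      n_attr <- n_attr + 1L
      if (kinds[[a]] == "numeric") {
        v <- tab[[a]][idx]
        st <- stats[stats$node_type == t & stats$attribute == a, ]
        rng <- st$max - st$min
        ok <- !is.na(v)
        if (is.na(rng) || !any(ok)) next
        if (rng == 0) {
          sx <- outer(ok, ok, "&") * 1
          sx[!outer(ok, ok, "&")] <- NA_real_
        } else {
          sx <- 1 - abs(outer(v, v, "-")) / rng
          sx[sx < 0] <- 0
        }
      } else {
        v <- tab[[a]][idx]
        sx <- (outer(v, v, "==")) * 1
      }
      present <- !is.na(sx)
      acc[present] <- acc[present] + sx[present]
      cnt <- cnt + present
    }
  }
  if (n_attr == 0L) {
    warn(sprintf("meta-path %s involves no declared attributes; similarities are 0",
                 format(metapath)))
  }
  ifelse(cnt > 0L, acc / cnt, 0)
}

#' Similarity of two meta-path sequences
#'
#' The mean attribute similarity over all attributes of all node positions
#' of the meta-path, comparing position-wise (node *i* of one sequence
#' against node *i* of the other). Comparisons with a missing value are
#' dropped from numerator and denominator; if every comparison is missing
#' (or the meta-path carries no attributes) the similarity is 0, with a
#' warning in the no-attributes case.
#'
#' @param net A `hetnet`.
#' @param metapath The `metapath` both sequences instantiate.
#' @param seq1,seq2 Character vectors of node IDs, one per position.
#' @param stats Attribute ranges from [attribute_stats()] (computed from
#'   `net` when omitted).
#' @return Similarity in `[0, 1]`; symmetric in its sequence arguments.
#' @export
sequence_similarity <- function(net, metapath, seq1, seq2, stats = NULL) {
  k <- length(metapath$types)
  if (length(seq1) != k || length(seq2) != k) {
    abort("sequences must have one node per meta-path position")
  }
  stats <- stats %||% attribute_stats(net)
  sm <- seq_sim_matrix(net, metapath, rbind(seq1, seq2), stats)
  sm[1, 2]
}

#' Score one ncRNA-disease pair along one meta-path
#'
#' If any materialized sequence of the meta-path runs from `ncrna` to
#' `disease`, the pair is directly connected along this meta-path and the
#' score is exactly 1. Otherwise the score is the maximum
#' [sequence_similarity()] between the sequences starting at `ncrna` and the
#' sequences ending at `disease`; if either set is empty, 0.
#'
#' @param net A `hetnet`.
#' @param metapath A `metapath`.
#' @param ncrna,disease Node IDs of the two target types.
#' @param sequences Optional precomputed [path_sequences()] matrix.
#' @param stats Optional precomputed [attribute_stats()].
#' @param seq_cap Passed to [path_sequences()] when `sequences` is omitted.
#' @return Score in `[0, 1]`.
#' @export
pathscore <- function(net, metapath, ncrna, disease,
                      sequences = NULL, stats = NULL, seq_cap = Inf) {
  sequences <- sequences %||% path_sequences(net, metapath, seq_cap = seq_cap)
  if (nrow(sequences) == 0L) return(0)
  stats <- stats %||% attribute_stats(net)
  k <- ncol(sequences)
  i1 <- which(sequences[, 1] == ncrna)
  i2 <- which(sequences[, k] == disease)
  if (length(intersect(i1, i2))) return(1)
  if (!length(i1) || !length(i2)) return(0)
  sm <- seq_sim_matrix(net, metapath, sequences, stats)
  max(sm[i1, i2, drop = FALSE])
}

#' Propagate attributes of off-meta-path node types
#'
#' Node types not touched by any meta-path would otherwise contribute
#' nothing to the similarity. For every node of an on-path type, the
#' off-path nodes reachable within `depth` hops (walking only through
#' off-path nodes) are collected per type and their attributes aggregated:
#' arithmetic mean for numeric, mode for categorical (ties broken by the
#' lexicographically smallest label). The aggregate is appended as a new
#' attribute named `<off type>.<attribute>_mean` / `_mode`; original
#' attributes are untouched, and nodes with no reachable off-path neighbor
#' get a missing value. `depth = 0` returns the network unchanged.
#'
#' @param net A `hetnet`.
#' @param metapaths List of `metapath`s (from [enumerate_metapaths()]).
#' @param depth Maximum number of hops (default 2).
#' @return A `hetnet` with enriched attributes (schema updated accordingly).
#' @export
enrich_attributes <- function(net, metapaths, depth = 2) {
  stopifnot(depth >= 0)
  if (depth == 0 || !length(metapaths)) return(net)
  on_path <- unique(unlist(lapply(metapaths, `[[`, "types")))
  off_path <- setdiff(net$schema$node_types, on_path)
  if (!length(off_path)) return(net)
  adj <- full_adjacency(net)
  new_cols <- list()  # type -> list(colname -> values)
  for (t in on_path) {
    ids <- net$nodes[[t]]$id
    # reachable off-path nodes per node, grouped by off-path type
    reach <- lapply(ids, function(id) {
      frontier <- tibble(type = t, id = id)
      seen <- character()
      hits <- list()
      for (d in seq_len(depth)) {
        nxt <- list()
        for (i in seq_len(nrow(frontier))) {
          nb <- adj[[paste(frontier$type[i], frontier$id[i], sep = "\r")]]
          if (is.null(nb)) next
          nxt[[length(nxt) + 1L]] <- nb
        }
        if (!length(nxt)) break
        nb <- distinct(bind_rows(nxt))
        nb <- nb[nb$type %in% off_path, ]
        key <- paste(nb$type, nb$id, sep = "\r")
        fresh <- !(key %in% seen)
        nb <- nb[fresh, ]
        if (!nrow(nb)) break
        seen <- c(seen, key[fresh])
        hits[[length(hits) + 1L]] <- nb
        frontier <- nb
      }
      if (length(hits)) bind_rows(hits) else
        tibble(type = character(), id = character())
    })
    for (ot in sort_c(off_path)) {
      kinds <- schema_kinds(net$schema, ot)
      for (a in names(kinds)) {
        vals <- net$nodes[[ot]]
        col <- vapply(reach, function(r) {
          src <- r$id[r$type == ot]
          if (!length(src)) return(NA_character_)
          v <- vals[[a]][match(src, vals$id)]
          if (kinds[[a]] == "numeric") {
            v <- v[!is.na(v)]
            if (!length(v)) NA_character_ else as.character(mean(v))
          } else {
            m <- stat_mode(v)
            if (is.na(m)) NA_character_ else m
          }
        }, "")
        suffix <- if (kinds[[a]] == "numeric") "_mean" else "_mode"
        cname <- paste0(ot, ".", a, suffix)
        new_cols[[t]][[cname]] <-
          if (kinds[[a]] == "numeric") as.numeric(col) else col
      }
    }
  }
  for (t in names(new_cols)) {
    for (cname in names(new_cols[[t]])) {
      net$nodes[[t]][[cname]] <- new_cols[[t]][[cname]]
      kind <- if (is.numeric(new_cols[[t]][[cname]])) "numeric" else "categorical"
      net$schema$attributes[[t]] <-
        c(schema_kinds(net$schema, t), stats::setNames(kind, cname))
    }
  }
  net
}

# type\rid -> tibble(type, id) of all adjacent nodes (any edge type).
full_adjacency <- function(net) {
  out <- list()
  et <- net$schema$edge_types
  for (i in seq_len(nrow(et))) {
    tab <- net$edges[[et$name[i]]]
    if (!nrow(tab)) next
    for (j in seq_len(nrow(tab))) {
      k1 <- paste(et$from[i], tab$from[j], sep = "\r")
      k2 <- paste(et$to[i], tab$to[j], sep = "\r")
      out[[k1]] <- bind_rows(out[[k1]], tibble(type = et$to[i], id = tab$to[j]))
      out[[k2]] <- bind_rows(out[[k2]], tibble(type = et$from[i], id = tab$from[j]))
    }
  }
  lapply(out, distinct)
}

#' Score every ncRNA-disease pair (degree of certainty)
#'
#' Stage 1 of the pipeline. Meta-paths are enumerated up to `max_len` edges,
#' off-meta-path attributes are propagated onto on-path nodes up to `depth`
#' hops, and every (ncRNA, disease) pair receives the maximum [pathscore()]
#' over all meta-paths (fuzzy max composition: one confirming meta-path
#' suffices). Directly linked pairs score exactly 1; pairs with no meta-path
#' evidence score 0.
#'
#' @param net A validated `hetnet`.
#' @param max_len Maximum meta-path length in edges (default 3).
#' @param depth Attribute-propagation depth (default 2).
#' @param seq_cap Per-(meta-path, start node) cap on materialized sequences;
#'   exceeding it truncates deterministically with a warning.
#' @return A tibble of class `pair_scores` with columns `ncrna`, `disease`,
#'   `score` and `best_metapath` (dot-joined type names of the maximizing
#'   meta-path, `NA` when the score is 0), sorted by `ncrna`, `disease`.
#' @export
score_all_pairs <- function(net, max_len = 3, depth = 2, seq_cap = 1000) {
  stopifnot(inherits(net, "hetnet"))
  mps <- enumerate_metapaths(net, max_len = max_len)
  net2 <- enrich_attributes(net, mps, depth = depth)
  stats <- attribute_stats(net2)
  tt <- net2$schema$target_types
  ncrnas <- sort_c(net2$nodes[[tt[1]]]$id)
  diseases <- sort_c(net2$nodes[[tt[2]]]$id)
  grid <- tidyr::expand_grid(ncrna = ncrnas, disease = diseases)
  best <- rep(0, nrow(grid))
  best_mp <- rep(NA_character_, nrow(grid))
  key <- pair_key(grid$ncrna, grid$disease)
  for (mp in mps) {
    seqs <- path_sequences(net2, mp, seq_cap = seq_cap)
    if (nrow(seqs) == 0L) next
    k <- ncol(seqs)
    sm <- NULL  # computed lazily: direct-only meta-paths never need it
    start_idx <- split(seq_len(nrow(seqs)), seqs[, 1])
    end_idx <- split(seq_len(nrow(seqs)), seqs[, k])
    direct_keys <- unique(pair_key(seqs[, 1], seqs[, k]))
    hit_direct <- key %in% direct_keys
    upd <- hit_direct & best < 1
    best[upd] <- 1
    best_mp[upd] <- format(mp)
    todo <- which(!hit_direct & best < 1)
    if (length(todo)) {
      for (i in todo) {
        i1 <- start_idx[[grid$ncrna[i]]]
        i2 <- end_idx[[grid$disease[i]]]
        if (is.null(i1) || is.null(i2)) next
        if (is.null(sm)) sm <- seq_sim_matrix(net2, mp, seqs, stats)
        v <- max(sm[i1, i2, drop = FALSE])
        if (v > best[i]) {
          best[i] <- v
          best_mp[i] <- format(mp)
        }
      }
    }
  }
  out <- grid
  out$score <- best
  out$best_metapath <- best_mp
  class(out) <- c("pair_scores", class(out))
  out
}

#' Write pair scores to a TSV file
#'
#' Columns `ncrna_id`, `disease_id`, `score`, `best_metapath`; rows in
#' deterministic (ncrna, disease) lexicographic order.
#'
#' @param scores A `pair_scores` tibble from [score_all_pairs()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  out <- tibble(ncrna_id = scores$ncrna, disease_id = scores$disease,
                score = scores$score, best_metapath = scores$best_metapath)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
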