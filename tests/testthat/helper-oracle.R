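# Independent brute-force pair scorer: enumerates every simple path from
# every ncRNA to every disease (distinct node types, <= max_len edges),
# groups paths by their (node-type, edge-type) signature, and evaluates the
# max-similarity scoring naively with explicit loops. Deliberately written
# without any of the package's scoring internals.

oracle_scores <- function(net, max_len = 3) {
  tt <- net$schema$target_types
  et <- net$schema$edge_types
  # directed adjacency rows: (edge, type_a, id_a, type_b, id_b), both ways
  adj <- list()
  for (i in seq_len(nrow(et))) {
    tab <- net$edges[[et$name[i]]]
    if (!nrow(tab)) next
    for (r in seq_len(nrow(tab))) {
      adj[[length(adj) + 1L]] <- list(e = et$name[i], ta = et$from[i],
                                      a = tab$from[r], tb = et$to[i],
                                      b = tab$to[r])
      adj[[length(adj) + 1L]] <- list(e = et$name[i], ta = et$to[i],
                                      a = tab$to[r], tb = et$from[i],
                                      b = tab$from[r])
    }
  }

  # enumerate all paths ncRNA -> disease
  paths <- list()  # each: list(types, edges, ids)
  grow <- function(types, edges, ids) {
    cur_t <- types[length(types)]
    cur_i <- ids[length(ids)]
    if (cur_t == tt[2]) {
      paths[[length(paths) + 1L]] <<- list(types = types, edges = edges,
                                           ids = ids)
      return(invisible())
    }
    if (length(edges) >= max_len) return(invisible())
    for (row in adj) {
      if (row$ta == cur_t && row$a == cur_i && !(row$tb %in% types)) {
        grow(c(types, row$tb), c(edges, row$e), c(ids, row$b))
      }
    }
    invisible()
  }
  for (n0 in net$nodes[[tt[1]]]$id) grow(tt[1], character(), n0)

  # group by meta-path signature
  sig <- vapply(paths, function(p) {
    paste(paste(p$types, collapse = "."), paste(p$edges, collapse = "."),
          sep = "~")
  }, "")
  groups <- split(paths, sig)

  # attribute lookup and global ranges
  kinds_of <- function(type) net$schema$attributes[[type]]
  val_of <- function(type, id, attr) {
    tab <- net$nodes[[type]]
    tab[[attr]][tab$id == id]
  }
  range_of <- function(type, attr) {
    v <- net$nodes[[type]][[attr]]
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_) else c(min(v), max(v))
  }

  sim_naive <- function(p1, p2) {
    acc <- 0
    cnt <- 0L
    n_attr <- 0L
    for (pos in seq_along(p1$types)) {
      type <- p1$types[pos]
      kinds <- kinds_of(type)
      for (a in names(kinds)) {
        n_attr <- n_attr + 1L
        v1 <- val_of(type, p1$ids[pos], a)
        v2 <- val_of(type, p2$ids[pos], a)
        if (is.na(v1) || is.na(v2)) next
        if (kinds[[a]] == "numeric") {
          rng <- range_of(type, a)
          span <- rng[2] - rng[1]
          s <- if (is.na(span)) NA_real_ else if (span == 0) 1 else
            1 - abs(v1 - v2) / span
          if (is.na(s)) next
        } else {
          s <- if (v1 == v2) 1 else 0
        }
        acc <- acc + s
        cnt <- cnt + 1L
      }
    }
    if (cnt == 0L) 0 else acc / cnt
  }

  ncrnas <- sort(net$nodes[[tt[1]]]$id, method = "radix")
  diseases <- sort(net$nodes[[tt[2]]]$id, method = "radix")
  out <- expand.grid(ncrna = ncrnas, disease = diseases,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$ncrna, out$disease, method = "radix"), ]
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    n <- out$ncrna[i]; d <- out$disease[i]
    best <- 0
    for (grp in groups) {
      starts <- Filter(function(p) p$ids[1] == n, grp)
      ends <- Filter(function(p) p$ids[length(p$ids)] == d, grp)
      connecting <- Filter(function(p) p$ids[length(p$ids)] == d, starts)
      sc <- if (length(connecting)) {
        1
      } else if (!length(starts) || !length(ends)) {
        0
      } else {
        m <- 0
        for (p1 in starts) for (p2 in ends) {
          s <- sim_naive(p1, p2)
          if (s > m) m <- s
        }
        m
      }
      if (sc > best) best <- sc
    }
    best
  }, 0)
  rownames(out) <- NULL
  out
}
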