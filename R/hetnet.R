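#' Declare the schema of a heterogeneous attributed network
#'
#' A schema names the node types, designates the two *target* types whose
#' links are to be predicted (by convention an ncRNA-like type and a
#' disease-like type; all remaining types are *task-relevant* evidence), and
#' declares the typed attributes and typed edges.
#'
#' @param node_types Character vector of node type names.
#' @param target_types Character vector of length 2: the ncRNA-like target
#'   type first, the disease-like target type second. Both must appear in
#'   `node_types`.
#' @param edge_types Data frame with columns `name`, `from`, `to` declaring
#'   one edge type per row; `from`/`to` name declared node types. Edges are
#'   stored typed but traversed as undirected.
#' @param attributes Named list, one entry per node type (types without
#'   attributes may be omitted). Each entry is a named character vector
#'   mapping attribute name to kind, `"numeric"` or `"categorical"`.
#'
#' @return An object of class `hetnet_schema`.
#' @examples
#' hetnet_schema(
#'   node_types   = c("ncRNA", "disease", "gene"),
#'   target_types = c("ncRNA", "disease"),
#'   edge_types   = data.frame(
#'     name = c("ncRNA-gene", "gene-disease"),
#'     from = c("ncRNA", "gene"),
#'     to   = c("gene", "disease")
#'   ),
#'   attributes = list(ncRNA = c(biotype = "categorical"))
#' )
#' @export
hetnet_schema <- function(node_types, target_types, edge_types,
                          attributes = list()) {
  node_types <- as.character(node_types)
  if (anyDuplicated(node_types)) abort("duplicated node type names")
  if (length(target_types) != 2L || target_types[1] == target_types[2]) {
    abort("`target_types` must be two distinct node type names")
  }
  if (!all(target_types %in% node_types)) {
    abort("`target_types` must both be declared in `node_types`")
  }
  edge_types <- as_tibble(edge_types)
  stopifnot(all(c("name", "from", "to") %in% names(edge_types)))
  edge_types <- edge_types[, c("name", "from", "to")]
  if (anyDuplicated(edge_types$name)) abort("duplicated edge type names")
  bad <- !(edge_types$from %in% node_types & edge_types$to %in% node_types)
  if (any(bad)) {
    abort(sprintf("edge type(s) %s reference undeclared node types",
                  paste(edge_types$name[bad], collapse = ", ")))
  }
  if (!all(names(attributes) %in% node_types)) {
    abort("`attributes` entries must be named after declared node types")
  }
  attributes <- lapply(attributes, function(a) {
    a <- unlist(a)
    kinds <- as.character(a)
    if (!all(kinds %in% c("numeric", "categorical"))) {
      abort("attribute kinds must be 'numeric' or 'categorical'")
    }
    if (anyDuplicated(names(a))) abort("duplicated attribute names in a type")
    stats::setNames(kinds, names(a))
  })
  structure(
    list(node_types = node_types,
         target_types = as.character(target_types),
         edge_types = edge_types,
         attributes = attributes),
    class = "hetnet_schema"
  )
}

#' @export
print.hetnet_schema <- function(x, ...) {
  cat("<hetnet_schema>\n")
  cat("  node types:   ", paste(x$node_types, collapse = ", "), "\n")
  cat("  target types: ", paste(x$target_types, collapse = " - "), "\n")
  cat("  edge types:   ",
      paste(sprintf("%s (%s-%s)", x$edge_types$name, x$edge_types$from,
                    x$edge_types$to), collapse = ", "), "\n")
  invisible(x)
}

schema_kinds <- function(schema, type) {
  schema$attributes[[type]] %||% stats::setNames(character(), character())
}

coerce_attr_columns <- function(tab, kinds, type, file = NULL) {
  for (a in names(kinds)) {
    if (!a %in% names(tab)) {
      abort(sprintf("node table for type '%s' lacks declared attribute '%s'",
                    type, a))
    }
    v <- tab[[a]]
    v[v %in% c("", "NA")] <- NA
    if (kinds[[a]] == "numeric") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        abort(sprintf(
          "non-numeric token '%s' in numeric column '%s' of type '%s'%s (row %d)",
          v[bad[1]], a, type,
          if (is.null(file)) "" else paste0(" [", file, "]"), bad[1]))
      }
      if (any(is.infinite(num))) {
        abort(sprintf("non-finite value in numeric column '%s' of type '%s'",
                      a, type))
      }
      tab[[a]] <- num
    } else {
      tab[[a]] <- as.character(v)
    }
  }
  tab
}

#' Assemble a heterogeneous attributed network
#'
#' Validates node and edge tables against a [hetnet_schema()]: node IDs are
#' unique within each type (they are case-sensitive opaque strings; two types
#' may reuse an ID), every edge endpoint resolves to a declared node, numeric
#' attributes are finite or missing, and duplicate edges collapse to one.
#' Missing cells (`NA` or the literal string `"NA"`/empty) stay missing; they
#' are never imputed at load time.
#'
#' @param schema A [hetnet_schema()].
#' @param nodes Named list of data frames, one per node type. The first
#'   column is the node ID; remaining columns are the declared attributes.
#' @param edges Named list of data frames, one per edge type name. The first
#'   two columns are source and target node IDs (in the declared `from`/`to`
#'   type order). Missing edge types are treated as empty.
#'
#' @return An object of class `hetnet`.
#' @seealso [load_network()], [write_network()], [neighbors()],
#'   [known_target_pairs()]
#' @export
hetnet <- function(schema, nodes, edges = list()) {
  stopifnot(inherits(schema, "hetnet_schema"))
  out_nodes <- list()
  for (type in schema$node_types) {
    tab <- nodes[[type]]
    if (is.null(tab)) abort(sprintf("missing node table for type '%s'", type))
    tab <- as_tibble(tab)
    names(tab)[1] <- "id"
    tab$id <- as.character(tab$id)
    if (anyDuplicated(tab$id)) {
      dup <- tab$id[duplicated(tab$id)][1]
      abort(sprintf("duplicate node ID '%s' in type '%s'", dup, type))
    }
    tab <- coerce_attr_columns(tab, schema_kinds(schema, type), type)
    out_nodes[[type]] <- tab[, c("id", names(schema_kinds(schema, type)))]
  }
  out_edges <- list()
  for (i in seq_len(nrow(schema$edge_types))) {
    et <- schema$edge_types[i, ]
    tab <- edges[[et$name]]
    if (is.null(tab) || nrow(tab) == 0L) {
      out_edges[[et$name]] <- tibble(from = character(), to = character())
      next
    }
    tab <- as_tibble(tab)
    names(tab)[1:2] <- c("from", "to")
    tab$from <- as.character(tab$from)
    tab$to <- as.character(tab$to)
    miss_from <- !(tab$from %in% out_nodes[[et$from]]$id)
    miss_to <- !(tab$to %in% out_nodes[[et$to]]$id)
    if (any(miss_from) || any(miss_to)) {
      row <- which(miss_from | miss_to)[1]
      bad_id <- if (miss_from[row]) tab$from[row] else tab$to[row]
      bad_ty <- if (miss_from[row]) et$from else et$to
      abort(sprintf(
        "edge type '%s' row %d references unknown %s ID '%s'",
        et$name, row, bad_ty, bad_id))
    }
    if (et$from == et$to) {
      # same-type edges are unordered pairs: canonicalize before dedup
      swap <- tab$from > tab$to
      tmp <- tab$from[swap]; tab$from[swap] <- tab$to[swap]; tab$to[swap] <- tmp
    }
    tab <- distinct(tibble(from = tab$from, to = tab$to))
    out_edges[[et$name]] <- tab[order_c(tab$from, tab$to), ]
  }
  structure(list(schema = schema, nodes = out_nodes, edges = out_edges),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  n_nodes <- sum(vapply(x$nodes, nrow, 0L))
  n_edges <- sum(vapply(x$edges, nrow, 0L))
  cat(sprintf("<hetnet> %d nodes, %d edges\n", n_nodes, n_edges))
  for (t in x$schema$node_types) {
    cat(sprintf("  %s: %d nodes%s\n", t, nrow(x$nodes[[t]]),
                if (t %in% x$schema$target_types) " [target]" else ""))
  }
  for (e in names(x$edges)) {
    cat(sprintf("  %s: %d edges\n", e, nrow(x$edges[[e]])))
  }
  invisible(x)
}

#' Load a heterogeneous network from delimited files
#'
#' Reads a YAML schema plus one delimited table per node type and per edge
#' type, and validates the result (see [hetnet()] for the integrity rules).
#' The schema file has the layout:
#'
#' ```yaml
#' target_types: [ncRNA, disease]
#' node_types:
#'   ncRNA:   {attributes: {biotype: categorical}}
#'   disease: {attributes: {severity: numeric}}
#'   gene:    {}
#' edge_types:
#'   - {name: ncRNA-gene,  from: ncRNA, to: gene}
#'   - {name: gene-disease, from: gene, to: disease}
#' ```
#'
#' Node tables carry the ID in column 1 and one column per declared
#' attribute; edge tables carry source and target IDs in columns 1-2. A
#' header row is required. Empty cells and the literal `NA` are missing.
#'
#' @param schema_file Path to the YAML schema.
#' @param node_tables Named character vector/list mapping node type to file
#'   path.
#' @param edge_tables Named character vector/list mapping edge type name to
#'   file path; edge types without a file are empty.
#' @param delim Field delimiter, tab by default.
#'
#' @return A validated `hetnet`.
#' @export
load_network <- function(schema_file, node_tables, edge_tables = list(),
                         delim = "\t") {
  for (f in c(schema_file, unlist(node_tables), unlist(edge_tables))) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  schema <- read_schema(schema_file)
  read1 <- function(path) {
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE,
      na = character())
  }
  nodes <- lapply(node_tables, read1)
  edges <- lapply(edge_tables, read1)
  hetnet(schema, nodes, edges)
}

read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  nts <- names(y$node_types)
  attrs <- list()
  for (t in nts) {
    a <- y$node_types[[t]]$attributes
    if (length(a)) attrs[[t]] <- unlist(a)
  }
  ets <- bind_rows(lapply(y$edge_types, as_tibble))
  hetnet_schema(node_types = nts,
                target_types = unlist(y$target_types),
                edge_types = ets,
                attributes = attrs)
}

#' Write a heterogeneous network to delimited files
#'
#' Inverse of [load_network()]: emits `schema.yaml`, one `<type>.tsv` per
#' node type and one `<edge type>.tsv` per edge type into `dir`. A load of
#' the written files reproduces the node and edge sets exactly.
#'
#' @param net A `hetnet`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "hetnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- net$schema
  ylist <- list(
    target_types = as.list(s$target_types),
    node_types = stats::setNames(lapply(s$node_types, function(t) {
      k <- schema_kinds(s, t)
      if (length(k)) list(attributes = as.list(k)) else list()
    }), s$node_types),
    edge_types = lapply(seq_len(nrow(s$edge_types)), function(i) {
      as.list(s$edge_types[i, ])
    })
  )
  schema_path <- file.path(dir, "schema.yaml")
  yaml::write_yaml(ylist, schema_path)
  paths <- list(schema = schema_path)
  safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  for (t in s$node_types) {
    p <- file.path(dir, paste0("nodes_", safe(t), ".tsv"))
    readr::write_tsv(net$nodes[[t]], p, progress = FALSE)
    paths$nodes[[t]] <- p
  }
  for (e in names(net$edges)) {
    p <- file.path(dir, paste0("edges_", safe(e), ".tsv"))
    readr::write_tsv(net$edges[[e]], p, progress = FALSE)
    paths$edges[[e]] <- p
  }
  invisible(paths)
}

node_type_of <- function(net, edge_type, end = c("from", "to")) {
  end <- match.arg(end)
  et <- net$schema$edge_types
  et[[end]][et$name == edge_type]
}

#' Adjacent nodes of a node
#'
#' Returns all nodes adjacent to `(type, id)` through any edge type (or only
#' the named one), regardless of which endpoint the node occupies: edges are
#' typed but traversed as undirected.
#'
#' @param net A `hetnet`.
#' @param type,id Node type and node ID.
#' @param via Optional edge type name restricting the traversal.
#' @return A tibble with columns `type` and `id`, sorted.
#' @export
neighbors <- function(net, type, id, via = NULL) {
  stopifnot(inherits(net, "hetnet"))
  if (!type %in% net$schema$node_types || !id %in% net$nodes[[type]]$id) {
    abort(sprintf("unknown node (%s, %s)", type, id))
  }
  et <- net$schema$edge_types
  use <- if (is.null(via)) et$name else intersect(via, et$name)
  out <- list()
  for (e in use) {
    row <- et[et$name == e, ]
    tab <- net$edges[[e]]
    if (row$from == type) {
      out[[length(out) + 1L]] <- tibble(type = row$to,
                                        id = tab$to[tab$from == id])
    }
    if (row$to == type) {
      out[[length(out) + 1L]] <- tibble(type = row$from,
                                        id = tab$from[tab$to == id])
    }
  }
  res <- if (length(out)) distinct(bind_rows(out)) else
    tibble(type = character(), id = character())
  res[order_c(res$type, res$id), ]
}

target_edge_types <- function(net) {
  tt <- net$schema$target_types
  et <- net$schema$edge_types
  et$name[(et$from == tt[1] & et$to == tt[2]) |
          (et$from == tt[2] & et$to == tt[1])]
}

#' Known (directly linked) target-type pairs
#'
#' The positive set for link prediction: every ncRNA-disease pair joined by a
#' direct edge of any target-target edge type. Empty when the schema declares
#' no such edge type.
#'
#' @param net A `hetnet`.
#' @return Tibble with columns `ncrna`, `disease`, sorted, one row per pair.
#' @export
known_target_pairs <- function(net) {
  tt <- net$schema$target_types
  et <- net$schema$edge_types
  out <- list()
  for (e in target_edge_types(net)) {
    row <- et[et$name == e, ]
    tab <- net$edges[[e]]
    if (row$from == tt[1]) {
      out[[length(out) + 1L]] <- tibble(ncrna = tab$from, disease = tab$to)
    } else {
      out[[length(out) + 1L]] <- tibble(ncrna = tab$to, disease = tab$from)
    }
  }
  res <- if (length(out)) distinct(bind_rows(out)) else
    tibble(ncrna = character(), disease = character())
  res[order_c(res$ncrna, res$disease), ]
}

# Remove specific direct target-target edges (used by the CV holdout).
drop_target_edges <- function(net, pairs) {
  tt <- net$schema$target_types
  et <- net$schema$edge_types
  drop_key <- pair_key(pairs$ncrna, pairs$disease)
  for (e in target_edge_types(net)) {
    row <- et[et$name == e, ]
    tab <- net$edges[[e]]
    key <- if (row$from == tt[1]) pair_key(tab$from, tab$to) else
      pair_key(tab$to, tab$from)
    net$edges[[e]] <- tab[!(key %in% drop_key), ]
  }
  net
}
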