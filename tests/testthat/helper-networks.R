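# Small network builders shared across tests.

# Three-type schema (ncRNA, disease, gene) with a direct target edge type;
# every type is on some meta-path, so attribute propagation is a no-op.
tri_schema <- function(with_direct = TRUE) {
  et <- tibble::tibble(
    name = c("ncRNA-gene", "gene-disease", if (with_direct) "ncRNA-disease"),
    from = c("ncRNA", "gene", if (with_direct) "ncRNA"),
    to   = c("gene", "disease", if (with_direct) "disease"))
  hetnet_schema(
    node_types = c("ncRNA", "disease", "gene"),
    target_types = c("ncRNA", "disease"),
    edge_types = et,
    attributes = list(
      ncRNA = c(expr = "numeric", family = "categorical"),
      disease = c(sev = "numeric"),
      gene = c(act = "numeric")))
}

# Fully random small network on the three-type schema; sprinkles missing
# attribute values. Deterministic given seed.
random_tri_net <- function(seed, n_nc = 4, n_d = 4, n_g = 3,
                           p_edge = 0.4, p_direct = 0.25, p_na = 0.1) {
  withr::with_seed(seed, {
    schema <- tri_schema()
    maybe_na <- function(v) {
      v[stats::runif(length(v)) < p_na] <- NA
      v
    }
    nodes <- list(
      ncRNA = tibble::tibble(
        id = sprintf("n%d", seq_len(n_nc)),
        expr = maybe_na(round(stats::runif(n_nc, 0, 10), 2)),
        family = maybe_na(sample(c("mir", "lnc", "sno"), n_nc, TRUE))),
      disease = tibble::tibble(
        id = sprintf("d%d", seq_len(n_d)),
        sev = maybe_na(round(stats::runif(n_d, 0, 5), 2))),
      gene = tibble::tibble(
        id = sprintf("g%d", seq_len(n_g)),
        act = maybe_na(round(stats::runif(n_g, -1, 1), 2))))
    rand_edges <- function(a, b, p) {
      g <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
      g[stats::runif(nrow(g)) < p, ]
    }
    edges <- list(
      "ncRNA-gene" = rand_edges(nodes$ncRNA$id, nodes$gene$id, p_edge),
      "gene-disease" = rand_edges(nodes$gene$id, nodes$disease$id, p_edge),
      "ncRNA-disease" = rand_edges(nodes$ncRNA$id, nodes$disease$id, p_direct))
    hetnet(schema, nodes, edges)
  })
}

# Hand-built 5-node network: 2 ncRNAs, 2 diseases, 1 gene, 3 edges.
tiny_net <- function() {
  schema <- tri_schema()
  nodes <- list(
    ncRNA = tibble::tibble(id = c("n1", "n2"), expr = c(1, 2),
                           family = c("mir", "lnc")),
    disease = tibble::tibble(id = c("d1", "d2"), sev = c(3, 4)),
    gene = tibble::tibble(id = "g1", act = 0.5))
  edges <- list(
    "ncRNA-gene" = tibble::tibble(from = "n1", to = "g1"),
    "gene-disease" = tibble::tibble(from = "g1", to = "d1"),
    "ncRNA-disease" = tibble::tibble(from = "n1", to = "d2"))
  hetnet(schema, nodes, edges)
}

# Write a network's tables to a temp dir and return load_network arguments.
net_files <- function(net, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- write_network(net, dir)
  list(schema = paths$schema,
       nodes = unlist(paths$nodes),
       edges = unlist(paths$edges))
}

# A hierarchy object wrapping the worked two-cluster example as one level.
fixture_hierarchy <- function() {
  fx <- fixture_prediction_example()
  structure(list(levels = list(fx$clusters), rel = fx$rel,
                 alpha = 0.2, beta = 0.4),
            class = "cluster_hierarchy")
}
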