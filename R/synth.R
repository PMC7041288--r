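#' Configuration for the planted-cluster network generator
#'
#' Describes a synthetic heterogeneous network with ncRNA, disease and gene
#' node types and planted multi-type clusters. Each planted cluster is a
#' block of ncRNAs, diseases and genes with dense internal connectivity
#' (ncRNA-gene and gene-disease edges with probability `p_gene`; direct
#' ncRNA-disease edges with probability `p_direct`) and correlated
#' attributes: every node type carries one numeric attribute drawn around a
#' cluster-specific mean (means spaced 1 apart, shared noise `attr_sd`) and
#' one categorical attribute equal to the cluster label, flipped to another
#' label with probability `flip_prob`. Cross-cluster noise edges of any type
#' appear with probability `p_noise`. Within-cluster attribute agreement
#' makes meta-path sequence similarity high inside clusters and low across
#' them, emulating the network autocorrelation that the scoring stage
#' exploits; generation is fully determined by `seed`.
#'
#' @param n_clusters Number of planted clusters.
#' @param ncrnas_per_cluster,diseases_per_cluster,genes_per_cluster Block
#'   side sizes.
#' @param p_direct Intra-cluster direct ncRNA-disease edge probability.
#' @param p_gene Intra-cluster ncRNA-gene and gene-disease edge probability.
#' @param p_noise Cross-cluster edge probability (any edge type).
#' @param attr_sd Standard deviation of the numeric attributes around their
#'   cluster mean (cluster means are spaced 1 apart).
#' @param flip_prob Probability that a categorical attribute takes a label
#'   other than its cluster's.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_clusters = 2,
                         ncrnas_per_cluster = 3,
                         diseases_per_cluster = 3,
                         genes_per_cluster = 2,
                         p_direct = 0.8,
                         p_gene = 1.0,
                         p_noise = 0.02,
                         attr_sd = 0.1,
                         flip_prob = 0.05,
                         seed = 1) {
  for (nm in c("p_direct", "p_gene", "p_noise", "flip_prob")) {
    check_prob(get(nm), nm)
  }
  counts <- c(n_clusters, ncrnas_per_cluster, diseases_per_cluster,
              genes_per_cluster)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("cluster counts and side sizes must be positive integers")
  }
  if (attr_sd < 0) abort("`attr_sd` must be non-negative")
  structure(list(n_clusters = n_clusters,
                 ncrnas_per_cluster = ncrnas_per_cluster,
                 diseases_per_cluster = diseases_per_cluster,
                 genes_per_cluster = genes_per_cluster,
                 p_direct = p_direct, p_gene = p_gene, p_noise = p_noise,
                 attr_sd = attr_sd, flip_prob = flip_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic network with planted multi-type clusters
#'
#' Realizes a [synth_config()] as a validated `hetnet` plus its ground
#' truth. Every planted direct ncRNA-disease edge is returned as a positive
#' pair, and the planted block memberships are returned for recovery tests.
#'
#' @param cfg A [synth_config()].
#' @return List with `network` (a `hetnet`) and `ground_truth` (list with
#'   `clusters`, a list of `ncrnas`/`diseases` sets, and `positive_pairs`,
#'   a tibble of the planted direct edges).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_network_impl(cfg))
}

generate_network_impl <- function(cfg) {
  k <- cfg$n_clusters
  mk_ids <- function(prefix, per, k) {
    lapply(seq_len(k), function(c) {
      sprintf("%s%02d_%02d", prefix, c, seq_len(per))
    })
  }
  nc <- mk_ids("n", cfg$ncrnas_per_cluster, k)
  di <- mk_ids("d", cfg$diseases_per_cluster, k)
  ge <- mk_ids("g", cfg$genes_per_cluster, k)
  labels <- sprintf("c%02d", seq_len(k))

  attr_tab <- function(ids_by_cluster, num_name, cat_name) {
    bind_rows(lapply(seq_len(k), function(c) {
      ids <- ids_by_cluster[[c]]
      num <- stats::rnorm(length(ids), mean = c, sd = cfg$attr_sd)
      flip <- stats::runif(length(ids)) < cfg$flip_prob
      lab <- rep(labels[c], length(ids))
      if (any(flip) && k > 1) {
        lab[flip] <- vapply(which(flip), function(i) {
          sample(setdiff(labels, labels[c]), 1)
        }, "")
      }
      out <- tibble(id = ids)
      out[[num_name]] <- num
      out[[cat_name]] <- lab
      out
    }))
  }
  nodes <- list(
    ncRNA = attr_tab(nc, "expression", "family"),
    disease = attr_tab(di, "severity", "category"),
    gene = attr_tab(ge, "activity", "pathway"))

  pair_block <- function(a, b, p) {
    if (p <= 0) return(tibble(from = character(), to = character()))
    g <- tidyr::expand_grid(from = a, to = b)
    g[stats::runif(nrow(g)) < p, ]
  }
  edges_of <- function(side_a, side_b, p_intra, p_cross) {
    intra <- bind_rows(lapply(seq_len(k), function(c) {
      pair_block(side_a[[c]], side_b[[c]], p_intra)
    }))
    cross <- bind_rows(lapply(seq_len(k), function(c1) {
      bind_rows(lapply(setdiff(seq_len(k), c1), function(c2) {
        pair_block(side_a[[c1]], side_b[[c2]], p_cross)
      }))
    }))
    bind_rows(intra, cross)
  }
  edges <- list(
    "ncRNA-gene" = edges_of(nc, ge, cfg$p_gene, cfg$p_noise),
    "gene-disease" = edges_of(ge, di, cfg$p_gene, cfg$p_noise),
    "ncRNA-disease" = edges_of(nc, di, cfg$p_direct, cfg$p_noise))

  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease", "gene"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble(
      name = c("ncRNA-gene", "gene-disease", "ncRNA-disease"),
      from = c("ncRNA", "gene", "ncRNA"),
      to = c("gene", "disease", "disease")),
    attributes = list(
      ncRNA = c(expression = "numeric", family = "categorical"),
      disease = c(severity = "numeric", category = "categorical"),
      gene = c(activity = "numeric", pathway = "categorical")))
  net <- hetnet(schema, nodes, edges)

  nd <- net$edges[["ncRNA-disease"]]
  positive_pairs <- tibble(ncrna = nd$from, disease = nd$to)
  positive_pairs <- positive_pairs[order_c(positive_pairs$ncrna,
                                           positive_pairs$disease), ]
  clusters <- lapply(seq_len(k), function(c) {
    list(ncrnas = sort_c(nc[[c]]), diseases = sort_c(di[[c]]))
  })
  list(network = net,
       ground_truth = list(clusters = clusters,
                           positive_pairs = positive_pairs))
}

#' Export a synthetic network to the on-disk table format
#'
#' Writes the same schema + TSV layout that [load_network()] consumes, plus
#' a `ground_truth.json` with the planted clusters and positive pairs.
#'
#' @param sim Result of [generate_network()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_synthetic <- function(sim, dir) {
  paths <- write_network(sim$network, dir)
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$ground_truth, gt, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(ground_truth = gt)))
}

#' Worked overlapping-cluster example
#'
#' Two overlapping multi-type clusters at one hierarchy level, used
#' throughout the documentation and tests: `C1` spans ncRNAs `{n1, n2}` and
#' diseases `{d1, d2, d3}` with retained relationship scores 0.7, 0.8, 0.9
#' (all on `n1`); `C2` spans ncRNA `{n2}` and diseases `{d3, d4}` with one
#' retained score 0.6 on `(n2, d4)`. The clusters overlap on `(n2, d3)`, so
#' their cohesiveness values (0.4 and 0.3) combine under every aggregator:
#' max 0.4, min 0.3, average 0.35, evidence combination 0.58.
#'
#' @return List with `clusters` (list of the two clusters) and `rel` (the
#'   retained scored pairs, a tibble).
#' @export
fixture_prediction_example <- function() {
  rel <- tibble(
    ncrna = c("n1", "n1", "n1", "n2"),
    disease = c("d1", "d2", "d3", "d4"),
    score = c(0.7, 0.8, 0.9, 0.6))
  clusters <- list(
    new_cluster(c("n1", "n2"), c("d1", "d2", "d3")),
    new_cluster("n2", c("d3", "d4")))
  smap <- rel_score_map(rel)
  clusters <- lapply(clusters, function(C) {
    C$h <- cohesiveness_impl(C, smap)
    C
  })
  list(clusters = clusters, rel = rel)
}

#' Small network exercising the sequence-comparison structure
#'
#' A network whose single indirect meta-path (ncRNA - gene - disease)
#' yields exactly 2 sequences starting at ncRNA `n1` and exactly 4
#' sequences ending at disease `d3`, with no sequence connecting the two,
#' so that the pair score is the maximum over the 2 x 4 pairwise sequence
#' similarities. Attributes give distinct, hand-checkable similarity
#' values.
#'
#' @return A validated `hetnet`.
#' @export
fixture_sequence_example <- function() {
  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease", "gene"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble(
      name = c("ncRNA-gene", "gene-disease", "ncRNA-disease"),
      from = c("ncRNA", "gene", "ncRNA"),
      to = c("gene", "disease", "disease")),
    attributes = list(
      ncRNA = c(conservation = "numeric", biotype = "categorical"),
      disease = c(prevalence = "numeric"),
      gene = c(activity = "numeric")))
  nodes <- list(
    ncRNA = tibble(id = c("n1", "n2", "n3", "n4"),
                   conservation = c(0.9, 0.8, 0.4, 0.1),
                   biotype = c("lncrna", "lncrna", "mirna", "mirna")),
    disease = tibble(id = c("d1", "d2", "d3"),
                     prevalence = c(0.2, 0.5, 0.9)),
    gene = tibble(id = c("g1", "g2", "g3"),
                  activity = c(1.0, 2.0, 4.0)))
  edges <- list(
    "ncRNA-gene" = tibble(
      from = c("n1", "n2", "n3", "n3", "n4"),
      to = c("g1", "g2", "g2", "g3", "g3")),
    "gene-disease" = tibble(
      from = c("g1", "g1", "g2", "g3"),
      to = c("d1", "d2", "d3", "d3")))
  hetnet(schema, nodes, edges)
}
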