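test_that("meta-path enumeration is exhaustive, bounded and ordered", {
  net <- tiny_net()
  mps <- enumerate_metapaths(net, max_len = 2)
  expect_length(mps, 2L)
  # shortest first
  expect_equal(mps[[1]]$types, c("ncRNA", "disease"))
  expect_equal(mps[[2]]$types, c("ncRNA", "gene", "disease"))

  # five-type schema: via genes, via proteins, and direct -> 3 meta-paths
  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease", "gene", "protein"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble::tibble(
      name = c("ncRNA-gene", "gene-disease", "ncRNA-protein",
               "protein-disease", "ncRNA-disease"),
      from = c("ncRNA", "gene", "ncRNA", "protein", "ncRNA"),
      to = c("gene", "disease", "protein", "disease", "disease")))
  nodes <- list(ncRNA = tibble::tibble(id = "n1"),
                disease = tibble::tibble(id = "d1"),
                gene = tibble::tibble(id = "g1"),
                protein = tibble::tibble(id = "p1"))
  net5 <- hetnet(schema, nodes, list())
  expect_length(enumerate_metapaths(net5, max_len = 2), 3L)

  # no path within the bound -> empty with a warning
  schema_nd <- tri_schema(with_direct = FALSE)
  net_nd <- hetnet(schema_nd, net$nodes,
                   net$edges[c("ncRNA-gene", "gene-disease")])
  expect_warning(mps1 <- enumerate_metapaths(net_nd, max_len = 1),
                 "no meta-path")
  expect_length(mps1, 0L)
})

test_that("attribute similarity follows the normalized-distance rule", {
  expect_equal(attribute_similarity(2, 4, "numeric", 0, 10), 0.8)
  expect_equal(attribute_similarity("mirna", "mirna", "categorical"), 1)
  expect_equal(attribute_similarity("mirna", "lncrna", "categorical"), 0)
  # constant attribute: identical present values are maximally similar
  expect_equal(attribute_similarity(5, 5, "numeric", 5, 5), 1)
  expect_true(is.na(attribute_similarity(NA, 3, "numeric", 0, 10)))
})

test_that("sequence similarity averages attribute similarities", {
  net <- fixture_sequence_example()
  mp <- enumerate_metapaths(net, max_len = 2)[[2]]
  expect_equal(mp$types, c("ncRNA", "gene", "disease"))
  stats <- attribute_stats(net)

  # identical sequences are maximally similar
  expect_equal(
    sequence_similarity(net, mp, c("n1", "g1", "d1"), c("n1", "g1", "d1"),
                        stats), 1)

  # hand evaluation: attributes are ncRNA conservation (range 0.8) and
  # biotype, gene activity (range 3), disease prevalence (range 0.7).
  # n1 vs n2: conservation 1-0.1/0.8 = 0.875, biotype equal = 1
  # g1 vs g2: activity 1-1/3
  # d1 vs d2: prevalence 1-0.3/0.7
  manual <- (0.875 + 1 + (1 - 1 / 3) + (1 - 0.3 / 0.7)) / 4
  expect_equal(
    sequence_similarity(net, mp, c("n1", "g1", "d1"), c("n2", "g2", "d2"),
                        stats), manual)

  # symmetry
  s1 <- sequence_similarity(net, mp, c("n1", "g1", "d1"), c("n3", "g2", "d3"),
                            stats)
  s2 <- sequence_similarity(net, mp, c("n3", "g2", "d3"), c("n1", "g1", "d1"),
                            stats)
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 <= 1)
})

test_that("missing attribute values are dropped pairwise", {
  schema <- tri_schema()
  nodes <- list(
    ncRNA = tibble::tibble(id = c("n1", "n2"), expr = c(2, NA),
                           family = c("mir", "mir")),
    disease = tibble::tibble(id = c("d1", "d2"), sev = c(1, 3)),
    gene = tibble::tibble(id = "g1", act = 0))
  net <- hetnet(schema, nodes, list(
    "ncRNA-disease" = tibble::tibble(from = c("n1", "n2"), to = c("d1", "d2"))))
  mp <- enumerate_metapaths(net, max_len = 1)[[1]]
  stats <- attribute_stats(net)
  # expr comparison drops (n2 is NA); family (1) and sev (1-2/2=0) remain
  expect_equal(
    sequence_similarity(net, mp, c("n1", "d1"), c("n2", "d2"), stats),
    (1 + 0) / 2)
})

test_that("a meta-path without declared attributes warns and scores 0", {
  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble::tibble(name = "nd", from = "ncRNA", to = "disease"))
  net <- hetnet(schema,
                list(ncRNA = tibble::tibble(id = c("n1", "n2")),
                     disease = tibble::tibble(id = c("d1", "d2"))),
                list(nd = tibble::tibble(from = "n1", to = "d1")))
  mp <- enumerate_metapaths(net, max_len = 1)[[1]]
  expect_warning(
    s <- sequence_similarity(net, mp, c("n1", "d1"), c("n2", "d2")),
    "no declared attributes")
  expect_equal(s, 0)
})

test_that("pathscore applies the direct-connection rule and the 2x4 max", {
  net <- fixture_sequence_example()
  mps <- enumerate_metapaths(net, max_len = 2)
  mp_direct <- mps[[1]]
  mp_gene <- mps[[2]]
  stats <- attribute_stats(net)

  seqs <- path_sequences(net, mp_gene)
  from_n1 <- seqs[seqs[, 1] == "n1", , drop = FALSE]
  into_d3 <- seqs[seqs[, 3] == "d3", , drop = FALSE]
  expect_equal(nrow(from_n1), 2L)
  expect_equal(nrow(into_d3), 4L)

  # the score is the max over the 8 pairwise similarity evaluations
  sims <- vapply(seq_len(nrow(from_n1)), function(i) {
    vapply(seq_len(nrow(into_d3)), function(j) {
      sequence_similarity(net, mp_gene, from_n1[i, ], into_d3[j, ], stats)
    }, 0)
  }, numeric(nrow(into_d3)))
  expect_length(sims, 8L)
  expect_equal(pathscore(net, mp_gene, "n1", "d3"), max(sims))
  expect_lt(max(sims), 1)

  # adding a direct edge makes the direct meta-path score 1
  net2 <- net
  net2$edges[["ncRNA-disease"]] <- tibble::tibble(from = "n1", to = "d3")
  expect_equal(pathscore(net2, mp_direct, "n1", "d3"), 1)
  # a sequence running n -> d along any meta-path also scores 1
  expect_equal(pathscore(net, mp_gene, "n2", "d3"), 1)
  # no sequence touches the ncRNA -> 0
  expect_equal(pathscore(net2, mp_direct, "n2", "d1"), 0)
})

test_that("attribute enrichment aggregates off-path neighborhoods", {
  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease", "gene", "protein"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble::tibble(
      name = c("ncRNA-gene", "gene-disease", "gene-protein"),
      from = c("ncRNA", "gene", "gene"),
      to = c("gene", "disease", "protein")),
    attributes = list(
      protein = c(score = "numeric", loc = "categorical")))
  nodes <- list(
    ncRNA = tibble::tibble(id = "n1"),
    disease = tibble::tibble(id = "d1"),
    gene = tibble::tibble(id = c("g1", "g2")),
    protein = tibble::tibble(id = c("p1", "p2", "p3"),
                             score = c(2, 4, 100),
                             loc = c("nucleus", "nucleus", "cytosol")))
  edges <- list(
    "ncRNA-gene" = tibble::tibble(from = "n1", to = "g1"),
    "gene-disease" = tibble::tibble(from = "g1", to = "d1"),
    "gene-protein" = tibble::tibble(from = c("g1", "g1"), to = c("p1", "p2")))
  net <- hetnet(schema, nodes, edges)
  mps <- enumerate_metapaths(net, max_len = 2)
  expect_equal(unique(unlist(lapply(mps, `[[`, "types"))),
               c("ncRNA", "gene", "disease"))

  # depth 0 is the identity
  expect_identical(enrich_attributes(net, mps, depth = 0), net)

  enriched <- enrich_attributes(net, mps, depth = 1)
  g <- enriched$nodes$gene
  expect_equal(g[["protein.score_mean"]][g$id == "g1"], 3)  # mean(2, 4)
  expect_equal(g[["protein.loc_mode"]][g$id == "g1"], "nucleus")
  # g2 has no off-path neighbor -> missing
  expect_true(is.na(g[["protein.score_mean"]][g$id == "g2"]))
  # new attributes are declared in the schema for downstream similarity
  expect_true("protein.score_mean" %in%
                names(enriched$schema$attributes$gene))

  # mode ties break to the lexicographically smallest label
  nodes$protein$loc <- c("nucleus", "cytosol", "x")
  edges[["gene-protein"]] <- tibble::tibble(from = c("g1", "g1"),
                                            to = c("p1", "p2"))
  net_tie <- hetnet(schema, nodes, edges)
  en2 <- enrich_attributes(net_tie, mps, depth = 1)
  expect_equal(en2$nodes$gene[["protein.loc_mode"]][1], "cytosol")
})

test_that("enrichment walks only through off-path nodes up to depth", {
  schema <- hetnet_schema(
    node_types = c("ncRNA", "disease", "gene", "protein", "complex"),
    target_types = c("ncRNA", "disease"),
    edge_types = tibble::tibble(
      name = c("ncRNA-gene", "gene-disease", "gene-protein",
               "protein-complex"),
      from = c("ncRNA", "gene", "gene", "protein"),
      to = c("gene", "disease", "protein", "complex")),
    attributes = list(complex = c(size = "numeric")))
  nodes <- list(
    ncRNA = tibble::tibble(id = "n1"),
    disease = tibble::tibble(id = "d1"),
    gene = tibble::tibble(id = "g1"),
    protein = tibble::tibble(id = "p1"),
    complex = tibble::tibble(id = "c1", size = 7))
  edges <- list(
    "ncRNA-gene" = tibble::tibble(from = "n1", to = "g1"),
    "gene-disease" = tibble::tibble(from = "g1", to = "d1"),
    "gene-protein" = tibble::tibble(from = "g1", to = "p1"),
    "protein-complex" = tibble::tibble(from = "p1", to = "c1"))
  net <- hetnet(schema, nodes, edges)
  mps <- enumerate_metapaths(net, max_len = 2)
  # the complex sits 2 hops away through the off-path protein
  d1 <- enrich_attributes(net, mps, depth = 1)
  expect_true(is.na(d1$nodes$gene[["complex.size_mean"]][1]))
  d2 <- enrich_attributes(net, mps, depth = 2)
  expect_equal(d2$nodes$gene[["complex.size_mean"]][1], 7)
})

test_that("score_all_pairs takes the fuzzy max and honors direct links", {
  net <- tiny_net()
  scores <- score_all_pairs(net, max_len = 2)
  expect_equal(nrow(scores), 4L)  # 2 ncRNAs x 2 diseases
  expect_true(all(scores$score >= 0 & scores$score <= 1))
  # direct edge n1-d2 -> exactly 1
  expect_equal(scores$score[scores$ncrna == "n1" & scores$disease == "d2"], 1)
  # n1-g1-d1 is a connecting sequence -> 1 through the gene meta-path
  expect_equal(scores$score[scores$ncrna == "n1" & scores$disease == "d1"], 1)
  # n2 is isolated -> no evidence, score 0 and no best meta-path
  n2 <- scores[scores$ncrna == "n2", ]
  expect_true(all(n2$score == 0))
  expect_true(all(is.na(n2$best_metapath)))
})

test_that("adding meta-paths never decreases a pair score", {
  # depth 0 keeps the attribute set fixed, isolating the max composition
  for (seed in c(3, 14, 15)) {
    net <- random_tri_net(seed)
    s1 <- score_all_pairs(net, max_len = 1, depth = 0)
    s2 <- score_all_pairs(net, max_len = 2, depth = 0)
    expect_equal(s1$ncrna, s2$ncrna)
    expect_true(all(s2$score - s1$score >= 0))
  }
})

test_that("score_all_pairs matches the brute-force oracle on small nets", {
  for (seed in c(2, 5, 8)) {
    net <- random_tri_net(seed)
    got <- score_all_pairs(net, max_len = 2, seq_cap = Inf)
    want <- oracle_scores(net, max_len = 2)
    expect_equal(got$score, want$score, tolerance = 0)
  }
})

test_that("the sequence cap truncates deterministically with a warning", {
  net <- fixture_sequence_example()
  mp <- enumerate_metapaths(net, max_len = 2)[[2]]
  expect_warning(seqs <- path_sequences(net, mp, seq_cap = 1),
                 "truncating")
  # one sequence per starting ncRNA, in lexicographic DFS order
  expect_equal(nrow(seqs), 4L)
  expect_warning(seqs2 <- path_sequences(net, mp, seq_cap = 1))
  expect_identical(seqs, seqs2)
})
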