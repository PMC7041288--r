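scores_tbl <- function(ncrna, disease, score) {
  tibble::tibble(ncrna = ncrna, disease = disease, score = score)
}

test_that("filtering keeps exactly the pairs at or above beta", {
  sc <- scores_tbl(c("n1", "n1", "n2"), c("d1", "d2", "d1"),
                   c(0.3, 0.45, 0.9))
  expect_equal(nrow(filter_pairs(sc, 0.4)), 2L)
  expect_equal(nrow(filter_pairs(sc, 0)), 3L)
  expect_warning(none <- filter_pairs(sc, 0.95), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("beta = 1 retains exactly the directly linked pairs", {
  net <- random_tri_net(21, p_direct = 0.4)
  sc <- score_all_pairs(net, max_len = 2, seq_cap = Inf)
  kept <- filter_pairs(sc, 1)
  # oracle: score 1 arises iff some path connects the pair (direct edge or
  # connecting sequence); with max_len 1 restriction to direct edges only
  direct <- known_target_pairs(net)
  sc1 <- score_all_pairs(net, max_len = 1)
  kept1 <- filter_pairs(sc1, 1)
  expect_setequal(paste(kept1$ncrna, kept1$disease),
                  paste(direct$ncrna, direct$disease))
  expect_true(all(paste(direct$ncrna, direct$disease) %in%
                    paste(kept$ncrna, kept$disease)))
})

test_that("cohesiveness divides retained scores by all possible pairs", {
  fx <- fixture_prediction_example()
  expect_equal(cohesiveness(fx$clusters[[1]], fx$rel), 0.4)
  expect_equal(cohesiveness(fx$clusters[[2]], fx$rel), 0.3)
  # complete biclique with all scores 1 reaches the ceiling
  rel <- scores_tbl(rep(c("n1", "n2"), each = 2),
                    rep(c("d1", "d2"), 2), rep(1, 4))
  C <- list(ncrnas = c("n1", "n2"), diseases = c("d1", "d2"))
  expect_equal(cohesiveness(C, rel), 1)
})

test_that("cluster ordering is by cohesiveness with deterministic ties", {
  rel <- scores_tbl(c("n1", "n2", "n3", "n4"), c("d1", "d2", "d3", "d4"),
                    c(0.9, 0.5, 0.6, 0.6))
  a <- list(ncrnas = "n1", diseases = "d1")
  b <- list(ncrnas = "n2", diseases = "d2")
  expect_equal(cluster_order(a, b, rel), -1L)
  expect_equal(cluster_order(b, a, rel), 1L)
  expect_equal(cluster_order(a, a, rel), 0L)

  # equal cohesiveness: fewer possible pairs precedes
  big <- list(ncrnas = c("n3", "n4"), diseases = c("d3", "d4"))
  rel2 <- scores_tbl(c("n3", "n3", "n4", "n4", "n5"),
                     c("d3", "d4", "d3", "d4", "d5"),
                     c(0.6, 0.6, 0.6, 0.6, 0.6))
  small <- list(ncrnas = "n5", diseases = "d5")
  expect_equal(cohesiveness(big, rel2), cohesiveness(small, rel2))
  expect_equal(cluster_order(small, big, rel2), -1L)
})

test_that("initial bicliques are one per pair, highest score first", {
  rel <- scores_tbl(c("n1", "n2", "n3"), c("d1", "d2", "d3"),
                    c(0.5, 0.9, 0.7))
  init <- init_bicliques(rel)
  expect_length(init, 3L)
  expect_equal(init[[1]]$ncrnas, "n2")
  expect_equal(init[[1]]$h, 0.9)
  expect_length(init_bicliques(rel[0, ]), 0L)
})

test_that("greedy biclique merging reaches the complete biclique", {
  rel <- scores_tbl(rep(c("n1", "n2"), each = 2), rep(c("d1", "d2"), 2),
                    c(0.8, 0.9, 0.85, 0.95))
  L1 <- merge_bicliques(init_bicliques(rel), rel)
  expect_length(L1, 1L)
  expect_equal(L1[[1]]$ncrnas, c("n1", "n2"))
  expect_equal(L1[[1]]$diseases, c("d1", "d2"))

  # missing cross pairs forbid any merge
  rel2 <- scores_tbl(c("n1", "n2"), c("d1", "d2"), c(0.8, 0.9))
  L1b <- merge_bicliques(init_bicliques(rel2), rel2)
  expect_length(L1b, 2L)
})

test_that("the biclique constraint responds to beta as in the 0.7/0.6 case", {
  # a 2x2 block where one pair scores 0.6 and the rest 0.7+
  sc <- scores_tbl(rep(c("n1", "n2"), each = 2), rep(c("d1", "d2"), 2),
                   c(0.7, 0.8, 0.6, 0.9))
  run <- function(beta) {
    rel <- filter_pairs(sc, beta)
    merge_bicliques(init_bicliques(rel), rel)
  }
  # beta 0.6: all four pairs retained -> one 2x2 biclique
  expect_length(run(0.6), 1L)
  # beta 0.7: the 0.6 pair is dropped -> the 2x2 union is no biclique
  L <- run(0.7)
  expect_true(all(vapply(L, function(C)
    length(C$ncrnas) * length(C$diseases), 0) < 4))
})

test_that("level merging is gated by alpha and stops at the fixpoint", {
  # two 1x1 clusters whose union has h = (0.4 + 0.3) / 4 = 0.175... use
  # scores giving union h = 0.35: (0.8 + 0.6)/4 = 0.35
  rel <- scores_tbl(c("n1", "n2"), c("d1", "d2"), c(0.8, 0.6))
  prev <- init_bicliques(rel)
  merged <- merge_level(prev, rel, alpha = 0.2)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$h, 0.35)
  expect_identical(merge_level(prev, rel, alpha = 0.4), "stop")
})

test_that("smaller alpha never yields a shallower hierarchy", {
  for (seed in c(1, 4, 9)) {
    sim <- generate_network(synth_config(seed = seed, p_noise = 0.05))
    sc <- score_all_pairs(sim$network, max_len = 2)
    k_small <- length(build_hierarchy(sc, alpha = 0.1, beta = 0.4)$levels)
    k_large <- length(build_hierarchy(sc, alpha = 0.2, beta = 0.4)$levels)
    expect_gte(k_small, k_large)
  }
})

test_that("build_hierarchy recovers planted bicliques and merges them", {
  sim <- generate_network(synth_config(
    n_clusters = 2, p_direct = 1, p_noise = 0, attr_sd = 0, flip_prob = 0,
    seed = 5))
  sc <- score_all_pairs(sim$network, max_len = 2)
  hier <- build_hierarchy(sc, alpha = 0.2, beta = 0.5)
  L1 <- hier$levels[[1]]
  expect_length(L1, 2L)
  got <- lapply(L1, function(C) C[c("ncrnas", "diseases")])
  want <- sim$ground_truth$clusters
  key <- function(C) paste(paste(C$ncrnas, collapse = ","),
                           paste(C$diseases, collapse = ","))
  expect_setequal(vapply(got, key, ""), vapply(want, key, ""))

  # both planted clusters are fully linked (p_direct = 1), so their union
  # has h = 18/36 = 0.5 > alpha: level 2 is their union
  expect_gte(length(hier$levels), 2L)
  L2 <- hier$levels[[2]]
  expect_length(L2, 1L)
  expect_equal(cohesiveness(L2[[1]], hier$rel), 0.5)
})

test_that("beta = 1 with no direct edges gives an empty hierarchy", {
  net <- random_tri_net(30, p_direct = 0)
  # also remove indirect connections' certainty by pruning gene edges
  net$edges[["ncRNA-gene"]] <- net$edges[["ncRNA-gene"]][0, ]
  sc <- score_all_pairs(net, max_len = 2)
  # warns both about the empty filtered set and the empty hierarchy
  expect_warning(expect_warning(
    hier <- build_hierarchy(sc, alpha = 0.2, beta = 1)))
  expect_length(hier$levels, 0L)
})

test_that("tidy and glance summarize the hierarchy", {
  hier <- fixture_hierarchy()
  long <- tidy(hier)
  expect_setequal(names(long),
                  c("level", "cluster", "h", "member_type", "member_id"))
  expect_equal(sum(long$member_type == "ncrna" & long$cluster == 1), 2L)
  g <- glance(hier)
  expect_equal(g$n_levels, 1L)
  expect_equal(g$n_clusters_l1, 2L)
})

test_that("hierarchies are deterministic and serializable", {
  sim <- generate_network(synth_config(seed = 12, p_noise = 0.05))
  sc <- score_all_pairs(sim$network, max_len = 2)
  h1 <- build_hierarchy(sc, alpha = 0.2, beta = 0.4)
  h2 <- build_hierarchy(sc, alpha = 0.2, beta = 0.4)
  expect_identical(h1, h2)

  dir <- withr::local_tempdir()
  paths <- write_hierarchy(h1, dir)
  expect_true(file.exists(file.path(dir, "hierarchy.json")))
  meta <- jsonlite::read_json(file.path(dir, "hierarchy.json"))
  expect_equal(meta$n_levels, length(h1$levels))
})
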