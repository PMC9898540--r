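test_that("feature matrix is log2(abundance + pseudocount) in fixed order", {
  ab <- toy_abundance(data.frame(
    barcode = c("A", "B", "Z"),
    cell_type = c("Gr", "Gr", "Gr"),
    timepoint = c(2.5, 2.5, 3.5),
    abundance = c(1.0, 0.5, 0.05)), timepoints = c(2.5, 3.5, 5.5, 6.5))
  expect_message(fm <- build_feature_matrix(ab, timepoints = c(2.5, 5.5, 6.5)),
                 "dropped")
  expect_equal(colnames(fm$features),
               paste0(rep(cell_types(), 3), "_",
                      rep(c("2.5", "5.5", "6.5"), each = 4)))
  expect_equal(fm$features["A\rm1", "Gr_2.5"], log2(1 + 1e-4))
  expect_equal(fm$features["A\rm1", "B_2.5"], log2(1e-4))
  expect_equal(unname(fm$features[, "Gr_2.5"][2]), log2(0.5 + 1e-4))
  # the all-zero clone Z was dropped (its only signal is at 3.5 months)
  expect_equal(nrow(fm$features), 2L)
  expect_error(build_feature_matrix(ab, timepoints = c(2.5, 4.5)),
               "unknown timepoint")
})

test_that("PCA scores are deterministic, sign-fixed and distance-preserving", {
  set.seed(3)
  x <- matrix(rnorm(20 * 12), 20, 12)
  rownames(x) <- sprintf("c%02d", 1:20)
  s1 <- run_pca(x, 12)
  s2 <- run_pca(x, 12)
  expect_identical(s1, s2)
  # full-rank rotation preserves pairwise distances of the prepared features
  prep <- scale(x)
  expect_equal(as.matrix(dist(s1)), as.matrix(dist(prep)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # rank-1 input: PC1 carries all variance
  r1 <- outer(seq_len(10), rep(1, 12)) + matrix(1, 10, 12)
  r1 <- r1 * rep(runif(12, .5, 2), each = 10)
  s <- run_pca(r1, 3, scale. = FALSE)
  expect_lt(sum(s[, 2:3]^2) / sum(s^2), 1e-12)
  # duplicated rows give identical score rows
  dup <- rbind(x, x[1, , drop = FALSE])
  sd_ <- run_pca(dup, 5)
  expect_equal(unname(sd_[21, ]), unname(sd_[1, ]))
  expect_error(run_pca(x[1, , drop = FALSE], 2), "at least 2")
  expect_error(run_pca(x, 13), "exceeds")
})

test_that("SNN graph respects separation, duplicates and completeness", {
  # two well-separated clouds: no cross-cloud edges
  set.seed(4)
  pts <- rbind(matrix(rnorm(20, 0, .1), 10, 2),
               matrix(rnorm(20, 50, .1), 10, 2))
  rownames(pts) <- sprintf("p%02d", 1:20)
  g <- knn_graph(pts, k = 3)
  el <- igraph::as_edgelist(g)
  side <- function(v) as.integer(substr(v, 2, 3)) > 10
  expect_true(all(side(el[, 1]) == side(el[, 2])))

  # identical points: mutual weight 1
  same <- matrix(1, 4, 2, dimnames = list(letters[1:4], NULL))
  gs <- knn_graph(same, k = 3)
  expect_equal(igraph::ecount(gs), 6)
  expect_true(all(igraph::E(gs)$weight == 1))

  # k = n - 1 gives the complete graph before weight pruning
  gk <- knn_graph(pts, k = 19)
  expect_equal(igraph::ecount(gk), choose(20, 2))

  expect_error(knn_graph(pts, k = 0), "positive")
  expect_error(knn_graph(pts, k = 20), "smaller")
})

test_that("community detection separates cliques and never splits a uniform complete graph", {
  # two disconnected cliques -> exactly their two communities
  g2 <- igraph::disjoint_union(igraph::make_full_graph(6),
                               igraph::make_full_graph(4))
  igraph::E(g2)$weight <- 1
  igraph::V(g2)$name <- sprintf("v%02d", 1:10)
  cl <- cluster_graph(g2, resolution = 1, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(unname(cl[1:6]), rep(0L, 6))  # larger clique is cluster 0

  # exhaustive oracle: on a uniform complete graph no split beats the
  # trivial partition's modularity, so Louvain returns one cluster
  g1 <- igraph::make_full_graph(6)
  igraph::E(g1)$weight <- 1
  igraph::V(g1)$name <- letters[1:6]
  mods <- vapply(all_partitions(6), function(p) {
    memb <- integer(6)
    for (i in seq_along(p)) memb[p[[i]]] <- i
    igraph::modularity(g1, memb, weights = igraph::E(g1)$weight)
  }, numeric(1))
  trivial <- igraph::modularity(g1, rep(1L, 6), weights = igraph::E(g1)$weight)
  expect_equal(max(mods), trivial)
  expect_equal(length(unique(cluster_graph(g1, 1, seed = 5))), 1L)

  # determinism
  set.seed(8)
  pts <- matrix(rnorm(120), 60, 2)
  rownames(pts) <- sprintf("p%02d", 1:60)
  g <- knn_graph(pts, k = 10)
  expect_identical(cluster_graph(g, 1, seed = 17), cluster_graph(g, 1, seed = 17))
})

test_that("2D embedding has the right shape, is seeded and keeps duplicates together", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40, 6)
  rownames(x) <- sprintf("c%02d", 1:40)
  e1 <- embed_2d(x, seed = 3)
  e2 <- embed_2d(x, seed = 3)
  expect_equal(dim(e1), c(40L, 2L))
  expect_identical(e1, e2)

  dup <- rbind(x, x[5, , drop = FALSE])
  rownames(dup) <- c(rownames(x), "dup")
  ed <- embed_2d(dup, seed = 3)
  dd <- as.matrix(dist(ed))
  expect_lt(dd["dup", "c05"], quantile(dd[upper.tri(dd)], 0.01))

  expect_error(embed_2d(x[1:2, ]), "at least 3")
})

test_that("cluster timing categories follow the majority rule and its oracle", {
  ab <- toy_abundance(data.frame(
    barcode = c("S1", "S2", "L1", "L2", "M1"),
    cell_type = "Gr",
    timepoint = c(2.5, 2.5, 6.5, 6.5, 5.5),
    abundance = 0.05), timepoints = c(2.5, 5.5, 6.5))
  asg <- setNames(c(0L, 0L, 1L, 1L, 2L),
                  clone_id(c("S1", "S2", "L1", "L2", "M1"), "m1"))
  terms <- categorize_clusters(ab, asg)
  expect_equal(unname(terms[c("0", "1", "2")]),
               c("short_term", "long_term", "middle_term"))

  # long-term takes precedence when both early and late majorities hold
  ab2 <- toy_abundance(data.frame(
    barcode = c("P", "P"), cell_type = "Gr", timepoint = c(2.5, 6.5),
    abundance = 0.05), timepoints = c(2.5, 5.5, 6.5))
  t2 <- categorize_clusters(ab2, setNames(0L, clone_id("P", "m1")))
  expect_equal(unname(t2), "long_term")

  # random assignments vs the literal tally oracle
  set.seed(14)
  ab3 <- random_abundance(30, timepoints = c(2.5, 5.5, 6.5))
  pres <- detect_produced_types(ab3)
  ids <- unique(clone_id(pres$barcode, pres$mouse))
  det <- sapply(c("2.5", "5.5", "6.5"), function(tp) {
    sub <- pres[pres$timepoint == as.numeric(tp), ]
    tapply(sub$present, clone_id(sub$barcode, sub$mouse), any)[ids]
  })
  asg3 <- setNames(sample(0:3, length(ids), replace = TRUE), ids)
  expect_equal(categorize_clusters(ab3, asg3),
               oracle_term_categories(det, asg3, "2.5", "6.5", "5.5"))
})

test_that("the clustering pipeline is deterministic and permutation-invariant", {
  sim <- generate_dataset(planted3_config(), seed = 3)
  ab <- run_quantify(sim)
  r1 <- cluster_clones(ab, k = 50, resolution = 0.5, seed = 17, embed = FALSE)
  r2 <- cluster_clones(ab, k = 50, resolution = 0.5, seed = 17, embed = FALSE)
  expect_identical(r1$clones, r2$clones)

  # permuting clone rows and sample columns changes nothing
  perm <- sample(nrow(ab))
  ab_p <- ab[perm, sample(ncol(ab))]
  r3 <- cluster_clones(ab_p, k = 50, resolution = 0.5, seed = 17,
                       embed = FALSE)
  expect_identical(r1$clones, r3$clones)
})
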