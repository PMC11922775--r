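make_toy <- function(sets, log2fc, p = NULL, anchor = NULL) {
  genes <- unique(unlist(sets))
  if (is.null(p)) p <- rep(0.01, length(genes))
  pc <- pathway_collection(sets, anchor = anchor)
  tab <- filter_significant(deg_table(genes, log2fc[genes], p), 0.05)
  net <- build_network(pc, tab)
  list(pc = pc, tab = tab, net = net)
}

test_that("pathway impact follows the expression-weighted centrality formula", {
  # single-gene pathway: impact = (-score) * |log2fc|
  toy <- make_toy(list(P = "g1", Q = "g1"),
                  c(g1 = 2))
  sc <- data.frame(gene = "g1", score = -0.5, degree = 2)
  expect_equal(pathway_impacts(toy$net, sc, toy$tab, "P"), 1.0)

  # genes with zero score contribute zero impact
  sc0 <- data.frame(gene = "g1", score = 0, degree = 2)
  expect_equal(pathway_impacts(toy$net, sc0, toy$tab, "P"), 0)

  expect_error(pathway_impacts(toy$net, sc, toy$tab, "missing"),
               "not in network")

  # random universe: spreadsheet-style recomputation
  set.seed(23)
  u <- random_small_universe(n_genes = 18, n_pathways = 5, max_size = 6)
  net <- build_network(u$pathways, u$table)
  scores <- node_removal_centrality(net)
  impacts <- pathway_impacts(net, scores, u$table)
  for (p in net$pathways) {
    g <- net$sig_members[[p]]
    manual <- mean(vapply(g, function(gg) {
      -scores$score[scores$gene == gg] *
        abs(u$table$log2fc[u$table$feature_id == gg])
    }, numeric(1)))
    expect_equal(impacts[[p]], manual, tolerance = 1e-12)
  }
})

test_that("impact similarity is an anchored min-max of absolute divergence", {
  expect_equal(similarity_to_anchor(c(anchor = 2), "anchor"),
               c(anchor = 1))
  sim <- similarity_to_anchor(c(anchor = 2, p = 2, q = 5), "anchor")
  expect_equal(sim, c(anchor = 1, p = 1, q = 0))
  sim3 <- similarity_to_anchor(c(anchor = 1, a = 2, b = 3, c = 5), "anchor")
  expect_equal(unname(sim3["a"]), 1)
  expect_gt(sim3[["b"]], 0); expect_lt(sim3[["b"]], 1)
  expect_equal(unname(sim3["c"]), 0)
})

test_that("connection strength blends Ochiai overlap with inverse hops", {
  # pathway sharing all genes with the anchor: Ochiai 1, hop 2
  toy <- make_toy(list(autophagy = c("g1", "g2"), P = c("g1", "g2"),
                       Q = c("g9", "g8")),
                  c(g1 = 1, g2 = 1, g8 = 1, g9 = 1), anchor = "autophagy")
  raw <- connection_strength(toy$net, normalize = FALSE)
  expect_equal(raw[["P"]], 0.5 * 1 + 0.5 * (1 / 3), tolerance = 1e-12)
  # different component, no shared genes
  expect_equal(raw[["Q"]], 0)
  # the anchor is 1 by convention after normalization
  norm <- connection_strength(toy$net)
  expect_equal(norm[["autophagy"]], 1)
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("key regulator index matches eigenvector closed forms", {
  # projection star: hub pathway shares one gene with each of 4 leaves
  sets <- list(hub = c("a", "b", "c", "d"),
               L1 = c("a", "x1"), L2 = c("b", "x2"),
               L3 = c("c", "x3"), L4 = c("d", "x4"))
  fc <- setNames(rep(1, 8), c("a", "b", "c", "d", "x1", "x2", "x3", "x4"))
  toy <- make_toy(sets, fc)
  idx <- key_regulator_index(toy$net)
  expect_equal(idx[["hub"]], 1)
  leaves <- idx[c("L1", "L2", "L3", "L4")]
  expect_true(all(abs(leaves - 1 / sqrt(4)) < 1e-8))
  # independent route: igraph's eigenvector centrality on the projection
  ig <- igraph::eigen_centrality(toy$net$projection, weights =
                                   igraph::E(toy$net$projection)$weight)$vector
  expect_equal(unname(idx[names(ig)]), unname(ig), tolerance = 1e-6)

  # two disconnected equal-weight pairs: componentwise values, overall max 1
  sets2 <- list(A = c("a", "s"), B = c("a", "t"),
                C = c("b", "u"), D = c("b", "v"))
  fc2 <- setNames(rep(1, 6), c("a", "b", "s", "t", "u", "v"))
  toy2 <- make_toy(sets2, fc2)
  idx2 <- key_regulator_index(toy2$net)
  expect_equal(unname(idx2), rep(1, 4))

  # pathway sharing no gene is isolated in the projection: index 0
  sets3 <- list(A = c("a", "b"), B = c("a", "c"), lone = c("z1", "z2"))
  fc3 <- setNames(rep(1, 5), c("a", "b", "c", "z1", "z2"))
  toy3 <- make_toy(sets3, fc3)
  expect_equal(key_regulator_index(toy3$net)[["lone"]], 0)
})

test_that("the combined coefficient is a monotone bounded blend", {
  cfg <- run_config()
  sim <- c(autophagy = 1, a = 1, b = 0.35)
  rec <- combine_and_rank(sim, sim, sim, cfg)
  expect_equal(rec$combined[rec$pathway == "a"], 1)
  expect_equal(rec$rank[rec$pathway == "a"], 1)
  expect_false("autophagy" %in% rec$pathway)

  bad <- c(autophagy = 1, a = 1.4)
  expect_error(combine_and_rank(bad, sim[1:2], sim[1:2], cfg), "outside")

  # raising any single component strictly raises the coefficient
  set.seed(29)
  for (i in 1:100) {
    comp <- runif(3)
    base <- sum(comp * cfg$weights)
    j <- sample(3, 1)
    bumped <- comp
    bumped[j] <- min(1, comp[j] + runif(1, 0.01, 0.3))
    expect_gt(sum(bumped * cfg$weights), base)
  }
})

test_that("minimum node distance and chains follow the membership hops", {
  # source gene inside the target pathway: one hop
  toy <- make_toy(list(autophagy = c("g1", "g2")), c(g1 = 1, g2 = 1),
                  anchor = "autophagy")
  res <- min_node_distance("g1", "autophagy", toy$net)
  expect_equal(res$distance, 1)
  expect_equal(res$chain, c("g1", "autophagy"))

  # ciliary-motor exemplar: Kif3a shares a pathway with Prkaca, which sits
  # in the autophagy pathway -> 3 hops through Prkaca
  sets <- list(cAMP = c("Kif3a", "Prkaca"),
               autophagy = c("Prkaca", "Atg7"))
  fc <- setNames(rep(1, 3), c("Kif3a", "Prkaca", "Atg7"))
  toy2 <- make_toy(sets, fc, anchor = "autophagy")
  res2 <- min_node_distance("Kif3a", "autophagy", toy2$net)
  expect_equal(res2$distance, 3)
  expect_equal(res2$chain, c("Kif3a", "cAMP", "Prkaca", "autophagy"))
  expect_equal(res2$kinds, c("gene", "pathway", "gene", "pathway"))

  # disconnected source is flagged unreachable, absent sources reported
  sets3 <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  fc3 <- setNames(rep(1, 4), paste0("g", 1:4))
  toy3 <- make_toy(sets3, fc3)
  res3 <- min_node_distance(c("g1", "ghost"), "B", toy3$net)
  expect_false(res3$reachable)
  expect_equal(res3$missing_sources, "ghost")
  expect_error(min_node_distance("ghost", "B", toy3$net), "no source gene")
})

test_that("shortest chains agree with the BFS oracle on random graphs", {
  set.seed(31)
  for (i in 1:20) {
    u <- random_small_universe(n_genes = sample(8:20, 1),
                               n_pathways = sample(2:6, 1), max_size = 6)
    net <- build_network(u$pathways, u$table)
    target <- sample(net$pathways, 1)
    sources <- sample(net$genes, min(3, length(net$genes)))
    d_oracle <- oracle_min_distance(net$sig_members, sources, target)
    res <- min_node_distance(sources, target, net)
    if (is.finite(d_oracle)) {
      expect_equal(res$distance, d_oracle)
      expect_equal(length(res$chain) - 1, res$distance)
      expect_true(res$chain[1] %in% sources)
      expect_equal(res$chain[length(res$chain)], target)
    } else {
      expect_false(res$reachable)
    }
  }
})

test_that("the planted near pathway outranks the planted far pathway", {
  for (seed in c(2, 6)) {
    u <- generate_universe(synthetic_spec(seed = seed, n_genes = 200,
                                          n_pathways = 16,
                                          planted_zone = list(start = 11, length = 15, direction = 1)))
    res <- prioritize_pathways(u$pathways, u$table, run_config(seed = seed))
    rec <- res$records
    expect_lt(rec$rank[rec$pathway == u$truth$near],
              rec$rank[rec$pathway == u$truth$far])
    expect_true(all(rec$combined >= 0 & rec$combined <= 1))
  }
})
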