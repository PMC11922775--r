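test_that("removal scores carry the central/peripheral sign convention", {
  # star: one pathway holding three genes; every gene is peripheral,
  # removal tightens the remainder
  pc <- pathway_collection(list(P = c("g1", "g2", "g3")))
  tab <- filter_significant(deg_table(paste0("g", 1:3), rep(1, 3),
                                      rep(0.01, 3)), 0.05)
  net <- build_network(pc, tab)
  sc <- node_removal_centrality(net)
  expect_true(all(sc$score > 0))
  expect_true(all(!sc$is_central))

  # bridge gene g2 joins two pathways; its removal disconnects the graph
  pc2 <- pathway_collection(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
  tab2 <- filter_significant(deg_table(paste0("g", 1:3), rep(1, 3),
                                       rep(0.01, 3)), 0.05)
  net2 <- build_network(pc2, tab2)
  sc2 <- node_removal_centrality(net2)
  expect_lt(sc2$score[sc2$gene == "g2"], 0)
  expect_true(sc2$is_central[sc2$gene == "g2"])
  # and the numeric value matches the brute-force recomputation
  expect_equal(sc2$score[sc2$gene == "g2"],
               oracle_removal_score(net2$sig_members, "g2"),
               tolerance = 1e-12)

  # single-gene network: score is the efficiency change by definition
  pc3 <- pathway_collection(list(P = "g1", Q = "g1"))
  tab3 <- filter_significant(deg_table("g1", 1, 0.01), 0.05)
  net3 <- build_network(pc3, tab3)
  sc3 <- node_removal_centrality(net3)
  expect_equal(sc3$score, 0 - connectedness(net3))
})

test_that("removing a cut vertex severing a node pair is always central", {
  set.seed(13)
  for (i in 1:8) {
    u <- random_small_universe(n_genes = sample(8:16, 1),
                               n_pathways = sample(3:5, 1), max_size = 5)
    net <- build_network(u$pathways, u$table)
    m <- net$membership
    cuts <- intersect(igraph::articulation_points(m)$name, net$genes)
    sc <- node_removal_centrality(net)
    for (g in cuts) {
      # severed side must contain at least one node pair for the drop
      # in efficiency to be guaranteed
      rest <- igraph::delete_vertices(m, g)
      comp <- igraph::components(rest)
      if (comp$no > 1 && sum(comp$csize > 1) > 1) {
        expect_lt(sc$score[sc$gene == g], 0)
      }
    }
  }
})

test_that("gene ordering is deterministic with documented tie-breaks", {
  sc <- data.frame(gene = c("a", "b", "c"),
                   score = c(-0.3, -0.1, 0.2),
                   degree = c(2, 2, 1))
  rk <- rank_genes(sc)
  expect_equal(rk$order$gene, c("a", "b", "c"))
  expect_equal(rk$central$gene, c("a", "b"))

  all_pos <- data.frame(gene = c("a", "b"), score = c(0.1, 0.2),
                        degree = c(1, 1))
  expect_warning(rk2 <- rank_genes(all_pos), "no central genes")
  expect_equal(nrow(rk2$central), 0)

  # tie on score: higher degree first, then lexicographic id
  tie <- data.frame(gene = c("zz", "aa", "mm"),
                    score = c(-0.2, -0.2, -0.2),
                    degree = c(1, 1, 5))
  expect_equal(rank_genes(tie)$order$gene, c("mm", "aa", "zz"))
})

test_that("ordered enrichment matches closed forms on small universes", {
  universe <- paste0("g", 1:10)
  pc <- pathway_collection(list(P = c("g1", "g2", "g3")))
  res <- ordered_enrichment(c("g1", "g2", "g3"), pc, universe)
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$k_star, 3)

  # pathway disjoint from the list
  pc2 <- pathway_collection(list(P = c("g8", "g9")))
  expect_equal(ordered_enrichment(c("g1", "g2"), pc2, universe)$p, 1)

  # single-gene pathway whose gene tops the list
  pc3 <- pathway_collection(list(P = "g4"))
  res3 <- ordered_enrichment(c("g4", "g1", "g2"), pc3, universe)
  expect_equal(res3$p, 1 / 10, tolerance = 1e-12)
  expect_equal(res3$k_star, 1)

  expect_error(ordered_enrichment(paste0("g", 1:5), pc,
                                  universe = paste0("g", 1:3)),
               "smaller")
})

test_that("min-prefix p-values equal exhaustive enumeration", {
  set.seed(17)
  for (i in 1:12) {
    N <- sample(5:12, 1)
    universe <- paste0("x", seq_len(N))
    K <- sample(1:(N - 1), 1)
    members <- paste0("x", seq_len(K))   # oracle codes members as 1..K
    L <- sample(2:N, 1)
    listed <- sample(universe, L)
    pc <- pathway_collection(list(P = members))
    res <- ordered_enrichment(listed, pc, universe)
    x <- cumsum(listed %in% members)
    p_oracle <- min(vapply(seq_len(L), function(k) {
      oracle_hyper_tail(N, K, k, x[k])
    }, numeric(1)))
    expect_equal(res$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("BH-adjusted q-values dominate p and order the output", {
  set.seed(19)
  u <- random_small_universe(n_genes = 25, n_pathways = 6, max_size = 8)
  universe <- sprintf("g%02d", 1:25)
  res <- ordered_enrichment(sample(universe, 10), u$pathways, universe)
  expect_true(all(res$q >= res$p))
  expect_true(!is.unsorted(res$q))
})
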