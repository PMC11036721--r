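test_that("hand-enumerated centralities on P3, K4 and the 4-leaf star", {
  p3 <- path_p3()
  expect_equal(unname(centrality(p3, "Betweenness")["b"]), 1)
  expect_equal(unname(centrality(p3, "Stress")["b"]), 1)
  expect_equal(unname(centrality(p3, "Closeness")["b"]), 2)
  expect_equal(unname(centrality(p3, "EcCentricity")["b"]), 1)
  expect_equal(unname(centrality(p3, "Radiality")["b"]), 2)
  expect_equal(unname(centrality(p3, "Degree")["b"]), 2)

  k4 <- complete_graph(letters[1:4])
  expect_equal(as.vector(centrality(k4, "MCC")), rep(6, 4))        # 3!
  expect_equal(as.vector(centrality(k4, "ClusteringCoefficient")), rep(1, 4))
  expect_equal(as.vector(centrality(k4, "DMNC")), rep(3 / 3^1.7, 4))

  s5 <- star_graph("c", 4)
  expect_equal(unname(centrality(s5, "Degree")["c"]), 4)
  expect_equal(unname(centrality(s5, "Betweenness")["c"]), 6)   # C(4,2)
  expect_equal(unname(centrality(s5, "MNC")["c"]), 1)
  expect_equal(unname(centrality(s5, "ClusteringCoefficient")["c"]), 0)
  expect_equal(unname(centrality(s5, "BottleNeck")["c"]), 4)
  expect_equal(unname(centrality(s5, "MCC")["c"]), 4)  # edgeless neighborhood -> degree

  expect_error(centrality(p3, "PageRank"), "unknown measure")
  expect_error(centrality(p3, "EPC"), "seed")
})

test_that("all deterministic measures equal brute-force oracles on 50 random graphs", {
  withr::with_seed(2024, {
    for (rep in 1:50) {
      n <- sample(4:10, 1)
      g <- random_er_graph(n, stats::runif(1, 0.2, 0.7))
      a <- oracle_adj(g)
      vs <- igraph::V(g)$name
      sb <- oracle_stress_betweenness(a)
      mnc <- oracle_mnc_dmnc(a)
      expect_equal(unname(centrality(g, "Degree")[vs]),
                   unname(oracle_degree(a)[vs]))
      expect_equal(unname(centrality(g, "Stress")[vs]),
                   unname(sb$stress[vs]))
      expect_equal(unname(centrality(g, "Betweenness")[vs]),
                   unname(sb$betweenness[vs]))
      expect_equal(unname(centrality(g, "Closeness")[vs]),
                   unname(oracle_closeness(a)[vs]))
      expect_equal(unname(centrality(g, "EcCentricity")[vs]),
                   unname(oracle_eccentricity_inv(a)[vs]))
      expect_equal(unname(centrality(g, "Radiality")[vs]),
                   unname(oracle_radiality(a)[vs]))
      expect_equal(unname(centrality(g, "ClusteringCoefficient")[vs]),
                   unname(oracle_clustering(a)[vs]))
      expect_equal(unname(centrality(g, "MNC")[vs]),
                   unname(mnc$size[vs]))
      expect_equal(unname(centrality(g, "DMNC")[vs]),
                   unname(mnc$dmnc[vs]))
      expect_equal(unname(centrality(g, "MCC")[vs]),
                   unname(oracle_mcc(a)[vs]))
      expect_equal(unname(centrality(g, "BottleNeck")[vs]),
                   unname(oracle_bottleneck(a)[vs]))
    }
  })
})

test_that("vertex-transitive graphs give constant scores; edges never lower degree/MCC", {
  # odd ring: shortest paths are unique, so even the tree-based BottleNeck
  # respects the symmetry (on even cycles its deterministic parent tie-break
  # necessarily picks one of two equal trees)
  ring <- graph_from_pairs(paste0("r", 1:7), paste0("r", c(2:7, 1)))
  igraph::E(ring)$combined_score <- 0.8
  for (meas in setdiff(CENTRALITY_MEASURES, "EPC")) {
    sc <- centrality(ring, meas)
    expect_lt(diff(range(sc)), 1e-12)
  }
  epc <- centrality(ring, "EPC", seed = 7, epc_rounds = 400)
  expect_lt(diff(range(epc)), 6 * max(attr(epc, "mc_se")))

  withr::with_seed(31, {
    for (rep in 1:10) {
      g <- random_er_graph(8, 0.4)
      free <- which(oracle_adj(g) == 0 & upper.tri(oracle_adj(g)), arr.ind = TRUE)
      if (!nrow(free)) next
      pick <- free[sample(nrow(free), 1), ]
      vs <- igraph::V(g)$name
      g2 <- igraph::add_edges(g, vs[pick])
      for (meas in c("Degree", "MCC")) {
        before <- centrality(g, meas)[vs[pick]]
        after <- centrality(g2, meas)[vs[pick]]
        expect_true(all(after >= before - 1e-12))
      }
    }
  })
})

test_that("EPC is seed-reproducible, respects edge probabilities, reports its SE", {
  g <- two_k4_with_bridge()
  igraph::E(g)$combined_score <- 0.7
  e1 <- centrality(g, "EPC", seed = 5, epc_rounds = 300)
  e2 <- centrality(g, "EPC", seed = 5, epc_rounds = 300)
  expect_equal(as.vector(e1), as.vector(e2))
  expect_length(attr(e1, "mc_se"), igraph::vcount(g))
  expect_true(all(attr(e1, "mc_se") >= 0))
  # probability-1 edges make EPC exactly (component size - 1)
  igraph::E(g)$combined_score <- 1
  esure <- centrality(g, "EPC", seed = 1, epc_rounds = 10)
  expect_equal(as.vector(esure), rep(igraph::vcount(g) - 1,
                                     igraph::vcount(g)))
})

test_that("consensus ranks nodes by top-k membership with stated tie-breaks", {
  # planted hub: member of a K6 and additionally wired to ten 2-node chains,
  # so it dominates degree, cliques, paths and reach
  k6 <- t(utils::combn(c("hub", paste0("x", 1:5)), 2))
  spokes <- cbind("hub", sprintf("t%02d", 1:10))
  chains <- cbind(sprintf("t%02d", 1:10), sprintf("u%02d", 1:10))
  ee <- rbind(k6, spokes, chains)
  hubfix <- graph_from_pairs(ee[, 1], ee[, 2])
  igraph::E(hubfix)$combined_score <- 0.9
  for (seed in 1:10) {
    cons <- consensus_hubs(all_centralities(hubfix, seed = seed,
                                            epc_rounds = 200))
    expect_equal(cons$table$gene[1], "hub")
    expect_gte(cons$table$n_lists[1], 10)
  }

  # full symmetry: K5 consensus is the lexicographic first five
  k5 <- complete_graph(paste0("n", 5:1))
  igraph::E(k5)$combined_score <- 0.8
  cons5 <- consensus_hubs(all_centralities(k5, seed = 3, epc_rounds = 100))
  expect_equal(cons5$hubs, paste0("n", 1:5))
  expect_equal(cons5$strict_intersection, paste0("n", 1:5))

  r <- all_centralities(path_p3(), seed = 1, epc_rounds = 10)
  expect_error(consensus_hubs(r[-1]), "MCC")
})
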