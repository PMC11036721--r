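de_fixture <- function() {
  data.frame(gene = c("lnc1", "lnc2", "circ1", "miR1", "miR2", "m1", "m2", "m3"),
             interval = "3w-4w",
             status = c("U", "D", "U", "D", "M", "U", "D", "U"))
}

test_that("pair filtering keeps only doubly-differential pairs with directions", {
  pairs <- data.frame(source_id = c("lnc1", "lnc2", "lnc1", "lncX"),
                      mirna_id = c("miR1", "miR1", "miR2", "miR1"))
  f <- filter_differential(pairs, de_fixture(), "lncRNA")
  expect_equal(nrow(f), 2)            # miR2 pair dropped (M); lncX unknown -> M
  expect_equal(f$source_direction, c("up", "down"))
  expect_equal(unique(f$mirna_direction), "down")
  empty <- filter_differential(pairs, de_fixture()[0, ], "lncRNA")
  expect_equal(nrow(empty), 0)
})

test_that("triple joins emit the cross product over shared miRNAs", {
  de <- de_fixture()
  lnc <- filter_differential(
    data.frame(source_id = c("lnc1", "lnc2"), mirna_id = c("miR1", "miR1")),
    de, "lncRNA")
  mr <- filter_differential(
    data.frame(source_id = c("m1", "m2", "m3"), mirna_id = "miR1"),
    de, "mRNA")
  tr <- join_triples(lnc, mr)
  expect_equal(nrow(tr), 6)           # 2 lncRNAs x 3 mRNAs
  net <- cerna_network(tr)
  st <- network_stats(net)
  expect_equal(st$n_edges, 5)         # 2 + 3 star edges
  expect_equal(st$n_nodes, 6)
  expect_equal(st$n_triples, 6)

  # one lncRNA, one mRNA, one miRNA -> 1 triple, 2 edges, 3 nodes
  tr1 <- join_triples(lnc[lnc$source_id == "lnc1", ],
                      mr[mr$source_id == "m1", ])
  st1 <- network_stats(cerna_network(tr1))
  expect_equal(c(st1$n_triples, st1$n_edges, st1$n_nodes), c(1, 2, 3))

  # no shared miRNA -> no triples
  mr2 <- mr; mr2$mirna_id <- "miR9"
  expect_equal(nrow(join_triples(lnc, mr2)), 0)

  # brute-force conservation: triples = sum over miRNAs of partner products
  set.seed(6)
  lp <- unique(data.frame(source_id = sample(paste0("l", 1:8), 30, TRUE),
                          mirna_id = sample(paste0("mi", 1:4), 30, TRUE)))
  lp$source_class <- "lncRNA"
  mp <- unique(data.frame(source_id = sample(paste0("g", 1:10), 30, TRUE),
                          mirna_id = sample(paste0("mi", 1:4), 30, TRUE)))
  got <- nrow(join_triples(lp, mp))
  want <- sum(vapply(paste0("mi", 1:4), function(mi)
    sum(lp$mirna_id == mi) * sum(mp$mirna_id == mi), numeric(1)))
  expect_equal(got, want)
})

test_that("quadruple joins combine lncRNA and circRNA triples on one miRNA", {
  lnc_tr <- expand.grid(source_id = c("lnc1", "lnc2"), mrna_id = c("m1", "m2"),
                        stringsAsFactors = FALSE)
  lnc_tr$source_class <- "lncRNA"; lnc_tr$mirna_id <- "miR1"
  circ_tr <- data.frame(source_id = c("c1", "c2"), source_class = "circRNA",
                        mirna_id = "miR1", mrna_id = c("m1", "m2"))
  q <- join_quadruples(lnc_tr, circ_tr)
  expect_equal(nrow(q), 8)            # 2 circ x 2 lnc x 2 mRNA
  circ_other <- circ_tr; circ_other$mirna_id <- "miR2"
  expect_equal(nrow(join_quadruples(lnc_tr, circ_other)), 0)
})

test_that("star networks reproduce the printed node/edge arithmetic", {
  # 431 lncRNA + 21 mRNA molecules on one miRNA hub -> 452 edges
  lnc <- data.frame(source_id = sprintf("lnc%03d", 1:431),
                    source_class = "lncRNA", mirna_id = "miR1",
                    mrna_id = "m001")
  mr <- sprintf("m%03d", 1:21)
  tr <- merge(lnc[, 1:3], data.frame(mirna_id = "miR1", mrna_id = mr))
  st <- network_stats(cerna_network(tr))
  expect_equal(st$n_edges, 452)
  expect_equal(as.integer(st$by_class[c("lncRNA", "mRNA")]), c(431, 21))
  # 222 nodes in a single-hub star -> 221 edges
  lnc2 <- data.frame(source_id = sprintf("L%03d", 1:200),
                     source_class = "lncRNA", mirna_id = "hubmiR",
                     mrna_id = "m1")
  tr2 <- merge(lnc2[, 1:3],
               data.frame(mirna_id = "hubmiR", mrna_id = sprintf("M%02d", 1:21)))
  st2 <- network_stats(cerna_network(tr2))
  expect_equal(st2$n_nodes, 222)
  expect_equal(st2$n_edges, 221)
  # no orphan nodes
  net2 <- cerna_network(tr2)
  expect_setequal(net2$nodes$id,
                  unique(c(net2$edges$molecule_id, net2$edges$mirna_id)))
  # empty network
  st0 <- network_stats(cerna_network(tr2[0, ]))
  expect_equal(st0$n_nodes + st0$n_edges + st0$n_triples, 0)
})

test_that("planted triples are recovered exactly end-to-end", {
  for (seed in 1:5) {
    sim <- simulate_pairs(6, c(mRNA = 8, lncRNA = 10, circRNA = 4),
                          sharing_rate = 0.5, seed = seed)
    ids <- unique(c(sim$pairs$mRNA$source_id, sim$pairs$lncRNA$source_id,
                    sim$pairs$circRNA$source_id,
                    unlist(lapply(sim$pairs, `[[`, "mirna_id"))))
    de <- data.frame(gene = ids, interval = "3w-4w", status = "U")
    mr <- filter_differential(sim$pairs$mRNA, de, "mRNA")
    lnc <- filter_differential(sim$pairs$lncRNA, de, "lncRNA")
    circ <- filter_differential(sim$pairs$circRNA, de, "circRNA")
    got <- rbind(join_triples(lnc, mr)[, c("source_id", "source_class",
                                           "mirna_id", "mrna_id")],
                 join_triples(circ, mr)[, c("source_id", "source_class",
                                            "mirna_id", "mrna_id")])
    want <- sim$truth$triples
    key <- function(x) sort(paste(x$source_id, x$mirna_id, x$mrna_id))
    expect_identical(key(got), key(want))
  }
})
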