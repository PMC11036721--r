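# Shared fixtures built in code.

# small deterministic count matrix: 3 genes x 2 samples, sample b = 2 x a
fix_counts_doubling <- function() {
  matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
         dimnames = list(paste0("g", 1:3), c("a", "b")))
}

# igraph helpers
graph_from_pairs <- function(from, to, score = 1) {
  igraph::graph_from_data_frame(
    data.frame(node1 = from, node2 = to, combined_score = score),
    directed = FALSE)
}

path_p3 <- function() graph_from_pairs(c("a", "b"), c("b", "c"))

complete_graph <- function(nodes) {
  p <- t(utils::combn(nodes, 2))
  graph_from_pairs(p[, 1], p[, 2])
}

star_graph <- function(center = "c", n_leaves = 4) {
  graph_from_pairs(rep(center, n_leaves), paste0("l", seq_len(n_leaves)))
}

# random ER graph with named vertices, possibly disconnected
random_er_graph <- function(n, p, score = NULL) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  nodes <- sprintf("v%02d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(node1 = nodes[pairs[1, keep]], node2 = nodes[pairs[2, keep]]),
    directed = FALSE, vertices = nodes)
  if (!is.null(score)) igraph::E(g)$combined_score <- score
  g
}

# two K4 blocks joined by a 3-node path (dense-module fixture)
two_k4_with_bridge <- function() {
  k1 <- t(utils::combn(paste0("a", 1:4), 2))
  k2 <- t(utils::combn(paste0("b", 1:4), 2))
  bridge <- cbind(c("a1", "p1", "p2", "p3"), c("p1", "p2", "p3", "b1"))
  graph_from_pairs(rbind(k1, k2, bridge)[, 1], rbind(k1, k2, bridge)[, 2])
}
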