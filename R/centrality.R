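#' @name centrality
#' @title Twelve topological centrality measures
#'
#' @description
#' Computes one of the twelve node-ranking measures used for hub-gene
#' screening. All graphs are treated as simple, undirected and unweighted for
#' path purposes; edge `combined_score` is used only by EPC as a retention
#' probability. Definitions (v a node, N(v) its neighbors, d(u,t) the
#' shortest-path distance):
#'
#' * **Degree** — |N(v)|.
#' * **MNC** — maximum neighborhood component: size of the largest connected
#'   component of the subgraph induced by N(v).
#' * **DMNC** — density of the MNC: edges(C) / nodes(C)^1.7 of that largest
#'   component C.
#' * **MCC** — maximal clique centrality: sum over maximal cliques C
#'   containing v of (|C| - 1)!. When no two neighbors of v are adjacent every
#'   such clique is an edge and the sum equals the degree.
#' * **ClusteringCoefficient** — 2 e(N(v)) / (deg (deg - 1)); 0 for deg < 2.
#' * **Betweenness** — standard shortest-path betweenness over unordered
#'   pairs.
#' * **Stress** — number of shortest paths (over unordered pairs) with v as an
#'   interior node.
#' * **Closeness** — harmonic: sum over reachable t != v of 1 / d(v,t)
#'   (unreachable nodes contribute 0, so disconnected graphs stay finite).
#' * **EcCentricity** — 1 / max reachable distance from v.
#' * **Radiality** — within v's component of diameter D and size n_c:
#'   sum over t != v of (D + 1 - d(v,t)) / (n_c - 1).
#' * **BottleNeck** — for each source s, a breadth-first shortest-path tree is
#'   grown (deterministic parent rule: the lexicographically smallest neighbor
#'   one step closer to s); v scores 1 for s when more than n_s / 4 of the
#'   tree's nodes descend from v (n_s = tree size); the score is the sum over
#'   sources.
#' * **EPC** — edge percolation clustering: over `epc_rounds` random
#'   realizations in which each edge is kept with probability equal to its
#'   `combined_score`, the mean number of other nodes in v's component.
#'   Requires a seed; the Monte-Carlo standard error is attached as attribute
#'   `mc_se`.
#'
#' @param g igraph with named vertices.
#' @param measure one of the names listed above.
#' @param seed integer seed, required for `"EPC"`.
#' @param epc_rounds number of percolation realizations (default 1000).
#' @return named numeric vector of scores (class `CentralityRanking`, with
#'   attribute `measure`).
#' @export
centrality <- function(g, measure, seed = NULL, epc_rounds = 1000) {
  if (!measure %in% CENTRALITY_MEASURES)
    abort("unknown measure '%s'; expected one of: %s", measure,
          paste(CENTRALITY_MEASURES, collapse = ", "))
  vs <- igraph::V(g)$name
  scores <- switch(
    measure,
    Degree = igraph::degree(g),
    MNC = mnc_component(g)$size,
    DMNC = mnc_component(g)$dmnc,
    MCC = mcc_scores(g),
    ClusteringCoefficient = {
      cc <- igraph::transitivity(g, type = "local", isolates = "zero")
      stats::setNames(cc, vs)
    },
    Betweenness = igraph::betweenness(g, directed = FALSE, weights = NULL),
    Stress = stress_scores(g),
    Closeness = {
      h <- igraph::harmonic_centrality(g, normalized = FALSE, weights = NA)
      stats::setNames(h, vs)
    },
    EcCentricity = {
      ecc <- igraph::eccentricity(g)
      ifelse(ecc > 0, 1 / ecc, 0)
    },
    Radiality = radiality_scores(g),
    BottleNeck = bottleneck_scores(g),
    EPC = {
      if (is.null(seed)) abort("EPC requires a seed")
      epc_scores(g, seed, epc_rounds)
    })
  out <- stats::setNames(as.numeric(scores[vs]), vs)
  if (measure == "EPC") attr(out, "mc_se") <- attr(scores, "mc_se")
  attr(out, "measure") <- measure
  class(out) <- c("CentralityRanking", class(out))
  out
}

#' The twelve measure names
#' @export
CENTRALITY_MEASURES <- c("MCC", "DMNC", "MNC", "Degree", "EPC", "BottleNeck",
                         "EcCentricity", "Closeness", "Radiality",
                         "Betweenness", "Stress", "ClusteringCoefficient")

mnc_component <- function(g) {
  vs <- igraph::V(g)$name
  size <- dmnc <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    nb <- igraph::neighbors(g, v)$name
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    members <- names(comp$membership)[comp$membership == big]
    h <- igraph::induced_subgraph(sub, members)
    size[v] <- length(members)
    dmnc[v] <- igraph::ecount(h) / length(members)^1.7
  }
  list(size = size, dmnc = dmnc)
}

mcc_scores <- function(g) {
  vs <- igraph::V(g)$name
  s <- stats::setNames(numeric(length(vs)), vs)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    nm <- cl$name
    s[nm] <- s[nm] + factorial(length(nm) - 1)
  }
  s
}

# all-pairs shortest-path counts by per-source BFS dynamic programming
sp_counts <- function(g) {
  n <- igraph::vcount(g)
  vs <- igraph::V(g)$name
  d <- igraph::distances(g, weights = NA)
  sigma <- matrix(0, n, n, dimnames = list(vs, vs))
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(x)
    as.integer(x))
  for (s in seq_len(n)) {
    sig <- numeric(n); sig[s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      pred <- adj[[v]][d[s, adj[[v]]] == d[s, v] - 1]
      sig[v] <- sum(sig[pred])
    }
    sigma[s, ] <- sig
  }
  list(d = d, sigma = sigma)
}

stress_scores <- function(g) {
  sp <- sp_counts(g)
  n <- nrow(sp$d); vs <- rownames(sp$d)
  out <- stats::setNames(numeric(n), vs)
  for (vi in seq_len(n)) {
    dv <- sp$d[, vi]
    ok <- outer(dv, dv, "+") == sp$d & is.finite(sp$d)
    ok[vi, ] <- ok[, vi] <- FALSE
    diag(ok) <- FALSE
    out[vi] <- sum(outer(sp$sigma[, vi], sp$sigma[vi, ]) * ok) / 2
  }
  out
}

radiality_scores <- function(g) {
  vs <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(vs)), vs)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub, weights = NA)
    D <- max(d)
    out[members] <- (rowSums(D + 1 - d) - (D + 1)) / (length(members) - 1)
  }
  out
}

# deterministic BFS shortest-path tree: parent = lexicographically smallest
# neighbor at distance d - 1 from the source
bottleneck_scores <- function(g, frac = 1 / 4) {
  vs <- sort(igraph::V(g)$name)
  n <- length(vs)
  d <- igraph::distances(g, weights = NA)[vs, vs, drop = FALSE]
  adj <- lapply(stats::setNames(vs, vs), function(v)
    sort(igraph::neighbors(g, v)$name))
  out <- stats::setNames(numeric(n), vs)
  for (s in vs) {
    reach <- vs[is.finite(d[s, vs])]
    n_s <- length(reach)
    if (n_s < 2) next
    parent <- stats::setNames(rep(NA_character_, n_s), reach)
    for (v in setdiff(reach, s))
      parent[v] <- adj[[v]][d[s, adj[[v]]] == d[s, v] - 1][1]
    # count descendants of each node in the tree
    desc <- stats::setNames(numeric(n_s), reach)
    for (v in setdiff(reach, s)) {
      p <- parent[v]
      while (!is.na(p)) { desc[p] <- desc[p] + 1; p <- parent[p] }
    }
    hit <- reach[desc > n_s * frac & reach != s]
    out[hit] <- out[hit] + 1
  }
  out
}

epc_scores <- function(g, seed, rounds = 1000) {
  vs <- igraph::V(g)$name
  p <- igraph::E(g)$combined_score
  if (is.null(p)) abort("EPC needs a combined_score edge attribute")
  withr::with_seed(seed, {
    acc <- matrix(0, rounds, length(vs), dimnames = list(NULL, vs))
    m <- igraph::ecount(g)
    for (r in seq_len(rounds)) {
      keep <- stats::runif(m) < p
      h <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
      comp <- igraph::components(h)
      acc[r, ] <- comp$csize[comp$membership[vs]] - 1
    }
    out <- colMeans(acc)
    attr(out, "mc_se") <- apply(acc, 2, stats::sd) / sqrt(rounds)
    out
  })
}

#' All twelve centralities of a graph
#'
#' @param g igraph with named vertices.
#' @param seed seed forwarded to the EPC percolation.
#' @param epc_rounds EPC realizations.
#' @return named list of `CentralityRanking` vectors, one per measure.
#' @export
all_centralities <- function(g, seed = 1, epc_rounds = 1000) {
  stats::setNames(lapply(CENTRALITY_MEASURES, function(m)
    centrality(g, m, seed = seed, epc_rounds = epc_rounds)),
    CENTRALITY_MEASURES)
}

#' Consensus hub selection across the twelve measures
#'
#' Each measure contributes a top-`k` list (descending score, ties broken
#' lexicographically). Nodes are then scored by how many of the twelve lists
#' contain them; candidates are ranked by that count, ties by mean rank
#' across all measures (rank 1 = best, ties to the minimum rank), then
#' lexicographically. The strict twelve-way intersection — often empty — is
#' also reported.
#'
#' @param rankings named list of all twelve `CentralityRanking` vectors on a
#'   common node set (as from [all_centralities()]).
#' @param k list depth (default 5).
#' @return list with `hubs` (first k consensus genes), `table` (gene,
#'   n_lists, mean_rank), `membership` (logical gene x measure matrix) and
#'   `strict_intersection`.
#' @export
consensus_hubs <- function(rankings, k = 5) {
  missing <- setdiff(CENTRALITY_MEASURES, names(rankings))
  if (length(missing))
    abort("missing measure(s): %s", paste(missing, collapse = ", "))
  nodes <- sort(names(rankings[[1]]))
  topk <- lapply(rankings[CENTRALITY_MEASURES], function(r) {
    ord <- names(r)[order(-r, names(r))]
    utils::head(ord, k)
  })
  membership <- vapply(topk, function(tk) nodes %in% tk,
                       logical(length(nodes)))
  rownames(membership) <- nodes
  n_lists <- rowSums(membership)
  ranks <- vapply(rankings[CENTRALITY_MEASURES], function(r)
    rank(-r[nodes], ties.method = "min"), numeric(length(nodes)))
  mean_rank <- rowMeans(ranks)
  ord <- order(-n_lists, mean_rank, nodes)
  tab <- data.frame(gene = nodes[ord], n_lists = as.integer(n_lists[ord]),
                    mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
  strict <- Reduce(intersect, topk)
  list(hubs = utils::head(tab$gene, k), table = tab,
       membership = membership, strict_intersection = sort(strict))
}
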