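#' Build a confidence-filtered interaction graph
#'
#' Drops edges with combined score below `min_score` (inclusive retention:
#' score >= threshold is kept, matching STRING's "minimum required score"
#' semantics), removes self-loops and parallel edges, and hides nodes left
#' without any edge. Scores on the STRING 0-999 integer dialect are detected
#' (any score > 1) and rescaled to 0-1 by division by 1000.
#'
#' @param edges data.frame with columns node1, node2, combined_score, or an
#'   igraph with a `combined_score` edge attribute.
#' @param min_score minimum retained combined score (default 0.400).
#' @return igraph; simple, undirected, edge attribute `combined_score`,
#'   no isolated nodes.
#' @export
build_graph <- function(edges, min_score = 0.400) {
  if (inherits(edges, "igraph")) {
    edges <- igraph::as_data_frame(edges, what = "edges")
    names(edges)[1:2] <- c("node1", "node2")
  }
  need <- c("node1", "node2", "combined_score")
  if (!all(need %in% names(edges))) {
    if (ncol(edges) >= 3) names(edges)[1:3] <- need
    else abort("edge table needs columns node1, node2, combined_score")
  }
  bad <- which(!is.finite(edges$combined_score) | edges$combined_score < 0)
  if (length(bad))
    abort("malformed score at edge-table row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (nrow(edges) && max(edges$combined_score) > 1)
    edges$combined_score <- edges$combined_score / 1000
  keep <- edges$combined_score >= min_score & edges$node1 != edges$node2
  edges <- edges[keep, need]
  if (nrow(edges) == 0) {
    warning("no edges at or above min_score; returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
  g
}

#' MCODE vertex weights
#'
#' Stage one of molecular-complex detection: for each node v, take the
#' subgraph induced by its closed neighborhood N\[v\], find its highest
#' k-core, and weight v by k times the density 2e/(n(n-1)) of that core
#' subgraph.
#'
#' @param g igraph (simple, no isolated nodes).
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(g) {
  vs <- igraph::V(g)$name
  w <- vapply(vs, function(v) {
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) return(0)
    h <- igraph::induced_subgraph(sub, names(core)[core >= k])
    n <- igraph::vcount(h)
    if (n < 2) return(0)
    k * 2 * igraph::ecount(h) / (n * (n - 1))
  }, numeric(1))
  stats::setNames(w, vs)
}

#' MCODE-style dense-module extraction
#'
#' Greedy seed-and-expand: nodes are visited in order of decreasing vertex
#' weight; from each unassigned seed, neighbors are included (breadth-first)
#' when their weight is at least `seed_weight * (1 - node_score_cutoff)` and
#' they are not already in a module. Post-processing: with `haircut`,
#' singly-connected module nodes are removed iteratively; modules whose
#' subgraph contains no `k_core_min`-core are discarded; with `fluff`,
#' unassigned neighbors whose closed-neighborhood density exceeds
#' `fluff_density` are appended. Modules are ranked by score = density x
#' size; every node belongs to at most one module.
#'
#' @param g igraph.
#' @param node_score_cutoff expansion tolerance in \[0,1\] (default 0.2).
#' @param k_core_min minimum core a module must contain (default 2).
#' @param haircut remove degree-1 module nodes (default TRUE).
#' @param fluff append dense unassigned neighbors (default FALSE).
#' @param fluff_density closed-neighborhood density threshold for fluff.
#' @return list of `ModuleResult`s: each has `nodes`, `seed`, `score`,
#'   `n_nodes`, `n_edges`; sorted by decreasing score.
#' @export
extract_modules <- function(g, node_score_cutoff = 0.2, k_core_min = 2,
                            haircut = TRUE, fluff = FALSE,
                            fluff_density = 0.2) {
  if (igraph::vcount(g) == 0) return(list())
  w <- vertex_weights(g)
  order_v <- names(sort(w, decreasing = TRUE))
  # stable deterministic order: weight desc, then name
  order_v <- order_v[order(-w[order_v], order_v)]
  assigned <- character(0)
  modules <- list()
  for (seed in order_v) {
    if (seed %in% assigned) next
    thr <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        igraph::neighbors(g, v)$name)))
      nb <- setdiff(nb, c(members, assigned))
      ok <- nb[w[nb] >= thr]
      members <- c(members, ok)
      frontier <- ok
    }
    sub <- igraph::induced_subgraph(g, members)
    if (haircut) {
      repeat {
        deg <- igraph::degree(sub)
        drop <- names(deg)[deg < 2]
        if (!length(drop) || igraph::vcount(sub) - length(drop) < 1) break
        sub <- igraph::delete_vertices(sub, drop)
        if (igraph::vcount(sub) == 0) break
      }
    }
    if (igraph::vcount(sub) == 0) { assigned <- c(assigned, members); next }
    if (max(igraph::coreness(sub)) < k_core_min) {
      assigned <- c(assigned, members)
      next
    }
    final_nodes <- igraph::V(sub)$name
    if (fluff) {
      cand <- setdiff(unique(unlist(lapply(final_nodes, function(v)
        igraph::neighbors(g, v)$name))), c(final_nodes, assigned, members))
      dens <- vapply(cand, function(v) {
        nb <- c(v, igraph::neighbors(g, v)$name)
        h <- igraph::induced_subgraph(g, nb)
        n <- igraph::vcount(h)
        if (n < 2) 0 else 2 * igraph::ecount(h) / (n * (n - 1))
      }, numeric(1))
      final_nodes <- c(final_nodes, cand[dens > fluff_density])
      sub <- igraph::induced_subgraph(g, final_nodes)
    }
    n <- igraph::vcount(sub); e <- igraph::ecount(sub)
    density <- if (n < 2) 0 else 2 * e / (n * (n - 1))
    modules[[length(modules) + 1]] <- list(
      nodes = sort(final_nodes), seed = seed, score = density * n,
      n_nodes = n, n_edges = e)
    assigned <- c(assigned, members, final_nodes)
  }
  modules[order(-vapply(modules, `[[`, numeric(1), "score"))]
}

#' Preliminary top-n hub genes of a module
#'
#' Ranks module members by within-module degree, breaking ties by whole-graph
#' degree and then lexicographically, and returns the first `n`.
#'
#' @param module a `ModuleResult` (or character vector of node names).
#' @param g the full igraph the module came from.
#' @param n number of hubs (default 5).
#' @return data.frame gene, module_degree, graph_degree, ordered by rank.
#' @export
preliminary_hubs <- function(module, g, n = 5) {
  nodes <- if (is.list(module)) module$nodes else module
  if (!length(nodes)) abort("empty module")
  sub <- igraph::induced_subgraph(g, nodes)
  md <- igraph::degree(sub)[nodes]
  gd <- igraph::degree(g, nodes)
  ord <- order(-md, -gd, nodes)
  if (length(nodes) < n) {
    warning(sprintf("module has only %d nodes; returning all", length(nodes)))
    n <- length(nodes)
  }
  data.frame(gene = nodes[ord], module_degree = unname(md[ord]),
             graph_degree = unname(gd[ord]),
             stringsAsFactors = FALSE)[seq_len(n), ]
}
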