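# Independent brute-force oracles for graphs of <= ~10 nodes. Everything here
# works from the adjacency matrix by direct enumeration and never calls the
# package's centrality code (igraph is used only to obtain the adjacency
# matrix of the fixture).

oracle_adj <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a[a > 1] <- 1
  a
}

# Floyd-Warshall all-pairs distances
oracle_dist <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# enumerate all shortest paths between two node indices (lists of index
# vectors), by backward recursion on the distance matrix
oracle_paths <- function(a, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  pred <- which(a[, t] == 1 & d[s, ] == d[s, t] - 1)
  out <- list()
  for (p in pred)
    for (pt in oracle_paths(a, d, s, p)) out[[length(out) + 1]] <- c(pt, t)
  out
}

oracle_stress_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_dist(a)
  stress <- btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_paths(a, d, s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      hits <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      stress[v] <- stress[v] + hits
      btw[v] <- btw[v] + hits / length(paths)
    }
  }
  names(stress) <- names(btw) <- rownames(a)
  list(stress = stress, betweenness = btw)
}

oracle_closeness <- function(a) {
  d <- oracle_dist(a)
  diag(d) <- Inf
  apply(d, 1, function(r) sum(1 / r[is.finite(r)]))
}

oracle_eccentricity_inv <- function(a) {
  d <- oracle_dist(a)
  apply(d, 1, function(r) {
    e <- max(r[is.finite(r)])
    if (e > 0) 1 / e else 0
  })
}

oracle_radiality <- function(a) {
  d <- oracle_dist(a)
  n <- nrow(a)
  out <- numeric(n)
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(is.finite(d[i, ]))
    seen[members] <- TRUE
    if (length(members) < 2) next
    dm <- d[members, members, drop = FALSE]
    D <- max(dm)
    for (j in seq_along(members))
      out[members[j]] <- sum(D + 1 - dm[j, -j]) / (length(members) - 1)
  }
  names(out) <- rownames(a)
  out
}

oracle_degree <- function(a) rowSums(a)

oracle_clustering <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- sum(a[nb, nb]) / 2
    out[v] <- 2 * e / (k * (k - 1))
  }
  stats::setNames(out, rownames(a))
}

oracle_mnc_dmnc <- function(a) {
  n <- nrow(a)
  size <- dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    if (!length(nb)) next
    sub <- a[nb, nb, drop = FALSE]
    d <- oracle_dist(sub)
    comp_of <- rep(NA_integer_, length(nb))
    cid <- 0
    for (i in seq_along(nb)) if (is.na(comp_of[i])) {
      cid <- cid + 1
      comp_of[is.finite(d[i, ])] <- cid
    }
    sizes <- tabulate(comp_of)
    big <- which.max(sizes)
    members <- which(comp_of == big)
    e <- sum(sub[members, members]) / 2
    size[v] <- sizes[big]
    dmnc[v] <- e / sizes[big]^1.7
  }
  list(size = stats::setNames(size, rownames(a)),
       dmnc = stats::setNames(dmnc, rownames(a)))
}

# subset enumeration of maximal cliques (n <= ~12)
oracle_mcc <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    sub <- a[members, members, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next            # not a clique
    outside <- setdiff(seq_len(n), members)
    if (any(vapply(outside, function(o) all(a[o, members] == 1), logical(1))))
      next                                             # not maximal
    out[members] <- out[members] + factorial(length(members) - 1)
  }
  stats::setNames(out, rownames(a))
}

# same deterministic parent rule as the package documents: parent of v in the
# tree from s is the lexicographically smallest neighbor one step closer
oracle_bottleneck <- function(a, frac = 1 / 4) {
  nodes <- sort(rownames(a))
  a <- a[nodes, nodes]
  d <- oracle_dist(a)
  n <- length(nodes)
  out <- stats::setNames(numeric(n), nodes)
  for (s in nodes) {
    reach <- nodes[is.finite(d[s, ])]
    n_s <- length(reach)
    if (n_s < 2) next
    parent <- stats::setNames(rep(NA_character_, n_s), reach)
    for (v in setdiff(reach, s)) {
      cand <- nodes[a[v, ] == 1 & d[s, ] == d[s, v] - 1]
      parent[v] <- sort(cand)[1]
    }
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

# exhaustive-combination ORA oracle on tiny universes: exact probability that
# a random query of size n drawn from the universe overlaps the set in >= k
# genes, by enumerating all C(N, n) queries
oracle_ora_p <- function(universe, set, query) {
  n <- length(query)
  k_obs <- length(intersect(query, set))
  combs <- utils::combn(universe, n)
  hits <- apply(combs, 2, function(q) length(intersect(q, set)) >= k_obs)
  mean(hits)
}
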