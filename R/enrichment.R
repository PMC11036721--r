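#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap with the query list is larger
#' than expected under random draws from the universe: the p-value is the
#' hypergeometric upper tail P(X >= k) with N universe genes, K set genes and
#' n query genes. Raw p < alpha flags significance; a Benjamini-Hochberg
#' column is included for users who prefer adjusted calls.
#'
#' @param query character vector of gene ids; ids outside the universe are
#'   dropped with a warning.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]); each
#'   set is restricted to the universe.
#' @param universe character vector of all assayed gene ids.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame: set, overlap_k, set_size_K, query_n, universe_N, p,
#'   p_bh, significant; ordered by p.
#' @export
ora <- function(query, sets, universe, alpha = 0.05) {
  if (!length(universe)) abort("empty universe")
  if (!length(query)) abort("empty query")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
    if (!length(query)) abort("no query genes left inside the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap_k = k, set_size_K = K, query_n = n,
               universe_N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}

#' Group genes by trajectory pattern
#'
#' Pattern-wise gene lists for enrichment; groups smaller than `min_genes`
#' are withheld (enrichment needs a certain number of genes to be
#' interpretable) and reported separately.
#'
#' @param traj `TrajectoryTable` from [encode_trajectories()].
#' @param min_genes minimum group size to emit (default 3).
#' @return list with `groups` (named list pattern -> gene ids) and `skipped`
#'   (patterns below the threshold).
#' @export
group_by_pattern <- function(traj, min_genes = 3) {
  sp <- split(traj$gene, traj$pattern)
  sizes <- lengths(sp)
  list(groups = sp[sizes >= min_genes],
       skipped = names(sp)[sizes < min_genes])
}
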