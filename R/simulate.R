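#' Configuration for the count simulator
#'
#' Describes a study in which one pooled RNA library is sequenced at each of
#' `n_timepoints` chronologically ordered ages, and each gene follows a planted
#' trajectory written as a string over the alphabet U (up), D (down), M
#' (maintained), one letter per adjacent interval. At a U the underlying mean
#' is multiplied by `fold_step` for all subsequent timepoints; at a D it is
#' divided; M leaves it unchanged (a step model: changes persist).
#'
#' Defaults mirror the pooled nine-week design the package targets: 9
#' timepoints, one library each, and a per-interval M probability of 0.99,
#' which makes roughly 92% of genes all-M — the order observed in real testis
#' time courses. Gene baseline means are log-normal; counts are
#' negative-binomial with variance mu + dispersion * mu^2 (gamma-Poisson),
#' so dispersion 0 is Poisson.
#'
#' @param n_genes number of genes (ignored when `pattern_assignments` is
#'   given, in which case its names define the genes).
#' @param n_timepoints number of ordered timepoints (default 9).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of per-gene
#'   baseline means.
#' @param dispersion NB dispersion alpha >= 0; variance = mu + alpha mu^2.
#' @param pattern_assignments optional named character vector gene -> pattern
#'   string of length `n_timepoints - 1` over {U,D,M}.
#' @param pattern_probs probabilities used to draw patterns when
#'   `pattern_assignments` is absent; named vector with elements U, D, M.
#' @param fold_step multiplier (> 1) applied at each U, divided at each D.
#' @param library_size_factors per-timepoint positive scale factors.
#' @param gene_length_range range (bp) from which exonic lengths are drawn.
#' @param n_replicates libraries per timepoint (default 1, the pooled design).
#' @param rna_class RNA class tag passed to [count_matrix()].
#' @param seed integer seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       n_timepoints = 9,
                       baseline_log_mean = log(50),
                       baseline_log_sd = 1.5,
                       dispersion = 0.05,
                       pattern_assignments = NULL,
                       pattern_probs = c(U = 0.005, D = 0.005, M = 0.99),
                       fold_step = 2,
                       library_size_factors = rep(1, n_timepoints),
                       gene_length_range = c(200, 10000),
                       n_replicates = 1,
                       rna_class = "mRNA",
                       seed = 1) {
  if (n_timepoints < 2) abort("need at least 2 timepoints")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (fold_step <= 1) abort("fold_step must be > 1")
  if (length(library_size_factors) != n_timepoints)
    abort("library_size_factors must have one entry per timepoint")
  if (any(library_size_factors <= 0)) abort("size factors must be > 0")
  k <- n_timepoints - 1L
  if (!is.null(pattern_assignments)) {
    if (is.null(names(pattern_assignments)))
      abort("pattern_assignments must be named by gene")
    bad_len <- nchar(pattern_assignments) != k
    bad_alpha <- grepl("[^UDM]", pattern_assignments)
    bad <- bad_len | bad_alpha
    if (any(bad))
      abort("invalid pattern for gene(s) %s: patterns must have length %d over {U,D,M}",
            paste(utils::head(names(pattern_assignments)[bad], 5), collapse = ", "), k)
  }
  structure(list(n_genes = n_genes, n_timepoints = n_timepoints,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion,
                 pattern_assignments = pattern_assignments,
                 pattern_probs = pattern_probs,
                 fold_step = fold_step,
                 library_size_factors = library_size_factors,
                 gene_length_range = gene_length_range,
                 n_replicates = n_replicates,
                 rna_class = rna_class,
                 seed = seed),
            class = "sim_config")
}

timepoint_labels <- function(n) {
  if (n == 9) paste0(3:11, "w") else paste0("T", seq_len(n))
}

#' Interval labels for chronologically adjacent timepoint pairs
#' @param sample_labels ordered sample names.
#' @return character vector like `"3w-4w"`.
#' @export
interval_labels <- function(sample_labels) {
  n <- length(sample_labels)
  paste0(sample_labels[-n], "-", sample_labels[-1])
}

#' Simulate NB counts with planted U/D/M trajectories
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()] including simulated gene
#'   lengths) and `truth` (planted pattern per gene, baseline means,
#'   per-gene-per-timepoint expected means before size-factor scaling).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_timepoints - 1L
  withr::with_seed(config$seed, {
    if (is.null(config$pattern_assignments)) {
      genes <- sprintf("gene%04d", seq_len(config$n_genes))
      p <- config$pattern_probs[c("U", "D", "M")]
      pat <- vapply(genes, function(g)
        paste(sample(c("U", "D", "M"), k, replace = TRUE, prob = p),
              collapse = ""), character(1))
    } else {
      pat <- config$pattern_assignments
      genes <- names(pat)
    }
    n_genes <- length(genes)
    mu0 <- stats::rlnorm(n_genes, config$baseline_log_mean,
                         config$baseline_log_sd)
    names(mu0) <- genes
    # cumulative fold multiplier along the trajectory
    steps <- t(vapply(pat, function(s) {
      ch <- strsplit(s, "")[[1]]
      cumprod(c(1, ifelse(ch == "U", config$fold_step,
                          ifelse(ch == "D", 1 / config$fold_step, 1))))
    }, numeric(config$n_timepoints)))
    mu <- mu0 * steps                      # genes x timepoints expected means
    labs <- timepoint_labels(config$n_timepoints)
    sf <- config$library_size_factors
    nrep <- config$n_replicates
    cols <- if (nrep == 1) labs
            else as.vector(t(outer(labs, seq_len(nrep), paste, sep = "_r")))
    counts <- matrix(0L, n_genes, length(cols),
                     dimnames = list(genes, cols))
    ci <- 0L
    for (t in seq_len(config$n_timepoints)) {
      for (r in seq_len(nrep)) {
        ci <- ci + 1L
        m <- sf[t] * mu[, t]
        counts[, ci] <- if (config$dispersion > 0)
          stats::rnbinom(n_genes, mu = m, size = 1 / config$dispersion)
        else stats::rpois(n_genes, m)
      }
    }
    lengths <- round(stats::runif(n_genes, config$gene_length_range[1],
                                  config$gene_length_range[2]))
    names(lengths) <- genes
    cm <- count_matrix(counts, lengths = lengths, rna_class = config$rna_class)
    truth <- list(patterns = pat, baseline_means = mu0, expected_means = mu,
                  size_factors = stats::setNames(sf, labs))
    list(counts = cm, truth = truth)
  })
}

#' Simulate a planted-partition interaction graph
#'
#' Nodes inside each planted module are wired with probability `intra_p`,
#' every other pair with `inter_p`; each realized edge receives a combined
#' score drawn uniformly from `score_range`. Ground-truth module membership is
#' returned for recovery benchmarks.
#'
#' @param n_nodes total number of nodes.
#' @param module_sizes integer vector of planted module sizes (their sum must
#'   not exceed `n_nodes`; remaining nodes are background).
#' @param intra_p,inter_p edge probabilities, `0 <= inter_p < intra_p <= 1`.
#' @param score_range range of uniform combined scores.
#' @param seed integer seed.
#' @return list with `graph` (igraph, edge attribute `combined_score`),
#'   `edges` (data.frame node1/node2/combined_score) and `truth` (named module
#'   id per node, `NA` for background).
#' @export
simulate_ppi <- function(n_nodes, module_sizes, intra_p, inter_p,
                         score_range = c(0.4, 1), seed = 1) {
  if (sum(module_sizes) > n_nodes)
    abort("module sizes (%d) exceed n_nodes (%d)", sum(module_sizes), n_nodes)
  if (!(inter_p >= 0 && inter_p < intra_p && intra_p <= 1))
    abort("need 0 <= inter_p < intra_p <= 1")
  withr::with_seed(seed, {
    nodes <- sprintf("node%03d", seq_len(n_nodes))
    membership <- rep(NA_integer_, n_nodes)
    idx <- 1L
    for (m in seq_along(module_sizes)) {
      membership[idx:(idx + module_sizes[m] - 1L)] <- m
      idx <- idx + module_sizes[m]
    }
    names(membership) <- nodes
    pairs <- utils::combn(n_nodes, 2)
    same <- !is.na(membership[pairs[1, ]]) & !is.na(membership[pairs[2, ]]) &
      membership[pairs[1, ]] == membership[pairs[2, ]]
    p <- ifelse(same, intra_p, inter_p)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- data.frame(node1 = nodes[pairs[1, keep]],
                        node2 = nodes[pairs[2, keep]],
                        combined_score = stats::runif(sum(keep),
                                                      score_range[1],
                                                      score_range[2]),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    list(graph = g, edges = edges, truth = membership)
  })
}

#' Simulate miRNA-target pair tables with planted ceRNA triples
#'
#' Each mRNA is paired with one miRNA. Each lncRNA/circRNA is then paired,
#' with probability `sharing_rate`, to a miRNA that also targets at least one
#' mRNA — creating planted molecule-miRNA-mRNA triples — and otherwise to a
#' miRNA with no mRNA target. With `sharing_rate` strictly between the
#' extremes, at least two miRNAs are required so both kinds exist.
#'
#' @param n_mirna number of miRNAs.
#' @param n_targets named integer vector with elements `mRNA`, `lncRNA`,
#'   `circRNA` (absent classes default to 0).
#' @param sharing_rate probability in \[0,1\] that a non-coding molecule shares
#'   its miRNA with an mRNA.
#' @param seed integer seed.
#' @return list with `pairs` (named list of data.frames source_id / mirna_id /
#'   score per class) and `truth$triples` (data.frame source_id, source_class,
#'   mirna_id, mrna_id of all planted triples).
#' @export
simulate_pairs <- function(n_mirna, n_targets, sharing_rate, seed = 1) {
  if (sharing_rate < 0 || sharing_rate > 1)
    abort("sharing_rate must be in [0,1]")
  nt <- function(cl) if (cl %in% names(n_targets)) n_targets[[cl]] else 0L
  withr::with_seed(seed, {
    mirnas <- sprintf("miR-%02d", seq_len(n_mirna))
    mrnas <- if (nt("mRNA")) sprintf("mrna%03d", seq_len(nt("mRNA"))) else character(0)
    # mRNAs attach to the first ceiling(n_mirna/2) miRNAs so that, unless
    # sharing_rate pins everything to one side, miRNAs of both kinds exist
    pool <- if (sharing_rate >= 1 || n_mirna == 1) mirnas
            else mirnas[seq_len(ceiling(n_mirna / 2))]
    mrna_pairs <- data.frame(source_id = mrnas,
                             mirna_id = if (length(mrnas))
                               sample(pool, length(mrnas), replace = TRUE)
                             else character(0),
                             score = if (length(mrnas))
                               stats::runif(length(mrnas)) else numeric(0),
                             stringsAsFactors = FALSE)
    shared_mirnas <- unique(mrna_pairs$mirna_id)
    free_mirnas <- setdiff(mirnas, shared_mirnas)
    triples <- list()
    make_class <- function(cl, prefix) {
      n <- nt(cl)
      if (!n) return(data.frame(source_id = character(0),
                                mirna_id = character(0), score = numeric(0)))
      ids <- sprintf("%s%03d", prefix, seq_len(n))
      share <- stats::runif(n) < sharing_rate
      if (any(share) && !length(shared_mirnas))
        abort("sharing requested but no miRNA targets an mRNA; add mRNA targets")
      if (any(!share) && !length(free_mirnas))
        abort("non-sharing requested but every miRNA targets an mRNA; increase n_mirna")
      mir <- character(n)
      mir[share] <- sample(shared_mirnas, sum(share), replace = TRUE)
      mir[!share] <- sample(free_mirnas, sum(!share), replace = TRUE)
      for (i in which(share)) {
        partners <- mrna_pairs$source_id[mrna_pairs$mirna_id == mir[i]]
        triples[[length(triples) + 1L]] <<- data.frame(
          source_id = ids[i], source_class = cl, mirna_id = mir[i],
          mrna_id = partners, stringsAsFactors = FALSE)
      }
      data.frame(source_id = ids, mirna_id = mir,
                 score = stats::runif(n), stringsAsFactors = FALSE)
    }
    lnc_pairs <- make_class("lncRNA", "lnc")
    circ_pairs <- make_class("circRNA", "circ")
    planted <- if (length(triples)) do.call(rbind, triples)
               else data.frame(source_id = character(0),
                               source_class = character(0),
                               mirna_id = character(0),
                               mrna_id = character(0))
    list(pairs = list(mRNA = mrna_pairs, lncRNA = lnc_pairs,
                      circRNA = circ_pairs),
         truth = list(triples = planted))
  })
}
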