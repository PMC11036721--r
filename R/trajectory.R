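#' Encode per-gene dynamics as U/D/M pattern strings
#'
#' Concatenates each gene's differential-expression statuses over the
#' chronologically ordered adjacent intervals into a single string over the
#' alphabet {U, D, M}, e.g. `"UMMMMMMM"` for a gene that rises once in the
#' first interval and then holds its level.
#'
#' @param records data.frame of `DERecord`s with columns gene, interval,
#'   status; `interval` should be a factor whose level order is chronological
#'   (as returned by [de_adjacent()]), otherwise order of first appearance is
#'   used.
#' @param rna_class optional class tag carried on the result.
#' @return data.frame (`TrajectoryTable`) with columns gene, pattern;
#'   attribute `k` is the number of intervals.
#' @export
encode_trajectories <- function(records, rna_class = NULL) {
  lv <- if (is.factor(records$interval)) levels(records$interval)
        else unique(records$interval)
  genes <- unique(records$gene)
  idx <- matrix(NA_integer_, length(genes), length(lv),
                dimnames = list(genes, lv))
  idx[cbind(match(records$gene, genes), match(as.character(records$interval), lv))] <-
    seq_len(nrow(records))
  if (anyNA(idx)) {
    miss <- which(is.na(idx), arr.ind = TRUE)
    abort("missing interval(s) for gene(s): %s",
          paste(utils::head(sprintf("%s@%s", genes[miss[, 1]], lv[miss[, 2]]), 5),
                collapse = ", "))
  }
  status <- matrix(records$status[idx], nrow(idx))
  out <- data.frame(gene = genes,
                    pattern = apply(status, 1, paste, collapse = ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- length(lv)
  attr(out, "rna_class") <- rna_class
  out
}

#' Ranked pattern-frequency table
#'
#' One row per distinct pattern with its gene count, percentage of all genes
#' (half-up, 2 decimals) and rank by descending count; ties in count are
#' broken lexicographically on the pattern string so ranking is
#' deterministic.
#'
#' @param traj `TrajectoryTable` from [encode_trajectories()], or any
#'   data.frame with a `pattern` column.
#' @return data.frame (`PatternFrequency`) with columns rank, pattern, count,
#'   percentage; counts sum to the number of genes.
#' @export
pattern_frequency <- function(traj) {
  if (nrow(traj) == 0) abort("empty trajectory table")
  tab <- table(traj$pattern)
  ord <- order(-as.integer(tab), names(tab))
  count <- as.integer(tab)[ord]
  data.frame(rank = seq_along(ord), pattern = names(tab)[ord], count = count,
             percentage = round_half_up(100 * count / sum(count), 2),
             stringsAsFactors = FALSE)
}

#' Pattern-space coverage
#'
#' Over k adjacent intervals the three-letter alphabet admits 3^k possible
#' trajectory strings; coverage is the percentage actually observed.
#' Observed unique patterns include the all-M pattern.
#'
#' @param x a `TrajectoryTable`, or directly the number of distinct observed
#'   patterns.
#' @param k number of intervals (taken from the table's `k` attribute or the
#'   pattern length when `x` is a table).
#' @return list with `n_unique`, `space_size` = 3^k and `coverage_pct`
#'   (half-up, 2 decimals).
#' @export
pattern_space_coverage <- function(x, k = NULL) {
  if (is.data.frame(x)) {
    if (is.null(k)) k <- attr(x, "k")
    if (is.null(k)) k <- nchar(x$pattern[1])
    n_unique <- length(unique(x$pattern))
  } else {
    n_unique <- as.integer(x)
    if (is.null(k)) abort("k is required when passing a unique-pattern count")
  }
  if (k < 1) abort("k must be >= 1")
  space <- 3^k
  if (n_unique > space)
    abort("%d unique patterns exceed the 3^%d = %d possible", n_unique, k, space)
  list(n_unique = n_unique, space_size = space,
       coverage_pct = round_half_up(100 * n_unique / space, 2))
}

#' Per-position tallies of non-maintained statuses
#'
#' Counts, at each interval position, how many genes carry a U and how many a
#' D, plus the number of genes whose whole pattern differs from all-M.
#'
#' @param traj `TrajectoryTable`.
#' @return list with `per_position` (data.frame position, U, D) and
#'   `n_nonstationary`.
#' @export
nonstationary_summary <- function(traj) {
  k <- attr(traj, "k")
  if (is.null(k)) k <- if (nrow(traj)) nchar(traj$pattern[1]) else 0L
  if (nrow(traj) == 0 || k == 0)
    return(list(per_position = data.frame(position = integer(0),
                                          U = integer(0), D = integer(0)),
                n_nonstationary = 0L))
  ch <- do.call(rbind, strsplit(traj$pattern, ""))
  per <- data.frame(position = seq_len(k),
                    U = colSums(ch == "U"), D = colSums(ch == "D"),
                    row.names = NULL)
  list(per_position = per,
       n_nonstationary = sum(traj$pattern != strrep("M", k)))
}
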