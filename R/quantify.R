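#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the reference profile is the per-gene geometric
#' mean across samples; each sample's factor is the median, over genes with
#' nonzero counts in every sample, of count / reference.
#'
#' @param counts matrix or [count_matrix()], genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- get_counts(counts)
  if (ncol(m) < 2) abort("size factors need at least 2 samples")
  expressed <- rowSums(m > 0) == ncol(m)
  if (!any(expressed))
    abort(paste("no gene has nonzero counts in every sample;",
                "consider a pseudo-reference fallback on filtered data"))
  lm_ <- log(m[expressed, , drop = FALSE])
  ref <- rowMeans(lm_)
  apply(lm_, 2, function(col) exp(stats::median(col - ref)))
}

#' Counts per million
#' @param counts matrix or [count_matrix()].
#' @return `NormalizedMatrix` (numeric matrix with attribute `unit = "CPM"`).
#' @export
cpm <- function(counts) {
  m <- get_counts(counts)
  tot <- colSums(m)
  if (any(tot == 0))
    abort("zero library total in sample(s): %s",
          paste(colnames(m)[tot == 0], collapse = ", "))
  out <- sweep(m, 2, tot, "/") * 1e6
  attr(out, "unit") <- "CPM"
  out
}

#' Transcripts per million
#'
#' Per-gene length-normalized rate (count / length in kb), rescaled so every
#' column sums to 1e6.
#'
#' @param counts matrix or [count_matrix()].
#' @param lengths named vector of exonic lengths in bp (taken from the
#'   `CountMatrix` when omitted).
#' @return `NormalizedMatrix` with attribute `unit = "TPM"`.
#' @export
tpm <- function(counts, lengths = NULL) {
  m <- get_counts(counts)
  lengths <- get_lengths(counts, lengths)
  check_lengths(m, lengths)
  rate <- m / (lengths[rownames(m)] / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    abort("zero total rate in sample(s): %s",
          paste(colnames(m)[tot == 0], collapse = ", "))
  out <- sweep(rate, 2, tot, "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}

#' Fragments per kilobase per million mapped reads
#' @inheritParams tpm
#' @return `NormalizedMatrix` with attribute `unit = "FPKM"`.
#' @export
fpkm <- function(counts, lengths = NULL) {
  m <- get_counts(counts)
  lengths <- get_lengths(counts, lengths)
  check_lengths(m, lengths)
  tot <- colSums(m)
  if (any(tot == 0))
    abort("zero library total in sample(s): %s",
          paste(colnames(m)[tot == 0], collapse = ", "))
  out <- m * 1e9 / outer(lengths[rownames(m)], tot)
  attr(out, "unit") <- "FPKM"
  out
}

check_lengths <- function(m, lengths) {
  if (is.null(lengths)) abort("gene lengths are required")
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    abort("lengths missing for genes: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  if (any(lengths <= 0)) abort("gene lengths must be positive")
}

#' Seven-category abundance binning
#'
#' Classifies every gene, per sample, into one of seven half-open abundance
#' bins: \[0,0.01), \[0.01,0.1), \[0.1,1), \[1,10), \[10,100), \[100,1000),
#' \[1000,Inf). Left-closed, so a value exactly on a boundary belongs to the
#' higher bin.
#'
#' @param norm normalized matrix (any unit).
#' @return integer matrix bins x samples of gene counts; per-sample columns
#'   sum to the number of genes.
#' @export
abundance_bins <- function(norm) {
  if (any(norm < 0)) abort("normalized values must be non-negative")
  breaks <- c(0, 0.01, 0.1, 1, 10, 100, 1000, Inf)
  labels <- c("[0,0.01)", "[0.01,0.1)", "[0.1,1)", "[1,10)",
              "[10,100)", "[100,1000)", "[1000,Inf)")
  out <- apply(as.matrix(norm), 2, function(col)
    table(cut(col, breaks, labels = labels, right = FALSE,
              include.lowest = FALSE)))
  # cut() with right = FALSE already puts 0 in the first bin via its own
  # left-closed convention; include.lowest not needed but 0 must land there
  if (any(colSums(out) != nrow(as.matrix(norm))))
    abort("binning failed to partition all genes")
  out
}

#' Library summary rates
#'
#' @param raw_reads,clean_reads,mapped_reads read totals with
#'   `0 <= mapped <= clean <= raw`.
#' @return named vector with `clean_rate` (and `mapping_rate` when
#'   `mapped_reads` is given), percentages rounded half-up to 2 decimals.
#' @export
library_rates <- function(raw_reads, clean_reads, mapped_reads = NULL) {
  if (raw_reads == 0) abort("raw_reads must be positive")
  if (clean_reads < 0 || clean_reads > raw_reads)
    abort("need 0 <= clean_reads <= raw_reads")
  out <- c(clean_rate = round_half_up(100 * clean_reads / raw_reads, 2))
  if (!is.null(mapped_reads)) {
    if (mapped_reads < 0 || mapped_reads > clean_reads)
      abort("need 0 <= mapped_reads <= clean_reads")
    out <- c(out, mapping_rate = round_half_up(100 * mapped_reads / clean_reads, 2))
  }
  out
}

#' Sample-level PCA on log-transformed expression
#'
#' log2(x + 1) transform, per-gene centering, exact singular value
#' decomposition. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param norm normalized matrix, genes x samples.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `variance` (per
#'   component, non-increasing) and `loadings`.
#' @export
pca_scores <- function(norm, n_components = 2) {
  m <- as.matrix(norm)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples")
  x <- log2(m + 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (n_components > avail) {
    warning(sprintf("only %d components available; truncating", avail))
    n_components <- avail
  }
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x[, keep, drop = FALSE], 2, flip, "*"),
       variance = pc$sdev[keep]^2,
       loadings = sweep(pc$rotation[, keep, drop = FALSE], 2, flip, "*"))
}

#' Sample-sample Pearson correlation matrix
#'
#' Computed on log2(x + 1) values, matching the PCA transform.
#'
#' @param norm normalized matrix, genes x samples.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(norm) {
  m <- log2(as.matrix(norm) + 1)
  if (ncol(m) < 2) abort("need at least 2 samples")
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    abort("zero-variance sample(s): %s",
          paste(colnames(m)[v == 0], collapse = ", "))
  stats::cor(m)
}
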