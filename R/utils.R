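#' Round half away from zero
#'
#' Printed percentages in this package follow the half-up convention (2.925
#' becomes 2.93), not the IEC 60559 half-to-even rule used by [base::round()].
#' A small epsilon guards against binary representations that sit fractionally
#' below the half boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Extract the count matrix from a CountMatrix or bare matrix
#' @noRd
get_counts <- function(x) {
  if (inherits(x, "CountMatrix")) x$counts else as.matrix(x)
}

get_lengths <- function(x, lengths = NULL) {
  if (!is.null(lengths)) return(lengths)
  if (inherits(x, "CountMatrix")) x$lengths else NULL
}

#' Count-matrix container
#'
#' Light container for a genes x samples table of non-negative integer counts
#' with an explicit chronological sample order, optional exonic gene lengths
#' (bp) and an RNA-class tag. Most functions in the package also accept a bare
#' matrix.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in chronologically ordered columns.
#' @param lengths optional named numeric vector of exonic lengths in bp.
#' @param rna_class one of `"mRNA"`, `"lncRNA"`, `"circRNA"`, `"miRNA"`.
#' @return object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, lengths = NULL,
                         rna_class = c("mRNA", "lncRNA", "circRNA", "miRNA")) {
  rna_class <- match.arg(rna_class)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    abort("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate gene ids in counts")
  if (any(counts < 0) || any(counts != floor(counts)))
    abort("counts must be non-negative integers")
  if (!is.null(lengths)) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
      abort("lengths missing for genes: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    if (any(lengths <= 0)) abort("gene lengths must be positive")
    lengths <- lengths[rownames(counts)]
  }
  structure(list(counts = counts, lengths = lengths, rna_class = rna_class),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d %s genes x %d samples (%s)\n",
              nrow(x$counts), x$rna_class, ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}
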