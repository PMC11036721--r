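#' Read a gene x timepoint count table
#'
#' Tab-separated, header row of chronologically ordered sample names, gene
#' ids in the first column.
#'
#' @param path TSV path.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a count or normalized matrix as TSV
#'
#' @param m matrix with gene rownames.
#' @param path output path.
#' @param unit optional unit written as a `# unit=` comment header.
#' @export
write_matrix_tsv <- function(m, path, unit = attr(m, "unit")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(unit)) writeLines(sprintf("# unit=%s", unit), con)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a 2-column gene-length table
#' @param path TSV path (gene, length_bp).
#' @return named numeric vector of lengths.
#' @export
read_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read a STRING-style weighted edge list
#'
#' Three columns (node1, node2, combined_score); scores on the 0-999 integer
#' dialect are rescaled by [build_graph()].
#'
#' @param path TSV path.
#' @return data.frame node1, node2, combined_score.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 3) abort("edge table needs 3 columns")
  names(df)[1:3] <- c("node1", "node2", "combined_score")
  df$combined_score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(df$combined_score))
  if (length(bad))
    abort("malformed score at line(s): %s",
          paste(utils::head(bad + 1, 5), collapse = ", "))
  df
}

#' Read a miRNA-target pair table
#' @param path TSV path (source_id, mirna_id, score).
#' @return data.frame source_id, mirna_id, score.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df)[1:2] <- c("source_id", "mirna_id")
  if (ncol(df) >= 3) names(df)[3] <- "score"
  df
}

#' Read a GMT gene-set collection
#' @param path GMT path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a network as SIF
#'
#' Simple interaction format for Cytoscape: `source relation target` per
#' line.
#'
#' @param edges data.frame whose first two columns are the endpoints.
#' @param path output path.
#' @param relation interaction label (default `"pp"`).
#' @export
write_sif <- function(edges, path, relation = "pp") {
  writeLines(sprintf("%s\t%s\t%s", edges[[1]], relation, edges[[2]]), path)
}
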