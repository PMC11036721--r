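#' Restrict miRNA-target pairs to differential molecules
#'
#' Keeps pairs whose molecule and miRNA are both differentially expressed
#' (status U or D) in the given interval's DE records, annotating each side's
#' direction. Molecules absent from the DE records are treated as
#' non-differential.
#'
#' @param pairs data.frame with columns source_id, mirna_id (optionally
#'   score), one molecule class per table.
#' @param de data.frame of `DERecord`s for one interval covering both the
#'   molecules and the miRNAs (stack the per-class records).
#' @param source_class class label recorded on the output
#'   (`"mRNA"`, `"lncRNA"` or `"circRNA"`).
#' @return filtered pair table with added columns source_class,
#'   source_direction, mirna_direction.
#' @export
filter_differential <- function(pairs, de,
                                source_class = c("mRNA", "lncRNA", "circRNA")) {
  source_class <- match.arg(source_class)
  status <- stats::setNames(de$status, de$gene)
  src <- status[pairs$source_id]
  mir <- status[pairs$mirna_id]
  src[is.na(src)] <- "M"; mir[is.na(mir)] <- "M"
  keep <- src != "M" & mir != "M"
  out <- pairs[keep, , drop = FALSE]
  out$source_class <- rep(source_class, nrow(out))
  out$source_direction <- ifelse(src[keep] == "U", "up", "down")
  out$mirna_direction <- ifelse(mir[keep] == "U", "up", "down")
  rownames(out) <- NULL
  out
}

#' Join ceRNA triples through shared miRNAs
#'
#' Emits (molecule, miRNA, mRNA) whenever the molecule-miRNA and mRNA-miRNA
#' pairs share the miRNA; duplicates are removed.
#'
#' @param mol_pairs filtered pair table for the sponge class (lncRNA or
#'   circRNA), from [filter_differential()].
#' @param mrna_pairs filtered miRNA-mRNA pair table for the same interval.
#' @return data.frame of triples: source_id, source_class, mirna_id, mrna_id
#'   (plus directions when present in the inputs).
#' @export
join_triples <- function(mol_pairs, mrna_pairs) {
  empty <- data.frame(source_id = character(0), source_class = character(0),
                      mirna_id = character(0), mrna_id = character(0))
  if (nrow(mol_pairs) == 0 || nrow(mrna_pairs) == 0) return(empty)
  mol <- unique(mol_pairs[, intersect(c("source_id", "source_class",
                                        "mirna_id", "source_direction",
                                        "mirna_direction"),
                                      names(mol_pairs))])
  mr <- unique(data.frame(mirna_id = mrna_pairs$mirna_id,
                          mrna_id = mrna_pairs$source_id,
                          mrna_direction =
                            if ("source_direction" %in% names(mrna_pairs))
                              mrna_pairs$source_direction else NA,
                          stringsAsFactors = FALSE))
  out <- merge(mol, mr, by = "mirna_id")
  cols <- intersect(c("source_id", "source_class", "mirna_id", "mrna_id",
                      "source_direction", "mirna_direction",
                      "mrna_direction"), names(out))
  out <- unique(out[, cols])
  out <- out[order(out$source_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join circRNA-miRNA-lncRNA-mRNA quadruples
#'
#' A quadruple (circRNA, miRNA, lncRNA, mRNA) is emitted for every pair of an
#' lncRNA triple and a circRNA triple sharing the same miRNA; all
#' combinations are produced and deduplicated.
#'
#' @param lnc_triples,circ_triples triple tables from [join_triples()] for
#'   the same interval.
#' @return data.frame circ_id, mirna_id, lnc_id, mrna_id.
#' @export
join_quadruples <- function(lnc_triples, circ_triples) {
  empty <- data.frame(circ_id = character(0), mirna_id = character(0),
                      lnc_id = character(0), mrna_id = character(0))
  if (nrow(lnc_triples) == 0 || nrow(circ_triples) == 0) return(empty)
  lnc <- unique(data.frame(mirna_id = lnc_triples$mirna_id,
                           lnc_id = lnc_triples$source_id,
                           mrna_id = lnc_triples$mrna_id,
                           stringsAsFactors = FALSE))
  circ <- unique(data.frame(mirna_id = circ_triples$mirna_id,
                            circ_id = circ_triples$source_id,
                            stringsAsFactors = FALSE))
  out <- unique(merge(circ, lnc, by = "mirna_id"))
  out <- out[order(out$circ_id, out$mirna_id, out$lnc_id, out$mrna_id),
             c("circ_id", "mirna_id", "lnc_id", "mrna_id")]
  rownames(out) <- NULL
  out
}

#' Assemble a ceRNA network from triple tables
#'
#' Nodes are the molecules and miRNAs appearing in the triples; edges are the
#' distinct molecule-miRNA links (each link is one edge no matter how many
#' triples traverse it). mRNA-miRNA links are edges too.
#'
#' @param triples one triple table or a list of them (e.g. lncRNA and circRNA
#'   triples of one interval).
#' @return `CeRNANetwork`: list with `nodes` (id, class, direction), `edges`
#'   (molecule_id, mirna_id), `triples` (stacked input).
#' @export
cerna_network <- function(triples) {
  if (is.data.frame(triples)) triples <- list(triples)
  tr <- do.call(rbind, lapply(triples, function(x) {
    x$source_direction <- if ("source_direction" %in% names(x))
      x$source_direction else rep(NA, nrow(x))
    x$mirna_direction <- if ("mirna_direction" %in% names(x))
      x$mirna_direction else rep(NA, nrow(x))
    x$mrna_direction <- if ("mrna_direction" %in% names(x))
      x$mrna_direction else rep(NA, nrow(x))
    x[, c("source_id", "source_class", "mirna_id", "mrna_id",
          "source_direction", "mirna_direction", "mrna_direction")]
  }))
  if (is.null(tr) || nrow(tr) == 0)
    return(structure(list(nodes = data.frame(id = character(0),
                                             class = character(0),
                                             direction = character(0)),
                          edges = data.frame(molecule_id = character(0),
                                             mirna_id = character(0)),
                          triples = tr), class = "CeRNANetwork"))
  nodes <- unique(rbind(
    data.frame(id = tr$source_id, class = tr$source_class,
               direction = tr$source_direction, stringsAsFactors = FALSE),
    data.frame(id = tr$mirna_id, class = "miRNA",
               direction = tr$mirna_direction, stringsAsFactors = FALSE),
    data.frame(id = tr$mrna_id, class = "mRNA",
               direction = tr$mrna_direction, stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$class, nodes$id), ]
  rownames(nodes) <- NULL
  edges <- unique(rbind(
    data.frame(molecule_id = tr$source_id, mirna_id = tr$mirna_id,
               stringsAsFactors = FALSE),
    data.frame(molecule_id = tr$mrna_id, mirna_id = tr$mirna_id,
               stringsAsFactors = FALSE)))
  edges <- edges[order(edges$mirna_id, edges$molecule_id), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triples = tr),
            class = "CeRNANetwork")
}

#' ceRNA network statistics
#'
#' @param net a `CeRNANetwork` from [cerna_network()].
#' @return list with `n_nodes`, `n_edges`, `n_triples`, and `by_class` /
#'   `by_class_direction` node tallies. In a single-miRNA star the edge count
#'   equals the number of molecule nodes.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "CeRNANetwork"))
  by_class <- table(net$nodes$class)
  by_cd <- table(net$nodes$class, net$nodes$direction)
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       n_triples = nrow(unique(net$triples[, c("source_id", "mirna_id",
                                               "mrna_id")])),
       by_class = by_class, by_class_direction = by_cd)
}
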