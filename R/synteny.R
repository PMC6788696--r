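# Windowed microsynteny: a syntenic score is the number of homologous
# genes shared within a 41-gene vicinity (anchor +/- 20); a region with
# score >= 4 is called syntenic, and a syntenic region lacking a homolog
# of the anchor itself is a syntenic proxy.

#' Construct a gene-order object
#'
#' @param contigs Named list: contig id -> character vector of gene ids in
#'   positional order (rank 0, 1, ... along the contig).
#' @return A `"gene_order"` object with a gene -> (contig, rank) reverse
#'   index.
#' @export
gene_order <- function(contigs) {
  stopifnot(is.list(contigs), !is.null(names(contigs)))
  genes <- unlist(contigs, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("gene(s) appear on more than one position: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  index <- data.frame(
    gene = genes,
    contig = rep(names(contigs), lengths(contigs)),
    rank = unlist(lapply(contigs, function(g) seq_along(g) - 1L),
                  use.names = FALSE),
    stringsAsFactors = FALSE)
  rownames(index) <- index$gene
  structure(list(contigs = contigs, index = index), class = "gene_order")
}

#' Build a symmetric homology map from gene pairs
#'
#' @param pairs data.frame (or 2-column matrix) of homologous gene-id
#'   pairs. Self-pairs are rejected (the relation is irreflexive).
#' @return A `"homology_map"` object.
#' @export
homology_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  if (any(a == b)) {
    stop("homology relation is irreflexive; self-pair(s): ",
         paste(unique(a[a == b]), collapse = ", "))
  }
  env <- new.env(parent = emptyenv())
  add <- function(x, y) {
    assign(x, unique(c(if (exists(x, envir = env)) get(x, envir = env), y)),
           envir = env)
  }
  for (i in seq_along(a)) { add(a[i], b[i]); add(b[i], a[i]) }
  structure(list(env = env), class = "homology_map")
}

#' Homologs of a gene under a homology map
#' @param map A [homology_map()].
#' @param gene Gene id.
#' @return Character vector (possibly empty).
#' @export
homologs <- function(map, gene) {
  if (exists(gene, envir = map$env)) get(gene, envir = map$env) else character(0)
}

#' Extract the gene window around an anchor
#'
#' @param order A [gene_order()].
#' @param anchor Gene id present in `order`.
#' @param up,down Genes to include up/downstream of the anchor (defaults
#'   give the 41-gene vicinity: anchor plus 20 each side), truncated at
#'   contig ends.
#' @return Character vector of gene ids, in contig order.
#' @export
extract_window <- function(order, anchor, up = 20, down = 20) {
  if (!anchor %in% order$index$gene) stop("unknown anchor gene: ", anchor)
  row <- order$index[anchor, ]
  genes <- order$contigs[[row$contig]]
  lo <- max(0L, row$rank - up)
  hi <- min(length(genes) - 1L, row$rank + down)
  genes[(lo:hi) + 1L]
}

#' Syntenic score of a target window against a query window
#'
#' The number of target-window genes having at least one homolog in the
#' query window; each target gene is counted once regardless of how many
#' homologous partners it has (no paralog inflation).
#'
#' @param query_window,target_window Non-empty gene-id vectors.
#' @param homology A [homology_map()].
#' @return Non-negative integer score.
#' @export
syntenic_score <- function(query_window, target_window, homology) {
  stopifnot(length(query_window) > 0, length(target_window) > 0)
  sum(vapply(target_window,
             function(g) any(homologs(homology, g) %in% query_window),
             logical(1)))
}

#' Is a score syntenic at the given threshold?
#' @param score Non-negative integer.
#' @param threshold Minimum syntenic score (default 4).
#' @return `TRUE` iff `score >= threshold`.
#' @export
call_synteny <- function(score, threshold = 4) {
  stopifnot(score >= 0)
  score >= threshold
}

#' Find syntenic regions of an anchor gene in a target genome
#'
#' Candidate target windows are centred on target genes homologous to any
#' gene of the anchor's query window; overlapping candidates on the same
#' contig are merged keeping the best score. A passing window lacking a
#' homolog of the anchor itself is flagged a syntenic proxy.
#'
#' @param anchor Gene id in `query_order`.
#' @param query_order,target_order [gene_order()] objects.
#' @param homology A [homology_map()].
#' @param up,down Window half-widths (default 20, the 41-gene vicinity).
#' @param threshold Syntenic-score threshold (default 4).
#' @param keep_all If `TRUE`, return sub-threshold candidates too.
#' @return data.frame: anchor, target_contig, center, win_start, win_end
#'   (target ranks, inclusive), score, is_syntenic, is_proxy.
#' @export
find_syntenic_regions <- function(anchor, query_order, target_order,
                                  homology, up = 20, down = 20,
                                  threshold = 4, keep_all = FALSE) {
  qwin <- extract_window(query_order, anchor, up, down)
  cand <- unique(unlist(lapply(qwin, homologs, map = homology)))
  cand <- cand[cand %in% target_order$index$gene]
  empty <- data.frame(anchor = character(0), target_contig = character(0),
                      center = character(0), win_start = integer(0),
                      win_end = integer(0), score = integer(0),
                      is_syntenic = logical(0), is_proxy = logical(0))
  if (length(cand) == 0) return(empty)
  anchor_homs <- homologs(homology, anchor)
  rows <- lapply(cand, function(g) {
    twin <- extract_window(target_order, g, up, down)
    row <- target_order$index[g, ]
    sc <- syntenic_score(qwin, twin, homology)
    data.frame(anchor = anchor, target_contig = row$contig, center = g,
               win_start = max(0L, row$rank - up),
               win_end = min(length(target_order$contigs[[row$contig]]) - 1L,
                             row$rank + down),
               score = sc, is_syntenic = sc >= threshold,
               is_proxy = sc >= threshold && !any(anchor_homs %in% twin))
  })
  calls <- do.call(rbind, rows)
  # merge overlapping candidate windows per contig, keep the best score
  kept <- lapply(split(calls, calls$target_contig), function(cc) {
    ir <- IRanges::IRanges(start = cc$win_start + 1L, end = cc$win_end + 1L)
    grp <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    do.call(rbind, lapply(split(cc, grp), function(g) {
      g[order(-g$score, g$win_start), ][1, , drop = FALSE]
    }))
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  if (!keep_all) out <- out[out$is_syntenic, , drop = FALSE]
  out[order(out$target_contig, out$win_start), , drop = FALSE]
}
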