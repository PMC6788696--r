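# Promoter analysis: strand-aware extraction of the region upstream of
# the transcription start site (TSS), cis-element scanning on both
# strands, and counting with overlapping sites of a motif counted once.

#' Extract upstream promoter regions
#'
#' For a + strand gene with TSS at 1-based position p, the promoter is
#' `[p - length, p - 1]`; for a - strand gene it is `[p + 1, p + length]`
#' reverse-complemented, so the returned sequence always reads away from
#' the gene in promoter orientation. Regions are clipped at contig bounds
#' and flagged truncated.
#'
#' @param genome Named character vector: contig id -> nucleotide sequence.
#' @param tss data.frame with columns gene, contig, position (1-based TSS),
#'   strand (`"+"`/`"-"`).
#' @param length Upstream length in bp (default 1500).
#' @return data.frame of class `"promoter_set"`: gene, contig, start, end
#'   (1-based inclusive genomic span), strand, seq, truncated.
#' @export
extract_upstream <- function(genome, tss, length = 1500) {
  stopifnot(all(c("gene", "contig", "position", "strand") %in% names(tss)))
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    g <- tss[i, ]
    if (!g$contig %in% names(genome)) stop("unknown contig: ", g$contig)
    clen <- nchar(genome[[g$contig]])
    if (g$position < 1 || g$position > clen) {
      stop(sprintf("TSS of %s at %d outside contig %s (length %d)",
                   g$gene, g$position, g$contig, clen))
    }
    if (g$strand == "+") {
      start <- max(1, g$position - length)
      end <- g$position - 1
    } else {
      start <- g$position + 1
      end <- min(clen, g$position + length)
    }
    truncated <- (end - start + 1) < length
    seq <- if (end >= start) substr(genome[[g$contig]], start, end) else ""
    if (g$strand == "-" && nzchar(seq)) {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    }
    data.frame(gene = g$gene, contig = g$contig, start = start, end = end,
               strand = g$strand, seq = seq, truncated = truncated)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("promoter_set", class(out))
  out
}

#' Scan a promoter sequence for a nucleotide motif on both strands
#'
#' IUPAC consensus motifs are matched with
#' [Biostrings::matchPattern()] (`fixed = FALSE`); PWMs with
#' [Biostrings::matchPWM()]. Both the promoter and its reverse complement
#' are scanned; all coordinates are reported on the promoter's own
#' coordinates (0-based half-open), ordered by start.
#'
#' @param seq Promoter nucleotide string.
#' @param motif A [motif_def()] with an IUPAC `pattern` or a `pwm`.
#' @param id Gene id recorded in the hit rows.
#' @return data.frame: motif, id, start, end, strand, text.
#' @export
scan_dna_motif <- function(seq, motif, id = NA_character_) {
  stopifnot(inherits(motif, "motif_def"))
  empty <- data.frame(motif = character(0), id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), text = character(0))
  if (!nzchar(seq)) return(empty)
  subj <- Biostrings::DNAString(seq)
  n <- nchar(seq)
  hits_on <- function(s, strand) {
    if (!is.null(motif$pattern)) {
      pat <- gsub(".", "N", motif$pattern, fixed = TRUE)
      if (!all(strsplit(pat, "")[[1]] %in%
               names(Biostrings::IUPAC_CODE_MAP))) {
        stop("motif '", motif$name, "' is not a nucleotide IUPAC consensus")
      }
      if (nchar(pat) > length(s)) return(NULL)
      v <- Biostrings::matchPattern(pat, s, fixed = FALSE)
    } else {
      if (ncol(motif$pwm) > length(s)) return(NULL)
      v <- Biostrings::matchPWM(motif$pwm, s, min.score = motif$min_score)
    }
    if (length(v) == 0) return(NULL)
    data.frame(motif = motif$name, id = id,
               start = BiocGenerics::start(v) - 1L,
               end = BiocGenerics::end(v),
               strand = strand,
               text = as.character(v))
  }
  fwd <- hits_on(subj, "+")
  rev_hits <- hits_on(Biostrings::reverseComplement(subj), "-")
  if (!is.null(rev_hits) && nrow(rev_hits) > 0) {
    # map reverse-complement coordinates back onto the promoter
    s <- n - rev_hits$end
    e <- n - rev_hits$start
    rev_hits$start <- s
    rev_hits$end <- e
  }
  out <- rbind(fwd, rev_hits)
  if (is.null(out)) return(empty)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Count motif sites with overlapping sites counted once
#'
#' Hits (all from one gene x motif pair) whose spans share at least one
#' position — on either strand — are merged into clusters; the cluster
#' count is returned. Invariant to hit order.
#'
#' @param hits data.frame with `start`/`end` columns (0-based half-open),
#'   as returned by [scan_dna_motif()].
#' @return Integer number of merged site clusters.
#' @export
count_once <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(0L)
  ir <- IRanges::IRanges(start = hits$start + 1L, end = hits$end)
  length(IRanges::reduce(ir))
}

#' Per-gene, per-motif presence/count matrix
#'
#' @param regions A `"promoter_set"` from [extract_upstream()] (or any
#'   data.frame with `gene` and `seq` columns).
#' @param motifs List of nucleotide [motif_def()] objects.
#' @return data.frame: gene, motif, raw_count, dedup_count, present.
#' @export
presence_matrix <- function(regions, motifs) {
  stopifnot(nrow(regions) > 0, length(motifs) > 0)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    for (m in motifs) {
      hits <- scan_dna_motif(regions$seq[i], m, id = regions$gene[i])
      dedup <- count_once(hits)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = regions$gene[i], motif = m$name,
        raw_count = nrow(hits), dedup_count = dedup,
        present = dedup >= 1L)
    }
  }
  do.call(rbind, rows)
}

#' The cis-element library shipped with the package
#'
#' Canonical consensus placeholders: the AuxRE core `TGTCTC` and a
#' B-ARR-binding core `RGATY`. These are documented substitutes for the
#' external PlantPAN position-weight matrices used in the source survey,
#' which are not redistributed here; the counting rules, not the matrices,
#' are this package's content.
#'
#' @return List of [motif_def()] objects.
#' @export
default_cis_library <- function() {
  list(motif_def("AuxRE", "TGTCTC", kind = "cis"),
       motif_def("B-ARR", "RGATY", kind = "cis"))
}
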