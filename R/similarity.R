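# Desk-scale homolog retrieval: Smith-Waterman local alignment with affine
# gaps and Karlin-Altschul E-values, standing in for a BLAST search stage.

#' Construct a scoring scheme
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`) and Karlin-Altschul
#' parameters for converting raw local scores to E-values. Defaults are
#' BLOSUM62 with the standard ungapped parameters (lambda = 0.3176,
#' K = 0.134).
#'
#' @param matrix Symmetric integer substitution matrix with residue
#'   row/column names. Default: BLOSUM62 from Biostrings.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param K,lambda Positive Karlin-Altschul parameters.
#' @return A `"scoring_scheme"` object.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           K = 0.134, lambda = 0.3176) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (K <= 0 || lambda <= 0) stop("Karlin-Altschul K and lambda must be > 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' The BLOSUM62 substitution matrix
#' @return Integer matrix (from Biostrings).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# residues -> 1-based row indices into the scheme matrix; errors on unknowns
.residue_index <- function(s, scheme, what = "sequence") {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(scheme$matrix))
  if (anyNA(idx)) {
    stop(what, " contains characters outside the substitution alphabet: ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param a,b Non-empty protein strings.
#' @param scheme A [scoring_scheme()].
#' @return List with `score` (>= 0) and `a_span`, `b_span`: 0-based
#'   half-open intervals achieving the score (empty, `c(0, 0)`, when the
#'   best score is 0).
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  ia <- .residue_index(a, scheme, "a")
  ib <- .residue_index(b, scheme, "b")
  S <- scheme$matrix[ia, ib, drop = FALSE]
  r <- sw_affine_cpp(S, scheme$gap_open, scheme$gap_extend)
  list(score = r$score,
       a_span = c(r$a_start, r$a_end),
       b_span = c(r$b_start, r$b_end))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)` for a raw local score against a
#' query of length `m` and a database of total length `n`.
#'
#' @param score Raw alignment score.
#' @param m Query length (>= 1).
#' @param n Database length in residues (>= 1).
#' @param scheme A [scoring_scheme()].
#' @return Expected number of chance hits at this score or better.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Search a sequence database for homologs of each query
#'
#' Every query is locally aligned against every database sequence; pairs
#' whose E-value is at or below `cutoff` are reported, one best-scoring hit
#' per (query, subject) pair. The database length used in the E-value is
#' the total residue count of the database.
#'
#' @param queries,database Named character vectors of protein sequences.
#'   Nucleotide databases should be translated first ([translate_cds()]),
#'   or pass `translate = TRUE`.
#' @param scheme A [scoring_scheme()].
#' @param cutoff Inclusive E-value threshold (default `1e-5`).
#' @param translate If `TRUE`, database entries are CDS and are translated
#'   in frame 1 before searching.
#' @return data.frame: query, subject, score, evalue, qstart, qend, sstart,
#'   send (0-based half-open spans), sorted by query then E-value.
#' @export
search_homologs <- function(queries, database, scheme = scoring_scheme(),
                            cutoff = 1e-5, translate = FALSE) {
  stopifnot(!is.null(names(queries)))
  empty <- data.frame(query = character(0), subject = character(0),
                      score = numeric(0), evalue = numeric(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0))
  if (length(database) == 0) return(empty)
  stopifnot(!is.null(names(database)))
  if (translate) database <- vapply(database, translate_cds, character(1))
  n_db <- sum(nchar(database))
  rows <- list()
  for (q in names(queries)) {
    for (s in names(database)) {
      al <- local_align(queries[[q]], database[[s]], scheme)
      ev <- evalue(al$score, nchar(queries[[q]]), n_db, scheme)
      if (ev <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, subject = s, score = al$score, evalue = ev,
          qstart = al$a_span[1], qend = al$a_span[2],
          sstart = al$b_span[1], send = al$b_span[2])
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$query, out$evalue), , drop = FALSE]
}
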