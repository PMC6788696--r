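# Iterative alignment-occupancy curation: length prefilter, column and
# sequence occupancy filters, and the align-filter loop run until no
# sequences are removed (a fixed point of the two filters).

#' Curation filter configuration
#'
#' Defaults reproduce the survey settings this package implements:
#' sequences kept if 120-971 residues long (inclusive); aligned columns
#' removed when more than 50% of their characters are gaps; sequences
#' removed when their residues cover less than half of the column-filtered
#' alignment length.
#'
#' @param min_len,max_len Inclusive length bounds for the prefilter.
#' @param max_col_missing Remove a column when its gap fraction strictly
#'   exceeds this (default 0.5).
#' @param min_seq_frac Remove a sequence when its non-gap residue count is
#'   strictly below this fraction of the alignment length (default 0.5).
#' @param max_iter Safety bound on curation iterations.
#' @return A `"filter_config"` list.
#' @export
filter_config <- function(min_len = 120, max_len = 971,
                          max_col_missing = 0.5, min_seq_frac = 0.5,
                          max_iter = 20) {
  stopifnot(min_len <= max_len,
            max_col_missing > 0, max_col_missing < 1,
            min_seq_frac > 0, min_seq_frac < 1,
            max_iter >= 1)
  structure(list(min_len = min_len, max_len = max_len,
                 max_col_missing = max_col_missing,
                 min_seq_frac = min_seq_frac, max_iter = max_iter),
            class = "filter_config")
}

#' Keep sequences within the configured length range
#'
#' @param seqs Named character vector of protein sequences.
#' @param cfg A [filter_config()].
#' @return The subset with `min_len <= length <= max_len` (both inclusive).
#' @export
length_prefilter <- function(seqs, cfg = filter_config()) {
  seqs[nchar(seqs) >= cfg$min_len & nchar(seqs) <= cfg$max_len]
}

#' Remove low-occupancy alignment columns
#'
#' A column is removed iff its gap fraction strictly exceeds
#' `cfg$max_col_missing`; a column with exactly 50% gaps is retained at the
#' default. `X` counts as present, not missing.
#'
#' @param aln An `"aln"` object.
#' @param cfg A [filter_config()].
#' @return List with `aln` (filtered) and `removed` (1-based original
#'   column indices).
#' @export
filter_columns <- function(aln, cfg = filter_config()) {
  m <- alignment_matrix(aln)
  gap_frac <- colMeans(m == aln$gap)
  drop <- which(gap_frac > cfg$max_col_missing)
  if (length(drop) == ncol(m)) {
    stop("degenerate curation: all ", ncol(m), " columns removed")
  }
  if (length(drop) > 0) m <- m[, -drop, drop = FALSE]
  list(aln = new_alignment(aln$ids, apply(m, 1, paste, collapse = "")),
       removed = drop)
}

#' Remove short sequences after column filtering
#'
#' A row is removed iff its non-gap residue count is strictly below
#' `cfg$min_seq_frac` times the alignment length ("less than half" at the
#' default); a row covering exactly half is retained.
#'
#' @param aln An `"aln"` object (normally the output of [filter_columns()]).
#' @param cfg A [filter_config()].
#' @return List with `aln` (filtered) and `removed` (character ids).
#' @export
filter_sequences <- function(aln, cfg = filter_config()) {
  m <- alignment_matrix(aln)
  resid <- rowSums(m != aln$gap)
  drop <- which(resid < cfg$min_seq_frac * ncol(m))
  if (length(drop) == nrow(m)) {
    stop("degenerate curation: all ", nrow(m), " sequences removed")
  }
  ids <- aln$ids[setdiff(seq_len(nrow(m)), drop)]
  list(aln = new_alignment(ids, aln$seqs[ids]), removed = aln$ids[drop])
}

#' Iterate the column and sequence filters to a fixed point (no realignment)
#'
#' Applies [filter_columns()] then [filter_sequences()] repeatedly until a
#' pass removes neither columns nor sequences. Used for invariant testing;
#' the full curation loop with realignment is [curate_to_fixed_point()].
#'
#' @param aln An `"aln"` object.
#' @param cfg A [filter_config()].
#' @return List with `aln`, `passes` (number of filter passes) and
#'   `removed_ids`.
#' @export
filter_to_fixed_point <- function(aln, cfg = filter_config()) {
  removed_ids <- character(0)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    fc <- filter_columns(aln, cfg)
    fs <- filter_sequences(fc$aln, cfg)
    removed_ids <- c(removed_ids, fs$removed)
    done <- length(fc$removed) == 0 && length(fs$removed) == 0
    aln <- fs$aln
    if (done) break
  }
  list(aln = aln, passes = passes, removed_ids = removed_ids)
}

#' Fraction of gap characters in an alignment
#'
#' @param aln An `"aln"` object.
#' @return Gap fraction in `[0, 1]` (multiply by 100 for the conventional
#'   percentage).
#' @export
gap_fraction <- function(aln) {
  m <- alignment_matrix(aln)
  mean(m == aln$gap)
}

#' Curate a sequence set by iterated alignment and occupancy filtering
#'
#' The core curation algorithm: starting from the length-prefiltered
#' sequences, each iteration (1) aligns the current (degapped) set with
#' `aligner`, (2) removes columns with more than `max_col_missing` missing
#' data, (3) removes sequences covering less than `min_seq_frac` of the
#' column-filtered alignment. The loop stops when an iteration removes no
#' sequences (converged) or after `max_iter` iterations.
#'
#' @param seqs Named character vector of protein sequences.
#' @param cfg A [filter_config()].
#' @param aligner Function `(named character vector) -> "aln"` whose output
#'   degaps back to its input. Default: [progressive_align()].
#' @param scheme [scoring_scheme()] passed to the default aligner.
#' @return A `"curation_result"`: list with `alignment` (final `"aln"`),
#'   `iterations` (data.frame: iteration, n_seqs_in, n_cols_removed,
#'   n_seqs_removed), `converged`, `gap_fraction`, `removed_ids`.
#' @export
curate_to_fixed_point <- function(seqs, cfg = filter_config(),
                                  aligner = NULL,
                                  scheme = scoring_scheme()) {
  if (is.null(aligner)) {
    aligner <- function(s) progressive_align(s, scheme)
  }
  current <- length_prefilter(seqs, cfg)
  if (length(current) < 2) {
    stop("fewer than 2 sequences survive the length prefilter")
  }
  log_rows <- list()
  removed_ids <- character(0)
  converged <- FALSE
  aln <- NULL
  for (it in seq_len(cfg$max_iter)) {
    aligned <- aligner(current)
    if (!identical(sort(names(current)), sort(aligned$ids)) ||
        !all(degap(aligned)[names(current)] == current)) {
      stop("aligner violated its contract: degapped output differs from input")
    }
    fc <- tryCatch(filter_columns(aligned, cfg), error = function(e) {
      stop("iteration ", it, ": ", conditionMessage(e), call. = FALSE)
    })
    fs <- tryCatch(filter_sequences(fc$aln, cfg), error = function(e) {
      stop("iteration ", it, ": ", conditionMessage(e), call. = FALSE)
    })
    log_rows[[it]] <- data.frame(iteration = it,
                                 n_seqs_in = length(current),
                                 n_cols_removed = length(fc$removed),
                                 n_seqs_removed = length(fs$removed))
    removed_ids <- c(removed_ids, fs$removed)
    aln <- fs$aln
    current <- degap(aln)
    if (length(fs$removed) == 0) {
      converged <- TRUE
      break
    }
  }
  structure(list(alignment = aln,
                 iterations = do.call(rbind, log_rows),
                 converged = converged,
                 gap_fraction = gap_fraction(aln),
                 removed_ids = removed_ids),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf(
    "Curation: %d iterations, %s; final %d x %d, %.2f%% gaps\n",
    nrow(x$iterations),
    if (x$converged) "converged" else "max iterations reached",
    length(x$alignment$ids), alignment_length(x$alignment),
    100 * x$gap_fraction))
  invisible(x)
}
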