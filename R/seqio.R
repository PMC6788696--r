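# Sequence and alignment I/O: FASTA (via Biostrings), relaxed/strict PHYLIP,
# CDS translation, and tab-separated gene-order tables.

#' Construct an alignment object
#'
#' A rectangular character matrix of aligned sequences, stored as a named
#' character vector of equal-length strings plus the canonical gap symbol
#' `"-"`. Both `-` and `.` are accepted as gap characters on input; `.` is
#' canonicalised to `-`.
#'
#' @param ids Character vector of unique, non-empty row identifiers.
#' @param seqs Character vector of aligned residue strings, all the same
#'   length.
#' @return An object of class `"aln"`: a list with elements `ids`, `seqs`
#'   (named by `ids`) and `gap`.
#' @export
new_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have equal length")
  }
  if (length(ids) == 0) stop("alignment must have at least one row")
  if (anyDuplicated(ids)) {
    stop("duplicate alignment row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("alignment row ids must be non-empty")
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    stop("alignment rows differ in length: ", paste(unique(w), collapse = ", "))
  }
  if (w[1] < 1L) stop("alignment length must be >= 1")
  structure(list(ids = ids, seqs = setNames(seqs, ids), gap = "-"),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites (%.2f%% gaps)\n",
              length(x$ids), alignment_length(x), 100 * gap_fraction(x)))
  invisible(x)
}

#' Number of aligned sites
#' @param aln An `"aln"` object.
#' @return Integer site count.
#' @export
alignment_length <- function(aln) nchar(aln$seqs[[1]])

#' Alignment as a character matrix
#' @param aln An `"aln"` object.
#' @return Character matrix, rows = sequences, columns = sites.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Remove all gap characters from alignment rows
#' @param aln An `"aln"` object.
#' @return Named character vector of degapped sequences.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", aln$seqs, fixed = TRUE), aln$ids)
}

#' Read a multi-record FASTA file
#'
#' Wraps [Biostrings::readBStringSet()]. Record ids are the first
#' whitespace-delimited token of each header; wrapped sequence lines are
#' concatenated.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- Biostrings::width(set)
  if (any(w == 0)) {
    stop("empty sequence for record(s): ", paste(ids[w == 0], collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PHYLIP alignment (sequential; strict or relaxed names)
#'
#' The first line must hold the taxon count and site count. Both the strict
#' dialect (names padded to 10 characters) and the relaxed dialect
#' (whitespace-delimited names of any length) are accepted; sequences may
#' continue over multiple lines and may contain internal whitespace. Gap
#' characters `-` and `.` are both read as gaps.
#'
#' @param path Path to a PHYLIP file.
#' @return An `"aln"` object with the header's row and site counts.
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || any(is.na(hdr[1:2]))) {
    stop("PHYLIP header must hold two integers, got: ", lines[1])
  }
  ntax <- hdr[1]; nsite <- hdr[2]
  body <- lines[-1]
  ids <- character(0); seqs <- character(0)
  k <- 1L
  for (t in seq_len(ntax)) {
    if (k > length(body)) {
      stop(sprintf("PHYLIP header says %d sequences but body holds %d",
                   ntax, t - 1L))
    }
    line <- body[k]; k <- k + 1L
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    id <- toks[1]
    res <- paste(toks[-1], collapse = "")
    if (nchar(id) > 10 && (nchar(res) > nsite || length(toks) == 1)) {
      # strict dialect: 10-char name fused to the sequence
      id <- trimws(substr(line, 1, 10))
      res <- gsub("\\s", "", substr(trimws(line), 11, nchar(line)))
    }
    while (nchar(res) < nsite && k <= length(body)) {
      res <- paste0(res, gsub("\\s", "", body[k]))
      k <- k + 1L
    }
    if (nchar(res) != nsite) {
      stop(sprintf("sequence '%s' has %d sites, header says %d",
                   id, nchar(res), nsite))
    }
    ids <- c(ids, id); seqs <- c(seqs, res)
  }
  if (k <= length(body)) {
    stop(sprintf("PHYLIP header says %d sequences but body holds more", ntax))
  }
  new_alignment(ids, seqs)
}

#' Write an alignment as relaxed sequential PHYLIP
#'
#' Names are whitespace-delimited (relaxed dialect), so ids containing
#' whitespace cannot be encoded and raise an error.
#'
#' @param aln An `"aln"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(inherits(aln, "aln"))
  if (any(grepl("\\s", aln$ids))) {
    stop("relaxed PHYLIP cannot encode ids containing whitespace: ",
         paste(aln$ids[grepl("\\s", aln$ids)], collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln$ids), alignment_length(aln)), con)
  writeLines(paste(aln$ids, unname(aln$seqs)), con)
  invisible(path)
}

#' Translate a CDS to protein (frame 1, standard genetic code)
#'
#' Wraps [Biostrings::translate()]. The trailing incomplete codon is
#' dropped; stop codons are rendered `*`; ambiguous codons that do not
#' resolve to a unique amino acid are rendered `X`.
#'
#' @param cds Nucleotide string (length >= 3).
#' @param frame Reading frame; only frame 1 is supported.
#' @return Protein string of length `floor(nchar(cds) / 3)`.
#' @export
translate_cds <- function(cds, frame = 1) {
  stopifnot(frame == 1)
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n < 3) stop("CDS shorter than one codon (", n, " nt)")
  cds <- substr(cds, 1, (n %/% 3) * 3)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "solve"))
}

#' Read a tab-separated gene-order table
#'
#' Expected columns (no header): contig, start, end, strand, gene id.
#' Coordinates are 1-based inclusive. Genes are sorted by start within each
#' contig and assigned 0-based ranks.
#'
#' @param path Path to the table.
#' @return A `"gene_order"` object (see [gene_order()]).
#' @export
read_gene_order <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("gene-order table needs 5 columns, got ", ncol(df))
  names(df)[1:5] <- c("contig", "start", "end", "strand", "gene")
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("non-numeric coordinates in gene-order table ", path)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene ids in gene-order table: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  df <- df[order(df$contig, df$start), , drop = FALSE]
  gene_order(split(as.character(df$gene), df$contig))
}
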