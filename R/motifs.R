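# Peptide-signature scanning and superclade/clade classification of
# homeodomain (HD) proteins. The three superclades (T1/T2/T3) are
# diagnosed by exact HD nonapeptides (NVYNWFQNR / NVFYWFQNR / NVFYWFQNH);
# finer clades by additional motifs with region hints relative to the HD.

#' Define a peptide or nucleotide motif
#'
#' Consensus patterns use one character per position, with square-bracket
#' character classes (`L[DE]LRLS`) and `.` as a wildcard. Position weight
#' matrices (with a score threshold) are supported for nucleotide motifs.
#'
#' @param name Motif name.
#' @param pattern Consensus string, or `NULL` when `pwm` is given.
#' @param label Associated superclade or clade label (optional).
#' @param region Optional region hint: one of `"HD-internal"`,
#'   `"upstream-of-HD"`, `"downstream-of-HD"`, `"C-terminal"`.
#' @param kind Role of the motif in classification: `"superclade"`,
#'   `"superclade-support"`, or `"clade"`.
#' @param pwm Numeric position weight matrix (rows = alphabet), or `NULL`.
#' @param min_score Minimum PWM score for a hit (`matchPWM` convention,
#'   e.g. `"90%"`).
#' @param placeholder Logical; `TRUE` marks a synthetic stand-in pattern
#'   (used for motifs only depicted graphically in the source survey).
#' @return A `"motif_def"` object.
#' @export
motif_def <- function(name, pattern = NULL, label = NA_character_,
                      region = NA_character_, kind = "clade",
                      pwm = NULL, min_score = "90%", placeholder = FALSE) {
  stopifnot(nzchar(name), !is.null(pattern) || !is.null(pwm))
  if (!is.null(pattern)) {
    pos <- .parse_pattern(pattern)
    if (length(pos) < 5) {
      stop("motif '", name, "' has ", length(pos),
           " positions; minimum is 5")
    }
    if (any(lengths(pos) == 0)) stop("empty character class in ", pattern)
  }
  if (!is.na(region) &&
      !region %in% c("HD-internal", "upstream-of-HD", "downstream-of-HD",
                     "C-terminal")) {
    stop("unknown region hint: ", region)
  }
  structure(list(name = name, pattern = pattern, label = label,
                 region = region, kind = kind, pwm = pwm,
                 min_score = min_score, placeholder = placeholder),
            class = "motif_def")
}

# split a consensus pattern into per-position character vectors
.parse_pattern <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  pos <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      j <- i + 1L
      while (j <= length(ch) && ch[j] != "]") j <- j + 1L
      if (j > length(ch)) stop("unclosed character class in ", pattern)
      pos[[length(pos) + 1L]] <- ch[(i + 1):(j - 1)]
      i <- j + 1L
    } else {
      pos[[length(pos) + 1L]] <- ch[i]
      i <- i + 1L
    }
  }
  pos
}

#' Number of positions in a motif's consensus pattern
#' @param motif A [motif_def()].
#' @return Integer pattern width.
#' @export
motif_width <- function(motif) {
  if (is.null(motif$pattern)) return(ncol(motif$pwm))
  length(.parse_pattern(motif$pattern))
}

# consensus pattern -> anchored-free perl regex (character classes kept)
.pattern_regex <- function(pattern) {
  pos <- .parse_pattern(pattern)
  paste(vapply(pos, function(p) {
    if (length(p) == 1 && p == ".") "." else if (length(p) == 1) {
      p
    } else {
      paste0("[", paste(p, collapse = ""), "]")
    }
  }, character(1)), collapse = "")
}

#' Scan a protein sequence for all (possibly overlapping) motif matches
#'
#' @param seq Protein string.
#' @param motif A [motif_def()] with a consensus pattern.
#' @param id Sequence id recorded in the hit rows.
#' @return data.frame: motif, id, start, end (0-based half-open), text;
#'   hits reported left to right, overlaps allowed.
#' @export
scan_pattern <- function(seq, motif, id = NA_character_) {
  stopifnot(inherits(motif, "motif_def"), !is.null(motif$pattern))
  w <- motif_width(motif)
  empty <- data.frame(motif = character(0), id = character(0),
                      start = integer(0), end = integer(0),
                      text = character(0))
  if (nchar(seq) < w) return(empty)
  rx <- sprintf("(?=%s)", .pattern_regex(motif$pattern))
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  data.frame(motif = motif$name, id = id,
             start = starts - 1L, end = starts - 1L + w,
             text = substring(seq, starts, starts + w - 1L))
}

#' The three HD superclade signature motifs
#'
#' NVYNWFQNR diagnoses T1 (the WOX10/13/14, formerly "ancient" lineage),
#' NVFYWFQNR diagnoses T2 (WOX8/9 + WOX11/12, "intermediate"), and
#' NVFYWFQNH diagnoses T3 (WUS/WOX1-7, "modern").
#'
#' @return List of three [motif_def()] objects.
#' @export
superclade_signatures <- function() {
  list(motif_def("HD-T1", "NVYNWFQNR", label = "T1", region = "HD-internal",
                 kind = "superclade"),
       motif_def("HD-T2", "NVFYWFQNR", label = "T2", region = "HD-internal",
                 kind = "superclade"),
       motif_def("HD-T3", "NVFYWFQNH", label = "T3", region = "HD-internal",
                 kind = "superclade"))
}

#' Load a motif library from a YAML config file
#'
#' @param path YAML file with a top-level `motifs` list; each entry has
#'   `name`, `pattern`, and optional `label`, `region`, `kind`,
#'   `placeholder`.
#' @return List of [motif_def()] objects.
#' @export
read_motif_library <- function(path) {
  if (!file.exists(path)) stop("no such motif library: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$motifs) || length(y$motifs) == 0) {
    stop("motif library has no motifs: ", path)
  }
  lapply(y$motifs, function(m) {
    motif_def(m$name, m$pattern,
              label = m$label %||% NA_character_,
              region = m$region %||% NA_character_,
              kind = m$kind %||% "clade",
              placeholder = isTRUE(m$placeholder))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The motif library shipped with the package
#'
#' Printed signature motifs are exact; motifs only depicted graphically in
#' the source survey ship as clearly flagged synthetic placeholder
#' patterns (which the simulator plants, keeping end-to-end clade recovery
#' well defined).
#'
#' @return List of [motif_def()] objects.
#' @export
default_motif_library <- function() {
  read_motif_library(system.file("extdata", "wox_motifs.yaml",
                                 package = "famcurate"))
}

#' Classify a protein into a superclade by its HD signature
#'
#' Exactly one signature found: that superclade. None: `"unclassified"`.
#' Two or more distinct signatures: `"unclassified"` with `ambiguous =
#' TRUE`. The T2 signature co-occurring with a WUS-box (a T3-diagnostic
#' motif) keeps the T2 call but flags it ambiguous, mirroring the observed
#' cross-occurrence of NVFYWFQNR in T3 proteins.
#'
#' @param seq Protein string.
#' @param signatures Motif library containing the three HD signatures
#'   (and optionally a WUS-box definition for the conflict rule).
#' @param id Sequence id.
#' @return A `"clade_assignment"` list: id, superclade, clade, ambiguous,
#'   evidence (data.frame of hits).
#' @export
classify_superclade <- function(seq, signatures = default_motif_library(),
                                id = NA_character_) {
  sigs <- Filter(function(m) identical(m$kind, "superclade"), signatures)
  if (length(sigs) == 0) stop("signature library has no superclade motifs")
  hits <- do.call(rbind, lapply(sigs, scan_pattern, seq = seq, id = id))
  support <- Filter(function(m) identical(m$kind, "superclade-support"),
                    signatures)
  support_hits <- do.call(rbind, lapply(support, scan_pattern,
                                        seq = seq, id = id))
  labels <- unique(vapply(sigs, `[[`, character(1), "label")[
    vapply(sigs, `[[`, character(1), "name") %in% hits$motif])
  ambiguous <- FALSE
  if (length(labels) == 0) {
    superclade <- "unclassified"
  } else if (length(labels) > 1) {
    superclade <- "unclassified"
    ambiguous <- TRUE
  } else {
    superclade <- labels
    if (superclade == "T2" && !is.null(support_hits) &&
        nrow(support_hits) > 0) {
      supp_lab <- vapply(support, `[[`, character(1), "label")[
        vapply(support, `[[`, character(1), "name") %in% support_hits$motif]
      if (any(supp_lab == "T3")) {
        ambiguous <- TRUE
        hits <- rbind(hits, support_hits)
      }
    }
  }
  structure(list(id = id, superclade = superclade, clade = NA_character_,
                 ambiguous = ambiguous, evidence = hits),
            class = "clade_assignment")
}

#' Classify the C-terminal EAR repression motif variant
#'
#' `L[DE]LRLS` is the WOX5/7-clade EAR variant; `L[DE]L[ST]LN` the
#' WUS-clade variant. Scanning is restricted to the C-terminal window
#' (default: last 30 residues).
#'
#' @param seq Protein string.
#' @param window C-terminal window size in residues.
#' @return List with `type` (`"WOX5/7"`, `"WUS"`, `"none"`, or both) and
#'   `ambiguous` (TRUE when both variants match).
#' @export
classify_ear <- function(seq, window = 30) {
  tail_seq <- substr(seq, max(1L, nchar(seq) - window + 1L), nchar(seq))
  w57 <- scan_pattern(tail_seq, motif_def("EAR-WOX5/7", "L[DE]LRLS"))
  wus <- scan_pattern(tail_seq, motif_def("EAR-WUS", "L[DE]L[ST]LN"))
  types <- c(if (nrow(w57) > 0) "WOX5/7", if (nrow(wus) > 0) "WUS")
  if (length(types) == 0) types <- "none"
  list(type = types, ambiguous = length(types) > 1)
}

#' Locate the homeodomain via its shared core anchor
#'
#' The anchor is the leftmost match of `NV[YF][YN]WFQN[RH]` (the shared
#' core of the three superclade nonapeptides). The HD span extends the
#' anchor by `up` residues upstream and `down` downstream (defaults give a
#' 66-residue domain), clipped to the sequence.
#'
#' @param seq Protein string.
#' @param up,down Extension upstream of the anchor start / downstream of
#'   the anchor end.
#' @return `NULL` when no anchor is found, else a list with `start`, `end`
#'   (0-based half-open), `anchor_start` and `clipped`.
#' @export
locate_hd <- function(seq, up = 50, down = 7) {
  core <- motif_def("HD-core", "NV[YF][YN]WFQN[RH]", kind = "anchor")
  hits <- scan_pattern(seq, core)
  if (nrow(hits) == 0) return(NULL)
  a0 <- hits$start[1]
  a1 <- hits$end[1]
  start <- a0 - up
  end <- a1 + down
  clipped <- start < 0 || end > nchar(seq)
  list(start = max(0L, start), end = min(nchar(seq), end),
       anchor_start = a0, clipped = clipped)
}

# does a hit satisfy a motif's region hint relative to the HD span?
.region_ok <- function(hit_start, hit_end, region, hd, seq_len, window = 30) {
  if (is.na(region)) return(TRUE)
  switch(region,
         "HD-internal" = TRUE,
         "upstream-of-HD" = !is.null(hd) && hit_end <= hd$start,
         "downstream-of-HD" = !is.null(hd) && hit_start >= hd$end,
         "C-terminal" = hit_start >= seq_len - window,
         TRUE)
}

#' Assign superclade and clade from the full motif library
#'
#' The superclade comes from [classify_superclade()]; the finer clade from
#' clade-labelled motif evidence whose region hints (relative to the HD
#' located by [locate_hd()]) are respected. Conflicting evidence across
#' superclades is flagged ambiguous, never silently resolved.
#'
#' @param seq Protein string.
#' @param library Motif library (list of [motif_def()]).
#' @param id Sequence id.
#' @param ear_window C-terminal window for C-terminal motifs.
#' @return A `"clade_assignment"` (see [classify_superclade()]).
#' @export
assign_clade <- function(seq, library = default_motif_library(),
                         id = NA_character_, ear_window = 30) {
  if (length(library) == 0) stop("empty motif library")
  sc <- classify_superclade(seq, library, id = id)
  hd <- locate_hd(seq)
  clade_motifs <- Filter(function(m) identical(m$kind, "clade"), library)
  ev <- sc$evidence
  found <- character(0)
  found_superclades <- character(0)
  for (m in clade_motifs) {
    hits <- scan_pattern(seq, m, id = id)
    if (nrow(hits) == 0) next
    ok <- mapply(.region_ok, hits$start, hits$end,
                 MoreArgs = list(region = m$region, hd = hd,
                                 seq_len = nchar(seq), window = ear_window))
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits) == 0) next
    ev <- rbind(ev, hits)
    found <- c(found, m$label)
    found_superclades <- c(found_superclades, .clade_superclade(m$label))
  }
  found <- unique(found)
  found_superclades <- unique(stats::na.omit(found_superclades))
  ambiguous <- sc$ambiguous
  clade <- NA_character_
  if (sc$superclade != "unclassified") {
    fs <- .clade_superclade(found)
    consistent <- found[!is.na(fs) & fs == sc$superclade]
    conflicting <- setdiff(found_superclades, sc$superclade)
    if (length(conflicting) > 0) ambiguous <- TRUE
    if (length(consistent) == 1) {
      clade <- consistent
    } else if (length(consistent) > 1) {
      ambiguous <- TRUE
    }
  }
  structure(list(id = id, superclade = sc$superclade, clade = clade,
                 ambiguous = ambiguous, evidence = ev),
            class = "clade_assignment")
}

# superclade owning each clade label
.clade_superclade <- function(label) {
  map <- c("WOX10/13/14" = "T1",
           "WOX8/9-11/12" = "T2",
           "WUS" = "T3", "WOX5/7" = "T3", "WOX2" = "T3",
           "WOX1/6" = "T3", "WOX4" = "T3", "WOX3" = "T3")
  unname(map[label])
}

#' Classify every sequence in a collection
#'
#' @param seqs Named character vector of protein sequences.
#' @param library Motif library.
#' @return data.frame: id, superclade, clade, ambiguous, evidence
#'   (semicolon-joined `motif:start-end` strings).
#' @export
classify_collection <- function(seqs, library = default_motif_library()) {
  rows <- lapply(names(seqs), function(id) {
    a <- assign_clade(seqs[[id]], library, id = id)
    ev <- if (nrow(a$evidence) > 0) {
      paste(sprintf("%s:%d-%d", a$evidence$motif, a$evidence$start,
                    a$evidence$end), collapse = ";")
    } else ""
    data.frame(id = id, superclade = a$superclade, clade = a$clade,
               ambiguous = a$ambiguous, evidence = ev)
  })
  do.call(rbind, rows)
}
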