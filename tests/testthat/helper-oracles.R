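# Independent oracles: alignment scoring by explicit enumeration or by
# cubic dynamic programming without the affine (three-state) optimisation,
# plus a loop-based replay of the occupancy filters. These deliberately
# share no code with the package implementations they check.

# score one explicit alignment (two equal-length gapped strings) under
# affine gaps: a gap run of length L costs open + L * ext
score_gapped <- function(ga, gb, submat, open, ext) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  sc <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      sc <- sc - ext - if (in_gap_a) 0 else open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      sc <- sc - ext - if (in_gap_b) 0 else open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      sc <- sc + submat[ca[k], cb[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  sc
}

# enumerate every global alignment of a and b, return the best score
enum_global <- function(a, b, submat, open, ext) {
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > nchar(a) && j > nchar(b)) {
      s <- score_gapped(ga, gb, submat, open, ext)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      rec(i + 1, j + 1, paste0(ga, substr(a, i, i)),
          paste0(gb, substr(b, j, j)))
    }
    if (i <= nchar(a)) rec(i + 1, j, paste0(ga, substr(a, i, i)),
                           paste0(gb, "-"))
    if (j <= nchar(b)) rec(i, j + 1, paste0(ga, "-"),
                           paste0(gb, substr(b, j, j)))
  }
  rec(1, 1, "", "")
  best
}

# best local score by enumerating every substring pair and every global
# alignment of each (floored at 0)
enum_local <- function(a, b, submat, open, ext) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- enum_global(substr(a, i1, i2), substr(b, j1, j2),
                       submat, open, ext)
      if (s > best) best <- s
    }
  }
  best
}

# cubic local DP: gap costs evaluated by trying every gap length, no
# three-state bookkeeping
dp_local <- function(a, b, submat, open, ext) {
  m <- nchar(a); n <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  H <- matrix(0, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    best <- H[i, j] + submat[ca[i], cb[j]]
    for (k in 1:i) best <- max(best, H[i - k + 1, j + 1] - (open + k * ext))
    for (k in 1:j) best <- max(best, H[i + 1, j - k + 1] - (open + k * ext))
    H[i + 1, j + 1] <- max(0, best)
  }
  max(H)
}

# cubic global DP, same spirit
dp_global <- function(a, b, submat, open, ext) {
  m <- nchar(a); n <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  H <- matrix(-Inf, m + 1, n + 1)
  H[1, 1] <- 0
  for (i in 0:m) for (j in 0:n) {
    if (i == 0 && j == 0) next
    best <- -Inf
    if (i > 0 && j > 0) best <- H[i, j] + submat[ca[i], cb[j]]
    if (i > 0) for (k in 1:i) {
      best <- max(best, H[i - k + 1, j + 1] - (open + k * ext))
    }
    if (j > 0) for (k in 1:j) {
      best <- max(best, H[i + 1, j - k + 1] - (open + k * ext))
    }
    H[i + 1, j + 1] <- best
  }
  H[m + 1, n + 1]
}

# loop-based replay of one column-then-sequence filter pass on a character
# matrix; returns the filtered matrix (or NULL when everything died)
replay_filter_pass <- function(mat, max_col_missing = 0.5,
                               min_seq_frac = 0.5) {
  keep_cols <- c()
  for (j in seq_len(ncol(mat))) {
    gaps <- 0
    for (i in seq_len(nrow(mat))) if (mat[i, j] == "-") gaps <- gaps + 1
    if (gaps / nrow(mat) <= max_col_missing) keep_cols <- c(keep_cols, j)
  }
  if (length(keep_cols) == 0) return(NULL)
  mat <- mat[, keep_cols, drop = FALSE]
  keep_rows <- c()
  for (i in seq_len(nrow(mat))) {
    res <- 0
    for (j in seq_len(ncol(mat))) if (mat[i, j] != "-") res <- res + 1
    if (res >= min_seq_frac * ncol(mat)) keep_rows <- c(keep_rows, i)
  }
  if (length(keep_rows) == 0) return(NULL)
  mat[keep_rows, , drop = FALSE]
}

# replay the filter loop until a pass changes nothing
replay_filter_loop <- function(mat) {
  repeat {
    nxt <- replay_filter_pass(mat)
    if (is.null(nxt)) return(NULL)
    if (identical(dim(nxt), dim(mat)) && all(nxt == mat)) return(mat)
    mat <- nxt
  }
}

# random gapped alignment as an "aln" object
rand_aln <- function(nrow, ncol, gap_prob = 0.3,
                     letters_pool = c("A", "C", "D", "E")) {
  m <- matrix(sample(c(letters_pool, "-"), nrow * ncol, replace = TRUE,
                     prob = c(rep((1 - gap_prob) / length(letters_pool),
                                  length(letters_pool)), gap_prob)),
              nrow, ncol)
  new_alignment(paste0("s", seq_len(nrow)),
                apply(m, 1, paste, collapse = ""))
}

# random protein string
rand_protein <- function(n, pool = c("A", "C", "D", "E", "F", "G", "H",
                                     "K", "L", "M")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# brute-force sliding-window scan of a consensus pattern (per-position
# character-class checks, no regex)
slide_scan <- function(seq, pattern_positions) {
  ch <- strsplit(seq, "")[[1]]
  w <- length(pattern_positions)
  hits <- integer(0)
  if (length(ch) < w) return(hits)
  for (s in 1:(length(ch) - w + 1)) {
    ok <- TRUE
    for (k in 1:w) {
      p <- pattern_positions[[k]]
      if (!(identical(p, ".") || ch[s + k - 1] %in% p)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s - 1L)  # 0-based
  }
  hits
}
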