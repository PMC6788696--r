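# Built-in aligner: global pairwise alignment, k-mer guide distances,
# neighbor-joining guide trees, and progressive profile-profile alignment.
# This is the default aligner behind curate_to_fixed_point(); any function
# satisfying the aligner contract (degapping the output recovers the input)
# can be swapped in.

#' Optimal global alignment of two sequences (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Non-empty protein strings.
#' @param scheme A [scoring_scheme()].
#' @param ids Row ids for the returned alignment.
#' @return List with `aln` (a 2-row `"aln"`) and `score`.
#' @export
global_align_pair <- function(a, b, scheme = scoring_scheme(),
                              ids = c("a", "b")) {
  stopifnot(nzchar(a), nzchar(b))
  ia <- .residue_index(a, scheme, "a")
  ib <- .residue_index(b, scheme, "b")
  S <- scheme$matrix[ia, ib, drop = FALSE]
  r <- nw_affine_cpp(S, scheme$gap_open, scheme$gap_extend)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ra <- ifelse(r$a > 0, ca[pmax(r$a, 1)], "-")
  rb <- ifelse(r$b > 0, cb[pmax(r$b, 1)], "-")
  list(aln = new_alignment(ids, c(paste(ra, collapse = ""),
                                  paste(rb, collapse = ""))),
       score = r$score)
}

# set of k-mers of a string (k shrinks for very short sequences)
.kmers <- function(s, k = 3) {
  n <- nchar(s)
  k <- min(k, n)
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Pairwise k-mer distances for guide-tree construction
#'
#' Distance `1 - shared k-mer fraction`, where the shared fraction is the
#' Sorensen-Dice overlap `|A & B| / ((|A| + |B|) / 2)` of the two k-mer
#' sets. Cheap and deterministic; used only to shape the guide tree.
#'
#' @param seqs Named character vector.
#' @param k k-mer size (default 3).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kmer_distance <- function(seqs, k = 3) {
  n <- length(seqs)
  sets <- lapply(seqs, .kmers, k = k)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      frac <- 2 * shared / (length(sets[[i]]) + length(sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - frac
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin validated wrapper around [ape::nj()]. On additive distance
#' matrices the reconstructed topology matches the generating tree.
#'
#' @param d Symmetric numeric matrix with zero diagonal, row/column names,
#'   and at least 3 labels.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d))
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 labels")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  ape::nj(as.dist(d))
}

#' Root a tree on the branch separating an outgroup from the ingroup
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Character vector of leaf labels forming the outgroup.
#' @return A rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing) > 0) {
    stop("outgroup labels absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(outgroup) >= length(tree$tip.label)) {
    stop("outgroup cannot include every leaf")
  }
  tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
           error = function(e) {
             stop("outgroup {", paste(outgroup, collapse = ", "),
                  "} is not monophyletic in the tree: ",
                  conditionMessage(e), call. = FALSE)
           })
}

# column residue-frequency profile of an alignment (alphabet x columns);
# gap characters contribute zero mass
.profile <- function(aln, alphabet) {
  m <- alignment_matrix(aln)
  L <- ncol(m)
  f <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (a in alphabet) f[a, ] <- colSums(m == a)
  f / nrow(m)
}

# merge two alignments by profile-profile global alignment
.profile_merge <- function(A, B, scheme) {
  alphabet <- rownames(scheme$matrix)
  fa <- .profile(A, alphabet)
  fb <- .profile(B, alphabet)
  S <- t(fa) %*% scheme$matrix %*% fb
  r <- nw_affine_cpp(S, scheme$gap_open, scheme$gap_extend)
  expand <- function(aln, path) {
    m <- alignment_matrix(aln)
    out <- matrix("-", nrow(m), length(path))
    nz <- path > 0
    out[, nz] <- m[, path[nz], drop = FALSE]
    new_alignment(aln$ids, apply(out, 1, paste, collapse = ""))
  }
  ea <- expand(A, r$a)
  eb <- expand(B, r$b)
  new_alignment(c(ea$ids, eb$ids), c(ea$seqs, eb$seqs))
}

#' Progressive multiple alignment along a neighbor-joining guide tree
#'
#' Guide tree from [kmer_distance()] via [nj_tree()] (rooted arbitrarily at
#' the first label); leaf alignments are merged to the root by
#' profile-profile global alignment with affine gaps. Output rows follow
#' the input order and degap exactly back to the input sequences.
#'
#' @param seqs Named character vector (>= 1 sequence).
#' @param scheme A [scoring_scheme()].
#' @return An `"aln"` object.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) return(new_alignment(names(seqs), seqs))
  single <- function(id) new_alignment(id, seqs[[id]])
  if (length(seqs) == 2) {
    merged <- .profile_merge(single(names(seqs)[1]), single(names(seqs)[2]),
                             scheme)
  } else {
    d <- kmer_distance(seqs)
    tr <- nj_tree(d)
    tr <- ape::root(tr, outgroup = names(seqs)[1], resolve.root = TRUE)
    children <- split(tr$edge[, 2], tr$edge[, 1])
    ntip <- length(tr$tip.label)
    build <- function(node) {
      if (node <= ntip) return(single(tr$tip.label[node]))
      subs <- lapply(children[[as.character(node)]], build)
      Reduce(function(A, B) .profile_merge(A, B, scheme), subs)
    }
    merged <- build(ntip + 1L)
  }
  new_alignment(names(seqs), merged$seqs[names(seqs)])
}
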