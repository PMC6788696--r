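# Seeded synthetic-data generator. Every generated entity carries exactly
# one truth record, so each pipeline stage can be validated against
# planted ground truth: clade-structured protein families with diagnostic
# motifs on a shared core, fragmentary transcript-like sequences, gene
# neighborhoods with planted shared-homolog blocks, and promoters with
# planted (including overlapping) cis-element instances.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' three superclades of 20 members each on a 300-residue core evolved
#' along a fixed balanced 8-leaf tree at 5% substitutions per site per
#' edge (planted motif spans held invariant); transcript fragments of
#' 125-145 residues (under half the core, so occupancy curation removes
#' them); syntenic blocks sharing 6 genes (positives) or 3 (negatives)
#' in 41-gene windows; 1.5 kb promoters with 0-3 planted instances per
#' cis element plus deliberate overlapping pairs.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_per_clade Members per superclade.
#' @param core_length Length of the family core (fixed layout of 300).
#' @param rate Per-site, per-tree-edge substitution probability.
#' @param fragment_frac Fraction of members replaced by fragments.
#' @param fragment_range Fragment length range (residues).
#' @param n_pos,n_neg Planted positive / negative synteny anchors.
#' @param shared_pos,shared_neg Homologous genes shared by positive /
#'   negative blocks.
#' @param proxy_frac Fraction of positive anchors whose own homolog is
#'   deleted from the target (planted syntenic proxies).
#' @param block_size Genes per planted target block.
#' @param n_promoters Promoters to simulate.
#' @param promoter_length Promoter length in bp.
#' @param max_instances Maximum planted instances per promoter per motif.
#' @param overlap_frac Fraction of promoters given an overlapping
#'   B-ARR site pair.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(seed = 42L, n_per_clade = 20L, core_length = 300L,
                       rate = 0.05, fragment_frac = 0.3,
                       fragment_range = c(125L, 145L),
                       n_pos = 10L, n_neg = 10L,
                       shared_pos = 6L, shared_neg = 3L,
                       proxy_frac = 0.2, block_size = 10L,
                       n_promoters = 20L, promoter_length = 1500L,
                       max_instances = 3L, overlap_frac = 0.3) {
  stopifnot(fragment_frac >= 0, fragment_frac <= 1,
            proxy_frac >= 0, proxy_frac <= 1,
            shared_pos > shared_neg, block_size >= shared_pos,
            fragment_range[1] <= fragment_range[2],
            core_length == 300L)
  structure(as.list(environment()), class = "sim_config")
}

# fixed sequence layout of the simulated family core (0-based spans,
# half-open); anchored on a 66-residue HD at [60, 126)
.sim_layout <- function() {
  list(total = 300L,
       hd = c(60L, 126L),
       anchor = c(110L, 119L),           # superclade nonapeptide slot
       t1_motif = c(15L, 24L),           # upstream of HD
       t2_motif = c(136L, 148L),         # downstream of HD
       wus_box = c(131L, 137L),          # downstream of HD
       ear = c(288L, 294L))              # C-terminal window
}

# clade plants: label -> list of (span, text) drawn from the shipped library
.sim_plants <- function(clade, ear_variant = c("WUS", "WOX5/7")) {
  lay <- .sim_layout()
  ear_variant <- match.arg(ear_variant)
  switch(clade,
         T1 = list(anchor = list(span = lay$anchor, text = "NVYNWFQNR"),
                   clade = list(span = lay$t1_motif, text = "WSQNAHLPG")),
         T2 = list(anchor = list(span = lay$anchor, text = "NVFYWFQNR"),
                   clade = list(span = lay$t2_motif, text = "VFINGQWPESLQ")),
         T3 = list(anchor = list(span = lay$anchor, text = "NVFYWFQNH"),
                   wus_box = list(span = lay$wus_box, text = "TLELFP"),
                   ear = list(span = lay$ear,
                              text = if (ear_variant == "WUS") "LELSLN"
                                     else "LDLRLS")),
         stop("unknown clade: ", clade))
}

# overwrite planted texts onto a character vector of residues
.apply_plants <- function(ch, plants) {
  for (p in plants) {
    idx <- (p$span[1] + 1L):p$span[2]
    ch[idx] <- strsplit(p$text, "", fixed = TRUE)[[1]]
  }
  ch
}

# per-site substitution on unmasked positions
.mutate <- function(ch, rate, mask) {
  if (rate <= 0) return(ch)
  hit <- which(runif(length(ch)) < rate & !mask)
  for (i in hit) {
    ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  }
  ch
}

#' Simulate a clade-structured protein family with planted motifs
#'
#' A shared ancestral core is drawn once, clade-diagnostic motifs (HD
#' signature nonapeptide plus clade motifs from the shipped library) are
#' planted at fixed positions, and each clade's template is evolved along
#' a balanced 8-leaf tree by per-site substitution with planted spans held
#' invariant. Members are assigned to leaves cyclically and receive one
#' additional private round of substitutions. T3 members alternate
#' between WUS-type and WOX5/7-type EAR variants.
#'
#' @param cfg A [sim_config()].
#' @return List with `seqs` (named character vector) and `truth`
#'   (data.frame: id, superclade, clade, leaf, fragment, planted spans).
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_per_clade < 1) stop("clade member count must be >= 1")
  set.seed(cfg$seed)
  lay <- .sim_layout()
  # ancestral background, redrawn until free of the HD core anchor and of
  # every library pattern, so planted motifs are the only diagnostic signal
  guard <- c("NV[YF][YN]WFQN[RH]", "WSQNAHLPG", "VFINGQWPESLQ", "TL.LFP",
             "L[DE]LRLS", "L[DE]L[ST]LN")
  repeat {
    bg <- sample(AA20, lay$total, replace = TRUE)
    s <- paste(bg, collapse = "")
    if (!any(vapply(guard, function(g) grepl(g, s), logical(1)))) break
  }
  clades <- c("T1", "T2", "T3")
  seqs <- character(0)
  truth <- list()
  for (cl in clades) {
    for (i in seq_len(cfg$n_per_clade)) {
      ear <- if (i %% 2 == 1) "WUS" else "WOX5/7"
      plants <- .sim_plants(cl, ear)
      mask <- rep(FALSE, lay$total)
      for (p in plants) mask[(p$span[1] + 1L):p$span[2]] <- TRUE
      template <- .apply_plants(bg, plants)
      # evolve along the root-to-leaf path of the balanced 8-leaf tree
      # (depth 3) plus one private terminal round
      leaf <- (i - 1L) %% 8L + 1L
      ch <- template
      for (e in 1:4) ch <- .mutate(ch, cfg$rate, mask)
      id <- sprintf("%s_%02d", cl, i)
      seqs[id] <- paste(ch, collapse = "")
      spans <- paste(vapply(plants, function(p) {
        sprintf("%d-%d", p$span[1], p$span[2])
      }, character(1)), collapse = ";")
      truth[[id]] <- data.frame(
        id = id, superclade = cl,
        clade = switch(cl, T1 = "WOX10/13/14", T2 = "WOX8/9-11/12",
                       T3 = if (ear == "WUS") "WUS" else "WOX5/7"),
        leaf = leaf, fragment = FALSE, planted_spans = spans)
    }
  }
  list(seqs = seqs, truth = do.call(rbind, truth))
}

#' Replace a fraction of sequences by contiguous fragments
#'
#' Emulates fragmentary transcriptome-derived sequences: a random fraction
#' of members is replaced by contiguous subsequences with lengths drawn
#' from `cfg$fragment_range`, and flagged in the truth table.
#'
#' @param seqs Named character vector (from [simulate_family()]).
#' @param truth Matching truth data.frame.
#' @param cfg A [sim_config()].
#' @return List with `seqs` and updated `truth` (fragment flags and
#'   fragment lengths).
#' @export
fragment_transcripts <- function(seqs, truth, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  n_frag <- floor(cfg$fragment_frac * length(seqs))
  truth$frag_len <- NA_integer_
  if (n_frag == 0) return(list(seqs = seqs, truth = truth))
  pick <- sample(names(seqs), n_frag)
  for (id in pick) {
    L <- nchar(seqs[[id]])
    fl <- sample(cfg$fragment_range[1]:cfg$fragment_range[2], 1)
    start <- sample(1:(L - fl + 1), 1)
    seqs[id] <- substr(seqs[[id]], start, start + fl - 1L)
    truth$fragment[truth$id == id] <- TRUE
    truth$frag_len[truth$id == id] <- fl
  }
  list(seqs = seqs, truth = truth)
}

#' Simulate a pair of gene orders with planted syntenic blocks
#'
#' The query contig carries evenly spaced anchors; for each, a block of
#' homologous partner genes is planted on the target contig. Positive
#' anchors share `shared_pos` genes with their block (at least one more
#' than the calling threshold), negatives share `shared_neg` (below it).
#' For a fraction of positives the anchor's own homolog is deleted,
#' planting a syntenic proxy. Background genes have no homologs.
#'
#' @param cfg A [sim_config()].
#' @return List with `query`, `target` ([gene_order()] objects),
#'   `homology` ([homology_map()]) and `truth` (data.frame: anchor, type,
#'   shared, proxy).
#' @export
simulate_neighborhoods <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  n_anchor <- cfg$n_pos + cfg$n_neg
  spacing <- 50L
  if (cfg$block_size > spacing - 10L) stop("block size exceeds contig spacing")
  q_len <- spacing * n_anchor + spacing
  q_genes <- sprintf("q%05d", seq_len(q_len))
  t_len <- spacing * n_anchor + spacing
  t_genes <- sprintf("t%05d", seq_len(t_len))
  types <- sample(c(rep("positive", cfg$n_pos), rep("negative", cfg$n_neg)))
  pairs <- list()
  truth <- list()
  for (a in seq_len(n_anchor)) {
    anchor_rank <- (a - 1L) * spacing + 25L           # 0-based rank
    anchor <- q_genes[anchor_rank + 1L]
    type <- types[a]
    k <- if (type == "positive") cfg$shared_pos else cfg$shared_neg
    proxy <- type == "positive" && runif(1) < cfg$proxy_frac
    # shared genes drawn from the anchor's 41-gene window
    win <- q_genes[(anchor_rank - 20L):(anchor_rank + 20L) + 1L]
    pool <- if (proxy) setdiff(win, anchor) else win
    shared <- c(if (!proxy) anchor,
                sample(setdiff(pool, anchor), k - as.integer(!proxy)))
    # partner block on the target contig: k partners inside a block of
    # block_size consecutive target genes
    block_start <- (a - 1L) * spacing + 20L
    block_ranks <- block_start + seq_len(cfg$block_size) - 1L
    partner_ranks <- sort(sample(block_ranks, k))
    partners <- t_genes[partner_ranks + 1L]
    pairs[[a]] <- data.frame(a = shared, b = partners)
    truth[[a]] <- data.frame(anchor = anchor, type = type, shared = k,
                             proxy = proxy)
  }
  list(query = gene_order(list(chrQ = q_genes)),
       target = gene_order(list(chrT = t_genes)),
       homology = homology_map(do.call(rbind, pairs)),
       truth = do.call(rbind, truth))
}

# forward-strand IUPAC regexes whose absence guarantees a motif cannot hit
# on either strand
.cis_guard_patterns <- function(motifs) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  to_rx <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(ch) {
      set <- iupac[[ch]]
      if (nchar(set) == 1) set else paste0("[", set, "]")
    }, character(1)), collapse = "")
  }
  unlist(lapply(motifs, function(m) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub(".", "N", m$pattern, fixed = TRUE))))
    c(to_rx(gsub(".", "N", m$pattern, fixed = TRUE)), to_rx(rc))
  }))
}

#' Simulate promoters with planted cis-element instances
#'
#' Backgrounds are rejection-sampled so that the only motif matches (on
#' either strand) are the planted ones, making the truth exact. Per
#' promoter and motif, 0 to `max_instances` disjoint instances are
#' planted; a fraction of promoters additionally receives an overlapping
#' B-ARR site pair (a palindromic GATC-core template yielding two
#' strand-twin hits that collapse to one cluster under
#' [count_once()]).
#'
#' @param cfg A [sim_config()].
#' @param motifs Cis-element library; default [default_cis_library()].
#' @return List with `regions` (data.frame: gene, seq) and `truth`
#'   (data.frame: gene, motif, planted_raw, planted_clusters).
#' @export
simulate_promoters <- function(cfg = sim_config(),
                               motifs = default_cis_library()) {
  set.seed(cfg$seed + 3L)
  plant_text <- list("AuxRE" = "TGTCTC", "B-ARR" = "AGATT")
  overlap_text <- "AGATCC"   # two overlapping B-ARR hits (+/-), one cluster
  guards <- .cis_guard_patterns(motifs)
  L <- cfg$promoter_length
  slot <- 30L
  n_slots <- L %/% slot
  regions <- list()
  truth <- list()
  for (g in seq_len(cfg$n_promoters)) {
    gene <- sprintf("gene%03d", g)
    counts <- setNames(sample(0:cfg$max_instances,
                              length(motifs), replace = TRUE),
                       vapply(motifs, `[[`, character(1), "name"))
    overlap <- runif(1) < cfg$overlap_frac
    # assign disjoint slots to all plants
    n_plants <- sum(counts) + as.integer(overlap)
    slots <- sample(n_slots, n_plants)
    plants <- list()
    si <- 1L
    for (m in names(counts)) {
      for (j in seq_len(counts[[m]])) {
        pos <- (slots[si] - 1L) * slot + 5L   # 0-based start
        plants[[length(plants) + 1L]] <-
          list(motif = m, start = pos, text = plant_text[[m]], clusters = 1L,
               raw = 1L)
        si <- si + 1L
      }
    }
    if (overlap) {
      pos <- (slots[si] - 1L) * slot + 5L
      plants[[length(plants) + 1L]] <-
        list(motif = "B-ARR", start = pos, text = overlap_text,
             clusters = 1L, raw = 2L)
    }
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mask <- rep(FALSE, L)
    for (p in plants) {
      idx <- p$start + seq_len(nchar(p$text))
      ch[idx] <- strsplit(p$text, "", fixed = TRUE)[[1]]
      mask[idx] <- TRUE
    }
    # rejection clean-up: redraw background positions involved in any
    # unplanned guard-pattern match until only planted matches remain
    expected <- lapply(plants, function(p) {
      c(p$start, p$start + nchar(p$text))
    })
    for (iter in 1:200) {
      s <- paste(ch, collapse = "")
      dirty <- integer(0)
      for (rx in guards) {
        m <- gregexpr(sprintf("(?=%s)", rx), s, perl = TRUE)[[1]]
        if (m[1] == -1) next
        w <- nchar(gsub("\\[[^]]*\\]", "N", rx))
        for (st in as.integer(m)) {
          span <- c(st - 1L, st - 1L + w)
          inside <- any(vapply(expected, function(e) {
            span[1] >= e[1] && span[2] <= e[2]
          }, logical(1)))
          if (!inside) {
            idx <- (span[1] + 1L):span[2]
            dirty <- c(dirty, idx[!mask[idx]])
          }
        }
      }
      if (length(dirty) == 0) break
      dirty <- unique(dirty)
      ch[dirty] <- sample(c("A", "C", "G", "T"), length(dirty),
                          replace = TRUE)
      if (iter == 200) stop("promoter background failed to converge")
    }
    regions[[g]] <- data.frame(gene = gene, seq = paste(ch, collapse = ""))
    for (m in names(counts)) {
      p_m <- Filter(function(p) p$motif == m, plants)
      truth[[length(truth) + 1L]] <- data.frame(
        gene = gene, motif = m,
        planted_raw = sum(vapply(p_m, `[[`, integer(1), "raw")),
        planted_clusters = sum(vapply(p_m, `[[`, integer(1), "clusters")))
    }
  }
  list(regions = do.call(rbind, regions), truth = do.call(rbind, truth))
}
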