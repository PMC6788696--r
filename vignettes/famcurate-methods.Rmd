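---
title: "Methods: curation, classification, synteny and promoter scanning in famcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, classification, synteny and promoter scanning in famcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcurate)
```

famcurate packages the bespoke computational stages of a large-scale
gene-family phylogenomic survey — the kind that assembles a
transcription-factor family such as WUSCHEL-RELATED HOMEOBOX (WOX) from
hundreds of genomes and transcriptomes — as tested, reusable functions.
This vignette explains each method, its assumptions, the tunable
parameters, and what the synthetic validation does and does not show.

## Homolog retrieval

`search_homologs()` performs all-vs-all Smith–Waterman local alignment
with affine gaps (a gap of length $L$ costs $o + L \cdot e$) and
converts raw scores $S$ to Karlin–Altschul E-values

$$E = K \, m \, n \, e^{-\lambda S},$$

with $m$ the query length and $n$ the total residue count of the
database. Hits with $E \le$ the cutoff (default $10^{-5}$, inclusive)
are reported, one best-scoring alignment per query–subject pair. The
defaults are BLOSUM62 with gap open 11 / extend 1 and the standard
ungapped parameters $\lambda = 0.3176$, $K = 0.134$; these are exposed
in `scoring_scheme()` rather than estimated on the fly, because at desk
scale determinism matters more than statistical refinement. This stage
is retrieval, not statistics: no sum-score corrections, no heuristic
seeding. CDS databases are translated in frame 1 with the standard
genetic code (stops rendered `*`, unresolvable ambiguous codons `X`).

The alignment kernels (local and global) are implemented once in C++
over a precomputed position-score matrix, which lets the same dynamic
program serve pairwise alignment (substitution lookups) and
profile–profile alignment (expected-score products) identically. Tests
verify the kernels against explicit enumeration of all alignments on
short strings, against a cubic dynamic program that tries every gap
length (no three-state bookkeeping), and against an independent
library implementation on random protein pairs.

## Iterative alignment curation

The curation algorithm is a fixed-point iteration. Starting from
sequences that pass an inclusive length prefilter (defaults 120–971
residues), each iteration:

1. aligns the current, degapped sequence set;
2. removes aligned columns whose gap fraction **strictly exceeds** 0.5
   (a column with exactly half gaps survives; `X` counts as present,
   since fragmentary transcript evidence manifests as gaps, not
   ambiguity codes);
3. removes sequences whose residue count is **strictly below** half of
   the *column-filtered* alignment length (exactly half survives).

The loop stops when an iteration removes no sequences (converged) or at
`max_iter` (default 20, with an explicit non-convergence flag rather
than a silent stop). Two readings of the procedure were genuinely open
and are resolved as declared package decisions: each iteration realigns
the surviving set from scratch (the alternative — merely re-trimming the
previous alignment — never re-opens columns that earlier removals have
changed), and criterion (2) measures coverage against the
post-column-filter length (the criteria are described as sequential, so
the sequence rule sees the column-filtered matrix). A converged result
is, by construction, a fixed point: one further pass of both filters
removes nothing, and the tests verify this on a thousand random
alignments against an independently coded replay of the loop.

The aligner is a contract, not an implementation detail: any function
mapping named sequences to an alignment whose degapped rows equal its
input can be passed to `curate_to_fixed_point()`. The built-in default
is a progressive aligner: 3-mer Sørensen–Dice distances
(`kmer_distance()`), a neighbor-joining guide tree (`nj_tree()`, via
ape), and leaf-to-root profile–profile merges under the same affine
scheme. It is deliberately simple — deterministic, dependency-free, and
adequate for families sharing a conserved core — and is not a substitute
for a production MSA tool on deeply divergent data.

## Superclade and clade classification

Classification replaces de novo motif discovery with scanning a curated
signature library (`inst/extdata/wox_motifs.yaml`, editable YAML). The
three superclades are diagnosed by exact homeodomain nonapeptides —
NVYNWFQNR (T1), NVFYWFQNR (T2), NVFYWFQNH (T3) — scanned with exact
character-class semantics: these peptides are presented in the
literature as exact diagnostics, so no mismatch tolerance is applied by
default. The homeodomain itself is located from the shared core
`NV[YF][YN]WFQN[RH]` and extended 50 residues upstream and 7 downstream
(a 66-residue domain; the exact placement of the domain boundary
relative to the anchor is not established, so the offsets are
configuration, not fact). Finer clades come from additional motifs with
region hints — upstream of the HD (T1 clade motif), downstream (T2
motif, WUS-box), or within the last 30 residues (EAR variants
L[DE]LRLS for WOX5/7 versus L[DE]L[ST]LN for WUS; the C-terminal window
is a declared, testable stand-in for "carboxy-terminal").

Ambiguity is surfaced, never resolved. Two distinct HD signatures yield
`unclassified` with `ambiguous = TRUE`; the T2 signature co-occurring
with a WUS-box keeps the T2 superclade call but flags it, because the
intermediate-clade nonapeptide demonstrably occurs in modern-clade
proteins. Clade motifs pointing outside the called superclade likewise
flag the assignment. Classification is deterministic and independent of
library listing order.

Motifs whose consensus is only depicted graphically in the source
survey (the T1WOX, T2WOX, WOX2, WOX1/6 and WOX4 clade motifs, and the
exact WUS-box string) ship as clearly flagged *synthetic placeholder*
patterns; the WUS-box uses the literature consensus core `TL.LFP`. The
simulator plants exactly these placeholder patterns, which keeps
end-to-end clade recovery well defined while making no claim that the
placeholders match the real family's consensus.

## Microsynteny

`find_syntenic_regions()` scores 41-gene windows (anchor ± 20, truncated
as-is at contig ends, no normalisation). The syntenic score counts
target-window genes having at least one homolog in the query window —
counting unique target genes rather than homologous pairs prevents
paralog inflation. A window with score ≥ 4 is syntenic; a syntenic
window lacking a homolog of the anchor itself is a syntenic proxy (the
anchor's copy was lost there). Candidate windows are centred on target
genes homologous to any query-window gene; overlapping candidates are
merged keeping the best score, since a region, not every possible
centre, is the meaningful unit of report. One caveat follows from the
unique-target counting rule: the score is bounded by the target window
size, and by the smaller of the two windows only when homology is
one-to-one.

## Promoter cis-elements

`extract_upstream()` takes the 1.5 kb upstream of each TSS, strand
aware: `[p-1500, p-1]` on the plus strand, `[p+1, p+1500]`
reverse-complemented on the minus strand, clipped and flagged at contig
bounds, so the returned sequence always reads in promoter orientation.
Scanning covers both strands of the promoter (a reverse-complement twin
at the same footprint would otherwise double-count near-palindromic
elements), and `count_once()` merges hits of the same motif whose spans
share at least one position, strand-agnostically, before counting — the
most conservative reading of "overlapping sites counted once". The
shipped cis library holds canonical consensus placeholders (AuxRE core
`TGTCTC`; B-ARR core `RGATY`): the survey's original position-weight
matrices are external database content and are not redistributed, so
real-data presence calls from that survey are not reproducible here and
are not claimed.

## The synthetic generator and what passing tests show

`simulate_family()` draws a 300-residue ancestral core (rejection
sampled to be free of every library pattern), plants each clade's
signature and clade motifs at fixed positions, and evolves the clade
template along a fixed balanced 8-leaf tree by per-site random
substitution at the configured rate (default 5% per site per edge) with
planted spans masked; each member then receives one private round of
substitutions. The defaults — 3 × 20 members, 30% fragmented to 125–145
residues — define the study conditions used by the tests, the analysis
scripts and the acceptance script. Because the synthetic core is 300
residues, those runs scale the curation prefilter to `min_len = 30` so
that fragments reach the alignment stage and are removed by the
occupancy rule (the behaviour under test) rather than by the length
prefilter; with real survey data the 120–971 defaults apply.

`simulate_neighborhoods()` plants homolog blocks sharing 6 genes
(positives) or 3 (negatives) inside otherwise homolog-free gene orders,
deleting the anchor's partner in a fraction of positives to plant
proxies. `simulate_promoters()` rejection-samples background sequence
until the only motif matches on either strand are the planted ones, so
raw and deduplicated counts have exact expected values; overlapping
pairs use a palindromic GATC-core template whose plus- and minus-strand
hits share a footprint.

The generator emulates the *statistical structure* the methods assume —
diagnostic motifs on a conserved core, fragments shorter than half the
core, blocks above/below the synteny threshold, motif-free promoter
background. It does not emulate indels outside fragmentation, empirical
substitution processes, paralog-rich homology, or promoters whose
background resembles real nucleotide composition. Passing tests
therefore demonstrate that the algorithms implement their stated rules
exactly and recover planted truth under those conditions; they do not
certify performance on real, messier data.

## Numerical and procedural choices

* Problem sizes: invariant and replay checks run on 1,000 random
  alignments up to 12 × 30; alignment kernels are checked exhaustively
  against enumeration for all string pairs of lengths ≤ 3 over a
  4-letter alphabet and on seeded samples of longer pairs (enumeration
  to length 4, cubic DP to length 6); classification on 20 seeded
   60-member families per noise level; synteny on 100 planted anchors
  per class; promoters on 500 seeded draws.
* Ties in the guide-tree and window-merge steps are broken
  deterministically (ape's neighbor joining; lowest window start).
* Degenerate curation (all columns or all rows removed) raises an error
  naming the iteration rather than returning an empty object.
* PHYLIP I/O accepts strict (10-character) and relaxed names and both
  `-` and `.` gaps on read, and writes relaxed sequential with `-`;
  write-then-read is exact identity, which the deposited-alignment
  checks rely on.
* All generators take a single integer seed; identical seeds give
  byte-identical outputs.

## Known limitations

The progressive aligner has no iterative refinement and will underalign
highly divergent regions; the E-value parameters are ungapped constants
rather than estimated for the gapped scheme; clade placeholders are
synthetic; synteny scoring is window-based and order-insensitive (no
collinearity chaining); and the deposited-alignment acceptance checks
require the original supplementary files, which are not redistributed
with the package.
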