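#!/usr/bin/env Rscript
# Stage 3: classify the curated members into superclades and clades by
# their planted peptide signatures, and score recovery against truth.

suppressPackageStartupMessages(library(famcurate))

aln <- read_phylip("results/curated.phy")
truth <- read.delim("results/synthetic/family_truth.tsv")
seqs <- degap(aln)

assignments <- classify_collection(seqs, default_motif_library())
write.table(assignments, "results/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- truth[match(assignments$id, truth$id), ]
cat(sprintf("superclade recovery: %.1f%% (%d sequences)\n",
            100 * mean(assignments$superclade == tr$superclade),
            nrow(assignments)))
cat(sprintf("clade recovery:      %.1f%%\n",
            100 * mean(assignments$clade == tr$clade, na.rm = TRUE)))
cat(sprintf("flagged ambiguous:   %d\n", sum(assignments$ambiguous)))
print(table(truth = tr$superclade, called = assignments$superclade))
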