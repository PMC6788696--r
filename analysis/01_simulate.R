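#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# One seeded draw defines the conditions used by every later stage: a
# three-superclade protein family of 60 members (planted HD signatures and
# clade motifs on a shared 300-residue core, 5% per-site substitution,
# 30% of members fragmented to 125-145 residues), a pair of gene orders
# with planted syntenic blocks, and 1.5 kb promoters with planted
# cis-element instances (including overlapping pairs).

suppressPackageStartupMessages(library(famcurate))

seed <- 42L
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)

fam <- simulate_family(cfg)
fr <- fragment_transcripts(fam$seqs, fam$truth, cfg)
write_fasta(fr$seqs, "results/synthetic/family.fasta")
write.table(fr$truth, "results/synthetic/family_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("family: %d members (%d fragmented), %d superclades\n",
            length(fr$seqs), sum(fr$truth$fragment),
            length(unique(fr$truth$superclade))))

nb <- simulate_neighborhoods(cfg)
write.table(data.frame(contig = "chrQ", gene = nb$query$contigs$chrQ),
            "results/synthetic/query_order.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(contig = "chrT", gene = nb$target$contigs$chrT),
            "results/synthetic/target_order.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(nb$truth, "results/synthetic/synteny_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pairs <- do.call(rbind, lapply(ls(nb$homology$env), function(g) {
  data.frame(a = g, b = homologs(nb$homology, g))
}))
pairs <- pairs[pairs$a < pairs$b, ]
write.table(pairs, "results/synthetic/homology_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("neighborhoods: %d anchors (%d positive, %d proxies planted)\n",
            nrow(nb$truth), sum(nb$truth$type == "positive"),
            sum(nb$truth$proxy)))

pr <- simulate_promoters(cfg)
write.table(pr$regions, "results/synthetic/promoters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pr$truth, "results/synthetic/promoter_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("promoters: %d x %d bp, %d planted site clusters\n",
            nrow(pr$regions), cfg$promoter_length,
            sum(pr$truth$planted_clusters)))
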