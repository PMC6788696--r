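test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 71)
  f1 <- simulate_family(cfg); f2 <- simulate_family(cfg)
  expect_identical(f1, f2)
  n1 <- simulate_neighborhoods(cfg); n2 <- simulate_neighborhoods(cfg)
  expect_identical(n1$truth, n2$truth)
  expect_identical(n1$query, n2$query)
  p1 <- simulate_promoters(cfg); p2 <- simulate_promoters(cfg)
  expect_identical(p1, p2)
  # a different seed changes the draw
  expect_false(identical(simulate_family(sim_config(seed = 72))$seqs,
                         f1$seqs))
})

test_that("family truth records are complete and plants are by construction", {
  cfg <- sim_config(seed = 73, n_per_clade = 10, rate = 0.08)
  fam <- simulate_family(cfg)
  expect_equal(nrow(fam$truth), length(fam$seqs))
  expect_identical(sort(fam$truth$id), sort(names(fam$seqs)))
  expect_equal(anyDuplicated(fam$truth$id), 0L)
  # every member carries its planted signature despite heavy noise
  sig <- c(T1 = "NVYNWFQNR", T2 = "NVFYWFQNR", T3 = "NVFYWFQNH")
  for (i in seq_len(nrow(fam$truth))) {
    expect_true(grepl(sig[[fam$truth$superclade[i]]],
                      fam$seqs[[fam$truth$id[i]]], fixed = TRUE))
  }
  # T3 members carry the EAR variant their clade label promises
  t3 <- fam$truth[fam$truth$superclade == "T3", ]
  for (i in seq_len(nrow(t3))) {
    pat <- if (t3$clade[i] == "WUS") "LELSLN" else "LDLRLS"
    expect_true(grepl(pat, fam$seqs[[t3$id[i]]], fixed = TRUE))
  }
})

test_that("zero substitution rate makes clade members identical", {
  fam <- simulate_family(sim_config(seed = 79, rate = 0, n_per_clade = 6))
  for (cl in c("T1", "T2", "T3")) {
    ids <- fam$truth$id[fam$truth$superclade == cl]
    seqs <- fam$seqs[ids]
    # T3 alternates EAR variants, so compare within variant
    grp <- fam$truth$clade[match(ids, fam$truth$id)]
    for (g in unique(grp)) {
      expect_equal(length(unique(seqs[grp == g])), 1, info = paste(cl, g))
    }
  }
})

test_that("fragmentation respects the fraction and length range", {
  cfg <- sim_config(seed = 83, fragment_frac = 0.4)
  fam <- simulate_family(cfg)
  fr <- fragment_transcripts(fam$seqs, fam$truth, cfg)
  n_frag <- sum(fr$truth$fragment)
  expect_equal(n_frag, floor(0.4 * length(fam$seqs)))
  fl <- nchar(fr$seqs[fr$truth$id[fr$truth$fragment]])
  expect_true(all(fl >= cfg$fragment_range[1] & fl <= cfg$fragment_range[2]))
  # fragments are contiguous substrings of the originals
  for (id in fr$truth$id[fr$truth$fragment]) {
    expect_true(grepl(fr$seqs[[id]], fam$seqs[[id]], fixed = TRUE))
  }
  # zero fraction is the identity
  none <- fragment_transcripts(fam$seqs, fam$truth,
                               sim_config(seed = 83, fragment_frac = 0))
  expect_identical(none$seqs, fam$seqs)
})

test_that("neighborhood truth separates positives from negatives by design", {
  cfg <- sim_config(seed = 89)
  nb <- simulate_neighborhoods(cfg)
  expect_equal(sum(nb$truth$type == "positive"), cfg$n_pos)
  expect_equal(sum(nb$truth$type == "negative"), cfg$n_neg)
  expect_true(all(nb$truth$shared[nb$truth$type == "positive"] ==
                    cfg$shared_pos))
  expect_true(all(nb$truth$shared[nb$truth$type == "negative"] ==
                    cfg$shared_neg))
  expect_false(any(nb$truth$proxy[nb$truth$type == "negative"]))
  # proxy anchors have no homolog anywhere in the target
  for (a in nb$truth$anchor[nb$truth$proxy]) {
    expect_length(homologs(nb$homology, a), 0)
  }
})

test_that("promoter truth is exact: raw scan counts equal planted counts", {
  cfg <- sim_config(seed = 97, n_promoters = 10)
  pr <- simulate_promoters(cfg)
  expect_equal(nrow(pr$truth),
               cfg$n_promoters * length(default_cis_library()))
  for (m in default_cis_library()) {
    for (g in unique(pr$regions$gene)) {
      hits <- scan_dna_motif(pr$regions$seq[pr$regions$gene == g], m, id = g)
      tr <- pr$truth[pr$truth$gene == g & pr$truth$motif == m$name, ]
      expect_equal(nrow(hits), tr$planted_raw, info = paste(g, m$name))
      expect_equal(count_once(hits), tr$planted_clusters,
                   info = paste(g, m$name))
    }
  }
})
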