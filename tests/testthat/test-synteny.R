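test_that("window extraction truncates at contig ends", {
  genes <- sprintf("g%03d", 1:101)
  go <- gene_order(list(c1 = genes))
  expect_length(extract_window(go, "g051"), 41)      # rank 50, full window
  expect_length(extract_window(go, "g001"), 21)      # truncated upstream
  expect_length(extract_window(go, "g101"), 21)      # truncated downstream
  expect_identical(extract_window(gene_order(list(c1 = "solo")), "solo"),
                   "solo")
  expect_error(extract_window(go, "nope"), "unknown anchor")
  expect_error(gene_order(list(a = c("x", "y"), b = "x")), "more than one")
})

test_that("syntenic scores count unique target genes with query homologs", {
  q <- paste0("q", 1:8)
  t <- paste0("t", 1:8)
  hom <- homology_map(data.frame(a = q[1:4], b = t[1:4]))
  expect_equal(syntenic_score(q, t, hom), 4)
  expect_equal(syntenic_score(q, t, homology_map(data.frame(a = "x", b = "y"))),
               0)
  # a target gene with several query homologs still counts once
  multi <- homology_map(data.frame(a = c("q1", "q2", "q3"),
                                   b = c("t1", "t1", "t1")))
  expect_equal(syntenic_score(q, t, multi), 1)
  # homolog-for-homolog mirror: score equals the window size
  mirror <- homology_map(data.frame(a = q, b = t))
  expect_equal(syntenic_score(q, t, mirror), 8)
  expect_error(homology_map(data.frame(a = "g", b = "g")), "irreflexive")
})

test_that("syntenic score equals a brute-force oracle on exhaustive small cases", {
  set.seed(43)
  for (rep in 1:60) {
    nq <- sample(1:8, 1); nt <- sample(1:8, 1)
    q <- paste0("q", 1:nq); t <- paste0("t", 1:nt)
    # random homology relation as a boolean matrix
    rel <- matrix(runif(nq * nt) < 0.3, nq, nt)
    prs <- which(rel, arr.ind = TRUE)
    if (nrow(prs) == 0) {
      hom <- homology_map(data.frame(a = "zzq", b = "zzt"))
    } else {
      hom <- homology_map(data.frame(a = q[prs[, 1]], b = t[prs[, 2]]))
    }
    # oracle: direct double loop over the relation
    want <- 0
    for (j in seq_len(nt)) {
      hit <- FALSE
      for (i in seq_len(nq)) if (rel[i, j]) hit <- TRUE
      want <- want + as.integer(hit)
    }
    expect_equal(syntenic_score(q, t, hom), want)
    # counting over target genes bounds the score by the target window;
    # the min-of-both-windows bound holds for one-to-one homology (checked
    # in the bijective-symmetry test)
    expect_lte(syntenic_score(q, t, hom), nt)
  }
})

test_that("bijective homology makes the score symmetric", {
  set.seed(47)
  q <- paste0("q", 1:7); t <- paste0("t", 1:7)
  hom <- homology_map(data.frame(a = q, b = sample(t)))
  expect_equal(syntenic_score(q, t, hom), syntenic_score(t, q, hom))
  expect_lte(syntenic_score(q, t, hom), min(length(q), length(t)))
})

test_that("the syntenic threshold is >= 4 exactly", {
  expect_true(call_synteny(4))
  expect_false(call_synteny(3))
  expect_false(call_synteny(0))
  expect_true(call_synteny(2, threshold = 2))
  expect_error(call_synteny(-1), ">= 0")
})

test_that("planted blocks are found, proxies flagged, negatives rejected", {
  cfg <- sim_config(seed = 51, n_pos = 6, n_neg = 6)
  nb <- simulate_neighborhoods(cfg)
  for (i in seq_len(nrow(nb$truth))) {
    tr <- nb$truth[i, ]
    calls <- find_syntenic_regions(tr$anchor, nb$query, nb$target,
                                   nb$homology)
    if (tr$type == "positive") {
      expect_equal(nrow(calls), 1)
      expect_equal(calls$score, tr$shared)
      expect_equal(calls$is_proxy, tr$proxy)
    } else {
      expect_equal(nrow(calls), 0)
      # sub-threshold candidates exist but stay below the threshold
      all_calls <- find_syntenic_regions(tr$anchor, nb$query, nb$target,
                                         nb$homology, keep_all = TRUE)
      expect_true(all(all_calls$score <= 3))
    }
  }
})

test_that("overlapping candidate windows are merged keeping the best score", {
  # one planted block: every partner-centred window overlaps the others,
  # so exactly one call must survive deduplication
  q <- sprintf("q%02d", 1:41)
  t <- sprintf("t%02d", 1:41)
  hom <- homology_map(data.frame(a = q[c(15, 18, 21, 24, 27)],
                                 b = t[c(15, 18, 21, 24, 27)]))
  go_q <- gene_order(list(cq = q))
  go_t <- gene_order(list(ct = t))
  calls <- find_syntenic_regions("q21", go_q, go_t, hom)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$score, 5)
  expect_false(calls$is_proxy)
})
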