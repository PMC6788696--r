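test_that("length prefilter bounds are inclusive", {
  seqs <- setNames(vapply(c(119, 120, 971, 972), function(n) {
    strrep("A", n)
  }, character(1)), c("under", "lo", "hi", "over"))
  kept <- length_prefilter(seqs)
  expect_identical(names(kept), c("lo", "hi"))
  expect_length(length_prefilter(character(0)), 0)
  expect_identical(length_prefilter(seqs[2:3]), seqs[2:3])
})

test_that("column filter removes strictly-above-half missing columns", {
  a <- new_alignment(paste0("s", 1:4),
                     c("A-A-", "A-A-", "A--A", "AAAA"))
  # col2: 4/4 gaps (removed); col3: 1/4; col4: 2/4 = exactly 50% (kept)
  fc <- filter_columns(a)
  expect_equal(fc$removed, 2)
  expect_equal(alignment_length(fc$aln), 3)

  b <- new_alignment(paste0("s", 1:4), c("A-", "A-", "AA", "A-"))
  # col2: 3/4 = 75% gaps -> removed
  expect_equal(filter_columns(b)$removed, 2)

  gapless <- new_alignment(c("x", "y"), c("MKV", "MKV"))
  fg <- filter_columns(gapless)
  expect_length(fg$removed, 0)
  expect_identical(fg$aln$seqs, gapless$seqs)

  allgap <- new_alignment(c("x", "y", "z"), c("A-", "--", "--"))
  expect_error(filter_columns(allgap), "degenerate")
})

test_that("sequence filter drops rows strictly below half coverage", {
  a <- new_alignment(c("full", "half", "short"),
                     c(strrep("A", 100),
                       paste0(strrep("A", 50), strrep("-", 50)),
                       paste0(strrep("A", 49), strrep("-", 51))))
  fs <- filter_sequences(a)
  expect_identical(fs$removed, "short")       # 49 < 50; exactly 50 kept
  expect_setequal(fs$aln$ids, c("full", "half"))

  # 70 residues in 145 columns: 70 < 72.5 -> removed
  b <- new_alignment(c("a", "b"),
                     c(strrep("A", 145),
                       paste0(strrep("A", 70), strrep("-", 75))))
  expect_identical(filter_sequences(b)$removed, "b")

  gapless <- new_alignment(c("x", "y"), c("MKVW", "MKVW"))
  expect_length(filter_sequences(gapless)$removed, 0)
})

test_that("both filters are idempotent", {
  set.seed(13)
  for (i in 1:25) {
    a <- rand_aln(sample(3:12, 1), sample(5:30, 1), gap_prob = 0.35)
    fc <- tryCatch(filter_columns(a), error = function(e) NULL)
    if (is.null(fc)) next
    expect_length(filter_columns(fc$aln)$removed, 0)
    fs <- tryCatch(filter_sequences(fc$aln), error = function(e) NULL)
    if (is.null(fs)) next
    expect_length(filter_sequences(fs$aln)$removed, 0)
  }
})

test_that("filter loop reaches a fixed point matching an independent replay", {
  set.seed(29)
  checked <- 0
  for (i in 1:120) {
    a <- rand_aln(sample(3:12, 1), sample(5:30, 1), gap_prob = 0.4)
    ours <- tryCatch(filter_to_fixed_point(a), error = function(e) NULL)
    theirs <- replay_filter_loop(alignment_matrix(a))
    if (is.null(ours)) {
      expect_null(theirs)
      next
    }
    expect_false(is.null(theirs))
    expect_identical(alignment_matrix(ours$aln),
                     theirs[rownames(theirs) %in% ours$aln$ids, ,
                            drop = FALSE])
    # fixed point: one more pass removes nothing
    expect_length(filter_columns(ours$aln)$removed, 0)
    expect_length(filter_sequences(ours$aln)$removed, 0)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("a sequence removal can cascade into further column removals", {
  # removing low-coverage row D tips columns 9-12 (its residues held them
  # at exactly half gaps) over the 50% threshold; losing those columns
  # then dooms row C, so the loop needs a third pass to verify the fixed
  # point
  a <- new_alignment(
    c("A", "B", "C", "D"),
    c("AAAAAAAA----",
      "AAAAAAAA----",
      "AA------AAAA",
      "A-------AAAA"))
  r <- filter_to_fixed_point(a)
  expect_gte(r$passes, 2)
  expect_setequal(r$aln$ids, c("A", "B"))
  expect_setequal(r$removed_ids, c("C", "D"))
  replay <- replay_filter_loop(alignment_matrix(a))
  expect_identical(sort(rownames(replay)), sort(r$aln$ids))
})

test_that("curation converges on simulated families and removes fragments", {
  cfg <- sim_config(seed = 19, rate = 0.03, n_per_clade = 8,
                    fragment_frac = 0.25)
  fam <- simulate_family(cfg)
  fr <- fragment_transcripts(fam$seqs, fam$truth, cfg)
  fcfg <- filter_config(min_len = 30)
  res <- curate_to_fixed_point(fr$seqs, fcfg)
  expect_true(res$converged)
  frag_ids <- fr$truth$id[fr$truth$fragment]
  expect_true(all(frag_ids %in% res$removed_ids))
  expect_setequal(res$alignment$ids, setdiff(fr$truth$id, frag_ids))
  # sequence count is non-increasing over iterations
  expect_true(all(diff(res$iterations$n_seqs_in) <= 0))
  # converged means the last iteration removed nothing
  expect_equal(res$iterations$n_seqs_removed[nrow(res$iterations)], 0)
  # final alignment is a fixed point of the filters
  expect_length(filter_columns(res$alignment, fcfg)$removed, 0)
  expect_length(filter_sequences(res$alignment, fcfg)$removed, 0)
})

test_that("an input already at fixed point converges in one iteration", {
  seqs <- setNames(rep(strrep("MKVW", 40), 3), c("a", "b", "c"))
  res <- curate_to_fixed_point(seqs, filter_config(min_len = 30))
  expect_true(res$converged)
  expect_equal(nrow(res$iterations), 1)
  expect_equal(unname(degap(res$alignment)), unname(seqs))
})

test_that("gap fraction arithmetic is exact", {
  expect_equal(gap_fraction(new_alignment(c("a", "b"), c("MK", "MW"))), 0)
  expect_equal(gap_fraction(new_alignment(c("a", "b"), c("M-", "MW"))), 0.25)
  a <- rand_aln(6, 20, gap_prob = 0.3)
  m <- alignment_matrix(a)
  expect_equal(gap_fraction(a), sum(m == "-") / length(m))
})
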