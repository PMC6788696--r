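test_that("pattern scanning matches character classes and reports spans", {
  ear57 <- motif_def("EAR-WOX5/7", "L[DE]LRLS")
  h <- scan_pattern("XXLDLRLSXX", ear57)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 2)
  expect_equal(h$end, 8)
  expect_equal(h$text, "LDLRLS")

  h2 <- scan_pattern("LELRLSLDLRLS", ear57)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$start, c(0, 6))

  expect_equal(nrow(scan_pattern("MKVWEDA", ear57)), 0)
  expect_equal(nrow(scan_pattern("LDLR", ear57)), 0)  # pattern longer than seq
})

test_that("pattern scanning equals a brute-force sliding window", {
  pats <- list(motif_def("a", "L[DE]LRLS"), motif_def("b", "NV[YF][YN]WFQN[RH]"),
               motif_def("c", "TL.LFP"))
  set.seed(37)
  pool <- c("L", "D", "E", "R", "S", "N", "V", "Y", "F", "W", "Q", "H",
            "T", "P")
  for (i in 1:60) {
    s <- rand_protein(sample(5:50, 1), pool)
    for (p in pats) {
      got <- scan_pattern(s, p)$start
      want <- slide_scan(s, famcurate:::.parse_pattern(p$pattern))
      expect_equal(got, want, info = paste(p$name, s))
    }
  }
})

test_that("overlapping matches are all reported", {
  m <- motif_def("ovl", "TATAT", kind = "cis")
  h <- scan_pattern("GTATATATG", m)
  expect_equal(h$start, c(1, 3))
})

test_that("motif definitions enforce the minimum width and regions", {
  expect_error(motif_def("tiny", "LDLR"), "minimum is 5")
  expect_error(motif_def("badreg", "LDLRLS", region = "middle"), "region")
  expect_equal(motif_width(motif_def("w", "L[DE]LRLS")), 6)
})

test_that("superclade classification follows the HD nonapeptides", {
  pad <- function(sig, extra = "") {
    paste0(strrep("AG", 20), sig, strrep("KV", 20), extra)
  }
  a1 <- classify_superclade(pad("NVYNWFQNR"))
  expect_equal(a1$superclade, "T1")
  expect_false(a1$ambiguous)

  expect_equal(classify_superclade(pad("NVFYWFQNR"))$superclade, "T2")
  expect_equal(classify_superclade(pad("NVFYWFQNH"))$superclade, "T3")

  u <- classify_superclade(pad("AAAAAAAAA"))
  expect_equal(u$superclade, "unclassified")
  expect_equal(nrow(u$evidence), 0)

  # T2 signature plus a WUS-box: kept as T2 but flagged ambiguous, with
  # both motifs in the evidence
  amb <- classify_superclade(pad("NVFYWFQNR", paste0("TLELFP", strrep("A", 10))))
  expect_equal(amb$superclade, "T2")
  expect_true(amb$ambiguous)
  expect_setequal(unique(amb$evidence$motif), c("HD-T2", "WUS-box"))

  # two distinct signatures cannot be resolved
  two <- classify_superclade(paste0(pad("NVYNWFQNR"), "NVFYWFQNH",
                                    strrep("K", 5)))
  expect_equal(two$superclade, "unclassified")
  expect_true(two$ambiguous)
})

test_that("EAR variants are recognised only in the C-terminal window", {
  expect_equal(classify_ear(paste0(strrep("A", 50), "LDLRLSAA"))$type, "WOX5/7")
  expect_equal(classify_ear(paste0(strrep("A", 50), "LELSLNAA"))$type, "WUS")
  expect_equal(classify_ear(paste0(strrep("A", 50), "LALRLSAA"))$type, "none")
  # an EAR-like string far from the C-terminus does not count
  expect_equal(classify_ear(paste0("LDLRLS", strrep("A", 60)))$type, "none")
  both <- classify_ear(paste0(strrep("A", 40), "LDLRLSAALELSLN"))
  expect_true(both$ambiguous)
  expect_setequal(both$type, c("WOX5/7", "WUS"))
})

test_that("HD location extends the core anchor with clipping", {
  mid <- paste0(strrep("A", 80), "NVFYWFQNH", strrep("K", 40))
  hd <- locate_hd(mid)
  expect_equal(hd$anchor_start, 80)
  expect_equal(hd$start, 30)       # 80 - 50
  expect_equal(hd$end, 96)         # 89 + 7
  expect_equal(hd$end - hd$start, 66)
  expect_false(hd$clipped)

  near <- paste0("AAAAA", "NVYNWFQNR", strrep("K", 40))
  hdn <- locate_hd(near)
  expect_true(hdn$clipped)
  expect_equal(hdn$start, 0)

  expect_null(locate_hd(strrep("AK", 50)))
})

test_that("clade assignment integrates signatures, regions and conflicts", {
  lib <- default_motif_library()
  fam <- simulate_family(sim_config(seed = 21, n_per_clade = 4, rate = 0))
  for (i in seq_len(nrow(fam$truth))) {
    a <- assign_clade(fam$seqs[[fam$truth$id[i]]], lib)
    expect_equal(a$superclade, fam$truth$superclade[i])
    expect_equal(a$clade, fam$truth$clade[i])
    expect_false(a$ambiguous)
  }

  # planted conflict: T1 signature but a T2 clade motif downstream
  t1 <- fam$seqs[[which(fam$truth$superclade == "T1")[1]]]
  conflict <- paste0(substr(t1, 1, 150), "VFINGQWPESLQ",
                     substr(t1, 163, nchar(t1)))
  ac <- assign_clade(conflict, lib)
  expect_true(ac$ambiguous)

  expect_error(assign_clade("MKVW", list()), "empty")
})

test_that("classification is independent of library listing order", {
  lib <- default_motif_library()
  fam <- simulate_family(sim_config(seed = 33, n_per_clade = 3, rate = 0.05))
  set.seed(1)
  shuffled <- lib[sample(length(lib))]
  a1 <- classify_collection(fam$seqs, lib)
  a2 <- classify_collection(fam$seqs, shuffled)
  expect_identical(a1$superclade, a2$superclade)
  expect_identical(a1$clade, a2$clade)
  expect_identical(a1$ambiguous, a2$ambiguous)
})

test_that("the shipped library loads with its printed signatures intact", {
  lib <- default_motif_library()
  names_ <- vapply(lib, `[[`, character(1), "name")
  pats <- setNames(vapply(lib, `[[`, character(1), "pattern"), names_)
  expect_equal(unname(pats["HD-T1"]), "NVYNWFQNR")
  expect_equal(unname(pats["HD-T2"]), "NVFYWFQNR")
  expect_equal(unname(pats["HD-T3"]), "NVFYWFQNH")
  expect_equal(unname(pats["EAR-WOX5/7"]), "L[DE]LRLS")
  expect_equal(unname(pats["EAR-WUS"]), "L[DE]L[ST]LN")
  # figure-only motifs are flagged as synthetic placeholders
  ph <- vapply(lib, `[[`, logical(1), "placeholder")
  expect_true(all(ph[grepl("T1WOX|T2WOX|WOX2|WOX1/6|WOX4", names_)]))
})
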