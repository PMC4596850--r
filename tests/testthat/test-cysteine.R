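test_that("extract_pattern records exact gaps and context", {
  p <- extract_pattern("ACCA")
  expect_equal(p$n_cys, 2L)
  expect_equal(unlist(p$gaps), 0L)
  expect_equal(p$lead, 1L)
  expect_equal(p$trail, 1L)

  p <- extract_pattern("CAAC")
  expect_equal(unlist(p$gaps), 2L)

  p <- extract_pattern("CACAACCA")
  expect_equal(unlist(p$gaps), c(1L, 2L, 0L))

  # property: re-extraction agrees with a direct position-scan oracle
  set.seed(71)
  for (i in 1:25) {
    s <- random_aa(sample(10:60, 1))
    if (sum(strsplit(s, "")[[1]] == "C") < 2) next
    expect_equal(unlist(extract_pattern(s)$gaps), scan_gaps(s))
  }

  expect_true(extract_pattern("AAAA")$acyclic)
  expect_true(extract_pattern("ACAA")$acyclic)
})

test_that("parse_pattern_string handles the published notation dialect", {
  pats <- dolomedes_family_patterns()
  counts <- vapply(pats, function(s) parse_pattern_string(s)$n_cys, 1L)
  expect_equal(unname(counts),
               c(10L, 8L, 10L, 8L, 12L, 12L, 10L, 10L))

  # family D's alternative-set gaps
  d <- parse_pattern_string(pats[["D"]])
  expect_equal(d$gaps[[4]], c(4L, 8L))
  expect_equal(d$gaps[[6]], c(6L, 7L))

  # family E: first gap exactly 6, trailing xn = variable trail
  e <- parse_pattern_string(pats[["E"]])
  expect_equal(e$gaps[[1]], 6L)
  expect_true(is.na(e$trail))

  # dialect: unicode dashes, underscores, whitespace, upper-case X
  expect_equal(parse_pattern_string("–Cx_7_-C–")$gaps[[1]], 7L)
  expect_equal(parse_pattern_string("-CC-")$gaps[[1]], 0L)
  expect_equal(parse_pattern_string("CXC")$gaps[[1]], 1L)

  expect_error(parse_pattern_string("C?-C"), "malformed")

  # printer and parser are mutual inverses modulo dialect
  for (s in pats) {
    p1 <- parse_pattern_string(s)
    p2 <- parse_pattern_string(format_pattern(p1))
    expect_equal(p2$gaps, p1$gaps)
    expect_equal(p2$n_cys, p1$n_cys)
  }
})

test_that("skeletonize canonicalizes gaps and renders discussion style", {
  pats <- dolomedes_family_patterns()
  expect_equal(skeletonize(parse_pattern_string(pats[["B"]]))$rendering,
               "C-C-CC-CXC-CXC")
  # families B and D share a skeleton despite different numeric spacers
  expect_equal(skeletonize(parse_pattern_string(pats[["D"]]))$rendering,
               skeletonize(parse_pattern_string(pats[["B"]]))$rendering)
  expect_equal(skeletonize(cys_pattern(2, list(0L)))$rendering, "CC")

  # idempotent under re-parsing of its own rendering
  for (s in pats) {
    sk <- skeletonize(parse_pattern_string(s))
    sk2 <- skeletonize(parse_pattern_string(sk$rendering))
    expect_equal(sk2$gap_classes, sk$gap_classes)
  }

  # a gap set mixing classes cannot be canonicalized
  expect_error(skeletonize(cys_pattern(2, list(c(1L, 4L)))), "mixes")
})

test_that("skeleton census merges B=D, E=F, G=H and counts 5 then 7", {
  pats <- dolomedes_family_patterns()
  cen <- count_distinct_skeletons(as.list(pats))
  expect_equal(cen$n_distinct, 5L)
  grp <- setNames(cen$groups, names(pats))
  expect_equal(grp[["B"]], grp[["D"]])
  expect_equal(grp[["E"]], grp[["F"]])
  expect_equal(grp[["G"]], grp[["H"]])
  expect_length(unique(grp[c("A", "B", "C", "E", "G")]), 5L)

  cen7 <- count_distinct_skeletons(c(as.list(pats),
                                     as.list(mizhoanus_specific_skeletons())))
  expect_equal(cen7$n_distinct, 7L)
  expect_equal(count_distinct_skeletons(list())$n_distinct, 0L)
})

test_that("PSM requires first gap 6 and adjacent C3-C4", {
  pats <- dolomedes_family_patterns()
  expect_true(detect_psm(parse_pattern_string(pats[["B"]])))
  expect_false(detect_psm(parse_pattern_string(pats[["A"]])))  # first gap 7
  expect_warning(flag <- detect_psm(cys_pattern(3, list(6L, 0L))), "4 cysteines")
  expect_false(flag)
})

test_that("ESM requires a pair of CXC units in the C-terminal half", {
  pats <- dolomedes_family_patterns()
  expect_true(detect_esm(parse_pattern_string(pats[["B"]])))
  expect_false(detect_esm(parse_pattern_string(pats[["A"]])))
  # one CXC at the end is not enough
  one_cxc <- cys_pattern(6, list(6L, 4L, 0L, 5L, 1L))
  expect_false(detect_esm(one_cxc))
})

test_that("disulfide capacity spans 4-6 over the printed patterns", {
  pats <- dolomedes_family_patterns()
  ss <- vapply(pats, function(s) max_disulfides(parse_pattern_string(s)), 1L)
  expect_equal(sort(unique(ss)), c(4L, 5L, 6L))
  expect_equal(max(ss), 6L)
  expect_equal(max_disulfides(9L), 4L)
})

test_that("realized sequences round-trip through extract_pattern", {
  # realizing an exact pattern as a concrete sequence and re-extracting
  # returns the same gaps
  set.seed(5)
  for (i in 1:20) {
    n_cys <- sample(4:12, 1)
    gaps <- sample(0:9, n_cys - 1, replace = TRUE)
    seq <- paste0(random_aa(3, setdiff(LETTERS, c("C", "B", "J", "O", "U",
                                                  "X", "Z"))),
                  paste(vapply(seq_len(n_cys - 1), function(i)
                    paste0("C", strrep("A", gaps[i])), ""), collapse = ""),
                  "C")
    expect_equal(unlist(extract_pattern(seq)$gaps), gaps)
  }
})

test_that("mature_profile summarizes length, cysteines, motifs and masses", {
  prof <- mature_profile("GCKSACCAAACACAAGCAAACAC", id = "x")
  expect_equal(prof$n_cys, 8L)
  expect_equal(prof$max_ss, 4L)
  expect_false(prof$acyclic)
  expect_equal(prof$length, 23L)
  expect_gt(prof$avg_mass, prof$length * 57)  # heavier than poly-Gly
  acy <- mature_profile("AAAA")
  expect_true(acy$acyclic)
})
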