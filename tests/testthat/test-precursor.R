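test_that("find_orf picks the longest forward-frame ORF", {
  expect_equal(find_orf("ATGGGTTGA", min_codons = 2)$aa, "MG")
  expect_null(find_orf("CCCGGGCCC"))  # no ATG

  # two ORFs: the longer wins, regardless of order
  orf40 <- paste0("ATG", strrep("GCT", 39), "TAA")
  orf60 <- paste0("ATG", strrep("AAA", 59), "TAA")
  seq <- paste0("CCT", orf40, "CC", orf60, "G")
  res <- find_orf(seq)
  expect_equal(nchar(res$aa), 60L)
  expect_equal(substr(res$aa, 2, 2), "K")

  # brute check of coordinates: translating the reported span gives aa+stop
  span <- substr(seq, res$start, res$end)
  expect_equal(nchar(span) %% 3, 0L)

  # short ORFs flagged (returned NULL) under the default threshold
  expect_null(find_orf("ATGGGTTGA"))
  expect_error(find_orf("ATGQ"), "non-nucleotide")
})

test_that("split_signal validates external sites and recovers synthetic cuts", {
  set.seed(2)
  tpl <- default_family_templates()
  pre <- generate_precursor(tpl$C)
  expect_equal(nchar(split_signal(pre$aa, site = 20)$signal), 20L)
  expect_error(split_signal(pre$aa, site = 10), "16-25")
  expect_error(split_signal(pre$aa, site = 26), "16-25")

  # heuristic recovers the generated cut on noise-free precursors
  for (i in 1:20) {
    nm <- sample(names(tpl), 1)
    pre <- generate_precursor(tpl[[nm]])
    sp <- split_signal(pre$aa)
    expect_equal(sp$site, pre$signal_range[2])
  }
})

test_that("find_pqm_cleavage applies the R-with-preceding-E rule in 12..38", {
  # R at position 7: below the minimum propeptide length -> no propeptide
  rem <- paste0("SLDEEAR", "SA", strrep("CAAK", 10))
  res <- find_pqm_cleavage(rem)
  expect_equal(res$site, 0L)
  expect_equal(res$propeptide, "")

  # ...EEAR ending at position 18 -> propeptide of 18
  rem <- paste0(strrep("S", 14), "EEAR", strrep("CAAK", 10))
  res <- find_pqm_cleavage(rem)
  expect_equal(res$site, 18L)
  expect_equal(nchar(res$propeptide), 18L)
  expect_equal(res$mature, strrep("CAAK", 10))

  # no R in the window -> no propeptide
  rem <- paste0(strrep("S", 40), strrep("CAAK", 10))
  expect_equal(find_pqm_cleavage(rem)$site, 0L)

  # last qualifying position wins
  rem <- paste0(strrep("S", 10), "ER", strrep("A", 6), "EAR",
                strrep("CAAK", 10))
  expect_equal(find_pqm_cleavage(rem)$site, 21L)

  # R without an acidic neighbour in the 3-window does not qualify
  rem <- paste0(strrep("S", 14), "AAAR", strrep("CAAK", 10))
  expect_equal(find_pqm_cleavage(rem)$site, 0L)
  # ...unless D is added to the acidic set
  rem <- paste0(strrep("S", 14), "DAAR", strrep("CAAK", 10))
  expect_equal(find_pqm_cleavage(rem)$site, 0L)
  expect_equal(find_pqm_cleavage(rem, acidic = c("E", "D"))$site, 18L)

  # a cut leaving a mature under 33 residues is refused
  rem <- paste0(strrep("S", 14), "EEAR", strrep("CA", 10))
  expect_equal(find_pqm_cleavage(rem)$site, 0L)
})

test_that("detect_amidation trims G / GK / GR with two-letter precedence", {
  res <- detect_amidation("ACKSGGK")
  expect_equal(res$mature, "ACKSG")
  expect_equal(res$trimmed_tail, "GK")
  expect_true(res$amidated)

  res <- detect_amidation("ACKSG")
  expect_equal(res$mature, "ACKS")
  expect_equal(res$trimmed_tail, "G")

  res <- detect_amidation("ACKSGR")
  expect_equal(res$trimmed_tail, "GR")
  expect_equal(res$mature, "ACKS")

  res <- detect_amidation("ACKSA")
  expect_false(res$amidated)
  expect_equal(res$mature, "ACKSA")

  # K alone (no preceding G) is not a signal
  expect_false(detect_amidation("ACKSAK")$amidated)
})

test_that("parsed regions tile the precursor exactly", {
  set.seed(4)
  tpl <- default_family_templates()
  for (i in 1:25) {
    pre <- generate_precursor(tpl[[sample(names(tpl), 1)]])
    p <- parse_precursor(pre$aa)
    expect_equal(p$signal_range[1], 1L)
    if (!is.null(p$propeptide_range)) {
      expect_equal(p$propeptide_range[1], p$signal_range[2] + 1L)
      expect_equal(p$mature_range[1], p$propeptide_range[2] + 1L)
    } else {
      expect_equal(p$mature_range[1], p$signal_range[2] + 1L)
    }
    expect_equal(p$mature_range[2], nchar(pre$aa))
    expect_gte(p$signal_range[2] - p$signal_range[1] + 1L, 16L)
    expect_lte(p$signal_range[2] - p$signal_range[1] + 1L, 25L)
  }
})

test_that("annotate_precursors handles nt and aa input and skips bad records", {
  set.seed(6)
  tpl <- default_family_templates()
  pre <- generate_precursor(tpl$D)
  nt <- reverse_translate(pre$aa, "random")
  seqs <- c(good_nt = paste0("CCT", nt, "GTC"),
            good_aa = pre$aa,
            no_orf = strrep("CGT", 60))
  res <- annotate_precursors(seqs)
  expect_equal(sort(res$table$id), c("good_aa", "good_nt"))
  expect_equal(res$skipped, "no_orf")
  # nt and aa routes agree
  expect_equal(res$table$mature[res$table$id == "good_nt"],
               res$table$mature[res$table$id == "good_aa"])
  expect_equal(res$table$trimmed_tail, c("GK", "GK"))
})
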