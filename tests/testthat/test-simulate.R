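test_that("family templates validate their invariants", {
  tpl <- default_family_templates()
  for (t in tpl) {
    expect_s3_class(t, "family_template")
    expect_equal(length(t$spacer_ranges), t$n_cys - 1L)
    expect_gte(t$mature_length_range[1], 35L)
    expect_lte(t$mature_length_range[2], 86L)
  }
  # propeptide-less families per the source descriptions
  expect_false(tpl$A$has_propeptide)
  expect_false(tpl$G$has_propeptide)
  expect_false(tpl$H$has_propeptide)
  expect_equal(tpl$D$amidation_tail, "GK")
  expect_equal(tpl$A$amidation_tail, "G")

  expect_error(family_template("x", list(c(1, 4)), c(40, 50)), "mixes")
  expect_warning(family_template("x", list(c(2, 2)), c(20, 30)), "canonical")
})

test_that("generate_precursor realizes the template exactly", {
  set.seed(51)
  tpl <- default_family_templates()
  # family B with its printed spacers: round-trips to family B's skeleton
  pre <- generate_precursor(tpl$B)
  pat <- extract_pattern(pre$mature_core)
  expect_equal(skeletonize(pat)$rendering,
               skeletonize(parse_pattern_string(
                 dolomedes_family_patterns()[["B"]]))$rendering)

  # amidation tail appended verbatim
  pre <- generate_precursor(tpl$D)
  expect_equal(substr(pre$aa, nchar(pre$aa) - 1L, nchar(pre$aa)), "GK")

  # cysteine count matches the template
  pre <- generate_precursor(tpl$B)
  expect_equal(sum(strsplit(pre$mature_core, "")[[1]] == "C"), 8L)

  # structural bounds hold across all families
  for (i in 1:30) {
    nm <- sample(names(tpl), 1)
    pre <- generate_precursor(tpl[[nm]])
    sig_len <- pre$signal_range[2]
    expect_gte(sig_len, 16L); expect_lte(sig_len, 25L)
    if (!is.null(pre$propeptide_range)) {
      plen <- diff(pre$propeptide_range) + 1L
      expect_gte(plen, 12L); expect_lte(plen, 38L)
    }
    expect_gte(nchar(pre$mature_core), 35L)
    expect_lte(nchar(pre$mature_core), 86L)
    # signal is hydrophobic-biased
    sig <- strsplit(substr(pre$aa, 1, sig_len), "")[[1]]
    expect_gte(mean(sig %in% c("A", "L", "I", "V", "F", "M", "W")), 0.4)
  }

  # infeasible configuration errors out
  bad <- family_template("bad", rep(list(c(10L, 10L)), 9), c(35L, 40L))
  expect_error(generate_precursor(bad), "infeasible")
})

test_that("founder-derived members are homologs of the founder", {
  set.seed(52)
  tpl <- default_family_templates()
  founder <- generate_precursor(tpl$C)
  member <- generate_precursor(tpl$C, founder = founder, divergence = 0.1)
  expect_equal(nchar(member$aa), nchar(founder$aa))
  id <- global_align(member$mature_core, founder$mature_core)$identity
  expect_gte(id, 0.75)
  expect_lt(id, 1)  # essentially always diverges somewhere at 0.1
  # skeleton preserved
  expect_equal(skeletonize(extract_pattern(member$mature_core))$rendering,
               founder$skeleton)
})

test_that("reverse_translate round-trips through the genetic code", {
  out <- reverse_translate("MG")
  expect_equal(nchar(out), 9L)
  expect_equal(substr(out, 1, 3), "ATG")
  expect_equal(find_orf(out, min_codons = 2)$aa, "MG")

  expect_error(reverse_translate(""), "empty")
  expect_error(reverse_translate("MZ"), "position 2")

  # deterministic policy: first codon in table order
  expect_identical(reverse_translate("C"), reverse_translate("C"))

  set.seed(53)
  for (i in 1:10) {
    aa <- paste0("M", random_aa(sample(30:60, 1)))
    nt <- reverse_translate(aa, "random")
    expect_equal(find_orf(nt)$aa, aa)
  }
})

test_that("generate_library is seeded, exact in count, and self-consistent", {
  cfg <- library_config(c(A = 3L, D = 3L),
                        category_mix = c(toxin = 25L, cellular = 6L,
                                         unknown = 3L),
                        substitution_rate = 0, seed = 77L)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1$reads, lib2$reads)
  expect_identical(lib1$truth, lib2$truth)
  expect_equal(length(lib1$reads), 34L)  # sum of category counts
  expect_equal(unname(table(lib1$truth$category)[c("toxin", "cellular",
                                                   "unknown")]),
               c(25L, 6L, 3L), ignore_attr = TRUE)
  expect_false(anyDuplicated(lib1$truth$est_id) > 0)

  # byte-identical FASTA under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(lib1$reads, f1); write_fasta(lib2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # substitution_rate = 0: copies identical up to the polyA tail
  cp <- lib1$truth[lib1$truth$transcript_id == lib1$truth$transcript_id[1], ]
  reads <- trim_polya(lib1$reads[cp$est_id])
  expect_equal(length(unique(unname(reads))), 1L)
})

test_that("noise-free libraries round-trip through the whole pipeline", {
  cfg <- library_config(setNames(rep(2L, 8), LETTERS[1:8]),
                        category_mix = c(toxin = 40L, cellular = 5L,
                                         unknown = 2L),
                        substitution_rate = 0, seed = 99L)
  lib <- generate_library(cfg)
  tox <- lib$reads[lib$truth$category == "toxin"]
  res <- annotate_precursors(trim_polya(tox))
  expect_length(res$skipped, 0L)
  tr <- lib$truth[match(res$table$id, lib$truth$est_id), ]
  expect_equal(res$table$signal_end, tr$signal_end)
  expect_equal(res$table$pro_end, tr$pro_end)
  expect_equal(res$table$mature_end, tr$mature_end)
  expect_equal(res$table$trimmed_tail, tr$amidation_tail)
  skel <- vapply(res$table$mature, function(m)
    skeletonize(extract_pattern(m))$rendering, "", USE.NAMES = FALSE)
  expect_equal(skel, tr$skeleton)
})

test_that("clustering a synthetic library recovers the source transcripts", {
  cfg <- library_config(setNames(rep(3L, 4), c("A", "C", "D", "G")),
                        category_mix = c(toxin = 45L, cellular = 10L,
                                         unknown = 5L),
                        substitution_rate = 0.01, seed = 120L)
  lib <- generate_library(cfg)
  kept <- filter_length(trim_polya(lib$reads))$kept
  cl <- cluster_ests(kept)
  n_transcripts <- length(unique(
    lib$truth$transcript_id[lib$truth$est_id %in% names(kept)]))
  expect_equal(length(cl), n_transcripts)
  # every cluster is pure: one source transcript per cluster
  for (x in cl) {
    src <- lib$truth$transcript_id[match(x$member_ids, lib$truth$est_id)]
    expect_length(unique(src), 1L)
  }
  expect_equal(sum(vapply(cl, `[[`, 1L, "size")), length(kept))
})

test_that("cluster-size bins follow the configured redundancy distribution", {
  # large transcript count; compare empirical bin frequencies by chi-square
  cfg <- library_config(c(A = 400L),
                        category_mix = c(toxin = 1200L, cellular = 0L,
                                         unknown = 0L),
                        substitution_rate = 0, seed = 101L)
  lib <- generate_library(cfg)
  sizes <- table(lib$truth$transcript_id)
  # drop the last transcript (may be truncated by the quota)
  last <- names(sizes)[which.max(as.integer(sub("TX", "", names(sizes))))]
  sizes <- sizes[names(sizes) != last]
  bins <- cluster_size_histogram(as.integer(sizes))
  expected <- cfg$redundancy_bins * sum(bins)
  chisq <- sum((bins - expected)^2 / expected)
  # 3 df; 0.001 quantile ~ 16.27
  expect_lt(chisq, 16.27)
})
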