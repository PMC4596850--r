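# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force recursion for alignment, direct
# position scans for patterns, exhaustive topology enumeration for NJ.

# Exhaustive global alignment score by recursion (tiny strings only).
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0L) return(gap * nchar(b))
  if (nchar(b) == 0L) return(gap * nchar(a))
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ra <- substr(a, 2, nchar(a)); rb <- substr(b, 2, nchar(b))
  max(brute_align_score(ra, rb, match, mismatch, gap) +
        if (a1 == b1) match else mismatch,
      brute_align_score(ra, b, match, mismatch, gap) + gap,
      brute_align_score(a, rb, match, mismatch, gap) + gap)
}

# Gap list by direct position scan.
scan_gaps <- function(seq) {
  pos <- which(strsplit(seq, "")[[1]] == "C")
  diff(pos) - 1L
}

# Longest-suffix polyA scan.
scan_polya <- function(seq, min_tail) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  run <- 0L
  while (run < n && chars[n - run] == "A") run <- run + 1L
  if (run >= min_tail) substr(seq, 1L, n - run) else seq
}

# Net-charge bisection oracle with an explicit group list, independent of
# compute_pi's bookkeeping.
oracle_pi <- function(seq, pos_pka, neg_pka) {
  chars <- strsplit(seq, "")[[1]]
  z <- function(ph) {
    s <- 0
    for (g in names(pos_pka)) {
      n <- if (g == "Nterm") 1 else sum(chars == g)
      s <- s + n / (1 + 10^(ph - pos_pka[[g]]))
    }
    for (g in names(neg_pka)) {
      n <- if (g == "Cterm") 1 else sum(chars == g)
      s <- s - n / (1 + 10^(neg_pka[[g]] - ph))
    }
    s
  }
  stats::uniroot(z, c(0, 14), tol = 1e-9)$root
}

# All three unrooted topologies on four taxa, least-squares branch fit;
# returns the index (1: ab|cd, 2: ac|bd, 3: ad|bc) of the best topology.
best_quartet <- function(d) {
  stopifnot(nrow(d) == 4)
  s <- function(i, j, k, l) d[i, j] + d[k, l]
  sums <- c(s(1, 2, 3, 4), s(1, 3, 2, 4), s(1, 4, 2, 3))
  which.min(sums)  # four-point condition: smallest pairing is the split
}

# Random amino-acid string.
random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small two-species library pair used by comparative tests: 4 shared
# families (A-D), 3 species-S-only (E-G), 2 species-M-only (M4, M5).
make_two_species_libraries <- function(seed = 21L, n_per_family = 4L,
                                       toxS = 60L, toxM = 50L) {
  tplS <- default_family_templates()[c("A", "B", "C", "D", "E", "F", "G")]
  tplM <- c(default_family_templates()[c("A", "B", "C", "D")],
            mizhoanus_family_templates())
  cfgS <- library_config(setNames(rep(n_per_family, length(tplS)), names(tplS)),
                         category_mix = c(toxin = toxS, cellular = 5L,
                                          unknown = 2L),
                         substitution_rate = 0, seed = seed)
  cfgM <- library_config(setNames(rep(n_per_family, length(tplM)), names(tplM)),
                         category_mix = c(toxin = toxM, cellular = 5L,
                                          unknown = 2L),
                         substitution_rate = 0, seed = seed + 1L)
  libS <- generate_library(cfgS, tplS)
  libM <- generate_library(cfgM, tplM, founders = libS$founders)
  list(S = libS, M = libM)
}

# Non-redundant mature peptides (one per transcript) with species tags.
mature_peptides <- function(lib, species) {
  tr <- lib$truth[lib$truth$category == "toxin", ]
  tr <- tr[!duplicated(tr$transcript_id), ]
  res <- annotate_precursors(setNames(tr$precursor_aa, tr$transcript_id))
  data.frame(id = paste0(species, "_", res$table$id), species = species,
             sequence = res$table$mature,
             family_true = tr$family[match(res$table$id, tr$transcript_id)],
             stringsAsFactors = FALSE)
}

# Split extraction via the public ape API, mirroring the internal one.
tree_splits_for_test <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  out <- character(0)
  for (node in (ntip + 2):(ntip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    side <- if (sort(tree$tip.label)[1] %in% tips)
      setdiff(tree$tip.label, tips) else tips
    if (length(side) >= 2 && length(side) <= ntip - 2)
      out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}
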