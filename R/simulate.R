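# Residue alphabets used by the generator. The signal-peptide cut heuristic
# admits cuts only at small residues within positions 16..25, and the PQM
# scan looks for R in remainder positions 12..38, so the generator keeps
# those residue classes out of the corresponding guard zones: a noise-free
# synthetic precursor then parses back to its generated boundaries exactly.
HYDROPHOBIC_AA <- c("A", "L", "I", "V", "F", "M", "W")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Family template for the synthetic toxin generator
#'
#' Describes one toxin family: its cysteine skeleton with per-gap spacer
#' ranges, mature length range, whether precursors carry a propeptide, the
#' C-terminal amidation tail, and the basicity of the mature filler
#' residues.
#'
#' @param name family label.
#' @param spacer_ranges list of integer vectors `c(lo, hi)` (or scalars),
#'   one per inter-cysteine gap; the gap class (adjacent 0 / single 1 /
#'   variable >= 2) must be constant across each range.
#' @param mature_length_range `c(lo, hi)` mature length in residues, before
#'   the amidation tail is appended; default bounds \[35, 86\].
#' @param has_propeptide logical; when `TRUE` the propeptide ends in a PQM.
#' @param amidation_tail one of `"none"`, `"G"`, `"GK"`, `"GR"`.
#' @param basicity_bias fraction of charged mature fillers drawn from
#'   `{K, R}` rather than `{D, E}` (default 0.5).
#' @param lead_range `c(lo, hi)` residues before the first cysteine.
#' @return Object of class `family_template`.
#' @export
family_template <- function(name, spacer_ranges, mature_length_range,
                            has_propeptide = TRUE,
                            amidation_tail = c("none", "G", "GK", "GR"),
                            basicity_bias = 0.5,
                            lead_range = c(1L, 6L)) {
  amidation_tail <- match.arg(amidation_tail)
  spacer_ranges <- lapply(spacer_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || any(r < 0L) || r[1] > r[2])
      stop("each spacer range must be c(lo, hi) with 0 <= lo <= hi")
    cls <- unique(ifelse(r == 0L, "a", ifelse(r == 1L, "s", "v")))
    if (length(cls) > 1L && !(all(r >= 2L)))
      stop("spacer range [", r[1], ",", r[2],
           "] mixes skeleton gap classes")
    r
  })
  mature_length_range <- as.integer(mature_length_range)
  stopifnot(length(mature_length_range) == 2L,
            mature_length_range[1] <= mature_length_range[2])
  if (mature_length_range[1] < 35L || mature_length_range[2] > 86L)
    warning("mature length range outside the canonical [35, 86]")
  n_cys <- length(spacer_ranges) + 1L
  skeleton <- {
    classes <- vapply(spacer_ranges, function(r)
      if (r[2] == 0L) "adjacent" else if (r[2] == 1L) "single" else "variable",
      "")
    p <- cys_pattern(n_cys, lapply(spacer_ranges, function(r)
      if (r[1] == r[2]) r[1] else NA_integer_))
    skeletonize(p)
  }
  structure(list(name = name, spacer_ranges = spacer_ranges,
                 n_cys = n_cys, skeleton = skeleton,
                 mature_length_range = mature_length_range,
                 has_propeptide = isTRUE(has_propeptide),
                 amidation_tail = amidation_tail,
                 basicity_bias = basicity_bias,
                 lead_range = as.integer(lead_range)),
            class = "family_template")
}

#' Templates mirroring the eight Dolomedes toxin families
#'
#' Spacer ranges follow the printed family patterns (exact spacers where
#' the pattern is exact, the printed alternatives where it lists sets);
#' mature length ranges, propeptide presence (absent in A, G, H),
#' amidation tails (single G in family A, GK in family D) and basicity
#' (basic family D, acidic family H) follow the family descriptions.
#'
#' @return Named list of [family_template] objects.
#' @export
default_family_templates <- function() {
  pats <- dolomedes_family_patterns()
  ranges_from_pattern <- function(key, variable_default = c(2L, 5L)) {
    p <- parse_pattern_string(pats[[key]])
    lapply(p$gaps, function(g) {
      if (length(g) == 1L && is.na(g)) variable_default
      else if (length(g) > 1L) range(g)
      else c(g, g)
    })
  }
  list(
    A = family_template("A", ranges_from_pattern("A"), c(60L, 75L),
                        has_propeptide = FALSE, amidation_tail = "G",
                        lead_range = c(2L, 8L)),
    B = family_template("B", ranges_from_pattern("B"), c(35L, 40L),
                        has_propeptide = TRUE, amidation_tail = "GR"),
    C = family_template("C", ranges_from_pattern("C"), c(53L, 62L),
                        has_propeptide = TRUE, amidation_tail = "none"),
    D = family_template("D", ranges_from_pattern("D"), c(43L, 51L),
                        has_propeptide = TRUE, amidation_tail = "GK",
                        basicity_bias = 0.85),
    E = family_template("E", ranges_from_pattern("E"), c(68L, 74L),
                        has_propeptide = TRUE, amidation_tail = "G"),
    F = family_template("F", ranges_from_pattern("F"), c(66L, 75L),
                        has_propeptide = TRUE, amidation_tail = "none"),
    G = family_template("G", ranges_from_pattern("G"), c(62L, 68L),
                        has_propeptide = FALSE, amidation_tail = "none",
                        lead_range = c(1L, 4L)),
    H = family_template("H", ranges_from_pattern("H"), c(80L, 86L),
                        has_propeptide = FALSE, amidation_tail = "none",
                        basicity_bias = 0.15, lead_range = c(0L, 3L))
  )
}

#' @rdname default_family_templates
#' @details `mizhoanus_family_templates()` adds the two families whose
#'   skeletons occur only in *D. mizhoanus* toxins (the `IV` and `V`
#'   skeleton strings of [mizhoanus_specific_skeletons()]), for building
#'   two-species libraries.
#' @export
mizhoanus_family_templates <- function() {
  sk <- mizhoanus_specific_skeletons()
  ranges_from_skeleton <- function(s, variable_default = c(2L, 5L)) {
    p <- parse_pattern_string(s)
    lapply(p$gaps, function(g) {
      if (length(g) == 1L && is.na(g)) variable_default
      else c(g, g)
    })
  }
  list(
    M4 = family_template("M4", ranges_from_skeleton(sk[["IV"]]), c(45L, 60L),
                         has_propeptide = TRUE, amidation_tail = "G"),
    M5 = family_template("M5", ranges_from_skeleton(sk[["V"]]), c(45L, 60L),
                         has_propeptide = TRUE, amidation_tail = "none")
  )
}

# Uniform integer draw on [lo, hi], safe for lo == hi (unlike sample()).
sample_int <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Sample one residue from `pool` excluding `excl`.
draw_aa <- function(pool, excl = character(0)) {
  pool <- setdiff(pool, excl)
  pool[sample.int(length(pool), 1L)]
}

# Residue draw for one mutable position, respecting the guard zones.
# `zone` is "signal" or "pro" or "mature"; `p` the 1-based position within
# its zone. Fixed positions (initial M, signal cut residue, propeptide E-R
# dipeptide, mature cysteines, last two mature residues' G/K/R exclusion)
# are handled by the callers.
draw_zone_aa <- function(zone, p, sig_len, pro_len, mature_len, basicity) {
  if (zone == "signal") {
    hyd <- stats::runif(1) < 0.7
    if (p >= 16L) {
      if (hyd) draw_aa(setdiff(HYDROPHOBIC_AA, "A"))
      else draw_aa(c("K", "R", "E", "D", "N", "Q", "H", "P", "Y"))
    } else {
      if (hyd) draw_aa(HYDROPHOBIC_AA)
      else draw_aa(c("K", "R", "E", "D", "N", "Q", "H", "P", "Y",
                     "S", "T", "G"))
    }
  } else if (zone == "pro") {
    excl <- "C"
    if (sig_len + p <= 25L) excl <- c(excl, "A", "G", "S", "T")
    draw_aa(setdiff(AA20, "R"), excl)
  } else {
    excl <- character(0)
    if (sig_len + pro_len + p <= 25L) excl <- c(excl, "A", "G", "S", "T")
    if (pro_len + p <= 38L) excl <- c(excl, "R")
    if (p >= mature_len - 1L) excl <- c(excl, "G", "K", "R")
    charged_basic <- c("K", "R"); charged_acidic <- c("D", "E")
    neutral <- c("N", "Q", "S", "T", "G", "A", "L", "I", "V", "F",
                 "Y", "W", "H", "P", "M")
    pool <- if (stats::runif(1) < 0.3) {
      if (stats::runif(1) < basicity) charged_basic else charged_acidic
    } else neutral
    pool2 <- setdiff(pool, excl)
    if (length(pool2) == 0L) pool2 <- setdiff(neutral, excl)
    pool2[sample.int(length(pool2), 1L)]
  }
}

#' Generate one toxin precursor from a family template
#'
#' Draws a signal peptide (16-25 residues, >= 60% hydrophobic, initial M,
#' small residue at the cut), an optional propeptide (12-38 residues ending
#' in a PQM: R preceded by E), and a mature peptide realizing the
#' template's cysteine skeleton with spacers from its ranges, the amidation
#' tail appended verbatim. Guard zones keep decoy signal-cut residues, and
#' arginines that would fake a PQM, out of the parser's scan windows, so
#' noise-free round-trips recover the generated coordinates exactly.
#'
#' With a `founder` (a previous result), the founder's layout and residues
#' are reused and each mutable position is resampled independently with
#' probability `divergence`: members of a family are homologs of their
#' founder rather than independent draws, mirroring the high within-family
#' sequence identity of real toxin families.
#'
#' Uses the R global RNG; seed it (or use [generate_library()], which
#' derives a per-record stream) for reproducibility.
#'
#' @param template a [family_template].
#' @param founder optional earlier `generate_precursor()` result for the
#'   same template.
#' @param divergence per-position resampling probability under a founder
#'   (default 0.1).
#' @return List: `aa` (precursor), `signal_range`, `propeptide_range`
#'   (NULL if absent), `mature_range` (includes tail), `amidation_tail`,
#'   `mature_core` (mature without tail), `skeleton` (rendering), `family`,
#'   `layout` (internal, for founder reuse).
#' @export
generate_precursor <- function(template, founder = NULL, divergence = 0.1) {
  stopifnot(inherits(template, "family_template"))
  if (is.null(founder)) {
    # mature layout first: gaps, target length, lead/trail context
    for (try in 1:50) {
      gaps <- vapply(template$spacer_ranges, function(r)
        if (r[1] == r[2]) r[1] else sample_int(r[1], r[2]), 1L)
      core_len <- template$n_cys + sum(gaps)
      target <- sample_int(template$mature_length_range[1],
                           template$mature_length_range[2])
      lead <- sample_int(template$lead_range[1], template$lead_range[2])
      trail <- target - lead - core_len
      if (trail >= 0L) break
      if (try == 50L)
        stop("infeasible spacer ranges vs mature length for family ",
             template$name)
    }
    # signal length: for propeptide-less precursors the first mature
    # cysteine must fall beyond the cut-heuristic scan window (position
    # 25), so the signal is drawn long enough that sig_len + lead >= 25
    sig_lo <- if (template$has_propeptide) 16L else max(16L, 25L - lead)
    sig_len <- sample_int(sig_lo, 25L)
    pro_len <- if (template$has_propeptide) sample_int(12L, 38L) else 0L
  } else {
    stopifnot(identical(founder$family, template$name))
    lay <- founder$layout
    gaps <- lay$gaps; lead <- lay$lead; trail <- lay$trail
    core_len <- template$n_cys + sum(gaps)
    sig_len <- lay$sig_len; pro_len <- lay$pro_len
  }
  mature_len <- lead + core_len + trail
  cys_pos <- lead + 1L + cumsum(c(0L, gaps + 1L))

  if (is.null(founder)) {
    signal <- character(sig_len)
    for (p in 2:(sig_len - 1L))
      signal[p] <- draw_zone_aa("signal", p, sig_len, pro_len, mature_len,
                                template$basicity_bias)
    propeptide <- character(pro_len)
    if (pro_len > 0L)
      for (p in seq_len(pro_len))
        propeptide[p] <- draw_zone_aa("pro", p, sig_len, pro_len, mature_len,
                                      template$basicity_bias)
    mature <- character(mature_len)
    mature[cys_pos] <- "C"
    for (p in which(mature == ""))
      mature[p] <- draw_zone_aa("mature", p, sig_len, pro_len, mature_len,
                                template$basicity_bias)
  } else {
    fchars <- strsplit(founder$aa, "", fixed = TRUE)[[1]]
    signal <- fchars[seq_len(sig_len)]
    propeptide <- if (pro_len > 0L)
      fchars[sig_len + seq_len(pro_len)] else character(0)
    mature <- fchars[sig_len + pro_len + seq_len(mature_len)]
    for (p in 2:(sig_len - 1L))
      if (stats::runif(1) < divergence)
        signal[p] <- draw_zone_aa("signal", p, sig_len, pro_len, mature_len,
                                  template$basicity_bias)
    if (pro_len > 2L) for (p in seq_len(pro_len - 2L))
      if (stats::runif(1) < divergence)
        propeptide[p] <- draw_zone_aa("pro", p, sig_len, pro_len, mature_len,
                                      template$basicity_bias)
    for (p in setdiff(seq_len(mature_len), cys_pos))
      if (stats::runif(1) < divergence)
        mature[p] <- draw_zone_aa("mature", p, sig_len, pro_len, mature_len,
                                  template$basicity_bias)
  }
  signal[1] <- "M"
  if (is.null(founder)) signal[sig_len] <- draw_aa(c("A", "G", "S", "T"))
  if (pro_len > 0L) {
    propeptide[pro_len] <- "R"
    propeptide[pro_len - 1L] <- "E"
  }

  tail <- if (template$amidation_tail == "none") "" else template$amidation_tail
  mature_str <- paste(mature, collapse = "")
  aa <- paste0(paste(signal, collapse = ""),
               paste(propeptide, collapse = ""),
               mature_str, tail)
  n <- nchar(aa)
  list(aa = aa,
       signal_range = c(1L, sig_len),
       propeptide_range = if (pro_len > 0L)
         c(sig_len + 1L, sig_len + pro_len) else NULL,
       mature_range = c(sig_len + pro_len + 1L, n),
       amidation_tail = tail,
       mature_core = mature_str,
       skeleton = template$skeleton$rendering,
       family = template$name,
       layout = list(sig_len = sig_len, pro_len = pro_len, lead = lead,
                     gaps = gaps, trail = trail))
}

#' Reverse-translate an amino-acid sequence
#'
#' Encodes each residue with a codon of the standard genetic code and
#' appends a stop codon. Under the `"first"` policy the first codon in
#' table order is used for every residue (deterministic); `"random"`
#' samples uniformly among synonymous codons. Translating the output
#' recovers the input (methionine is encoded by ATG, so a sequence
#' starting with M begins with the start codon).
#'
#' @param aa_sequence amino-acid string over the 20 standard residues.
#' @param policy `"first"` or `"random"`.
#' @return nucleotide string of length `3 * (nchar(aa) + 1)`.
#' @export
reverse_translate <- function(aa_sequence, policy = c("first", "random")) {
  policy <- match.arg(policy)
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1L)
  if (!nzchar(aa_sequence)) stop("empty amino-acid sequence")
  chars <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  code <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(code), unname(code))
  bad <- which(!chars %in% names(codons_by_aa) | chars == "*")
  if (length(bad))
    stop("unknown residue ", sQuote(chars[bad[1]]), " at position ", bad[1])
  nt <- vapply(chars, function(a) {
    cs <- codons_by_aa[[a]]
    if (policy == "first") cs[1L] else cs[sample.int(length(cs), 1L)]
  }, "", USE.NAMES = FALSE)
  stop_codon <- if (policy == "first") "TAA" else
    sample(c("TAA", "TAG", "TGA"), 1L)
  paste0(paste(nt, collapse = ""), stop_codon)
}

#' Library configuration for the synthetic EST generator
#'
#' @param family_sizes named integer vector: distinct toxin transcripts per
#'   family template.
#' @param category_mix named counts of emitted ESTs per category; default
#'   `c(toxin = 190, cellular = 65, unknown = 12)`, the composition of the
#'   267-EST library the generator emulates.
#' @param redundancy_bins probabilities of a transcript's copy number
#'   falling in the cluster-size bins `1`, `2-9`, `10-19`, `20-70`;
#'   default is the observed cluster-size prevalence (58, 19, 4, 2 of 83).
#' @param substitution_rate per-site substitution probability applied
#'   independently to each EST copy (default 0.01, single-pass read scale).
#' @param polya_length_range polyA tail length bounds, default `c(8, 30)`
#'   (all tails removable at the trimming threshold of 6).
#' @param seed integer master seed; per-record streams are derived from it
#'   by counter, so records are order-independent.
#' @return Object of class `library_config`.
#' @export
library_config <- function(family_sizes,
                           category_mix = c(toxin = 190L, cellular = 65L,
                                            unknown = 12L),
                           redundancy_bins = c(`1` = 58, `2-9` = 19,
                                               `10-19` = 4, `20-70` = 2) / 83,
                           substitution_rate = 0.01,
                           polya_length_range = c(8L, 30L),
                           seed = 1L) {
  stopifnot(!is.null(names(family_sizes)), all(family_sizes >= 0),
            all(category_mix >= 0),
            substitution_rate >= 0, substitution_rate < 1,
            length(redundancy_bins) == 4L,
            abs(sum(redundancy_bins) - 1) < 1e-8)
  structure(list(family_sizes = family_sizes,
                 category_mix = category_mix,
                 redundancy_bins = redundancy_bins,
                 substitution_rate = substitution_rate,
                 polya_length_range = as.integer(polya_length_range),
                 seed = as.integer(seed)),
            class = "library_config")
}

# Derive a deterministic per-record RNG stream from the master seed and a
# counter; keeps generated records independent of emission order.
with_stream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
                        2147483562))
  force(expr)
}

random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_nt <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic EST library with ground truth
#'
#' Emits FASTA-style reads emulating a directional venom-gland cDNA
#' library: toxin transcripts built from family templates (reverse
#' translated with random codon usage, short ORF-free UTRs, polyA tail),
#' plus cellular and unknown decoy reads, with per-transcript copy numbers
#' drawn from the configured cluster-size bins and per-copy substitution
#' noise. Same config and seed give byte-identical output.
#'
#' Within a family, distinct transcripts are homologs: the family's first
#' transcript founds it and later ones diverge from the founder at rate
#' `family_divergence` per position. Passing the `founders` of a previous
#' library makes shared families cross-species homologs (each species'
#' founder diverges from the common one at `species_divergence`), so a
#' two-species library with a known shared/specific family split can be
#' built.
#'
#' @param config a [library_config].
#' @param templates named list of [family_template]s (default
#'   [default_family_templates()] restricted to `names(config$family_sizes)`).
#' @param founders optional `founders` element of a previous library, for
#'   cross-species homology.
#' @param family_divergence per-position divergence of family members from
#'   their founder (default 0.1).
#' @param species_divergence per-position divergence of this library's
#'   family founders from the shared `founders` (default 0.15).
#' @return List: `reads` (named character vector), `truth` (data.frame:
#'   est_id, transcript_id, category, family, aa-level region coordinates,
#'   amidation_tail, skeleton, precursor_aa), `founders`, `config`.
#' @export
generate_library <- function(config, templates = default_family_templates(),
                             founders = NULL, family_divergence = 0.1,
                             species_divergence = 0.15) {
  stopifnot(inherits(config, "library_config"))
  missing_t <- setdiff(names(config$family_sizes), names(templates))
  if (length(missing_t))
    stop("no template for families: ", paste(missing_t, collapse = ", "))

  bin_lo <- c(1L, 2L, 10L, 20L); bin_hi <- c(1L, 9L, 19L, 70L)
  draw_copies <- function() {
    b <- sample.int(4L, 1L, prob = config$redundancy_bins)
    if (bin_lo[b] == bin_hi[b]) bin_lo[b]
    else sample_int(bin_lo[b], bin_hi[b])
  }

  reads <- character(0); truth <- list()
  counter <- 0L
  emit <- function(id, seq_, transcript, category, family, pre) {
    reads[[id]] <<- seq_
    truth[[length(truth) + 1L]] <<- data.frame(
      est_id = id, transcript_id = transcript, category = category,
      family = family,
      signal_start = if (is.null(pre)) NA_integer_ else pre$signal_range[1],
      signal_end = if (is.null(pre)) NA_integer_ else pre$signal_range[2],
      pro_start = if (is.null(pre) || is.null(pre$propeptide_range))
        NA_integer_ else pre$propeptide_range[1],
      pro_end = if (is.null(pre) || is.null(pre$propeptide_range))
        NA_integer_ else pre$propeptide_range[2],
      mature_start = if (is.null(pre)) NA_integer_ else pre$mature_range[1],
      mature_end = if (is.null(pre)) NA_integer_ else pre$mature_range[2],
      amidation_tail = if (is.null(pre)) "" else pre$amidation_tail,
      skeleton = if (is.null(pre)) NA_character_ else pre$skeleton,
      precursor_aa = if (is.null(pre)) NA_character_ else pre$aa,
      stringsAsFactors = FALSE)
  }

  # toxin transcripts: cycle through families until the toxin quota is met
  quota <- config$category_mix[["toxin"]]
  # round-robin over families so every family is represented even when the
  # EST quota is reached before all configured transcripts are emitted
  fam_expanded <- unlist(lapply(seq_len(max(config$family_sizes)), function(k)
    names(config$family_sizes)[config$family_sizes >= k]))
  fam_founders <- list()
  emitted <- 0L; t_idx <- 0L
  while (emitted < quota && length(fam_expanded) > 0L) {
    t_idx <- t_idx + 1L
    fam <- fam_expanded[((t_idx - 1L) %% length(fam_expanded)) + 1L]
    counter <- counter + 1L
    rec <- with_stream(config$seed, counter, {
      pre <- if (!is.null(fam_founders[[fam]]))
        generate_precursor(templates[[fam]], founder = fam_founders[[fam]],
                           divergence = family_divergence)
      else if (!is.null(founders[[fam]]))
        generate_precursor(templates[[fam]], founder = founders[[fam]],
                           divergence = species_divergence)
      else generate_precursor(templates[[fam]])
      cds <- reverse_translate(pre$aa, policy = "random")
      # UTRs long enough that every toxin cDNA clears the >400 bp clone
      # filter; drawn A-free so no decoy ATG/ORF can outrun the real one
      utr5 <- random_nt(sample(20:60, 1L), c("C", "G", "T"))
      utr3 <- random_nt(sample(200:400, 1L), c("C", "G", "T"))
      list(pre = pre, base = paste0(utr5, cds, utr3),
           copies = draw_copies())
    })
    if (is.null(fam_founders[[fam]])) fam_founders[[fam]] <- rec$pre
    transcript_id <- sprintf("TX%04d", t_idx)
    n_copies <- min(rec$copies, quota - emitted)
    for (cp in seq_len(n_copies)) {
      counter <- counter + 1L
      read <- with_stream(config$seed, counter, {
        body <- mutate_nt(rec$base, config$substitution_rate)
        tail_len <- sample_int(config$polya_length_range[1],
                               config$polya_length_range[2])
        paste0(body, strrep("A", tail_len))
      })
      emit(sprintf("%s_E%02d", transcript_id, cp), read, transcript_id,
           "toxin", fam, rec$pre)
      emitted <- emitted + 1L
    }
  }

  # decoy transcripts: random reads with category labels; content is
  # irrelevant downstream, redundancy drawn from the same bins
  for (category in c("cellular", "unknown")) {
    quota <- config$category_mix[[category]]
    emitted <- 0L; d_idx <- 0L
    while (emitted < quota) {
      d_idx <- d_idx + 1L
      counter <- counter + 1L
      rec <- with_stream(config$seed, counter, {
        list(base = random_nt(sample(420:700, 1L)), copies = draw_copies())
      })
      transcript_id <- sprintf("%s%04d", toupper(substr(category, 1, 2)), d_idx)
      n_copies <- min(rec$copies, quota - emitted)
      for (cp in seq_len(n_copies)) {
        counter <- counter + 1L
        read <- with_stream(config$seed, counter, {
          body <- mutate_nt(rec$base, config$substitution_rate)
          tail_len <- sample_int(config$polya_length_range[1],
                                 config$polya_length_range[2])
          paste0(body, strrep("A", tail_len))
        })
        emit(sprintf("%s_E%02d", transcript_id, cp), read, transcript_id,
             category, NA_character_, NULL)
        emitted <- emitted + 1L
      }
    }
  }

  list(reads = reads, truth = do.call(rbind, truth),
       founders = fam_founders, config = config)
}
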