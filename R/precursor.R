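# Kyte-Doolittle hydropathy scale, used by the signal-peptide heuristic.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Residues accepted at the last position of a signal peptide (small,
# neutral side chains typical of signal-peptidase -1 sites).
SIGNAL_CUT_RESIDUES <- c("A", "G", "S", "C", "T")

#' Find the longest open reading frame in a directional cDNA read
#'
#' Scans the three forward frames (the library is directional) for the
#' longest ATG-to-stop open reading frame under the standard genetic code.
#' Ties are broken by the earliest start position.
#'
#' @param nt_sequence nucleotide string (A, C, G, T, N).
#' @param min_codons minimum ORF length in codons including the start
#'   (default 30); shorter ORFs are reported as absent.
#' @return List: `aa` (translated sequence without the stop), `frame` (1-3),
#'   `start`, `end` (1-based nucleotide coordinates of ATG..stop), or `NULL`
#'   when no qualifying ORF exists.
#' @export
find_orf <- function(nt_sequence, min_codons = 30L) {
  stopifnot(is.character(nt_sequence), length(nt_sequence) == 1L)
  s <- toupper(nt_sequence)
  if (grepl("[^ACGTN]", s)) stop("non-nucleotide character in sequence")
  n <- nchar(s)
  best <- NULL
  for (frame in 1:3) {
    codon_starts <- seq.int(frame, n - 2L, by = 3L)
    if (length(codon_starts) == 0L) next
    codons <- substring(s, codon_starts, codon_starts + 2L)
    aa <- translate_codons(codons)
    open_at <- NA_integer_
    for (k in seq_along(aa)) {
      if (is.na(open_at) && aa[k] == "M") open_at <- k
      if (!is.na(open_at) && aa[k] == "*") {
        len <- k - open_at  # codons excluding stop
        if (len >= min_codons &&
            (is.null(best) || len > best$len ||
             (len == best$len && codon_starts[open_at] < best$start))) {
          best <- list(len = len,
                       aa = paste(aa[open_at:(k - 1L)], collapse = ""),
                       frame = frame,
                       start = codon_starts[open_at],
                       end = codon_starts[k] + 2L)
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.null(best)) return(NULL)
  best[c("aa", "frame", "start", "end")]
}

# Translate codons under the standard genetic code; codons containing N
# translate to X (never M or *, so they cannot open or close an ORF).
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Split a precursor into signal peptide and remainder
#'
#' With an externally predicted site (e.g. from SignalP) the cut is applied
#' after validating it lies in the canonical 16-25 residue range. Without
#' one, a closed-loop heuristic picks the cut position in 16..25 that
#' maximizes the mean Kyte-Doolittle hydropathy of the prefix, subject to
#' the residue at the cut being a small residue (A, G, S, C, T); ties go to
#' the smallest position. The heuristic exists so synthetic round-trip
#' tests run without an external predictor; real analyses should supply
#' predicted sites.
#'
#' @param precursor_aa amino-acid precursor sequence (length > 35).
#' @param site optional externally predicted signal length.
#' @return List `signal`, `remainder`, `site`; or `NULL` (flag
#'   "unparsed-signal") when no admissible cut exists.
#' @export
split_signal <- function(precursor_aa, site = NULL) {
  stopifnot(nchar(precursor_aa) > 35L)
  chars <- strsplit(precursor_aa, "", fixed = TRUE)[[1]]
  if (!is.null(site)) {
    site <- as.integer(site)
    if (site < 16L || site > 25L)
      stop("signal site ", site, " outside the canonical 16-25 range")
  } else {
    cand <- 16:25
    cand <- cand[cand < length(chars)]
    cand <- cand[chars[cand] %in% SIGNAL_CUT_RESIDUES]
    if (length(cand) == 0L) return(NULL)
    hyd <- vapply(cand, function(p) mean(KYTE_DOOLITTLE[chars[1:p]]), 0)
    site <- cand[which.max(hyd)]  # which.max takes the first = smallest pos
  }
  list(signal = substr(precursor_aa, 1L, site),
       remainder = substr(precursor_aa, site + 1L, nchar(precursor_aa)),
       site = site)
}

#' Locate the propeptide/mature boundary by the Processing Quadruplet Motif
#'
#' The PQM is operationalized as an arginine at the cleavage position with
#' at least one acidic residue (glutamate by default) among the three
#' preceding residues. Positions 12..38 of the remainder (the admissible
#' propeptide length range) are scanned and the *last* qualifying position
#' is taken. If cleaving there would leave a mature peptide shorter than
#' `min_mature` residues, or no position qualifies, the precursor is
#' reported as having no propeptide (families whose precursors go straight
#' from signal to mature).
#'
#' @param remainder_aa sequence following the signal peptide.
#' @param acidic acidic residue set preceding the arginine; `"E"` (default)
#'   or `c("E", "D")`.
#' @param min_len,max_len admissible propeptide length bounds (12, 38).
#' @param min_mature minimum mature length for a cut to be accepted (33).
#' @return List `propeptide`, `mature`, `site`; `site = 0` and empty
#'   propeptide when there is none.
#' @export
find_pqm_cleavage <- function(remainder_aa, acidic = "E",
                              min_len = 12L, max_len = 38L,
                              min_mature = 33L) {
  stopifnot(nzchar(remainder_aa))
  chars <- strsplit(remainder_aa, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hi <- min(max_len, n)
  site <- 0L
  if (hi >= min_len) {
    for (p in seq.int(min_len, hi)) {
      if (chars[p] != "R") next
      win <- chars[max(1L, p - 3L):(p - 1L)]
      if (!any(win %in% acidic)) next
      if (n - p < min_mature) next  # mature length bound is a hard constraint
      site <- p
    }
  }
  list(propeptide = substr(remainder_aa, 1L, site),
       mature = substr(remainder_aa, site + 1L, n),
       site = site)
}

#' Detect and trim a C-terminal amidation signal
#'
#' Mature toxins ending in `G`, `GK` or `GR` are processed to an amidated
#' C-terminus; the signal residues are trimmed from the genetic sequence.
#' Two-letter signals take precedence over the single `G`.
#'
#' @param mature_aa mature peptide sequence (length >= 4).
#' @return List `mature` (processed), `amidated`, `trimmed_tail` (one of
#'   `""`, `"G"`, `"GK"`, `"GR"`).
#' @export
detect_amidation <- function(mature_aa) {
  stopifnot(nchar(mature_aa) >= 4L)
  n <- nchar(mature_aa)
  last2 <- substr(mature_aa, n - 1L, n)
  last1 <- substr(mature_aa, n, n)
  if (last2 %in% c("GK", "GR")) {
    list(mature = substr(mature_aa, 1L, n - 2L), amidated = TRUE,
         trimmed_tail = last2)
  } else if (last1 == "G") {
    list(mature = substr(mature_aa, 1L, n - 1L), amidated = TRUE,
         trimmed_tail = "G")
  } else {
    list(mature = mature_aa, amidated = FALSE, trimmed_tail = "")
  }
}

#' Parse a toxin precursor into its processing regions
#'
#' Applies [split_signal()], [find_pqm_cleavage()] and [detect_amidation()]
#' in turn and returns a `toxin_precursor` with 1-based inclusive region
#' coordinates that tile the precursor exactly.
#'
#' @param aa_sequence full precursor amino-acid sequence.
#' @param id identifier.
#' @param signal_site optional externally predicted signal length.
#' @param acidic acidic set for the PQM rule.
#' @return Object of class `toxin_precursor` with fields `id`,
#'   `aa_sequence`, `signal_range`, `propeptide_range` (NULL if absent),
#'   `mature_range` (pre-trim), `mature` (processed sequence), `amidated`,
#'   `trimmed_tail`; or `NULL` when the signal cannot be parsed.
#' @export
parse_precursor <- function(aa_sequence, id = NA_character_,
                            signal_site = NULL, acidic = "E") {
  sp <- split_signal(aa_sequence, site = signal_site)
  if (is.null(sp)) return(NULL)
  pq <- find_pqm_cleavage(sp$remainder, acidic = acidic)
  am <- detect_amidation(pq$mature)
  sig_end <- sp$site
  pro_end <- sig_end + pq$site
  n <- nchar(aa_sequence)
  structure(list(
    id = id,
    aa_sequence = aa_sequence,
    signal_range = c(1L, sig_end),
    propeptide_range = if (pq$site > 0L) c(sig_end + 1L, pro_end) else NULL,
    mature_range = c(pro_end + 1L, n),
    mature = am$mature,
    amidated = am$amidated,
    trimmed_tail = am$trimmed_tail
  ), class = "toxin_precursor")
}

#' @export
print.toxin_precursor <- function(x, ...) {
  cat("<toxin_precursor> ", x$id, "\n",
      "  signal    ", x$signal_range[1], "-", x$signal_range[2], "\n", sep = "")
  if (!is.null(x$propeptide_range))
    cat("  propeptide ", x$propeptide_range[1], "-", x$propeptide_range[2],
        "\n", sep = "")
  cat("  mature    ", x$mature_range[1], "-", x$mature_range[2],
      if (x$amidated) paste0("  (amidated, -", x$trimmed_tail, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Annotate a set of toxin ESTs or precursor sequences
#'
#' For nucleotide input each record is translated via [find_orf()]; records
#' without a qualifying ORF are skipped and listed. Amino-acid input is
#' parsed directly. The alphabet is auto-detected.
#'
#' @param sequences named character vector of nucleotide or amino-acid
#'   sequences.
#' @param signal_sites optional named integer vector of external signal
#'   predictions (by record id).
#' @param acidic acidic set for the PQM rule.
#' @return List: `precursors` (list of `toxin_precursor`), `table`
#'   (data.frame: id, signal/pro/mature coordinates, amidation, tail,
#'   mature sequence), `skipped` (ids without ORF or signal).
#' @export
annotate_precursors <- function(sequences, signal_sites = NULL, acidic = "E") {
  stopifnot(!is.null(names(sequences)))
  is_nt <- !grepl("[^ACGTNacgtn]", sequences)
  precursors <- list(); skipped <- character(0)
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    aa <- if (is_nt[i]) {
      orf <- find_orf(sequences[[i]])
      if (is.null(orf)) { skipped <- c(skipped, id); next }
      orf$aa
    } else toupper(sequences[[i]])
    site <- if (!is.null(signal_sites) && id %in% names(signal_sites))
      signal_sites[[id]] else NULL
    p <- tryCatch(parse_precursor(aa, id = id, signal_site = site,
                                  acidic = acidic),
                  error = function(e) NULL)
    if (is.null(p)) { skipped <- c(skipped, id); next }
    precursors[[id]] <- p
  }
  tab <- do.call(rbind, lapply(precursors, function(p) data.frame(
    id = p$id,
    signal_start = p$signal_range[1], signal_end = p$signal_range[2],
    pro_start = if (is.null(p$propeptide_range)) NA_integer_ else p$propeptide_range[1],
    pro_end = if (is.null(p$propeptide_range)) NA_integer_ else p$propeptide_range[2],
    mature_start = p$mature_range[1], mature_end = p$mature_range[2],
    amidated = p$amidated, trimmed_tail = p$trimmed_tail,
    mature = p$mature, stringsAsFactors = FALSE)))
  if (is.null(tab)) tab <- data.frame()
  rownames(tab) <- NULL
  list(precursors = precursors, table = tab, skipped = skipped)
}
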