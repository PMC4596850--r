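# Residue mass tables (Da). Monoisotopic and average masses of amino-acid
# residues (i.e. minus water); peptide mass = sum(residues) + water.
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MONO <- 18.010565
WATER_AVG <- 18.0153
# Loss per disulfide bond (2 H) and for C-terminal amidation (OH -> NH2).
SS_LOSS_MONO <- 2.015650
SS_LOSS_AVG <- 2.0159
AMIDE_LOSS_MONO <- 0.984016
AMIDE_LOSS_AVG <- 0.9847

#' Theoretical peptide mass
#'
#' Mass of a linear peptide as the sum of residue masses plus water, with
#' optional disulfide bonds (loss of 2 H each) and C-terminal amidation
#' (OH -> NH2, loss of 0.98 Da). Average mass is the MALDI-TOF linear-mode
#' default for 3-9 kDa toxins; monoisotopic mass is available for
#' high-resolution comparisons.
#'
#' @param aa_sequence amino-acid string over the 20 standard residues.
#' @param mode `"average"` (default) or `"mono"`.
#' @param n_disulfides number of disulfide bonds formed (each removes two
#'   hydrogens); must not exceed `floor(n_cys / 2)`.
#' @param amidated logical; `TRUE` applies the C-terminal amide correction.
#' @return mass in Daltons.
#' @examples
#' peptide_mass("G")                       # 75.07 Da
#' peptide_mass("GG", mode = "mono")       # 132.0535 Da
#' @export
peptide_mass <- function(aa_sequence, mode = c("average", "mono"),
                         n_disulfides = 0L, amidated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1L,
            nzchar(aa_sequence))
  chars <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  tab <- if (mode == "mono") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  m <- tab[chars]
  if (anyNA(m))
    stop("unknown residue ", sQuote(chars[which(is.na(m))[1]]),
         " at position ", which(is.na(m))[1])
  n_cys <- sum(chars == "C")
  n_disulfides <- as.integer(n_disulfides)
  if (n_disulfides < 0L || n_disulfides > n_cys %/% 2L)
    stop("n_disulfides (", n_disulfides, ") exceeds cysteine capacity (",
         n_cys %/% 2L, ")")
  water <- if (mode == "mono") WATER_MONO else WATER_AVG
  ss <- if (mode == "mono") SS_LOSS_MONO else SS_LOSS_AVG
  amide <- if (mode == "mono") AMIDE_LOSS_MONO else AMIDE_LOSS_AVG
  sum(m) + water - n_disulfides * ss - (if (isTRUE(amidated)) amide else 0)
}

#' pKa sets for isoelectric-point calculation
#'
#' `"bjellqvist"` (default) is the peptide-calibrated table used by common
#' proteomics tools; `"lehninger"` uses free-amino-acid textbook values
#' (glycine pI 5.97 under this set). Each set lists side-chain pKa values
#' for the ionizable residues plus the terminal amine and carboxyl.
#'
#' @param name `"bjellqvist"` or `"lehninger"`.
#' @return Named list with elements `positive` (named pKa vector including
#'   `Nterm`) and `negative` (named pKa vector including `Cterm`).
#' @export
pka_set <- function(name = c("bjellqvist", "lehninger")) {
  name <- match.arg(name)
  tab <- switch(name,
    bjellqvist = list(
      positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
      negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)),
    lehninger = list(
      positive = c(Nterm = 9.60, K = 10.53, R = 12.48, H = 6.00),
      negative = c(Cterm = 2.34, D = 3.65, E = 4.25, C = 8.33, Y = 10.07)))
  attr(tab, "name") <- name
  tab
}

#' Isoelectric point by charge bisection
#'
#' Net charge at a given pH is the Henderson-Hasselbalch sum of positive
#' group fractions minus negative group fractions; the pI is found by
#' bisection on pH in \[0, 14\] to |Z| < 1e-4. The function depends only on
#' residue composition, not order.
#'
#' @param aa_sequence amino-acid string.
#' @param pka a set from [pka_set()] or a set name.
#' @return pH units; the pKa set used is attached as attribute `"pka_set"`.
#' @export
compute_pi <- function(aa_sequence, pka = pka_set("bjellqvist")) {
  if (is.character(pka)) pka <- pka_set(pka)
  stopifnot(nzchar(aa_sequence))
  chars <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  counts <- table(chars)
  pos <- pka$positive; neg <- pka$negative
  n_pos <- c(Nterm = 1, vapply(setdiff(names(pos), "Nterm"),
                               function(a) counts[a][[1]] %||% 0, 0))
  names(n_pos) <- names(pos)
  n_neg <- c(Cterm = 1, vapply(setdiff(names(neg), "Cterm"),
                               function(a) counts[a][[1]] %||% 0, 0))
  names(n_neg) <- names(neg)
  n_pos[is.na(n_pos)] <- 0; n_neg[is.na(n_neg)] <- 0

  charge <- function(ph) {
    sum(n_pos / (1 + 10^(ph - pos))) - sum(n_neg / (1 + 10^(neg - ph)))
  }
  lo <- 0; hi <- 14
  # Z(pH) is strictly decreasing; bisect until |Z| < 1e-4
  repeat {
    mid <- (lo + hi) / 2
    z <- charge(mid)
    if (abs(z) < 1e-4 || (hi - lo) < 1e-10) break
    if (z > 0) lo <- mid else hi <- mid
  }
  structure(mid, pka_set = attr(pka, "name"))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Match calculated peptide masses to an observed mass list
#'
#' Greedy one-to-one closest matching: candidate (peptide, observed) pairs
#' are ranked by ascending absolute mass difference (ties broken by peptide
#' id, then observed mass) and accepted while both sides are unassigned and
#' the difference is within tolerance. This emulates reconciling
#' cDNA-deduced theoretical masses with a MALDI-TOF mass list; unmatched
#' entries are reported (low-abundance peptides or unmodelled PTMs).
#'
#' @param calculated data.frame with columns `id`, `mass` (Da), or a named
#'   numeric vector.
#' @param observed numeric vector of observed masses (Da).
#' @param tolerance maximum |delta| accepted, in Da (default 1.0).
#' @return List with `matches` (data.frame: peptide_id, calculated, observed,
#'   delta, within_tolerance), `unmatched_peptides`, `unmatched_observed`.
#' @export
match_masses <- function(calculated, observed, tolerance = 1.0) {
  stopifnot(tolerance > 0)
  if (is.numeric(calculated))
    calculated <- data.frame(id = names(calculated), mass = unname(calculated),
                             stringsAsFactors = FALSE)
  stopifnot(all(c("id", "mass") %in% names(calculated)))
  observed <- as.numeric(observed)
  empty <- data.frame(peptide_id = character(0), calculated = numeric(0),
                      observed = numeric(0), delta = numeric(0),
                      within_tolerance = logical(0), stringsAsFactors = FALSE)
  if (nrow(calculated) == 0L || length(observed) == 0L)
    return(list(matches = empty,
                unmatched_peptides = calculated$id,
                unmatched_observed = observed))

  cand <- expand.grid(pi_ = seq_len(nrow(calculated)),
                      oi = seq_along(observed))
  cand$delta <- abs(calculated$mass[cand$pi_] - observed[cand$oi])
  cand <- cand[cand$delta <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$delta, calculated$id[cand$pi_],
                     observed[cand$oi]), , drop = FALSE]
  used_p <- logical(nrow(calculated)); used_o <- logical(length(observed))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    p <- cand$pi_[r]; o <- cand$oi[r]
    if (used_p[p] || used_o[o]) next
    used_p[p] <- TRUE; used_o[o] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_id = calculated$id[p],
      calculated = calculated$mass[p],
      observed = observed[o],
      delta = observed[o] - calculated$mass[p],
      within_tolerance = TRUE, stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else empty
  list(matches = matches,
       unmatched_peptides = calculated$id[!used_p],
       unmatched_observed = observed[!used_o])
}
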