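#' Cysteine pattern of a mature peptide
#'
#' A `cys_pattern` records the ordered spacing of cysteine residues along a
#' mature toxin: the number of cysteines, the inter-cysteine gaps, and the
#' lengths of the leading/trailing non-cysteine context. Each gap is an exact
#' integer, an integer set (alternative spacings observed across a family,
#' written `x4/8` in pattern notation), or variable (`NA`, written as a bare
#' hyphen or `xn`).
#'
#' @param n_cys integer, number of cysteines (>= 1).
#' @param gaps list of length `n_cys - 1`; each element an integer vector
#'   (length 1 = exact gap, length > 1 = alternative set) or `NA` (variable).
#' @param lead,trail length of sequence context before the first / after the
#'   last cysteine; integer or `NA` for variable/unspecified.
#' @param acyclic logical; `TRUE` marks peptides with fewer than two
#'   cysteines, which carry no pattern and are excluded from scaffold
#'   grouping.
#' @return An object of class `cys_pattern`.
#' @export
cys_pattern <- function(n_cys, gaps, lead = NA_integer_, trail = NA_integer_,
                        acyclic = FALSE) {
  n_cys <- as.integer(n_cys)
  if (!acyclic && length(gaps) != n_cys - 1L)
    stop("need exactly n_cys - 1 gaps, got ", length(gaps))
  gaps <- lapply(gaps, function(g) {
    if (length(g) == 1L && is.na(g)) return(NA_integer_)
    g <- sort(unique(as.integer(g)))
    if (any(g < 0L)) stop("gaps must be >= 0")
    g
  })
  structure(
    list(n_cys = n_cys, gaps = gaps,
         lead = as.integer(lead), trail = as.integer(trail),
         acyclic = isTRUE(acyclic)),
    class = "cys_pattern"
  )
}

#' @export
print.cys_pattern <- function(x, ...) {
  if (x$acyclic) {
    cat("<cys_pattern> acyclic (", x$n_cys, " cysteine)\n", sep = "")
  } else {
    cat("<cys_pattern> ", x$n_cys, " cysteines: ",
        format_pattern(x), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the cysteine pattern of a mature peptide sequence
#'
#' Scans the amino-acid sequence for cysteine positions and records the exact
#' inter-cysteine gaps together with the leading and trailing context lengths.
#'
#' @param mature_aa single amino-acid string.
#' @return A [cys_pattern]. Sequences with fewer than two cysteines are
#'   flagged `acyclic`.
#' @examples
#' extract_pattern("CAAC")      # gaps = 2
#' extract_pattern("CACAACCA")  # gaps = 1, 2, 0
#' @export
extract_pattern <- function(mature_aa) {
  stopifnot(is.character(mature_aa), length(mature_aa) == 1L)
  chars <- strsplit(toupper(mature_aa), "", fixed = TRUE)[[1]]
  pos <- which(chars == "C")
  n <- length(pos)
  if (n < 2L)
    return(cys_pattern(n, list(), lead = NA, trail = NA, acyclic = TRUE))
  gaps <- as.list(diff(pos) - 1L)
  cys_pattern(n, gaps,
              lead = pos[1L] - 1L,
              trail = length(chars) - pos[n])
}

# Normalize the notation dialect: unicode dashes and minus signs to "-",
# subscript underscores and whitespace removed, upper-case X to x.
normalize_pattern_string <- function(s) {
  s <- gsub("[‒–—―−]", "-", s)
  s <- gsub("[[:space:]_]", "", s)
  s <- gsub("X", "x", s)
  s
}

#' Parse cysteine-pattern notation
#'
#' Parses the pattern notation used for spider-toxin cysteine frameworks,
#' e.g. `"-Cx6-Cx3-Cx-CCx6-Cx5-Cx7-Cx6-Cx6-C-"` or the spacer-free
#' discussion style `"C-C-CC-CXC-CXC-"`. Tokens: `C` a cysteine; `xN` exactly
#' N residues; `xA/B` either A or B residues; bare `x` (or `X`) one residue;
#' `xn` a variable number; a hyphen between cysteines with no `x` token is a
#' variable gap. Hyphens next to `x` tokens are separators only. En/em
#' dashes, minus signs, underscores and whitespace are normalized away
#' before parsing.
#'
#' @param notation single pattern string.
#' @return A [cys_pattern].
#' @seealso [format_pattern()] for the inverse rendering.
#' @export
parse_pattern_string <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  s <- normalize_pattern_string(notation)
  if (!nzchar(s)) stop("empty pattern string")

  # tokenize: C | x[digits[/digits]] | x n | -
  toks <- list(); i <- 1L; n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  while (i <= n) {
    ch <- chars[i]
    if (ch == "C") { toks[[length(toks) + 1L]] <- list(t = "C"); i <- i + 1L }
    else if (ch == "-") { toks[[length(toks) + 1L]] <- list(t = "-"); i <- i + 1L }
    else if (ch == "x") {
      j <- i + 1L
      if (j <= n && chars[j] == "n") {
        toks[[length(toks) + 1L]] <- list(t = "x", v = NA_integer_)
        i <- j + 1L
      } else {
        num <- ""
        while (j <= n && grepl("[0-9/]", chars[j])) { num <- paste0(num, chars[j]); j <- j + 1L }
        if (!nzchar(num)) {
          toks[[length(toks) + 1L]] <- list(t = "x", v = 1L)
        } else {
          parts <- strsplit(num, "/", fixed = TRUE)[[1]]
          if (!all(grepl("^[0-9]+$", parts)))
            stop("malformed pattern token at offset ", i, " in ", sQuote(notation))
          toks[[length(toks) + 1L]] <- list(t = "x", v = as.integer(parts))
        }
        i <- j
      }
    } else {
      stop("malformed pattern token ", sQuote(ch), " at offset ", i,
           " in ", sQuote(notation))
    }
  }

  types <- vapply(toks, `[[`, "", "t")
  cys_idx <- which(types == "C")
  n_cys <- length(cys_idx)
  if (n_cys < 1L) stop("pattern string contains no cysteine")

  # segment = tokens between consecutive C's (and before first / after last)
  segment_gap <- function(lo, hi) {
    if (hi < lo) return(0L)  # adjacent C's
    seg <- toks[lo:hi]
    xs <- seg[vapply(seg, `[[`, "", "t") == "x"]
    if (length(xs) == 0L) return(NA_integer_)  # hyphen-only: variable
    vals <- lapply(xs, `[[`, "v")
    if (any(vapply(vals, function(v) any(is.na(v)), TRUE)))
      return(NA_integer_)                      # contains xn: variable
    sets <- vals[vapply(vals, length, 1L) > 1L]
    if (length(sets) > 1L)
      stop("at most one alternative-set token allowed per gap")
    base <- sum(vapply(vals[vapply(vals, length, 1L) == 1L], identity, 1L))
    if (length(sets) == 1L) base + sets[[1]] else base
  }

  gaps <- if (n_cys >= 2L) {
    lapply(seq_len(n_cys - 1L), function(k)
      segment_gap(cys_idx[k] + 1L, cys_idx[k + 1L] - 1L))
  } else list()

  lead_seg <- if (cys_idx[1] > 1L) segment_gap(1L, cys_idx[1] - 1L) else 0L
  trail_seg <- if (cys_idx[n_cys] < length(toks))
    segment_gap(cys_idx[n_cys] + 1L, length(toks)) else 0L
  lead <- if (length(lead_seg) == 1L) lead_seg else NA_integer_
  trail <- if (length(trail_seg) == 1L) trail_seg else NA_integer_

  cys_pattern(n_cys, gaps, lead = lead, trail = trail,
              acyclic = n_cys < 2L)
}

#' Render a cysteine pattern in standard notation
#'
#' Inverse of [parse_pattern_string()] up to dash/whitespace dialect:
#' `parse_pattern_string(format_pattern(p))` reproduces `p`.
#'
#' @param pattern a [cys_pattern].
#' @return single string, e.g. `"-Cx6-Cx3-Cx-CCx6-C"`.
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "cys_pattern"))
  if (pattern$acyclic) stop("acyclic pattern has no rendering")
  gap_tok <- function(g) {
    if (length(g) == 1L && is.na(g)) return("-")
    if (length(g) > 1L) return(paste0("x", paste(g, collapse = "/")))
    if (g == 0L) return("")
    paste0("x", g)
  }
  lead <- if (is.na(pattern$lead)) "-" else if (pattern$lead > 0L)
    paste0("x", pattern$lead, "-") else ""
  trail <- if (is.na(pattern$trail)) "-" else if (pattern$trail > 0L)
    paste0("-x", pattern$trail) else ""
  mid <- "C"
  for (g in pattern$gaps) {
    tok <- gap_tok(g)
    sep <- if (tok == "" || tok == "-") "" else "-"
    mid <- paste0(mid, tok, sep, "C")
  }
  paste0(lead, mid, trail)
}

#' Canonicalize a cysteine pattern to its spacer-free skeleton
#'
#' Collapses every gap to one of three classes: `adjacent` (0 residues,
#' rendered `CC`), `single` (1 residue, rendered `CXC`) and `variable`
#' (2 or more, an alternative set with minimum >= 2, or unspecified;
#' rendered as a hyphen). Two patterns share a scaffold when their gap-class
#' sequences and cysteine counts agree; this is the grouping under which
#' toxin families with different numeric spacers collapse onto a common
#' framework.
#'
#' @param pattern a [cys_pattern].
#' @return Object of class `cys_skeleton` with fields `n_cys`,
#'   `gap_classes` (character vector over adjacent/single/variable) and
#'   `rendering` (e.g. `"C-C-CC-CXC-CXC"`).
#' @export
skeletonize <- function(pattern) {
  stopifnot(inherits(pattern, "cys_pattern"))
  if (pattern$acyclic) stop("cannot skeletonize an acyclic pattern")
  classify <- function(g) {
    if (length(g) == 1L && is.na(g)) return("variable")
    cls <- ifelse(g == 0L, "adjacent", ifelse(g == 1L, "single", "variable"))
    u <- unique(cls)
    if (length(u) > 1L)
      stop("gap set {", paste(g, collapse = ","),
           "} mixes skeleton classes; cannot canonicalize")
    u
  }
  classes <- vapply(pattern$gaps, classify, "")
  rendering <- "C"
  for (cl in classes) {
    rendering <- paste0(rendering,
                        switch(cl, adjacent = "C", single = "XC",
                               variable = "-C"))
  }
  structure(list(n_cys = pattern$n_cys, gap_classes = classes,
                 rendering = rendering),
            class = "cys_skeleton")
}

#' @export
print.cys_skeleton <- function(x, ...) {
  cat("<cys_skeleton> ", x$n_cys, " cysteines: ", x$rendering, "\n", sep = "")
  invisible(x)
}

#' @export
format.cys_skeleton <- function(x, ...) x$rendering

# Equality key: gap-class sequence plus cysteine count, so frameworks with
# the same class string but different C counts never merge.
skeleton_key <- function(skel) {
  paste0(skel$n_cys, ":", paste(skel$gap_classes, collapse = ","))
}

#' Count distinct cysteine skeletons
#'
#' Groups patterns by skeleton identity (gap-class sequence and cysteine
#' count) in order of first occurrence.
#'
#' @param patterns list of [cys_pattern] objects (or strings, which are
#'   parsed).
#' @return List with `n_distinct`, `groups` (integer group index per input)
#'   and `skeletons` (one `cys_skeleton` per group, first-occurrence order).
#' @export
count_distinct_skeletons <- function(patterns) {
  if (length(patterns) == 0L)
    return(list(n_distinct = 0L, groups = integer(0), skeletons = list()))
  patterns <- lapply(patterns, function(p)
    if (is.character(p)) parse_pattern_string(p) else p)
  skels <- lapply(patterns, skeletonize)
  keys <- vapply(skels, skeleton_key, "")
  uk <- unique(keys)
  list(n_distinct = length(uk),
       groups = match(keys, uk),
       skeletons = skels[match(uk, keys)])
}

#' Detect the Principal Structural Motif (PSM)
#'
#' PSM requires exactly six residues between the first and second cysteines
#' and none between the third and fourth. It is a hallmark of ion-channel
#' blocking spider toxins.
#'
#' @param pattern a [cys_pattern].
#' @return logical flag. Patterns with fewer than four cysteines are `FALSE`
#'   with a warning.
#' @export
detect_psm <- function(pattern) {
  stopifnot(inherits(pattern, "cys_pattern"))
  if (pattern$acyclic || pattern$n_cys < 4L) {
    warning("PSM requires at least 4 cysteines")
    return(FALSE)
  }
  g1 <- pattern$gaps[[1L]]; g3 <- pattern$gaps[[3L]]
  ok1 <- !all(is.na(g1)) && 6L %in% g1
  ok3 <- !all(is.na(g3)) && 0L %in% g3
  ok1 && ok3
}

#' Detect the Extra Structural Motif (ESM)
#'
#' ESM is a pair of `CXC` fragments (single-residue gaps) in the C-terminal
#' region of the cysteine framework. The C-terminal region is taken as the
#' trailing `region_fraction` of the framework: gaps whose left cysteine
#' index exceeds `n_cys * (1 - region_fraction)`.
#'
#' @param pattern a [cys_pattern].
#' @param region_fraction fraction of the framework counted as C-terminal
#'   (default 0.5).
#' @return logical flag.
#' @export
detect_esm <- function(pattern, region_fraction = 0.5) {
  stopifnot(inherits(pattern, "cys_pattern"))
  if (pattern$acyclic || pattern$n_cys < 4L) return(FALSE)
  cutoff <- pattern$n_cys * (1 - region_fraction)
  singles <- 0L
  for (i in seq_along(pattern$gaps)) {
    if (i <= cutoff) next
    g <- pattern$gaps[[i]]
    if (!all(is.na(g)) && identical(g, 1L)) singles <- singles + 1L
  }
  singles >= 2L
}

#' Maximum number of disulfide bonds
#'
#' @param n_cys cysteine count (or a [cys_pattern]).
#' @return `floor(n_cys / 2)`.
#' @export
max_disulfides <- function(n_cys) {
  if (inherits(n_cys, "cys_pattern")) n_cys <- n_cys$n_cys
  as.integer(n_cys %/% 2L)
}

#' Physicochemical profile of a mature peptide
#'
#' Summarizes a mature toxin: length, cysteine count, maximum disulfides,
#' monoisotopic and average mass (fully reduced, free acid), isoelectric
#' point, PSM/ESM flags, pattern and skeleton renderings.
#'
#' @param mature_aa amino-acid string.
#' @param id optional identifier carried into the result.
#' @return One-row data.frame.
#' @export
mature_profile <- function(mature_aa, id = NA_character_) {
  pat <- extract_pattern(mature_aa)
  acyclic <- pat$acyclic
  psm <- if (!acyclic && pat$n_cys >= 4L) detect_psm(pat) else FALSE
  esm <- if (!acyclic) detect_esm(pat) else FALSE
  data.frame(
    id = id,
    length = nchar(mature_aa),
    n_cys = pat$n_cys,
    max_ss = max_disulfides(pat$n_cys),
    mono_mass = peptide_mass(mature_aa, mode = "mono"),
    avg_mass = peptide_mass(mature_aa, mode = "average"),
    pi = compute_pi(mature_aa),
    psm = psm,
    esm = esm,
    acyclic = acyclic,
    pattern = if (acyclic) NA_character_ else format_pattern(pat),
    skeleton = if (acyclic) NA_character_ else skeletonize(pat)$rendering,
    stringsAsFactors = FALSE
  )
}

#' Printed cysteine patterns of the Dolomedes toxin families
#'
#' The eight family consensus patterns (A-H) reported for the
#' *D. sulfurous* venom-gland library, plus the two spacer-free skeletons
#' observed only in *D. mizhoanus* toxins. These strings are inputs for the
#' cross-species skeleton census: the eight family patterns collapse to five
#' distinct skeletons (B = D, E = F, G = H) and the two *D. mizhoanus*
#' specific skeletons bring the total to seven.
#'
#' @return Named character vector of pattern strings (names `A`..`H`).
#' @export
dolomedes_family_patterns <- function() {
  c(A = "-Cx7-Cx8-CCx4-Cx5-CCx3-Cx3-Cx17-C-",
    B = "-Cx6C-CC-CxC-CxC-",
    C = "-Cx6-Cx3-Cx-CCx6-Cx5-Cx7-Cx6-Cx6-C-",
    D = "Cx6-Cx6-CCx4/8-CxC-x6/7-CxC-",
    E = "-Cx6-Cx3-Cx-CC-x5-CxC-x10-CxC-x7-Cx6-Cx7-Cxn-",
    F = "-Cx6-Cx3/4-Cx-CC-x5/6-CxC-x6/7-CxC-x7-Cx6-Cx6/12-Cxn-",
    G = "-Cx5-Cx4-CC-x8-C-x9-C-x12-CxC-x5-C-x5-C-",
    H = "Cx5-Cx4-CC-x10-Cx9-Cx16-CxC-x5-Cx18-Cxn")
}

#' @rdname dolomedes_family_patterns
#' @export
mizhoanus_specific_skeletons <- function() {
  c(IV = "C-CXC-CXC-CXC-C-C-C",
    V  = "C-C-C-CC-CXC-CXC-C")
}
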