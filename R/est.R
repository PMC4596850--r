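#' Trim a polyA tail
#'
#' Removes the maximal trailing run of `A` when it is at least `min_tail`
#' long; shorter runs are left untouched. A read that is entirely tail
#' becomes empty and is flagged.
#'
#' @param sequence nucleotide string (or vector of them).
#' @param min_tail minimum tail length to trim (default 6).
#' @return Character vector of trimmed sequences; attribute `"empty"` marks
#'   reads that were all tail.
#' @export
trim_polya <- function(sequence, min_tail = 6L) {
  stopifnot(min_tail >= 1L)
  trim1 <- function(s) {
    m <- regmatches(s, regexpr("A+$", s))
    if (length(m) == 1L && nchar(m) >= min_tail)
      substr(s, 1L, nchar(s) - nchar(m)) else s
  }
  out <- vapply(toupper(sequence), trim1, "", USE.NAMES = FALSE)
  names(out) <- names(sequence)
  attr(out, "empty") <- !nzchar(out)
  out
}

#' Length and quality filtering of ESTs
#'
#' Keeps reads strictly longer than `min_len` nucleotides (clone selection
#' used cDNA length > 400 bp) with an ambiguity fraction of at most
#' `max_n_frac` `N` bases, standing in for chromatogram quality screening.
#'
#' @param sequences named character vector of (trimmed) reads.
#' @param min_len strict lower length bound (default 400).
#' @param max_n_frac maximum fraction of `N` bases (default 0.05).
#' @return List `kept` (named character vector) and `discarded` (data.frame
#'   id/reason log).
#' @export
filter_length <- function(sequences, min_len = 400L, max_n_frac = 0.05) {
  len <- nchar(sequences)
  n_frac <- ifelse(len > 0,
                   vapply(gregexpr("N", sequences, fixed = TRUE),
                          function(m) sum(m > 0), 0) / pmax(len, 1L), 1)
  too_short <- len <= min_len
  too_ambiguous <- !too_short & n_frac > max_n_frac
  keep <- !too_short & !too_ambiguous
  discarded <- data.frame(
    id = names(sequences)[!keep] %||char% character(0),
    reason = c("length", "ambiguity")[1L + too_ambiguous[!keep]],
    stringsAsFactors = FALSE)
  list(kept = sequences[keep], discarded = discarded)
}

`%||char%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
    "", USE.NAMES = FALSE))
}

# Candidate pairs by shared k-mers (either orientation), then ungapped
# identity at the most frequent shared-k-mer diagonal.
kmer_candidates <- function(seqs, k) {
  tabs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]; n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    kmers <- unique(substring(s, starts, starts + k - 1L))
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (!length(kmers)) return(NULL)
    data.frame(kmer = kmers, i = i, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) == 0L) return(matrix(integer(0), ncol = 2))
  pairs <- lapply(split(tab$i, tab$kmer), function(members) {
    if (length(members) < 2L) return(NULL)
    t(utils::combn(sort(members), 2L))
  })
  out <- unique(do.call(rbind, pairs))
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Best ungapped identity between two reads over shared-k-mer diagonals,
# in the given orientation.
pair_identity <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(list(identity = 0, overlap = 0L))
  sa <- seq_len(na - k + 1L); sb <- seq_len(nb - k + 1L)
  ka <- substring(a, sa, sa + k - 1L)
  kb <- substring(b, sb, sb + k - 1L)
  shared <- intersect(ka, kb)
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0L) return(list(identity = 0, overlap = 0L))
  offs <- unique(unlist(lapply(shared, function(km) {
    pa <- sa[ka == km][1L]; pb <- sb[kb == km][1L]
    pa - pb
  })))
  best <- list(identity = 0, overlap = 0L)
  for (off in offs) {
    r <- .ungapped_identity(a, b, off)
    if (r$identity > best$identity ||
        (r$identity == best$identity && r$overlap > best$overlap)) best <- r
  }
  best
}

#' Cluster ESTs by sequence identity
#'
#' Single-linkage clustering: two reads are joined when their best ungapped
#' overlap (in either orientation; candidate offsets from shared k-mers)
#' reaches `identity_threshold` over at least `min_overlap` nucleotides.
#' `N` bases never count as matches. Clusters of size one are singletons,
#' larger ones contigs; output is ordered by descending size then by the
#' lexicographically smallest representative id.
#'
#' @param sequences named character vector of cleaned reads.
#' @param identity_threshold fraction in (0, 1] (default 0.95).
#' @param min_overlap minimum overlap in nt (default 100).
#' @param k k-mer size for candidate detection (default 21; must be small
#'   enough that true pairs share an exact k-mer at the chosen error rate).
#' @return List of clusters, each `list(id, member_ids, representative,
#'   size, is_contig)`.
#' @export
cluster_ests <- function(sequences, identity_threshold = 0.95,
                         min_overlap = 100L, k = 21L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            !is.null(names(sequences)))
  n <- length(sequences)
  seqs <- toupper(unname(sequences))
  ids <- names(sequences)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  if (n > 1L) {
    rcs <- revcomp(seqs)
    cand_fwd <- kmer_candidates(seqs, k)
    # reverse-orientation candidates: read i vs revcomp of read j
    cand_rev <- kmer_candidates(c(seqs, rcs), k)
    if (nrow(cand_rev))
      cand_rev <- cand_rev[cand_rev[, 1] <= n & cand_rev[, 2] > n &
                             cand_rev[, 2] - n != cand_rev[, 1], , drop = FALSE]
    check <- function(i, j, b_seq) {
      r <- pair_identity(seqs[i], b_seq, k)
      r$overlap >= min_overlap && r$identity >= identity_threshold
    }
    if (nrow(cand_fwd)) for (r in seq_len(nrow(cand_fwd))) {
      i <- cand_fwd[r, 1]; j <- cand_fwd[r, 2]
      if (find(i) != find(j) && check(i, j, seqs[j])) union_(i, j)
    }
    if (nrow(cand_rev)) for (r in seq_len(nrow(cand_rev))) {
      i <- cand_rev[r, 1]; j <- cand_rev[r, 2] - n
      if (find(i) != find(j) && check(i, j, rcs[j])) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), roots)
  clusters <- lapply(groups, function(g) {
    lens <- nchar(seqs[g])
    rep_i <- g[order(-lens, ids[g], method = "radix")][1L]
    list(member_ids = ids[g], representative = sequences[[rep_i]],
         representative_id = ids[rep_i], size = length(g),
         is_contig = length(g) >= 2L)
  })
  ord <- order(-vapply(clusters, `[[`, 1L, "size"),
               vapply(clusters, `[[`, "", "representative_id"),
               method = "radix")
  clusters <- clusters[ord]
  for (i in seq_along(clusters))
    clusters[[i]]$id <- sprintf("CL%03d", i)
  unname(clusters)
}

#' Cluster-size histogram
#'
#' Bins cluster sizes into the standard prevalence bins: singletons (1),
#' small (2-9), medium (10-19) and large (20-70+) clusters.
#'
#' @param clusters output of [cluster_ests()] (or an integer vector of
#'   sizes).
#' @return Named integer vector over bins `1`, `2-9`, `10-19`, `20-70`.
#' @export
cluster_size_histogram <- function(clusters) {
  sizes <- if (is.numeric(clusters)) as.integer(clusters) else
    vapply(clusters, `[[`, 1L, "size")
  if (any(sizes < 1L)) stop("cluster sizes must be >= 1")
  breaks <- c(1L, 2L, 10L, 20L)
  bin <- findInterval(sizes, breaks)
  counts <- tabulate(bin, nbins = 4L)
  names(counts) <- c("1", "2-9", "10-19", "20-70")
  counts
}

#' Library composition summary
#'
#' Counts and percentages of toxin / cellular / unknown transcript
#' categories. Display percentages use largest-remainder rounding so they
#' sum to exactly 100 (190/65/12 of 267 prints as 71/24/5); raw fractions
#' are retained.
#'
#' @param annotation data.frame with columns `est_id` and `category`
#'   (values `toxin`, `cellular`, `unknown`).
#' @param est_ids optional vector of ids that must all be annotated; an
#'   error lists any unlabeled ids.
#' @return List `counts`, `fractions`, `percent` (rounded), `total`.
#' @export
composition_summary <- function(annotation, est_ids = NULL) {
  stopifnot(all(c("est_id", "category") %in% names(annotation)))
  bad <- setdiff(annotation$category, c("toxin", "cellular", "unknown"))
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "))
  if (!is.null(est_ids)) {
    missing <- setdiff(est_ids, annotation$est_id)
    if (length(missing))
      stop("unlabeled EST ids: ", paste(missing, collapse = ", "))
  }
  cats <- factor(annotation$category, levels = c("toxin", "cellular", "unknown"))
  counts <- table(cats)
  total <- sum(counts)
  fr <- as.numeric(counts) / total
  pct <- floor(100 * fr)
  short <- 100L - sum(pct)
  if (short > 0L) {
    top_up <- order(100 * fr - pct, decreasing = TRUE)[seq_len(short)]
    pct[top_up] <- pct[top_up] + 1L
  }
  list(counts = setNames(as.integer(counts), names(counts)),
       fractions = setNames(fr, names(counts)),
       percent = setNames(as.integer(pct), names(counts)),
       total = as.integer(total))
}
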