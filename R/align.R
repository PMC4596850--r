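#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch end-to-end dynamic programming under a linear gap
#' penalty. Identity is the number of matched columns divided by the total
#' number of alignment columns. Traceback ties are resolved deterministically
#' (diagonal, then gap-in-second, then gap-in-first).
#'
#' @param seq_a,seq_b non-empty amino-acid (or nucleotide) strings.
#' @param match,mismatch,gap scores (defaults 1, -1, -2).
#' @return List: `score`, `aligned_a`, `aligned_b`, `identity` (fraction),
#'   `matches`, `columns`.
#' @examples
#' global_align("ACDEFG", "ACDEYG")$identity  # 5/6
#' @export
global_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  res <- .nw_align(toupper(seq_a), toupper(seq_b), match, mismatch, gap)
  res$identity <- res$matches / res$columns
  res
}

#' Pairwise distance matrix from alignment identity
#'
#' Distance is `1 - identity` from [global_align()] over all sequence pairs.
#'
#' @param sequences named character vector (names are taken as labels) or a
#'   list with `id`/`sequence` columns.
#' @param ... scoring parameters passed to [global_align()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = labels.
#' @export
distance_matrix <- function(sequences, ...) {
  if (is.data.frame(sequences)) {
    labels <- sequences$id
    seqs <- sequences$sequence
  } else {
    labels <- names(sequences)
    seqs <- unname(sequences)
  }
  if (is.null(labels) || any(!nzchar(labels)))
    stop("all sequences must be labelled")
  if (anyDuplicated(labels))
    stop("duplicate sequence ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      id <- global_align(seqs[i], seqs[j], ...)$identity
      d[i, j] <- d[j, i] <- 1 - id
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step join the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (row sums `r`), with ties
#' broken by the lexicographically smallest pair of cluster representative
#' labels (the smallest leaf label in each cluster). Branch lengths use the
#' standard limb-length formulas; negative lengths are clamped to zero with
#' a warning.
#'
#' @param d symmetric distance matrix with labelled dimnames (or a `dist`).
#' @return An [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have labelled dimnames")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")

  clamp <- function(x) {
    if (x < 0) {
      warning("negative branch length clamped to 0")
      0
    } else x
  }
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  # newick fragment and representative (smallest leaf) label per active node
  node_nwk <- labels
  rep_lab <- labels
  active <- seq_len(n)
  dm <- d

  while (length(active) > 3L) {
    na <- length(active)
    sub <- dm[active, active, drop = FALSE]
    r <- rowSums(sub)
    q <- (na - 2) * sub - outer(r, r, `+`)
    diag(q) <- Inf
    best <- min(q)
    cand <- which(q - best < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on sorted representative label pairs
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_lab[active[ij[1]]], rep_lab[active[ij[2]]]),
                method = "radix")
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys, method = "radix")[1L], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    ii <- pick[1]; jj <- pick[2]
    dij <- sub[ii, jj]
    li <- clamp(dij / 2 + (r[ii] - r[jj]) / (2 * (na - 2)))
    lj <- clamp(dij - (dij / 2 + (r[ii] - r[jj]) / (2 * (na - 2))))
    # new node
    new_nwk <- paste0("(", node_nwk[i], ":", fmt(li), ",",
                      node_nwk[j], ":", fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    node_nwk <- c(node_nwk, new_nwk)
    rep_lab <- c(rep_lab, new_rep)
    u <- length(node_nwk)
    # distances from new node to remaining
    rest <- setdiff(active, c(i, j))
    newd <- (dm[i, rest] + dm[j, rest] - dij) / 2
    dm <- rbind(cbind(dm, 0), 0)
    dm[u, rest] <- newd; dm[rest, u] <- newd
    active <- c(rest, u)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- clamp((dm[a, b] + dm[a, c3] - dm[b, c3]) / 2)
  lb <- clamp((dm[a, b] + dm[b, c3] - dm[a, c3]) / 2)
  lc <- clamp((dm[a, c3] + dm[b, c3] - dm[a, b]) / 2)
  nwk <- paste0("(", node_nwk[a], ":", fmt(la), ",",
                node_nwk[b], ":", fmt(lb), ",",
                node_nwk[c3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted tree as canonical strings:
# for each internal edge, the tip set on the side NOT containing the
# lexicographically smallest tip label, sorted and collapsed.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label, method = "radix")[1L]
  tr <- stats::reorder(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (k in seq_len(ntip)) below[[k]] <- tree$tip.label[k]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    if (child <= ntip) next
    side <- below[[child]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side, method = "radix"), collapse = "\r"))
  }
  unique(keys)
}

#' Bootstrap support for neighbor-joining splits
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate from recomputed p-distances, and reports for each internal
#' split of the original tree the fraction of replicates containing it.
#'
#' @param alignment character matrix (rows = sequences, labelled rownames;
#'   columns = aligned positions, gaps as `"-"`).
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed; results are reproducible.
#' @return List: `tree` (original NJ tree), `splits` (data.frame of split
#'   keys and support fractions), `node_support` mapping for plotting.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = 1) {
  stopifnot(is.matrix(alignment), ncol(alignment) >= 2L,
            !is.null(rownames(alignment)))
  pdist <- function(aln) {
    n <- nrow(aln)
    d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      d[i, j] <- d[j, i] <- if (!any(ok)) 1 else
        1 - sum(aln[i, ok] == aln[j, ok]) / sum(ok)
    }
    d
  }
  ref_tree <- nj_tree(pdist(alignment))
  ref_splits <- tree_splits(ref_tree)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(as.integer(seed))
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(alignment), ncol(alignment), replace = TRUE)
    bt <- nj_tree(pdist(alignment[, cols, drop = FALSE]))
    hit <- intersect(tree_splits(bt), ref_splits)
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_replicates
  splits_df <- data.frame(
    split = vapply(strsplit(names(support), "\r", fixed = TRUE),
                   paste, "", collapse = ","),
    support = unname(support), stringsAsFactors = FALSE)
  list(tree = ref_tree, splits = splits_df, support = support)
}
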