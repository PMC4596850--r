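#' Classify mature peptides into families
#'
#' Two-stage partition: peptides are first grouped by cysteine skeleton
#' (gap-class sequence plus cysteine count), then, within each skeleton,
#' split into connected components of the graph joining pairs whose global
#' alignment identity reaches `identity_threshold`. Families are labelled
#' `F1`, `F2`, ... by decreasing size (ties by smallest member id), and a
#' family is flagged shared when it contains members of more than one
#' species.
#'
#' @param peptides data.frame with columns `id`, `species`, `sequence`
#'   (mature peptides). Peptides with fewer than two cysteines are assigned
#'   to an `acyclic` pseudo-skeleton.
#' @param identity_threshold identity fraction for within-skeleton linkage
#'   (default 0.4, reflecting the 31-89% cross-family identity range).
#' @param ... alignment scoring parameters for [global_align()].
#' @return data.frame: `id`, `species`, `skeleton`, `family`, `shared`.
#' @export
classify_families <- function(peptides, identity_threshold = 0.4, ...) {
  stopifnot(all(c("id", "species", "sequence") %in% names(peptides)))
  if (nrow(peptides) == 0L)
    return(data.frame(id = character(0), species = character(0),
                      skeleton = character(0), family = character(0),
                      shared = logical(0), stringsAsFactors = FALSE))
  if (anyDuplicated(peptides$id)) stop("duplicate peptide ids")
  # deterministic processing order regardless of input order
  peptides <- peptides[order(peptides$id, method = "radix"), , drop = FALSE]

  skel <- vapply(peptides$sequence, function(s) {
    p <- extract_pattern(s)
    if (p$acyclic) "acyclic" else skeleton_key(skeletonize(p))
  }, "", USE.NAMES = FALSE)
  skel_render <- vapply(peptides$sequence, function(s) {
    p <- extract_pattern(s)
    if (p$acyclic) "acyclic" else skeletonize(p)$rendering
  }, "", USE.NAMES = FALSE)

  comp <- integer(nrow(peptides))
  next_comp <- 0L
  for (sk in unique(skel)) {
    members <- which(skel == sk)
    m <- length(members)
    parent <- seq_len(m)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (m > 1L) for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      ident <- global_align(peptides$sequence[members[a]],
                            peptides$sequence[members[b]], ...)$identity
      if (ident >= identity_threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(m), find, 1L)
    comp[members] <- next_comp + match(roots, unique(roots))
    next_comp <- max(comp)
  }

  sizes <- table(comp)
  first_id <- vapply(split(peptides$id, comp), min, "")
  ord <- order(-as.integer(sizes), first_id, method = "radix")
  fam_label <- setNames(paste0("F", seq_along(ord)), names(sizes)[ord])
  family <- unname(fam_label[as.character(comp)])
  shared_by_family <- vapply(split(peptides$species, family),
                             function(s) length(unique(s)) > 1L, TRUE)
  data.frame(id = peptides$id, species = peptides$species,
             skeleton = skel_render, family = family,
             shared = unname(shared_by_family[family]),
             stringsAsFactors = FALSE)
}

#' Cross-species family and skeleton report
#'
#' Summarizes a family assignment: per-family sizes by species with shared
#' flags, and a skeleton census with shared / species-specific counts.
#'
#' @param assignments output of [classify_families()].
#' @return List: `families` (data.frame family/skeleton/sizes/shared),
#'   `skeletons` (data.frame skeleton/species presence/shared),
#'   `n_families`, `n_skeletons`, `n_shared_skeletons`,
#'   `n_specific_skeletons`.
#' @export
cross_species_report <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(list(families = data.frame(), skeletons = data.frame(),
                n_families = 0L, n_skeletons = 0L,
                n_shared_skeletons = 0L, n_specific_skeletons = 0L))
  species <- sort(unique(assignments$species), method = "radix")
  fam_rows <- lapply(split(assignments, assignments$family), function(g) {
    counts <- vapply(species, function(sp) sum(g$species == sp), 1L)
    df <- data.frame(family = g$family[1L], skeleton = g$skeleton[1L],
                     size = nrow(g), shared = g$shared[1L],
                     stringsAsFactors = FALSE)
    for (sp in species) df[[paste0("n_", sp)]] <- counts[[sp]]
    df
  })
  families <- do.call(rbind, fam_rows)
  families <- families[order(-families$size, families$family,
                             method = "radix"), , drop = FALSE]
  rownames(families) <- NULL

  skel_rows <- lapply(split(assignments, assignments$skeleton), function(g) {
    present <- vapply(species, function(sp) any(g$species == sp), TRUE)
    data.frame(skeleton = g$skeleton[1L],
               n_species = sum(present),
               shared = sum(present) > 1L,
               species = paste(species[present], collapse = "+"),
               stringsAsFactors = FALSE)
  })
  skeletons <- do.call(rbind, skel_rows)
  rownames(skeletons) <- NULL
  list(families = families, skeletons = skeletons,
       n_families = length(unique(assignments$family)),
       n_skeletons = nrow(skeletons),
       n_shared_skeletons = sum(skeletons$shared),
       n_specific_skeletons = sum(!skeletons$shared))
}
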