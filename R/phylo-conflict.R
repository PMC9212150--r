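#' Filter homology groups usable for split-support comparison
#'
#' A group is single-locus informative when (i) it has at least four
#' member sequences (fewer yield no nontrivial splits), (ii) no genome
#' contributes more than one member (multi-copy groups make split
#' support intractable), and (iii) no internal branch of its inferred
#' tree is shorter than `branch_floor` substitutions/site (such branches
#' imply zero mutations and an unresolvable relationship).  The branch
#' rule is a strict less-than: a branch of exactly `branch_floor` is
#' retained.
#'
#' @param partition An `mhg_partition` (or any tibble with `mhg_id` and
#'   `genome`).
#' @param trees Optional named list of `phylo` objects, names matching
#'   `mhg_id`; groups without a tree skip the branch-length rule.
#' @param branch_floor Minimum internal branch length (default 0.0005,
#'   below the reciprocal of a typical ~1.5 kb marker length, so shorter
#'   branches imply no mutations).
#' @return A tibble `mhg_id`, `n_members`, `max_copies_per_genome`,
#'   `min_internal_branch`, `informative`.
#' @export
filter_informative <- function(partition, trees = NULL, branch_floor = 0.0005) {
  ids <- sort(unique(partition$mhg_id))
  rows <- lapply(ids, function(id) {
    g <- partition$genome[partition$mhg_id == id]
    tr <- if (!is.null(trees)) trees[[as.character(id)]] else NULL
    mib <- min_internal_branch(tr)
    tibble(
      mhg_id = id,
      n_members = length(g),
      max_copies_per_genome = max(table(g)),
      min_internal_branch = mib,
      informative = length(g) >= 4L &&
        max(table(g)) <= 1L &&
        (is.na(mib) || !(mib < branch_floor))
    )
  })
  bind_rows(rows)
}

min_internal_branch <- function(tree) {
  if (is.null(tree) || is.null(tree$edge.length)) return(NA_real_)
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  internal <- tr$edge[, 2] > n
  if (!any(internal)) return(NA_real_)
  min(tr$edge.length[internal])
}

#' Split support across a marker and its overlapping homology groups
#'
#' For each (marker, group) pair sharing at least `min_shared` taxa,
#' every split observed anywhere in either bootstrap distribution is
#' recorded with its bootstrap frequency in both sources, after
#' restricting all trees to the pair's shared taxon set and normalizing
#' each split to a single bitmask over that set.  Pairs sharing fewer
#' than `min_shared` taxa contribute nothing (four is the minimum for a
#' nontrivial shared split).
#'
#' @param marker_boots List of bootstrap `phylo` trees for the marker.
#' @param mhg_boots Named list (by group id) of lists of bootstrap trees.
#' @param min_shared Minimum shared taxa per pair (default 4).
#' @return A tibble `mhg_id`, `split` (comma-joined taxon names),
#'   `marker_support`, `mhg_support`.
#' @export
split_support <- function(marker_boots, mhg_boots, min_shared = 4L) {
  if (!length(marker_boots)) abort("no marker bootstrap trees supplied")
  marker_taxa <- marker_boots[[1]]$tip.label
  out <- list()
  for (id in names(mhg_boots)) {
    boots <- mhg_boots[[id]]
    if (!length(boots)) next
    shared <- sort(intersect(marker_taxa, boots[[1]]$tip.label))
    if (length(shared) < min_shared) next
    mb <- lapply(marker_boots, restrict_tree, taxa = shared)
    gb <- lapply(boots, restrict_tree, taxa = shared)
    mb <- mb[!vapply(mb, is.null, logical(1))]
    gb <- gb[!vapply(gb, is.null, logical(1))]
    splits <- sort(unique(c(
      unlist(lapply(mb, tree_bipartitions, universe = shared)),
      unlist(lapply(gb, tree_bipartitions, universe = shared))
    )))
    if (!length(splits)) next
    fm <- split_frequencies(splits, mb, shared)
    fg <- split_frequencies(splits, gb, shared)
    out[[length(out) + 1L]] <- tibble(
      mhg_id = id,
      split = vapply(splits, function(s) {
        paste(split_taxa(s, shared), collapse = ",")
      }, character(1)),
      marker_support = unname(fm),
      mhg_support = unname(fg)
    )
  }
  if (!length(out)) {
    return(tibble(mhg_id = character(), split = character(),
                  marker_support = double(), mhg_support = double()))
  }
  bind_rows(out)
}

# Prune a tree down to `taxa`; NULL when fewer than 4 remain.
restrict_tree <- function(tree, taxa) {
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) < 4L) return(NULL)
  ape::keep.tip(tree, keep)
}
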