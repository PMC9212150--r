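#' Read and write newick tree sets
#'
#' Thin wrappers over ape's newick parser that always return a list of
#' trees and fail loudly on malformed input.
#'
#' @param path Newick file (one or more trees).
#' @return A list of `phylo` objects.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf("malformed newick in %s: %d '(' vs %d ')'", path, n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(sprintf("malformed newick in %s: %s",
                                                   path, conditionMessage(e))))
  if (is.null(tr)) abort(sprintf("no trees parsed from %s", path))
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @rdname read_trees
#' @param trees A `phylo` or list of `phylo`.
#' @return `write_trees()` returns `path` invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

# Tip sets of the clade below every internal edge of an unrooted tree.
clade_tip_sets <- function(tree) {
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  if (n < 4L) return(list())
  post <- ape::reorder.phylo(tr, "postorder")
  sets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tr$tip.label[i]
  for (r in seq_len(nrow(post$edge))) {
    par <- post$edge[r, 1]; ch <- post$edge[r, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  internal <- which(tr$edge[, 2] > n)
  lapply(internal, function(r) sets[[tr$edge[r, 2]]])
}

#' Nontrivial bipartitions of a tree as canonical bitmasks
#'
#' Every internal edge induces a two-way split of the tree's tips.  The
#' split is embedded in an ordered taxon universe (taxa absent from the
#' tree get bit 0 on both sides) and represented by exactly one bitmask:
#' the side containing the tree's lowest-index taxon in the universe is
#' the one encoded (bitwise normalization, so the same split from any
#' tree over any subset is always the same string).  Trivial splits
#' (fewer than two of the tree's tips on either side) are excluded.
#'
#' @param tree A `phylo`.
#' @param universe Ordered character vector of taxon names; defaults to
#'   the tree's sorted tip labels.
#' @return Character vector of 0/1 bitmask strings (deduplicated, sorted)
#'   with the universe attached as an attribute.
#' @export
tree_bipartitions <- function(tree, universe = NULL) {
  universe <- universe %||% sort(tree$tip.label)
  if (!all(tree$tip.label %in% universe)) {
    abort("tree contains tips outside the taxon universe")
  }
  tips <- tree$tip.label
  anchor <- universe[min(match(tips, universe))]   # lowest-index taxon present
  out <- character(0)
  for (side in clade_tip_sets(tree)) {
    k <- length(side)
    if (k < 2L || length(tips) - k < 2L) next
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    mask <- rep("0", length(universe))
    mask[match(side, universe)] <- "1"
    out <- c(out, paste(mask, collapse = ""))
  }
  structure(sort(unique(out)), universe = universe)
}

#' Robinson-Foulds distance between two trees
#'
#' The raw distance is the size of the symmetric difference of the two
#' trees' nontrivial bipartition sets; the normalized distance divides by
#' its maximum, `2 * (n - 3)` for `n` shared tips.
#'
#' @param t1,t2 `phylo` objects over the same tip set.
#' @return A list with elements `raw` (integer) and `normalized`
#'   (fraction in \[0, 1\]).
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees must share the same tip set")
  }
  universe <- sort(t1$tip.label)
  b1 <- tree_bipartitions(t1, universe)
  b2 <- tree_bipartitions(t2, universe)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(universe)
  denom <- 2L * (n - 3L)
  list(raw = as.integer(raw),
       normalized = if (denom > 0L) raw / denom else 0)
}

#' Taxon names on the encoded side of a bitmask split
#'
#' @param split Bitmask string from [tree_bipartitions()].
#' @param universe The ordered taxon universe it was encoded against.
#' @return Character vector of taxon names.
#' @export
split_taxa <- function(split, universe) {
  universe[strsplit(split, "")[[1]] == "1"]
}
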