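# Desk-scale tree estimation: neighbor-joining on Jukes-Cantor distances
# with column-resampling bootstrap.  This stands in for full maximum
# likelihood inference where a quick, deterministic estimator is wanted;
# its accuracy limits are discussed in the methods vignette.

msa_to_dnabin <- function(msa) {
  if (!is.matrix(msa) || !is.character(msa)) {
    abort("an MSA must be a character matrix (taxa x columns)")
  }
  ape::as.DNAbin(tolower(msa))
}

jc_distances <- function(msa) {
  d <- ape::dist.dna(msa_to_dnabin(msa), model = "JC69",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d))) {
    warn("saturated pairwise distance(s) (p >= 3/4); capped")
    cap <- if (any(is.finite(d))) max(d[is.finite(d)], 1) * 2 else 5
    d[!is.finite(d)] <- cap
  }
  d
}

#' Neighbor-joining tree from an alignment
#'
#' Jukes-Cantor distances (pairwise deletion; saturated distances capped
#' with a warning) followed by neighbor joining.  Negative branch
#' lengths produced by NJ are clamped to zero.
#'
#' @param msa Character matrix, taxa as rows (rownames are tip labels),
#'   alignment columns as columns.
#' @return A `phylo`.
#' @export
nj_tree <- function(msa) {
  if (nrow(msa) < 4L) abort("need at least 4 sequences to build an unrooted tree")
  if (ncol(msa) < 1L) abort("alignment has no columns")
  tr <- ape::nj(jc_distances(msa))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap trees by column resampling
#'
#' Resamples alignment columns with replacement `B` times and rebuilds
#' the NJ tree from each pseudo-replicate.
#'
#' @inheritParams nj_tree
#' @param B Number of bootstrap replicates (0 returns an empty list).
#' @param seed Optional seed scoped to this call.
#' @return List of `phylo` objects of length `B`.
#' @export
bootstrap_trees <- function(msa, B = 100L, seed = NULL) {
  if (B == 0L) return(list())
  with_seed_opt(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      suppressWarnings(nj_tree(msa[, cols, drop = FALSE]))
    })
  })
}

# Bootstrap frequency of each of `splits` among `boots` trees, counting
# each split at most once per tree.
split_frequencies <- function(splits, boots, universe) {
  if (!length(boots)) return(setNames(rep(NA_real_, length(splits)), splits))
  counts <- setNames(rep(0L, length(splits)), splits)
  for (tr in boots) {
    bs <- tree_bipartitions(tr, universe)
    hit <- splits %in% bs
    counts[hit] <- counts[hit] + 1L
  }
  counts / length(boots)
}
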