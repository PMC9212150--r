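# Recombinant-marker simulation study: a marker gene is modelled as a
# concatenation of non-recombining components whose true trees form a
# chain, each one nearest-neighbor interchange (NNI) away from its
# predecessor -- a conservative facsimile of horizontal recombination,
# since an NNI only exchanges segments between closely related taxa.

#' Apply one random nearest-neighbor interchange
#'
#' Chooses one internal edge of the unrooted tree uniformly at random
#' and applies one of its two alternative subtree exchanges (coin flip).
#' Branch lengths travel with their subtrees.
#'
#' @param tree A `phylo` with at least 4 tips.
#' @param seed Optional seed scoped to this call.
#' @return The rearranged `phylo`; its RF distance to the input is
#'   always raw 2.
#' @export
random_nni <- function(tree, seed = NULL) {
  if (length(tree$tip.label) < 4L) abort("NNI needs at least 4 tips")
  with_seed_opt(seed, {
    tr <- ape::unroot(tree)
    n <- length(tr$tip.label)
    internal <- which(tr$edge[, 2] > n)
    pick <- internal[sample.int(length(internal), 1L)]
    u <- tr$edge[pick, 1]; v <- tr$edge[pick, 2]
    # one fixed exchange partner on u's side: its lowest other child
    u_children <- setdiff(which(tr$edge[, 1] == u), pick)
    row_a <- u_children[1]
    # the two alternative exchanges swap it with either child of v
    v_children <- which(tr$edge[, 1] == v)
    row_b <- v_children[sample.int(2L, 1L)]
    tr$edge[row_a, 1] <- v
    tr$edge[row_b, 1] <- u
    ape::read.tree(text = ape::write.tree(tr))
  })
}

#' Build a chain of NNI-linked component trees
#'
#' Component tree 1 is one NNI from the base tree, component 2 one NNI
#' from component 1, and so on: consecutive trees are always at raw RF
#' distance 2.
#'
#' @param base Base `phylo` (the species tree the chain drifts from).
#' @param k Number of component trees.
#' @param seed Optional seed scoped to this call.
#' @return A list of class `nni_chain`: `base`, `trees` (length `k`).
#' @export
build_nni_chain <- function(base, k, seed = NULL) {
  if (k < 1L) abort("`k` must be >= 1")
  with_seed_opt(seed, {
    trees <- vector("list", k)
    cur <- base
    for (i in seq_len(k)) {
      cur <- random_nni(cur)
      trees[[i]] <- cur
    }
    structure(list(base = base, trees = trees), class = "nni_chain")
  })
}

#' @export
print.nni_chain <- function(x, ...) {
  cat(sprintf("<nni_chain> %d component trees over %d tips\n",
              length(x$trees), length(x$base$tip.label)))
  invisible(x)
}

#' Simulate a sequence alignment down a tree under Jukes-Cantor
#'
#' Sites evolve independently under the equal-rates, equal-base-
#' frequencies substitution model from a uniform-random root sequence.
#'
#' @param tree A `phylo` with branch lengths (substitutions/site).
#' @param length Alignment width in bp.
#' @param seed Optional seed scoped to this call.
#' @return Character matrix (taxa x columns) of A/C/G/T.
#' @export
simulate_alignment <- function(tree, length, seed = NULL) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (length < 1L) abort("`length` must be >= 1")
  with_seed_opt(seed, {
    dat <- phangorn::simSeq(tree, l = length, type = "DNA")
    toupper(as.character(dat))
  })
}

#' Simulate one recombinant marker gene
#'
#' Simulates an alignment on every component tree of the chain and
#' concatenates them in order; each column's true tree is recorded in a
#' provenance map.
#'
#' @param chain An `nni_chain`.
#' @param seg_len Width per component in bp (scalar or per-component
#'   vector).
#' @param seed Optional seed scoped to this call.
#' @return A list of class `recomb_marker`: `alignment` (character
#'   matrix of width `sum(seg_len)`), `provenance` (integer vector, the
#'   component index of each column), `chain`.
#' @export
simulate_marker <- function(chain, seg_len = 100L, seed = NULL) {
  k <- length(chain$trees)
  seg_len <- rep_len(as.integer(seg_len), k)
  with_seed_opt(seed, {
    parts <- lapply(seq_len(k), function(i) {
      simulate_alignment(chain$trees[[i]], seg_len[i])
    })
    taxa <- rownames(parts[[1]])
    parts <- lapply(parts, function(p) p[taxa, , drop = FALSE])
    structure(list(
      alignment = do.call(cbind, parts),
      provenance = rep(seq_len(k), seg_len),
      chain = chain
    ), class = "recomb_marker")
  })
}

#' Random base species tree for the simulation study
#'
#' A pure-birth topology with equal branch lengths, unrooted; stands in
#' for an empirical species tree when none is supplied.
#'
#' @param n_tips Number of taxa.
#' @param branch_length Length of every branch (substitutions/site).
#' @param seed Optional seed scoped to this call.
#' @return A `phylo`.
#' @export
random_base_tree <- function(n_tips = 19L, branch_length = 0.05, seed = NULL) {
  with_seed_opt(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
    tr <- ape::unroot(tr)
    tr$edge.length <- rep(branch_length, nrow(tr$edge))
    tr
  })
}

#' Recombinant-marker phylogenetic conflict experiment
#'
#' For each replicate: builds a component-tree chain from the base tree,
#' simulates `seg_len` bp per component, concatenates them into one
#' marker alignment, infers a tree from the marker and from every
#' component segment (NJ on JC distances, plus `B` bootstrap trees
#' each), and records (i) the normalized RF distance between the
#' inferred marker tree and every true component tree, (ii) the
#' per-branch bootstrap support of marker and component trees, and
#' (iii) for component-tree branches, whether the branch is in the true
#' component tree.
#'
#' @param base Base `phylo`; defaults to [random_base_tree()] with
#'   `n_tips` tips.
#' @param n_tips Tips for the default base tree.
#' @param replicates Number of replicate markers.
#' @param k Components per marker.
#' @param seg_len bp per component.
#' @param B Bootstrap replicates per inferred tree (0 skips support).
#' @param branch_length Branch length of the default base tree.
#' @param seed Seed for the whole experiment (chains, sequences,
#'   bootstraps).
#' @return A list of class `marker_conflict`: `rf` (tibble: replicate,
#'   component, rf_raw, rf_norm, rf_component_norm), `support` (tibble:
#'   replicate, source, component, split, support, correct), `params`.
#' @export
marker_conflict_experiment <- function(base = NULL, n_tips = 19L,
                                       replicates = 10L, k = 15L,
                                       seg_len = 100L, B = 100L,
                                       branch_length = 0.05, seed = NULL) {
  with_seed_opt(seed, {
    if (is.null(base)) base <- random_base_tree(n_tips, branch_length)
    universe <- sort(base$tip.label)
    rf_rows <- list(); sup_rows <- list()
    for (r in seq_len(replicates)) {
      chain <- build_nni_chain(base, k)
      marker <- simulate_marker(chain, seg_len)
      marker_tree <- suppressWarnings(nj_tree(marker$alignment))
      marker_boots <- if (B > 0L) bootstrap_trees(marker$alignment, B) else list()
      if (B > 0L) {
        msplits <- tree_bipartitions(marker_tree, universe)
        sup_rows[[length(sup_rows) + 1L]] <- tibble(
          replicate = r, source = "marker", component = NA_integer_,
          split = as.character(msplits),
          support = unname(split_frequencies(msplits, marker_boots, universe)),
          correct = NA
        )
      }
      for (j in seq_len(k)) {
        cols <- marker$provenance == j
        seg <- marker$alignment[, cols, drop = FALSE]
        comp_tree <- suppressWarnings(nj_tree(seg))
        true_tree <- chain$trees[[j]]
        rf_m <- rf_distance(marker_tree, true_tree)
        rf_c <- rf_distance(comp_tree, true_tree)
        rf_rows[[length(rf_rows) + 1L]] <- tibble(
          replicate = r, component = j,
          rf_raw = rf_m$raw, rf_norm = rf_m$normalized,
          rf_component_norm = rf_c$normalized
        )
        if (B > 0L) {
          comp_boots <- suppressWarnings(bootstrap_trees(seg, B))
          csplits <- tree_bipartitions(comp_tree, universe)
          tsplits <- tree_bipartitions(true_tree, universe)
          sup_rows[[length(sup_rows) + 1L]] <- tibble(
            replicate = r, source = "component", component = j,
            split = as.character(csplits),
            support = unname(split_frequencies(csplits, comp_boots, universe)),
            correct = as.character(csplits) %in% as.character(tsplits)
          )
        }
      }
    }
    structure(list(
      rf = bind_rows(rf_rows),
      support = if (length(sup_rows)) bind_rows(sup_rows) else
        tibble(replicate = integer(), source = character(),
               component = integer(), split = character(),
               support = double(), correct = logical()),
      params = list(n_tips = length(base$tip.label), replicates = replicates,
                    k = k, seg_len = seg_len, B = B,
                    branch_length = branch_length)
    ), class = "marker_conflict")
  })
}

#' @export
print.marker_conflict <- function(x, ...) {
  p <- x$params
  cat(sprintf("<marker_conflict> %d replicates x %d components x %d bp (B = %d)\n",
              p$replicates, p$k, p$seg_len, p$B))
  cat(sprintf("  mean marker-vs-component normalized RF: %.3f\n",
              mean(x$rf$rf_norm)))
  invisible(x)
}

#' @rdname marker_conflict_experiment
#' @param x A `marker_conflict` report.
#' @param ... Unused.
#' @method tidy marker_conflict
#' @export
tidy.marker_conflict <- function(x, ...) x$rf

#' @rdname marker_conflict_experiment
#' @method glance marker_conflict
#' @export
glance.marker_conflict <- function(x, ...) {
  s <- x$support
  comp <- s[s$source == "component", , drop = FALSE]
  tibble(
    mean_marker_rf = mean(x$rf$rf_norm),
    mean_component_rf = mean(x$rf$rf_component_norm),
    median_marker_support = median(s$support[s$source == "marker"]),
    median_component_support = median(comp$support),
    median_true_support = median(comp$support[comp$correct]),
    median_incorrect_support = median(comp$support[!comp$correct])
  )
}
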