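#' Brute-force transitive-closure homology partition
#'
#' Independent, deliberately simple reference computation used to
#' validate the graph engine: every alignment is expanded into per-base
#' cross-genome correspondences (residue-residue columns only), the
#' transitive closure is taken with an orientation-aware union-find, and
#' maximal runs of bases whose closure classes advance in parallel are
#' grouped.  Quadratic-ish and memory hungry; intended for small
#' fixtures, not real genomes.
#'
#' @param genomes Genome tibble (lengths are taken from here).
#' @param alignments Filtered alignment tibble.
#' @return A partition tibble in [mhg_delineate()]'s schema (class
#'   `mhg_partition`, without pile-up metadata).
#' @export
transitive_homology_partition <- function(genomes, alignments) {
  offs <- c(0, cumsum(genomes$length))
  names(offs) <- c(genomes$genome, ".end")
  flat <- function(g, p) offs[[g]] + p + 1L   # 1-based flat index
  total <- sum(genomes$length)

  parent <- seq_len(total)
  psign <- rep(1L, total)

  # non-compressing find; closure classes are tiny, so paths stay short
  find2 <- function(x) {
    s <- 1L
    while (parent[x] != x) { s <- s * psign[x]; x <- parent[x] }
    c(x, s)
  }
  union2 <- function(a, b, sab) {
    fa <- find2(a); fb <- find2(b)
    if (fa[1] == fb[1]) return(invisible(NULL))
    parent[fb[1]] <<- fa[1]
    psign[fb[1]] <<- fa[2] * sab * fb[2]
    invisible(NULL)
  }

  covered <- rep(FALSE, total)
  for (i in seq_len(nrow(alignments))) {
    qb <- alignments$query_bits[[i]]; sb <- alignments$subject_bits[[i]]
    qg <- alignments$query_genome[i]; sg <- alignments$subject_genome[i]
    qpos <- alignments$query_start[i] + cumsum(qb) - 1L      # residue positions per column
    spos_fwd <- alignments$subject_start[i] + cumsum(sb) - 1L
    o <- if (alignments$orientation[i] == "same") 1L else -1L
    spos <- if (o == 1L) spos_fwd else alignments$subject_end[i] - cumsum(sb)
    covered[flat(qg, alignments$query_start[i]:(alignments$query_end[i] - 1L))] <- TRUE
    covered[flat(sg, alignments$subject_start[i]:(alignments$subject_end[i] - 1L))] <- TRUE
    both <- which(qb == 1L & sb == 1L)
    for (c in both) {
      union2(flat(qg, qpos[c]), flat(sg, spos[c]), o)
    }
  }

  if (!any(covered)) {
    return(new_mhg_partition(tibble(mhg_id = integer(), genome = character(),
                                    start = integer(), end = integer(),
                                    strand = character()), pileup = NULL))
  }

  roots <- rep(NA_integer_, total)
  signs <- rep(NA_integer_, total)
  for (x in which(covered)) {
    f <- find2(x); roots[x] <- f[1]; signs[x] <- f[2]
  }
  class_members <- split(which(covered), roots[covered])

  # run boundaries: position p and p+1 stay together iff the whole class
  # of p, shifted by each element's relative orientation, is the class
  # of p+1
  genome_of <- rep(seq_len(nrow(genomes)), genomes$length)
  run_id <- rep(NA_integer_, total)
  n_runs <- 0L
  cov_idx <- which(covered)
  for (x in cov_idx) {
    prev_ok <- FALSE
    if (x > 1L && covered[x - 1L] && genome_of[x] == genome_of[x - 1L]) {
      cls_prev <- class_members[[as.character(roots[x - 1L])]]
      rel <- signs[cls_prev] * signs[x - 1L]
      shifted <- sort(cls_prev + rel)
      cls_here <- class_members[[as.character(roots[x])]]
      prev_ok <- length(shifted) == length(cls_here) &&
        all(shifted == sort(cls_here))
    }
    if (prev_ok) {
      run_id[x] <- run_id[x - 1L]
    } else {
      n_runs <- n_runs + 1L
      run_id[x] <- n_runs
    }
  }

  rid <- run_id[cov_idx]
  runs <- tibble(
    first = as.numeric(tapply(cov_idx, rid, min)),
    last = as.numeric(tapply(cov_idx, rid, max))
  )
  run_at <- function(x) which(runs$first <= x & runs$last >= x)

  assigned <- rep(FALSE, nrow(runs))
  groups <- list()
  for (ri in seq_len(nrow(runs))) {
    if (assigned[ri]) next
    a <- runs$first[ri]; b <- runs$last[ri]
    len <- b - a + 1
    cls <- class_members[[as.character(roots[a])]]
    mem <- lapply(cls, function(el) {
      rel <- signs[el] * signs[a]
      lo <- if (rel == 1L) el else el - len + 1
      hi <- lo + len - 1
      rj <- run_at(lo)
      if (length(rj) != 1L || runs$first[rj] != lo || runs$last[rj] != hi) {
        abort("internal error: closure classes do not tile into parallel runs")
      }
      assigned[rj] <<- TRUE
      gI <- genome_of[lo]
      tibble(genome = genomes$genome[gI],
             start = as.integer(lo - offs[[genomes$genome[gI]]] - 1L),
             end = as.integer(hi - offs[[genomes$genome[gI]]]),
             strand = if (rel == 1L) "+" else "-")
    })
    groups[[length(groups) + 1L]] <- bind_rows(mem)
  }

  out <- bind_rows(lapply(seq_along(groups), function(i) {
    tb <- groups[[i]][order(groups[[i]]$genome, groups[[i]]$start), , drop = FALSE]
    if (tb$strand[1] == "-") tb$strand <- ifelse(tb$strand == "+", "-", "+")
    tibble(mhg_id = i, genome = tb$genome, start = tb$start,
           end = tb$end, strand = tb$strand)
  }))
  new_mhg_partition(out, pileup = NULL)
}
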