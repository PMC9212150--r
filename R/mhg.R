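#' Map a breakpoint across a pairwise local alignment
#'
#' Converts a genome coordinate on one side of a local alignment to the
#' homologous coordinate on the other side by walking the alignment's
#' bit arrays: the breakpoint's residue offset is located as the leftmost
#' alignment column at which the source array has accumulated that many
#' 1s, and the destination offset is the number of 1s the destination
#' array has accumulated before that column.  For opposite-orientation
#' alignments the destination offset is applied from the destination
#' segment's end (reflection).  When the breakpoint lands in a run of
#' destination gap columns it is placed before the run (leftmost), the
#' unique position consistent with counting residues strictly before the
#' column.
#'
#' @param alignment A one-row alignment tibble.
#' @param source `"query"` or `"subject"`: the side `pos` refers to.
#' @param pos Breakpoint position (0-based, between
#'   `start` and `end` of the source segment inclusive).
#' @return The homologous position on the destination genome.
#' @export
map_breakpoint <- function(alignment, source = c("query", "subject"), pos) {
  source <- match.arg(source)
  if (nrow(alignment) != 1L) abort("`alignment` must be a single alignment row")
  qs <- alignment$query_start; qe <- alignment$query_end
  ss <- alignment$subject_start; se <- alignment$subject_end
  qb <- alignment$query_bits[[1]]; sb <- alignment$subject_bits[[1]]
  o <- if (alignment$orientation == "same") 1L else -1L
  if (source == "query") {
    if (pos < qs || pos > qe) abort("breakpoint outside the aligned query segment")
    c <- leftmost_col(qb, pos - qs)
    k <- ones_before(sb, c)
    if (o == 1L) ss + k else se - k
  } else {
    if (pos < ss || pos > se) abort("breakpoint outside the aligned subject segment")
    k <- if (o == 1L) pos - ss else se - pos
    qs + ones_before(qb, leftmost_col(sb, k))
  }
}

#' Delineate maximal homologous groups
#'
#' The core pipeline: pile filtered alignments up into per-genome node
#' ranges, build the alignment graph, and traverse each connected
#' component's edges in a deterministic order.  For every edge the
#' segmentations of its two aligned spans are driven to a common
#' refinement by propagating breakpoints (alignment endpoints and any
#' pre-existing group boundaries) through the alignment's bit arrays,
#' splitting the groups that contain them; each aligned pair of
#' post-split groups is then merged through the restricted alignment.
#' After all edges have been visited the groups are the maximal
#' homologous groups of the input.
#'
#' @param alignments Alignment tibble.  Pass pre-filtered alignments, or
#'   supply `max_scores` (and optionally `bitscore_fraction`) to apply
#'   [filter_alignments()] first.
#' @param max_scores Optional named vector of per-genome maximum self bit
#'   scores; when given, relative-score filtering is applied.
#' @param bitscore_fraction Relative bit-score threshold used with
#'   `max_scores` (default 0.05).
#' @param min_alignment_length Minimum alignment length in columns used
#'   with `max_scores` (default 0).
#' @param verbose Log stage-level counts to stderr.
#' @return A tibble of class `mhg_partition` with one row per member
#'   sequence: `mhg_id`, `genome`, `start`, `end` (0-based half-open),
#'   `strand` (relative to the group frame, first member `+`).
#'   Attributes: `n_mhgs`, `pileup` (the node ranges), `log` (stage
#'   counts), `warnings` (reconciliation notes).
#' @export
mhg_delineate <- function(alignments, max_scores = NULL,
                          bitscore_fraction = 0.05,
                          min_alignment_length = 0L, verbose = FALSE) {
  n_in <- nrow(alignments)
  if (!is.null(max_scores)) {
    alignments <- filter_alignments(alignments, max_scores,
                                    fraction = bitscore_fraction,
                                    min_length = min_alignment_length)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("alignments: %d in, %d after filtering", n_in, nrow(alignments))
  ranges <- pile_up(alignments)
  if (nrow(ranges) == 0L) {
    out <- tibble(mhg_id = integer(), genome = character(), start = integer(),
                  end = integer(), strand = character())
    return(new_mhg_partition(out, ranges, log = list(edges = 0L), warnings = character()))
  }
  graph <- build_alignment_graph(ranges, alignments)
  nodes <- alignment_components(graph)
  say("graph: %d nodes, %d edges, %d components",
      nrow(nodes), nrow(graph$edges), max(nodes$component))

  comp_of <- setNames(nodes$component, nodes$node_id)
  ed <- graph$edges
  ed$component <- comp_of[as.character(ed$node_a)]
  lo <- pmin(ed$node_a, ed$node_b); hi <- pmax(ed$node_a, ed$node_b)
  ord <- order(ed$component, lo, hi, ed$edge_id)

  eng <- new_engine(ranges)
  for (i in ord) {
    eng_process_edge(eng,
                     qg = ed$query_genome[i], qs = ed$query_start[i],
                     qe = ed$query_end[i],
                     sg = ed$subject_genome[i], ss = ed$subject_start[i],
                     se = ed$subject_end[i],
                     orient = ed$orientation[i],
                     qbits = ed$query_bits[[i]], sbits = ed$subject_bits[[i]])
  }
  out <- eng_finalize(eng)
  say("traversal: %d splits, %d merges, %d final groups",
      eng$n_splits, eng$n_merges, max(out$mhg_id, 0L))
  if (length(eng$warnings)) {
    warn(sprintf("%d boundary reconciliation note(s); see attr(, \"warnings\")",
                 length(eng$warnings)))
  }
  new_mhg_partition(out, ranges,
                    log = list(alignments_in = n_in,
                               alignments_used = nrow(alignments),
                               nodes = nrow(nodes), edges = nrow(ed),
                               components = max(nodes$component),
                               splits = eng$n_splits, merges = eng$n_merges),
                    warnings = eng$warnings)
}

new_mhg_partition <- function(tbl, pileup, log = list(), warnings = character()) {
  structure(tbl,
            class = c("mhg_partition", class(tibble())),
            n_mhgs = if (nrow(tbl)) max(tbl$mhg_id) else 0L,
            pileup = pileup, log = log, warnings = warnings)
}

#' @export
print.mhg_partition <- function(x, ...) {
  cat(sprintf("<mhg_partition> %d group(s), %d member sequence(s), %d genome(s)\n",
              attr(x, "n_mhgs"), nrow(x), length(unique(x$genome))))
  NextMethod()
}

#' @rdname mhg_delineate
#' @param x An `mhg_partition`.
#' @param ... Unused.
#' @method tidy mhg_partition
#' @export
tidy.mhg_partition <- function(x, ...) {
  as_tibble(unclass2_tibble(x))
}

#' @rdname mhg_delineate
#' @method glance mhg_partition
#' @export
glance.mhg_partition <- function(x, ...) {
  sizes <- if (nrow(x)) table(x$mhg_id) else integer(0)
  tibble(
    n_mhgs = attr(x, "n_mhgs"),
    n_members = nrow(x),
    n_genomes = length(unique(x$genome)),
    mean_members = if (length(sizes)) mean(sizes) else NA_real_,
    total_bp = sum(x$end - x$start)
  )
}

unclass2_tibble <- function(x) {
  attr(x, "pileup") <- NULL; attr(x, "log") <- NULL
  attr(x, "warnings") <- NULL; attr(x, "n_mhgs") <- NULL
  class(x) <- class(tibble())
  x
}

#' Canonical string form of a homology partition
#'
#' Reduces a partition (or any tibble with `mhg_id`/`genome`/`start`/
#' `end`/`strand` columns) to a sorted character vector with one entry
#' per group, members sorted and the group frame flipped so its first
#' member is on the `+` strand.  Two partitions are equal iff their
#' canonical forms are identical, regardless of group ids or frames.
#'
#' @param partition Partition tibble.
#' @return Character vector, one canonical signature per group.
#' @export
canonical_partition <- function(partition) {
  if (nrow(partition) == 0L) return(character(0))
  sig <- vapply(split(seq_len(nrow(partition)), partition$mhg_id), function(i) {
    m <- partition[i, , drop = FALSE]
    m <- m[order(m$genome, m$start), , drop = FALSE]
    s <- ifelse(m$strand == "+", 1L, -1L)
    if (s[1] == -1L) s <- -s
    paste(sprintf("%s:%d-%d:%s", m$genome, m$start, m$end,
                  ifelse(s == 1L, "+", "-")), collapse = ",")
  }, character(1))
  sort(unname(sig))
}

#' Write a partition as tab-separated text
#'
#' One group per line: `mhg_id<TAB>genome:start-end:strand,...`
#' (0-based half-open).
#'
#' @param partition An `mhg_partition`.
#' @param path Output path.
#' @param config_hash Optional reproducibility hash written as a header
#'   comment.
#' @return `path`, invisibly.
#' @export
write_mhg_tsv <- function(partition, path, config_hash = NULL) {
  lines <- vapply(split(seq_len(nrow(partition)), partition$mhg_id), function(i) {
    m <- partition[i, , drop = FALSE]
    paste0(m$mhg_id[1], "\t",
           paste(sprintf("%s:%d-%d:%s", m$genome, m$start, m$end, m$strand),
                 collapse = ","))
  }, character(1))
  if (!is.null(config_hash)) lines <- c(sprintf("# config_hash=%s", config_hash), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a partition as BED (one file, name column carries the group id)
#'
#' @param partition An `mhg_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mhg_bed <- function(partition, path) {
  lines <- sprintf("%s\t%d\t%d\tmhg_%d\t0\t%s",
                   partition$genome, partition$start, partition$end,
                   partition$mhg_id, partition$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a partition written by [write_mhg_tsv()]
#'
#' @param path Input path.
#' @return An `mhg_partition` tibble (without pile-up metadata).
#' @export
read_mhg_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    mem <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    m <- regmatches(mem, regexec("^(.+):(\\d+)-(\\d+):([+-])$", mem))
    tibble(mhg_id = as.integer(parts[1]),
           genome = vapply(m, `[`, "", 2),
           start = as.integer(vapply(m, `[`, "", 3)),
           end = as.integer(vapply(m, `[`, "", 4)),
           strand = vapply(m, `[`, "", 5))
  })
  out <- bind_rows(rows)
  new_mhg_partition(out, pileup = NULL)
}
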