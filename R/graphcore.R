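#' Pile up alignment segments into non-overlapping per-genome ranges
#'
#' Per genome, takes the union of strictly overlapping query and subject
#' segments of the filtered alignments.  The resulting ranges are the
#' connected components of the interval-overlap relation; abutting but
#' not overlapping intervals (`end == start`) are kept separate, because
#' an abutment is a real boundary, not shared sequence.  Each range seeds
#' one initial single-sequence homology group.
#'
#' @param alignments Filtered alignment tibble.
#' @return A tibble of node ranges: `node_id`, `genome`, `start`, `end`,
#'   ordered by `(genome, start)`.
#' @export
pile_up <- function(alignments) {
  segs <- bind_rows(
    tibble(genome = alignments$query_genome,
           start = alignments$query_start, end = alignments$query_end),
    tibble(genome = alignments$subject_genome,
           start = alignments$subject_start, end = alignments$subject_end)
  )
  if (nrow(segs) == 0L) {
    return(tibble(node_id = integer(), genome = character(),
                  start = integer(), end = integer()))
  }
  segs <- arrange(segs, .data$genome, .data$start, .data$end)
  out <- list()
  for (g in unique(segs$genome)) {
    s <- segs[segs$genome == g, , drop = FALSE]
    cs <- s$start[1]; ce <- s$end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] < ce) {            # strict overlap only
        ce <- max(ce, s$end[i])
      } else {
        out[[length(out) + 1L]] <- tibble(genome = g, start = cs, end = ce)
        cs <- s$start[i]; ce <- s$end[i]
      }
    }
    out[[length(out) + 1L]] <- tibble(genome = g, start = cs, end = ce)
  }
  ranges <- arrange(bind_rows(out), .data$genome, .data$start)
  ranges$node_id <- seq_len(nrow(ranges))
  ranges[, c("node_id", "genome", "start", "end")]
}

# Node containing [start, end) on `genome`; errors if not fully contained
# in exactly one range (which would violate the pile-up postcondition).
containing_node <- function(ranges, genome, start, end) {
  r <- ranges[ranges$genome == genome, , drop = FALSE]
  i <- findInterval(start, r$start)
  if (i < 1L || r$end[i] < end || r$start[i] > start) {
    abort(sprintf("segment %s:%d-%d is not contained in any piled-up range",
                  genome, start, end))
  }
  r$node_id[i]
}

#' Build the alignment graph
#'
#' One node per piled-up range, one edge per local alignment connecting
#' the two nodes that contain its query and subject segments.  Parallel
#' edges and self loops (both segments in one range, e.g. tandem
#' repeats) are permitted.
#'
#' @param ranges Node ranges from [pile_up()].
#' @param alignments The same filtered alignment tibble.
#' @return A list with class `"alignment_graph"`: `nodes` (the range
#'   tibble) and `edges` (alignment tibble plus `edge_id`, `node_a`,
#'   `node_b`).
#' @export
build_alignment_graph <- function(ranges, alignments) {
  edges <- alignments
  n <- nrow(edges)
  edges$edge_id <- seq_len(n)
  edges$node_a <- vapply(seq_len(n), function(i) {
    containing_node(ranges, edges$query_genome[i],
                    edges$query_start[i], edges$query_end[i])
  }, integer(1))
  edges$node_b <- vapply(seq_len(n), function(i) {
    containing_node(ranges, edges$subject_genome[i],
                    edges$subject_start[i], edges$subject_end[i])
  }, integer(1))
  structure(list(nodes = ranges, edges = edges), class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("<alignment_graph> %d nodes, %d edges over %d genome(s)\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$genome))))
  invisible(x)
}

#' Connected components of the alignment graph
#'
#' Components bound the scope of any merge: a homology group can only
#' contain subsequences of nodes from the same component, so each
#' component is traversed independently.
#'
#' @param graph An `alignment_graph`.
#' @return The node tibble with a `component` column; components are
#'   numbered deterministically by their smallest `node_id`.
#' @export
alignment_components <- function(graph) {
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph$edges$node_a),
                   to = as.character(graph$edges$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id))
  )
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(nodes$node_id)]
  # renumber by smallest node_id in each component
  first <- tapply(nodes$node_id, comp, min)
  relabel <- rank(first)
  nodes$component <- as.integer(relabel[as.character(comp)])
  nodes
}

#' Export the alignment graph as an edge-list text file
#'
#' Debugging aid: one line per edge, `node_a<TAB>node_b<TAB>`
#' `genome:start-end` for both endpoints.
#'
#' @param graph An `alignment_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  loc <- function(id) {
    r <- graph$nodes[match(id, graph$nodes$node_id), ]
    sprintf("%s:%d-%d", r$genome, r$start, r$end)
  }
  lines <- sprintf("%d\t%d\t%s\t%s", graph$edges$node_a, graph$edges$node_b,
                   loc(graph$edges$node_a), loc(graph$edges$node_b))
  writeLines(lines, path)
  invisible(path)
}
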