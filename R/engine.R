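# Internal partition/merge engine.
#
# State lives in an environment:
#   member vectors: genome, start, end (0-based half-open), strand
#     (+1/-1, relative to the owning group's frame), mhg (owning group
#     id), active
#   mhg_members / mhg_edges: group id -> member ids / internal edge ids
#   edges: internal alignment edges; columns ascend along member m1's
#     genome coordinates; orient +1 means columns also ascend along m2,
#     -1 means they descend from m2's end (reflection)
#   idx: per-genome ordered interval index (the genome segmentation),
#     mapping a position to the unique covering member
#
# Invariant maintained throughout: per genome, active member intervals
# are pairwise disjoint and their union equals the pile-up cover.

new_engine <- function(nodes) {
  e <- new.env(parent = emptyenv())
  n <- nrow(nodes)
  e$genome <- nodes$genome
  e$start <- as.numeric(nodes$start)
  e$end <- as.numeric(nodes$end)
  e$strand <- rep(1L, n)
  e$mhg <- seq_len(n)
  e$active <- rep(TRUE, n)
  e$mhg_members <- as.list(seq_len(n))
  e$mhg_edges <- rep(list(integer()), max(n, 0L))
  e$edges <- list()
  e$n_members <- n
  e$n_mhgs <- n
  e$n_splits <- 0L
  e$n_merges <- 0L
  e$warnings <- character()
  e$idx <- list()
  for (g in unique(nodes$genome)) {
    sel <- which(nodes$genome == g)
    o <- sel[order(nodes$start[sel])]
    e$idx[[g]] <- list(start = as.numeric(nodes$start[o]),
                       end = as.numeric(nodes$end[o]),
                       member = o)
  }
  e
}

eng_note <- function(e, msg) e$warnings <- c(e$warnings, msg)

# Member covering position p (start <= p < end), or NA.
eng_find_member <- function(e, g, p) {
  ix <- e$idx[[g]]
  if (is.null(ix) || length(ix$start) == 0L) return(NA_integer_)
  i <- findInterval(p, ix$start)
  if (i >= 1L && p < ix$end[i]) ix$member[i] else NA_integer_
}

# Would cutting at p split a member? (p strictly inside one)
eng_needs_cut <- function(e, g, p) {
  ix <- e$idx[[g]]
  if (is.null(ix)) return(FALSE)
  i <- findInterval(p, ix$start)
  i >= 1L && ix$start[i] < p && p < ix$end[i]
}

# Member boundary positions strictly inside (a, b) on genome g.
eng_boundaries <- function(e, g, a, b) {
  ix <- e$idx[[g]]
  if (is.null(ix)) return(numeric(0))
  bd <- unique(c(ix$start, ix$end))
  sort(bd[bd > a & bd < b])
}

# Replace one member's index entry with its (sorted) pieces.
eng_idx_replace <- function(e, m, pieces) {
  g <- e$genome[m]
  ix <- e$idx[[g]]
  at <- which(ix$member == m)
  keep <- setdiff(seq_along(ix$member), at)
  ns <- c(ix$start[keep], vapply(pieces, function(p) e$start[p], numeric(1)))
  ne <- c(ix$end[keep], vapply(pieces, function(p) e$end[p], numeric(1)))
  nm <- c(ix$member[keep], unlist(pieces))
  o <- order(ns)
  e$idx[[g]] <- list(start = ns[o], end = ne[o], member = nm[o])
}

eng_new_member <- function(e, g, s, en, strand, mhg) {
  id <- e$n_members + 1L
  e$n_members <- id
  e$genome[id] <- g; e$start[id] <- s; e$end[id] <- en
  e$strand[id] <- strand; e$mhg[id] <- mhg; e$active[id] <- TRUE
  id
}

eng_new_edge <- function(e, m1, m2, b1, b2, orient) {
  id <- length(e$edges) + 1L
  e$edges[[id]] <- list(m1 = m1, m2 = m2, b1 = b1, b2 = b2, orient = orient)
  id
}

# Map a breakpoint across one internal edge.
edge_map_pos <- function(e, eid, from_member, pos) {
  ed <- e$edges[[eid]]
  if (from_member == ed$m1) {
    k <- pos - e$start[ed$m1]
    c <- leftmost_col(ed$b1, k)
    o2 <- ones_before(ed$b2, c)
    if (ed$orient == 1L) e$start[ed$m2] + o2 else e$end[ed$m2] - o2
  } else {
    k <- if (ed$orient == 1L) pos - e$start[ed$m2] else e$end[ed$m2] - pos
    c <- leftmost_col(ed$b2, k)
    e$start[ed$m1] + ones_before(ed$b1, c)
  }
}

# Breadth-first propagation of a breakpoint from seed_member through the
# group's internal edges; one position per member.  When two paths map a
# breakpoint to different positions on one member (possible when gap
# placement differs between overlapping alignments) the minimum is kept
# and a reconciliation note logged.
eng_propagate <- function(e, mhg_id, seed_member, pos) {
  if (pos < e$start[seed_member] || pos > e$end[seed_member]) {
    abort("breakpoint outside the seed member")
  }
  members <- e$mhg_members[[mhg_id]]
  posmap <- setNames(rep(NA_real_, length(members)), members)
  posmap[as.character(seed_member)] <- pos
  eids <- e$mhg_edges[[mhg_id]]
  queue <- seed_member
  while (length(queue)) {
    m <- queue[1]; queue <- queue[-1]
    pm <- posmap[[as.character(m)]]
    for (eid in eids) {
      ed <- e$edges[[eid]]
      other <- if (ed$m1 == m) ed$m2 else if (ed$m2 == m) ed$m1 else next
      p2 <- edge_map_pos(e, eid, m, pm)
      key <- as.character(other)
      cur <- posmap[[key]]
      if (is.na(cur)) {
        posmap[[key]] <- p2
        queue <- c(queue, other)
      } else if (cur != p2) {
        eng_note(e, sprintf(
          "inconsistent breakpoint propagation on member %s (%s vs %s); keeping minimum",
          key, format(cur), format(p2)))
        posmap[[key]] <- min(cur, p2)
      }
    }
  }
  if (anyNA(posmap)) abort("internal error: disconnected homology group")
  posmap
}

# Column cut of an internal edge implied by per-member cut positions.
edge_column_cut <- function(e, ed, cuts) {
  k1 <- cuts[[as.character(ed$m1)]] - e$start[ed$m1]
  c1 <- leftmost_col(ed$b1, k1)
  p2 <- cuts[[as.character(ed$m2)]]
  k2 <- if (ed$orient == 1L) p2 - e$start[ed$m2] else e$end[ed$m2] - p2
  c2 <- leftmost_col(ed$b2, k2)
  if (c1 != c2) {
    # differing gap placement between overlapping alignments; reconcile
    eng_note(e, sprintf("edge column cut mismatch (%d vs %d); keeping minimum", c1, c2))
    min(c1, c2)
  } else {
    c1
  }
}

# Split one group at propagated cut positions into a left and a right
# group.  For +1-strand members left is [start, cut); for -1-strand
# members the two sides swap so that homology columns stay together.
# Members whose cut sits at a boundary go entirely to one side.
eng_partition <- function(e, mhg_id, cuts) {
  members <- e$mhg_members[[mhg_id]]
  left_iv <- list(); right_iv <- list()
  for (m in members) {
    p <- min(max(cuts[[as.character(m)]], e$start[m]), e$end[m])
    if (e$strand[m] == 1L) {
      left_iv[[as.character(m)]] <- c(e$start[m], p)
      right_iv[[as.character(m)]] <- c(p, e$end[m])
    } else {
      left_iv[[as.character(m)]] <- c(p, e$end[m])
      right_iv[[as.character(m)]] <- c(e$start[m], p)
    }
  }
  nonempty <- function(iv) iv[2] > iv[1]
  anyL <- any(vapply(left_iv, nonempty, logical(1)))
  anyR <- any(vapply(right_iv, nonempty, logical(1)))
  if (!anyL || !anyR) return(invisible(NULL))   # breakpoint at an existing boundary
  e$n_splits <- e$n_splits + 1L

  left_id <- e$n_mhgs + 1L; right_id <- e$n_mhgs + 2L
  e$n_mhgs <- right_id
  pieceL <- setNames(rep(NA_integer_, length(members)), members)
  pieceR <- pieceL
  for (m in members) {
    key <- as.character(m)
    li <- left_iv[[key]]; ri <- right_iv[[key]]
    if (nonempty(li) && nonempty(ri)) {
      e$active[m] <- FALSE
      pl <- eng_new_member(e, e$genome[m], li[1], li[2], e$strand[m], left_id)
      pr <- eng_new_member(e, e$genome[m], ri[1], ri[2], e$strand[m], right_id)
      pieceL[key] <- pl; pieceR[key] <- pr
      eng_idx_replace(e, m, list(pl, pr))
    } else if (nonempty(li)) {
      e$mhg[m] <- left_id; pieceL[key] <- m
    } else {
      e$mhg[m] <- right_id; pieceR[key] <- m
    }
  }
  e$mhg_members[[left_id]] <- unname(pieceL[!is.na(pieceL)])
  e$mhg_members[[right_id]] <- unname(pieceR[!is.na(pieceR)])

  edgesL <- integer(); edgesR <- integer()
  for (eid in e$mhg_edges[[mhg_id]]) {
    ed <- e$edges[[eid]]
    c <- edge_column_cut(e, ed, cuts)
    L <- length(ed$b1)
    # columns [0, c) hold member m1's residues on its genome-left side,
    # which is the group's left side iff m1 is on the + relative strand
    lowL <- e$strand[ed$m1] == 1L
    k1 <- as.character(ed$m1); k2 <- as.character(ed$m2)
    attach_edge <- function(cols, side) {
      ms <- if (side == "L") c(pieceL[k1], pieceL[k2]) else c(pieceR[k1], pieceR[k2])
      if (anyNA(ms)) {
        eng_note(e, "internal edge dropped at a degenerate split")
        return(NULL)
      }
      nid <- eng_new_edge(e, ms[1], ms[2], ed$b1[cols], ed$b2[cols], ed$orient)
      if (side == "L") edgesL <<- c(edgesL, nid) else edgesR <<- c(edgesR, nid)
    }
    if (c > 0L) attach_edge(seq_len(c), if (lowL) "L" else "R")
    if (c < L) attach_edge((c + 1L):L, if (lowL) "R" else "L")
  }
  e$mhg_edges[[left_id]] <- edgesL
  e$mhg_edges[[right_id]] <- edgesR
  e$mhg_members[[mhg_id]] <- integer()
  e$mhg_edges[[mhg_id]] <- integer()
  invisible(list(left = left_id, right = right_id))
}

# Merge group b into group a via an alignment edge connecting member mx
# (in a) to member my (in b) across their full extents.  Relative
# strands of b's members flip when the connecting alignment is
# opposite-orientation relative to the current frames.
eng_merge <- function(e, mhg_a, mhg_b, mx, my, b1, b2, orient) {
  if (mhg_a == mhg_b) {
    if (mx != my) {
      if (e$strand[mx] * orient != e$strand[my]) {
        eng_note(e, "orientation-inconsistent cycle; alignment edge not added")
      } else {
        e$mhg_edges[[mhg_a]] <- c(e$mhg_edges[[mhg_a]],
                                  eng_new_edge(e, mx, my, b1, b2, orient))
      }
    }
    return(mhg_a)
  }
  if (e$strand[mx] * orient != e$strand[my]) {
    for (m in e$mhg_members[[mhg_b]]) e$strand[m] <- -e$strand[m]
  }
  for (m in e$mhg_members[[mhg_b]]) e$mhg[m] <- mhg_a
  e$mhg_members[[mhg_a]] <- c(e$mhg_members[[mhg_a]], e$mhg_members[[mhg_b]])
  e$mhg_edges[[mhg_a]] <- c(e$mhg_edges[[mhg_a]], e$mhg_edges[[mhg_b]],
                            eng_new_edge(e, mx, my, b1, b2, orient))
  e$mhg_members[[mhg_b]] <- integer()
  e$mhg_edges[[mhg_b]] <- integer()
  e$n_merges <- e$n_merges + 1L
  mhg_a
}

# Apply one cut request: split the group owning position p on genome g.
eng_apply_cut <- function(e, g, p) {
  m <- eng_find_member(e, g, p)
  if (is.na(m)) abort(sprintf("internal error: no member covers %s:%s", g, format(p)))
  cuts <- eng_propagate(e, e$mhg[m], m, p)
  eng_partition(e, e$mhg[m], cuts)
}

# Process one alignment-graph edge: drive the segmentations of the query
# and subject spans to a common refinement (mapping breakpoints through
# the alignment's bit arrays), then merge each aligned pair of post-split
# groups through the restricted alignment.
eng_process_edge <- function(e, qg, qs, qe, sg, ss, se, orient, qbits, sbits) {
  o <- if (orient == "same") 1L else -1L
  al_fwd <- function(p) {        # query position -> subject position
    c <- leftmost_col(qbits, p - qs)
    k <- ones_before(sbits, c)
    if (o == 1L) ss + k else se - k
  }
  al_rev <- function(p) {        # subject position -> query position
    k <- if (o == 1L) p - ss else se - p
    qs + ones_before(qbits, leftmost_col(sbits, k))
  }
  repeat {
    req <- list()
    add <- function(g, p) {
      if (eng_needs_cut(e, g, p)) req[[length(req) + 1L]] <<- list(g = g, p = p)
    }
    add(qg, qs); add(qg, qe); add(sg, ss); add(sg, se)
    for (b in eng_boundaries(e, qg, qs, qe)) add(sg, al_fwd(b))
    for (b in eng_boundaries(e, sg, ss, se)) add(qg, al_rev(b))
    if (!length(req)) break
    ord <- order(vapply(req, function(r) r$g, character(1)),
                 vapply(req, function(r) r$p, numeric(1)))
    r <- req[[ord[1]]]
    eng_apply_cut(e, r$g, r$p)
  }

  # ordered query pieces spanning [qs, qe)
  ix <- e$idx[[qg]]
  sel <- which(ix$start >= qs & ix$end <= qe)
  sel <- sel[order(ix$start[sel])]
  for (s_i in sel) {
    a <- ix$start[s_i]; b <- ix$end[s_i]; mq <- ix$member[s_i]
    ca <- leftmost_col(qbits, a - qs)
    cb <- leftmost_col(qbits, b - qs)
    oa <- ones_before(sbits, ca); ob <- ones_before(sbits, cb)
    if (ob == oa) next                      # query piece has no subject homolog
    if (o == 1L) { sa <- ss + oa; sb <- ss + ob } else { sa <- se - ob; sb <- se - oa }
    ms <- eng_find_member(e, sg, sa)
    if (is.na(ms) || e$start[ms] != sa || e$end[ms] != sb) {
      eng_note(e, sprintf("no clean subject counterpart for %s:%s-%s; pair skipped",
                          qg, format(a), format(b)))
      next
    }
    if (mq == ms) next
    cols <- if (cb > ca) (ca + 1L):cb else integer(0)
    eng_merge(e, e$mhg[mq], e$mhg[ms], mq, ms, qbits[cols], sbits[cols], o)
  }
  invisible(NULL)
}

# Maximality repair: alignment endpoints falling strictly inside a
# homologous run (overlapping alignments with slightly different
# extents) leave adjacent groups whose members abut bijectively and
# strand-consistently.  Such neighbours are one maximal group; coalesce
# them.  `rows` is a list of member tibbles (genome, start, end,
# strand_num).
coalesce_groups <- function(rows) {
  repeat {
    loc <- list()   # "genome:pos" -> c(group, member) keyed by start/end
    for (gi in seq_along(rows)) {
      tb <- rows[[gi]]
      for (mi in seq_len(nrow(tb))) {
        loc[[paste0("s", tb$genome[mi], ":", tb$start[mi])]] <- c(gi, mi)
        loc[[paste0("e", tb$genome[mi], ":", tb$end[mi])]] <- c(gi, mi)
      }
    }
    merged <- FALSE
    for (gi in seq_along(rows)) {
      tb <- rows[[gi]]
      # partner of member mi on the group-right side, or NULL
      partner <- function(mi) {
        key <- if (tb$strand_num[mi] == 1L) {
          paste0("s", tb$genome[mi], ":", tb$end[mi])
        } else {
          paste0("e", tb$genome[mi], ":", tb$start[mi])
        }
        loc[[key]]
      }
      p1 <- partner(1L)
      if (is.null(p1) || p1[1] == gi) next
      gj <- p1[1]; other <- rows[[gj]]
      if (nrow(other) != nrow(tb)) next
      f <- tb$strand_num[1] * other$strand_num[p1[2]]
      ok <- TRUE
      pj <- integer(nrow(tb))
      for (mi in seq_len(nrow(tb))) {
        p <- partner(mi)
        if (is.null(p) || p[1] != gj ||
            other$strand_num[p[2]] != tb$strand_num[mi] * f) { ok <- FALSE; break }
        pj[mi] <- p[2]
      }
      if (!ok || anyDuplicated(pj)) next
      for (mi in seq_len(nrow(tb))) {
        if (tb$strand_num[mi] == 1L) {
          tb$end[mi] <- other$end[pj[mi]]
        } else {
          tb$start[mi] <- other$start[pj[mi]]
        }
      }
      rows[[gi]] <- tb
      rows[[gj]] <- NULL
      merged <- TRUE
      break
    }
    if (!merged) return(rows)
  }
}

# Final partition: active groups coalesced to maximal length, members
# sorted, deterministic ids, canonical frame (first member on the +
# strand), with per-genome non-overlap verified.
eng_finalize <- function(e) {
  groups <- which(lengths(e$mhg_members) > 0L)
  rows <- lapply(groups, function(gid) {
    ms <- e$mhg_members[[gid]]
    tb <- tibble(genome = e$genome[ms], start = e$start[ms],
                 end = e$end[ms], strand_num = e$strand[ms])
    tb <- arrange(tb, .data$genome, .data$start)
    if (tb$strand_num[1] == -1L) tb$strand_num <- -tb$strand_num
    tb
  })
  rows <- coalesce_groups(rows)
  if (length(rows)) {
    key_g <- vapply(rows, function(tb) tb$genome[1], character(1))
    key_s <- vapply(rows, function(tb) tb$start[1], numeric(1))
    o <- order(key_g, key_s)
    rows <- rows[o]
  }
  out <- bind_rows(lapply(seq_along(rows), function(i) {
    tb <- rows[[i]]
    tibble(mhg_id = i, genome = tb$genome,
           start = as.integer(tb$start), end = as.integer(tb$end),
           strand = ifelse(tb$strand_num == 1L, "+", "-"))
  }))
  if (nrow(out) == 0L) {
    out <- tibble(mhg_id = integer(), genome = character(),
                  start = integer(), end = integer(), strand = character())
  }
  # per-genome non-overlap is a hard output invariant
  for (g in unique(out$genome)) {
    s <- out[out$genome == g, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
      abort(sprintf("internal consistency error: overlapping members on genome %s", g))
    }
  }
  out
}
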