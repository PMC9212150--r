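# Built-in local aligner for small inputs (fixtures and examples).
#
# Seed-and-extend, ungapped: shared k-mers seed diagonals, and every
# seeded diagonal is scanned for its maximal-scoring ungapped segments
# (Ruzzo-Tompa), on both strands.  Bit arrays are therefore all-ones;
# gapped alignments enter the package via BLAST tabular input instead.
# Scores are raw match/mismatch sums and play the role of bit scores in
# relative-score filtering (which is scale-free).

# All maximal scoring subsequences of a score vector (Ruzzo-Tompa).
# Returns a matrix with columns start, end (1-based element indices).
rt_maximal_segments <- function(scores) {
  n <- length(scores)
  starts <- integer(0); ends <- integer(0); Ls <- numeric(0); Rs <- numeric(0)
  cum <- 0
  for (i in seq_len(n)) {
    x <- scores[i]
    if (x <= 0) { cum <- cum + x; next }
    st <- i; en <- i; L <- cum; R <- cum + x
    cum <- cum + x
    repeat {
      k <- length(Ls)
      j <- 0L
      while (k >= 1L) {           # nearest list entry with L_j < L
        if (Ls[k] < L) { j <- k; break }
        k <- k - 1L
      }
      if (j == 0L || Rs[j] >= R) {
        starts <- c(starts, st); ends <- c(ends, en)
        Ls <- c(Ls, L); Rs <- c(Rs, R)
        break
      }
      # extend entry j through the current candidate and re-test
      st <- starts[j]; L <- Ls[j]
      starts <- starts[seq_len(j - 1L)]; ends <- ends[seq_len(j - 1L)]
      Ls <- Ls[seq_len(j - 1L)]; Rs <- Rs[seq_len(j - 1L)]
    }
  }
  cbind(start = starts, end = ends)
}

# Maximal-scoring ungapped segments along one diagonal.
# m: logical match vector; returns tibble rows (a, b, score) with
# 1-based [a, b] index range into m.
diagonal_segments <- function(m, match, mismatch, score_floor) {
  r <- rle(m)
  run_scores <- ifelse(r$values, match, mismatch) * r$lengths
  seg <- rt_maximal_segments(run_scores)
  if (nrow(seg) == 0L) return(NULL)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  a <- run_start[seg[, "start"]]
  b <- run_end[seg[, "end"]]
  sc <- vapply(seq_len(nrow(seg)), function(i) {
    sum(run_scores[seg[i, "start"]:seg[i, "end"]])
  }, numeric(1))
  keep <- sc >= score_floor
  if (!any(keep)) return(NULL)
  list(a = a[keep], b = b[keep], score = sc[keep])
}

# Diagonals (j - i, 0-based) on which x and y share a k-mer.
shared_diagonals <- function(x, y, k) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx < k || ny < k) return(integer(0))
  xk <- substring(x, 1:(nx - k + 1L), k:nx)
  yk <- substring(y, 1:(ny - k + 1L), k:ny)
  ypos <- split(seq_along(yk), yk)
  hit <- ypos[xk]
  ij <- which(!vapply(hit, is.null, logical(1)))
  if (!length(ij)) return(integer(0))
  d <- unlist(lapply(ij, function(i) hit[[i]] - i), use.names = FALSE)
  sort(unique(d))
}

# One genome pair, one strand.  Returns alignment rows in y's forward
# coordinates when rc = FALSE; caller converts when y was
# reverse-complemented.
scan_pair <- function(xid, x, yid, y, match, mismatch, score_floor, word_size,
                      skip_diag0 = FALSE) {
  xv <- utf8ToInt(x); yv <- utf8ToInt(y)
  n_code <- utf8ToInt("N")
  nx <- length(xv); ny <- length(yv)
  diags <- shared_diagonals(x, y, word_size)
  if (skip_diag0) diags <- diags[diags > 0L]
  rows <- list()
  for (d in diags) {
    i0 <- max(0L, -d); i1 <- min(nx, ny - d) - 1L
    if (i1 < i0) next
    ix <- (i0 + 1L):(i1 + 1L)
    m <- xv[ix] == yv[ix + d] & xv[ix] != n_code
    seg <- diagonal_segments(m, match, mismatch, score_floor)
    if (is.null(seg)) next
    for (s in seq_along(seg$a)) {
      qa <- i0 + seg$a[s] - 1L; qb <- i0 + seg$b[s]     # 0-based half-open
      rows[[length(rows) + 1L]] <- list(
        q_start = qa, q_end = qb, s_start = qa + d, s_end = qb + d,
        score = seg$score[s]
      )
    }
  }
  rows
}

#' Compute pairwise local alignments with the built-in exact aligner
#'
#' Intended for small inputs (fixtures, examples; up to a few tens of kb
#' per genome).  Finds, for every genome pair and for every genome
#' against itself, all maximal-scoring ungapped local alignments above
#' `score_floor` on both strands, seeded by shared `word_size`-mers.
#' Trivial full-length self hits are emitted so that
#' [max_self_bitscore()] has its reference point; [filter_alignments()]
#' drops them again.  Output order is deterministic.
#'
#' @param genomes Genome tibble ([read_genomes()] schema).
#' @param match,mismatch Per-column scores (mismatch must be negative).
#' @param gap Accepted for interface compatibility; the built-in aligner
#'   is ungapped and ignores it (gapped alignments come from BLAST
#'   tabular input).
#' @param score_floor Minimum segment score to report.
#' @param word_size Seed k-mer length; homologies shorter than this are
#'   invisible to the aligner.
#' @return Alignment tibble (see `read_blast_pairs()` for the schema).
#' @export
align_local <- function(genomes, match = 2, mismatch = -3, gap = NULL,
                        score_floor = 50, word_size = 9L) {
  if (mismatch >= 0) abort("`mismatch` must be negative")
  n <- nrow(genomes)
  out <- list()
  emit <- function(qid, sid, qa, qb, sa, sb, orient, score, qaln, saln) {
    out[[length(out) + 1L]] <<- alignment_tbl(
      query_genome = qid, query_start = qa, query_end = qb,
      subject_genome = sid, subject_start = sa, subject_end = sb,
      orientation = orient, bitscore = score,
      query_bits = list(rep(1L, qb - qa)), subject_bits = list(rep(1L, qb - qa)),
      query_aln = substr(genomes$sequence[genomes$genome == qid], qa + 1L, qb),
      subject_aln = saln
    )
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      x <- genomes$sequence[i]; y <- genomes$sequence[j]
      xid <- genomes$genome[i]; yid <- genomes$genome[j]
      selfpair <- i == j
      if (selfpair) {
        # trivial full-length self hit, reference for the score filter
        emit(xid, xid, 0L, nchar(x), 0L, nchar(x), "same",
             match * nchar(x), x, x)
      }
      fw <- scan_pair(xid, x, yid, y, match, mismatch, score_floor, word_size,
                      skip_diag0 = selfpair)
      for (h in fw) {
        emit(xid, yid, h$q_start, h$q_end, h$s_start, h$s_end, "same", h$score,
             NULL, substr(y, h$s_start + 1L, h$s_end))
      }
      yrc <- revcomp_chr(y)
      ny <- nchar(y)
      rv <- scan_pair(xid, x, yid, yrc, match, mismatch, score_floor, word_size)
      for (h in rv) {
        sa <- ny - h$s_end; sb <- ny - h$s_start
        if (selfpair) {
          # each inverted self repeat is found twice (roles swapped);
          # keep one canonical copy, drop pure self-palindromes
          if (h$q_start > sa || (h$q_start == sa && h$q_end >= sb)) next
        }
        emit(xid, yid, h$q_start, h$q_end, sa, sb, "opposite", h$score,
             NULL, substr(yrc, h$s_start + 1L, h$s_end))
      }
    }
  }
  al <- if (length(out)) bind_rows(out) else alignment_tbl()
  al <- arrange(al, .data$query_genome, .data$subject_genome,
                .data$query_start, .data$subject_start, .data$orientation)
  validate_alignments(al)
  al
}
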