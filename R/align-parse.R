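# Pairwise local alignments are carried as a tibble with one row per
# alignment and the columns
#   query_genome, query_start, query_end    (0-based half-open, + strand)
#   subject_genome, subject_start, subject_end
#   orientation ("same"/"opposite"), bitscore,
#   query_bits, subject_bits (list columns of integer 0/1 vectors in
#   alignment-column order following the query),
#   query_aln, subject_aln (aligned sequence strings, possibly NA).
# The bit arrays are the only carrier of cross-genome coordinate mapping:
# 1 marks a residue, 0 a gap column.

alignment_tbl <- function(query_genome = character(), query_start = integer(),
                          query_end = integer(), subject_genome = character(),
                          subject_start = integer(), subject_end = integer(),
                          orientation = character(), bitscore = double(),
                          query_bits = list(), subject_bits = list(),
                          query_aln = character(), subject_aln = character()) {
  tibble(query_genome, query_start, query_end,
         subject_genome, subject_start, subject_end,
         orientation, bitscore, query_bits, subject_bits,
         query_aln, subject_aln)
}

validate_alignments <- function(al) {
  for (i in seq_len(nrow(al))) {
    qb <- al$query_bits[[i]]; sb <- al$subject_bits[[i]]
    if (length(qb) != length(sb)) {
      abort(sprintf("alignment %d: bit arrays differ in length", i))
    }
    if (any(qb == 0L & sb == 0L)) {
      abort(sprintf("alignment %d: column with a gap in both sequences", i))
    }
    if (sum(qb) != al$query_end[i] - al$query_start[i]) {
      abort(sprintf("alignment %d: query residue count disagrees with coordinates", i))
    }
    if (sum(sb) != al$subject_end[i] - al$subject_start[i]) {
      abort(sprintf("alignment %d: subject residue count disagrees with coordinates", i))
    }
  }
  invisible(al)
}

#' Parse pairwise local alignments from BLAST tabular output
#'
#' Expects the extended tabular format
#' `-outfmt "6 qseqid sseqid qstart qend sstart send bitscore qseq sseq"`
#' with 1-based inclusive coordinates and reverse-strand subject hits
#' encoded by `sstart > send`.  Gap characters (`-`) in `qseq`/`sseq`
#' define the per-alignment bit arrays; a bit is 1 where the row's
#' sequence has a residue.  Reverse-strand hits are converted to a
#' plus-coordinate subject segment with `orientation = "opposite"`; their
#' aligned sequence columns already follow the query in BLAST output, so
#' column order is preserved.
#'
#' @param path BLAST tabular file.
#' @return Alignment tibble (see [align_local()] for the schema).
#' @export
read_blast_pairs <- function(path) {
  if (!file.exists(path)) abort(sprintf("BLAST tabular file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", blank.lines.skip = TRUE)
  if (ncol(raw) < 9L) {
    abort("expected 9 columns: qseqid sseqid qstart qend sstart send bitscore qseq sseq")
  }
  names(raw)[1:9] <- c("qseqid", "sseqid", "qstart", "qend",
                       "sstart", "send", "bitscore", "qseq", "sseq")
  qstart <- as.integer(raw$qstart); qend <- as.integer(raw$qend)
  sstart <- as.integer(raw$sstart); send <- as.integer(raw$send)
  if (any(qstart > qend)) abort("query coordinates must be forward (qstart <= qend)")
  opposite <- sstart > send
  s_lo <- ifelse(opposite, send, sstart)
  s_hi <- ifelse(opposite, sstart, send)
  qseq <- toupper(raw$qseq); sseq <- toupper(raw$sseq)
  bits <- function(s) lapply(strsplit(s, ""), function(ch) as.integer(ch != "-"))
  al <- alignment_tbl(
    query_genome = raw$qseqid,
    query_start = qstart - 1L, query_end = qend,
    subject_genome = raw$sseqid,
    subject_start = s_lo - 1L, subject_end = s_hi,
    orientation = ifelse(opposite, "opposite", "same"),
    bitscore = as.numeric(raw$bitscore),
    query_bits = bits(qseq), subject_bits = bits(sseq),
    query_aln = qseq, subject_aln = sseq
  )
  validate_alignments(al)
  al
}

#' Serialize alignments back to BLAST tabular
#'
#' Inverse of [read_blast_pairs()]: coordinates return to 1-based
#' inclusive and reverse-strand subjects to `sstart > send`.
#'
#' @param alignments Alignment tibble carrying `query_aln`/`subject_aln`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_pairs <- function(alignments, path) {
  if (any(is.na(alignments$query_aln))) {
    abort("alignments lack aligned sequence strings; cannot serialize")
  }
  opp <- alignments$orientation == "opposite"
  sstart <- ifelse(opp, alignments$subject_end, alignments$subject_start + 1L)
  send <- ifelse(opp, alignments$subject_start + 1L, alignments$subject_end)
  lines <- paste(alignments$query_genome, alignments$subject_genome,
                 alignments$query_start + 1L, alignments$query_end,
                 sstart, send,
                 format(alignments$bitscore, trim = TRUE, scientific = FALSE),
                 alignments$query_aln, alignments$subject_aln, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Maximum self-alignment bit score of a genome
#'
#' The reference point for relative bit-score filtering: the maximum bit
#' score among alignments of a genome against itself (dominated by the
#' trivial full-length self hit).
#'
#' @param alignments Alignment tibble in which query and subject lie on
#'   the same genome.
#' @return A named numeric vector, one maximum per genome.
#' @export
max_self_bitscore <- function(alignments) {
  if (nrow(alignments) == 0L) abort("no self alignments supplied")
  if (any(alignments$query_genome != alignments$subject_genome)) {
    abort("max_self_bitscore expects self alignments (query genome == subject genome)")
  }
  m <- tapply(alignments$bitscore, alignments$query_genome, max)
  setNames(as.numeric(m), names(m))
}

#' Filter alignments by relative bit score
#'
#' Keeps an alignment iff its bit score is at least `fraction` times the
#' maximum self-alignment bit score of its query's genome.  Trivial self
#' hits (query and subject are the identical interval of one genome) are
#' always dropped.  Optionally also enforces a minimum number of
#' alignment columns.
#'
#' @param alignments Alignment tibble.
#' @param max_scores Named numeric vector of per-genome maximum self bit
#'   scores (see [max_self_bitscore()]).
#' @param fraction Relative bit-score threshold in (0, 1].
#' @param min_length Minimum alignment length in columns (default 0, no
#'   length filter).
#' @return The retained alignment rows.
#' @export
filter_alignments <- function(alignments, max_scores, fraction = 0.05,
                              min_length = 0L) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  missing <- setdiff(unique(alignments$query_genome), names(max_scores))
  if (length(missing)) {
    abort(sprintf("no maximum self bit score for genome(s): %s",
                  paste(missing, collapse = ", ")))
  }
  trivial <- alignments$query_genome == alignments$subject_genome &
    alignments$query_start == alignments$subject_start &
    alignments$query_end == alignments$subject_end &
    alignments$orientation == "same"
  keep <- !trivial &
    alignments$bitscore >= fraction * unname(max_scores[alignments$query_genome]) &
    lengths(alignments$query_bits) >= min_length
  alignments[keep, , drop = FALSE]
}
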