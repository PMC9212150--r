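# Shared test helpers: hand-built alignment rows, tiny genome pairs, and
# an end-to-end fixture pipeline used by several suites.

# One alignment row from explicit pieces (bits as 0/1 vectors).
make_alignment <- function(qg, qs, qe, sg, ss, se, orientation = "same",
                           bitscore = 100, qbits = NULL, sbits = NULL) {
  L <- max(qe - qs, se - ss)
  qbits <- qbits %||% rep(1L, L)
  sbits <- sbits %||% rep(1L, L)
  tibble::tibble(
    query_genome = qg, query_start = qs, query_end = qe,
    subject_genome = sg, subject_start = ss, subject_end = se,
    orientation = orientation, bitscore = bitscore,
    query_bits = list(qbits), subject_bits = list(sbits),
    query_aln = NA_character_, subject_aln = NA_character_
  )
}

`%||%` <- rlang::`%||%`

# Random gapped bit-array pair with no all-gap columns.
random_bits <- function(L) {
  repeat {
    qb <- rbinom(L, 1, 0.8)
    sb <- rbinom(L, 1, 0.8)
    bad <- qb == 0L & sb == 0L
    sb[bad] <- 1L
    if (sum(qb) > 0 && sum(sb) > 0) return(list(q = as.integer(qb), s = as.integer(sb)))
  }
}

# Built-in-aligner pipeline on a fixture: self-alignments feed the
# relative-score filter, then delineation.
fixture_pipeline <- function(genomes, bitscore_fraction = 0.01, ...) {
  al <- align_local(genomes, ...)
  selfs <- al[al$query_genome == al$subject_genome, , drop = FALSE]
  flt <- filter_alignments(al, max_self_bitscore(selfs),
                           fraction = bitscore_fraction)
  list(partition = mhg_delineate(flt), alignments = flt)
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

write_tmp_lines <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
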