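# Internal helpers shared across modules.  Coordinates are 0-based
# half-open throughout; bit arrays are integer vectors of 0/1 where 1
# marks a residue and 0 a gap column.

# Leftmost alignment-column count c (0..L) such that the number of 1s in
# `bits` over columns [0, c) equals k.  k must be attainable.
leftmost_col <- function(bits, k) {
  if (k == 0L) return(0L)
  c <- match(k, cumsum(bits))
  if (is.na(c)) {
    abort(sprintf("residue offset %d exceeds the %d residues in the bit array",
                  k, sum(bits)))
  }
  c
}

# Number of 1s in `bits` over columns [0, c).
ones_before <- function(bits, c) {
  if (c == 0L) 0L else sum(bits[seq_len(c)])
}

# Maybe-seeded evaluation: if seed is NULL use the caller's RNG stream,
# otherwise run under a local seed without touching the global stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Union length of a set of half-open intervals (two-column matrix or
# data frame with start/end).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) {
      tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i]
    } else {
      ce <- max(ce, end[i])
    }
  }
  tot + (ce - cs)
}

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string", what))
  }
}
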