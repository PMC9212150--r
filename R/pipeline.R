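#' Run configuration
#'
#' Collects the thresholds and paths a full run depends on, validates
#' their ranges, and provides a stable hash that output writers embed as
#' a reproducibility record.
#'
#' @param bitscore_fraction Relative bit-score threshold in (0, 1].
#' @param min_alignment_length Minimum alignment columns (>= 0).
#' @param min_taxa Minimum distinct genomes per group for coverage
#'   analytics (>= 2).
#' @param branch_length_floor Internal-branch floor for
#'   [filter_informative()].
#' @param bootstrap_B Bootstrap replicates.
#' @param seed Integer seed.
#' @param paths Named list of input/output paths (free-form).
#' @return A list of class `mhg_config` with a `hash` field.
#' @export
mhg_config <- function(bitscore_fraction = 0.05, min_alignment_length = 0L,
                       min_taxa = 2L, branch_length_floor = 0.0005,
                       bootstrap_B = 100L, seed = 1L, paths = list()) {
  if (bitscore_fraction <= 0 || bitscore_fraction > 1) {
    abort("`bitscore_fraction` must be in (0, 1]")
  }
  if (min_alignment_length < 0L) abort("`min_alignment_length` must be >= 0")
  if (min_taxa < 2L) abort("`min_taxa` must be >= 2")
  if (branch_length_floor < 0) abort("`branch_length_floor` must be >= 0")
  cfg <- list(bitscore_fraction = bitscore_fraction,
              min_alignment_length = as.integer(min_alignment_length),
              min_taxa = as.integer(min_taxa),
              branch_length_floor = branch_length_floor,
              bootstrap_B = as.integer(bootstrap_B),
              seed = as.integer(seed), paths = paths)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "paths")])
  structure(cfg, class = "mhg_config")
}

#' @export
print.mhg_config <- function(x, ...) {
  cat("<mhg_config>", x$hash, "\n")
  for (k in setdiff(names(x), c("paths", "hash"))) {
    cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  }
  invisible(x)
}

#' End-to-end delineation run
#'
#' Reads genomes and alignments (BLAST tabular, or computes them with
#' the built-in aligner), applies relative bit-score filtering against
#' per-genome self-alignment maxima, delineates the partition, and
#' optionally writes TSV/BED output stamped with the config hash.
#'
#' @param cfg An [mhg_config()]; `cfg$paths` may name `fasta` (vector of
#'   FASTA paths), `blast_tab` (BLAST tabular file; omit to use the
#'   built-in aligner), `out_tsv`, `out_bed`.
#' @param genomes,alignments Alternatively, pass the objects directly.
#' @param verbose Log stage counts to stderr.
#' @return The `mhg_partition`, with the config attached as attribute
#'   `config`.
#' @export
run_delineate <- function(cfg = mhg_config(), genomes = NULL,
                          alignments = NULL, verbose = TRUE) {
  if (is.null(genomes)) {
    if (is.null(cfg$paths$fasta)) abort("no genomes: supply `genomes` or cfg$paths$fasta")
    genomes <- read_genomes(cfg$paths$fasta)
  }
  if (is.null(alignments)) {
    alignments <- if (!is.null(cfg$paths$blast_tab)) {
      read_blast_pairs(cfg$paths$blast_tab)
    } else {
      align_local(genomes)
    }
  }
  selfs <- alignments[alignments$query_genome == alignments$subject_genome, ,
                      drop = FALSE]
  part <- if (nrow(selfs)) {
    mhg_delineate(alignments, max_scores = max_self_bitscore(selfs),
                  bitscore_fraction = cfg$bitscore_fraction,
                  min_alignment_length = cfg$min_alignment_length,
                  verbose = verbose)
  } else {
    mhg_delineate(alignments, verbose = verbose)
  }
  attr(part, "config") <- cfg
  if (!is.null(cfg$paths$out_tsv)) write_mhg_tsv(part, cfg$paths$out_tsv, cfg$hash)
  if (!is.null(cfg$paths$out_bed)) write_mhg_bed(part, cfg$paths$out_bed)
  part
}

#' End-to-end recombinant-marker simulation run
#'
#' Thin wrapper over [marker_conflict_experiment()] wiring in the
#' config's seed and bootstrap size and optionally writing the report.
#'
#' @param cfg An [mhg_config()]; `cfg$paths` may name `out_rf` and
#'   `out_support` (TSV reports).
#' @param ... Passed to [marker_conflict_experiment()] (e.g.
#'   `replicates`, `k`, `seg_len`, `n_tips`).
#' @return The `marker_conflict` report.
#' @export
run_simulation <- function(cfg = mhg_config(), ...) {
  rep <- marker_conflict_experiment(B = cfg$bootstrap_B, seed = cfg$seed, ...)
  write_tsv_plain <- function(tb, path) {
    utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$paths$out_rf)) write_tsv_plain(rep$rf, cfg$paths$out_rf)
  if (!is.null(cfg$paths$out_support)) write_tsv_plain(rep$support, cfg$paths$out_support)
  rep
}
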