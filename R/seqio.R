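#' Read genome assemblies from FASTA
#'
#' Each FASTA record becomes one genome sequence in the registry; record
#' ids are taken up to the first whitespace and must be unique across all
#' files.  Sequences are uppercased.  Characters outside the A/C/G/T/N
#' alphabet are rejected in strict mode (the default, because the
#' alignment bit-array machinery assumes a 5-letter alphabet) or coerced
#' to N with `ambiguous = "N"`.
#'
#' @param paths Character vector of FASTA file paths.
#' @param ambiguous `"error"` (default) or `"N"`: what to do with IUPAC
#'   ambiguity codes other than N.
#' @return A tibble with columns `genome` (id), `sequence`, and `length`
#'   (bp), one row per genome.
#' @export
read_genomes <- function(paths, ambiguous = c("error", "N")) {
  ambiguous <- match.arg(ambiguous)
  sets <- lapply(paths, function(p) {
    if (!file.exists(p)) abort(sprintf("FASTA file not found: %s", p))
    s <- Biostrings::readBStringSet(p)
    if (length(s) == 0L) abort(sprintf("FASTA file has no records: %s", p))
    s
  })
  seqs <- unname(toupper(unlist(lapply(sets, as.character))))
  ids <- sub("\\s.*$", "", unlist(lapply(sets, names)))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate genome id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "error") {
      abort(sprintf("genome %s contains characters outside {A,C,G,T,N}; use ambiguous = \"N\" to coerce",
                    ids[which(bad)[1]]))
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  tibble(genome = unname(ids), sequence = unname(seqs), length = nchar(seqs))
}

#' Write genomes to a FASTA file
#'
#' @param genomes Genome tibble from [read_genomes()] or
#'   [simulate_genomes()].
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, width = 70L) {
  set <- Biostrings::DNAStringSet(setNames(genomes$sequence, genomes$genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read genomic features from GFF3 or BED
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention (GFF3 is 1-based inclusive; BED is already 0-based
#' half-open).
#'
#' @param path Feature file path.
#' @param format `"gff3"` or `"bed"`.
#' @param kind Feature kind to record (`"gene"`, `"intergenic"` or
#'   `"marker"`); defaults to `"gene"`.
#' @return A tibble with columns `genome`, `start`, `end` (0-based
#'   half-open), `kind`, and `name`.
#' @export
read_features <- function(path, format = c("gff3", "bed"), kind = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("feature file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) abort(sprintf("malformed %s file %s: %s",
                                      toupper(format), path, conditionMessage(e)))
  )
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(end0 <= start0)) {
    abort(sprintf("feature with end <= start after coordinate conversion in %s", path))
  }
  nm <- if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else if (!is.null(gr$name)) as.character(gr$name)
        else rep(NA_character_, length(gr))
  tibble(
    genome = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0,
    kind = kind,
    name = nm
  )
}

#' Write features to BED
#'
#' @param features Feature tibble (`genome`, `start`, `end`, and
#'   optionally `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  nm <- if ("name" %in% names(features)) features$name else "."
  nm[is.na(nm)] <- "."
  lines <- paste(features$genome, format(features$start, scientific = FALSE, trim = TRUE),
                 format(features$end, scientific = FALSE, trim = TRUE), nm, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Complement of genic features along a genome
#'
#' Returns the maximal intervals of each genome not covered by any of the
#' supplied (possibly overlapping) genic features, labelled
#' `kind = "intergenic"`.
#'
#' @param genomes Genome tibble (needs `genome` and `length`).
#' @param features Genic feature tibble.
#' @return Intergenic feature tibble in the same coordinate convention.
#' @export
complement_features <- function(genomes, features) {
  if (any(!features$genome %in% genomes$genome)) {
    abort("features refer to genomes absent from the genome set")
  }
  out <- lapply(seq_len(nrow(genomes)), function(i) {
    g <- genomes$genome[i]; len <- genomes$length[i]
    f <- features[features$genome == g, , drop = FALSE]
    if (any(f$end > len)) abort(sprintf("feature beyond the end of genome %s", g))
    genic <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    inter <- IRanges::setdiff(IRanges::IRanges(1L, len), genic)
    tibble(genome = g,
           start = IRanges::start(inter) - 1L,
           end = IRanges::end(inter),
           kind = "intergenic", name = NA_character_)
  })
  bind_rows(out)
}
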