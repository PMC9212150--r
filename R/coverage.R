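#' Pairwise occurrence of homology groups across taxa
#'
#' For every pair of taxa, counts the groups containing at least one
#' member from both; the diagonal counts the groups touching each taxon
#' at all.
#'
#' @param partition An `mhg_partition` (or compatible tibble).
#' @param taxa Taxon universe; defaults to the genomes present.
#' @return A long tibble `taxon_a`, `taxon_b`, `n_mhgs` covering all
#'   ordered pairs (symmetric).
#' @export
mhg_occurrence <- function(partition, taxa = NULL) {
  taxa <- taxa %||% sort(unique(partition$genome))
  sets <- lapply(split(partition$genome, partition$mhg_id), unique)
  grid <- expand.grid(taxon_a = taxa, taxon_b = taxa,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_mhgs <- vapply(seq_len(nrow(grid)), function(i) {
    a <- grid$taxon_a[i]; b <- grid$taxon_b[i]
    sum(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
  }, numeric(1))
  as_tibble(grid)
}

#' Widen an occurrence table into a taxa-by-taxa matrix
#'
#' @param occurrence Output of [mhg_occurrence()].
#' @return A symmetric integer matrix with taxa as dimnames.
#' @export
occurrence_matrix <- function(occurrence) {
  taxa <- unique(occurrence$taxon_a)
  m <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  m[cbind(occurrence$taxon_a, occurrence$taxon_b)] <- as.integer(occurrence$n_mhgs)
  m
}

# groups whose members span >= min_taxa distinct genomes
groups_with_min_taxa <- function(partition, min_taxa) {
  n_tax <- tapply(partition$genome, partition$mhg_id,
                  function(g) length(unique(g)))
  as.integer(names(n_tax)[n_tax >= min_taxa])
}

#' Base-pair coverage of genomes by homology groups
#'
#' Base pair coverage is the proportion of a genome (or of a masked
#' subset of it, e.g. its genic or intergenic part) covered by any
#' member of a group whose members span at least `min_taxa` distinct
#' genomes.
#'
#' @param partition An `mhg_partition`.
#' @param genomes Genome tibble (for lengths).
#' @param features Optional feature tibble restricting the denominator
#'   (e.g. genic features, or their [complement_features()]).
#' @param min_taxa One or more thresholds on the number of distinct
#'   genomes per group (>= 2).
#' @return A tibble `genome`, `min_taxa`, `covered_bp`, `total_bp`,
#'   `coverage`.
#' @export
mhg_base_coverage <- function(partition, genomes, features = NULL,
                              min_taxa = 2L) {
  if (any(min_taxa < 2L)) abort("`min_taxa` must be >= 2")
  if (!is.null(features) && nrow(features) == 0L) {
    abort("`features` was supplied but is empty")
  }
  out <- list()
  for (mt in sort(min_taxa)) {
    keep <- groups_with_min_taxa(partition, mt)
    p <- partition[partition$mhg_id %in% keep, , drop = FALSE]
    for (i in seq_len(nrow(genomes))) {
      g <- genomes$genome[i]; len <- genomes$length[i]
      mem <- p[p$genome == g, , drop = FALSE]
      cov <- IRanges::reduce(IRanges::IRanges(mem$start + 1L, mem$end))
      if (is.null(features)) {
        denom <- len
        covered <- sum(IRanges::width(cov))
      } else {
        f <- features[features$genome == g, , drop = FALSE]
        mask <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
        denom <- sum(IRanges::width(mask))
        covered <- sum(IRanges::width(IRanges::intersect(cov, mask)))
      }
      out[[length(out) + 1L]] <- tibble(
        genome = g, min_taxa = mt,
        covered_bp = covered, total_bp = denom,
        coverage = if (denom > 0) covered / denom else NA_real_
      )
    }
  }
  bind_rows(out)
}

#' Classify homology groups by genic context
#'
#' A group is `gene_only` when every member interval lies inside the
#' union of genic features of its genome (the union, not a single
#' feature, so operons and overlapping genes count), `intergenic_only`
#' when every member is disjoint from all genic features, and `mixed`
#' otherwise.
#'
#' @param partition An `mhg_partition`.
#' @param features Genic feature tibble; required for every genome that
#'   has members.
#' @return A tibble `mhg_id`, `location`.
#' @export
classify_mhg_location <- function(partition, features) {
  need <- unique(partition$genome)
  missing <- setdiff(need, unique(features$genome))
  if (length(missing)) {
    abort(sprintf("no features for genome(s): %s", paste(missing, collapse = ", ")))
  }
  genic <- lapply(split(features, features$genome), function(f) {
    IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
  })
  res <- vapply(split(seq_len(nrow(partition)), partition$mhg_id), function(i) {
    m <- partition[i, , drop = FALSE]
    inside <- disjoint <- TRUE
    for (j in seq_len(nrow(m))) {
      iv <- IRanges::IRanges(m$start[j] + 1L, m$end[j])
      gset <- genic[[m$genome[j]]]
      ov <- sum(IRanges::width(IRanges::intersect(iv, gset)))
      w <- IRanges::width(iv)
      if (ov < w) inside <- FALSE
      if (ov > 0L) disjoint <- FALSE
    }
    if (inside) "gene_only" else if (disjoint) "intergenic_only" else "mixed"
  }, character(1))
  tibble(mhg_id = as.integer(names(res)), location = unname(res))
}

#' Per-genome coverage table across genic contexts
#'
#' Convenience wrapper producing the columns `genome`, `min_taxa`,
#' `gene_cov`, `intergene_cov`, `total_cov`.
#'
#' @inheritParams mhg_base_coverage
#' @param genic Genic feature tibble.
#' @return A coverage tibble.
#' @export
coverage_table <- function(partition, genomes, genic, min_taxa = 2L) {
  inter <- complement_features(genomes, genic)
  tot <- mhg_base_coverage(partition, genomes, NULL, min_taxa)
  gen <- mhg_base_coverage(partition, genomes, genic, min_taxa)
  itg <- mhg_base_coverage(partition, genomes, inter, min_taxa)
  out <- tot[, c("genome", "min_taxa")]
  out$gene_cov <- gen$coverage
  out$intergene_cov <- itg$coverage
  out$total_cov <- tot$coverage
  out
}
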