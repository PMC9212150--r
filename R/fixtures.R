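# Synthetic genome sets with planted, ground-truth homology structure.
#
# Each family starts as one ancestral block; per genome the family may
# be lost, duplicated, inverted, translocated (placement order is
# random), fissioned (the block is physically split in a subset of
# genomes, which plants a homology boundary that delineation must
# recover in *all* genomes), and point-substituted.  Blocks are
# separated by random spacer sequence with no planted homology.
#
# The spacer base immediately flanking each block copy is a guard
# character chosen per (family, boundary, copy) so that no two copies --
# including reverse-complemented ones, and including pieces at a fission
# cut against the continuation base of unsplit copies -- share a
# matching flank.  Up to four copies per family (three split copies at a
# cut) this makes exact local alignments stop exactly at planted
# boundaries; beyond that the guard alphabet wraps and boundaries may
# shift by a few bases.

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Generate genomes with planted homologous blocks
#'
#' @param n_genomes Number of genomes.
#' @param n_families Number of ancestral block families.
#' @param block_len Ancestral block length in bp (scalar or per-family
#'   vector).
#' @param sub_rate Per-base substitution probability applied
#'   independently to every block copy.
#' @param p_inversion Probability a copy is inserted
#'   reverse-complemented.
#' @param p_duplication Probability a genome carries a second copy of a
#'   family.
#' @param p_loss Probability a genome lacks a family entirely (scalar or
#'   per-genome vector).
#' @param p_fission Probability a family is fissioned: a cut point is
#'   chosen and the block is physically split in a random proper subset
#'   of the genomes carrying it.
#' @param spacer_len Range (length-2 vector) of spacer lengths.
#' @param genome_budget Optional per-genome length cap; exceeding it is
#'   an error.
#' @param seed Optional seed scoped to this call.
#' @return A list: `genomes` (genome tibble) and `truth` (class
#'   `planted_truth`: `blocks` tibble with `family`, `piece`, `copy`,
#'   `genome`, `start`, `end`, `strand`; `events` tibble; `params`).
#' @export
simulate_genomes <- function(n_genomes = 4L, n_families = 6L, block_len = 300L,
                             sub_rate = 0, p_inversion = 0, p_duplication = 0,
                             p_loss = 0, p_fission = 0,
                             spacer_len = c(100L, 200L),
                             genome_budget = NULL, seed = NULL) {
  stopifnot(n_genomes >= 1L, n_families >= 1L, spacer_len[1] >= 4L)
  block_len <- rep_len(as.integer(block_len), n_families)
  p_loss <- rep_len(p_loss, n_genomes)
  with_seed_opt(seed, {
    fam_seq <- vapply(block_len, random_dna, character(1))
    fissioned <- runif(n_families) < p_fission & block_len >= 120L
    cut_at <- rep(NA_integer_, n_families)
    for (f in which(fissioned)) cut_at[f] <- sample(50:(block_len[f] - 50L), 1L)
    split_in <- matrix(FALSE, n_genomes, n_families)
    for (f in which(fissioned)) {
      sp <- runif(n_genomes) < 0.5
      if (!any(sp)) sp[sample.int(n_genomes, 1L)] <- TRUE
      if (all(sp) && n_genomes > 1L) sp[sample.int(n_genomes, 1L)] <- FALSE
      split_in[, f] <- sp
    }
    # per-(family, boundary) guard alphabets; indexed by global copy number
    permL <- lapply(seq_len(n_families), function(f) sample(DNA_BASES))
    permR <- lapply(seq_len(n_families), function(f) sample(DNA_BASES))
    permCutR <- lapply(seq_len(n_families), function(f) {
      if (!fissioned[f]) return(NULL)
      sample(setdiff(DNA_BASES, substr(fam_seq[f], cut_at[f] + 1L, cut_at[f] + 1L)))
    })
    permCutL <- lapply(seq_len(n_families), function(f) {
      if (!fissioned[f]) return(NULL)
      sample(setdiff(DNA_BASES, substr(fam_seq[f], cut_at[f], cut_at[f])))
    })
    guard <- function(perm, c) perm[(c - 1L) %% length(perm) + 1L]

    # pass 1: copies, strands, substitutions, events
    copy_count <- integer(n_families)
    split_count <- integer(n_families)   # cut-guard rank among split copies
    plan <- list()      # per genome: list of units
    events <- list()
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("g%d", g)
      units <- list()
      for (f in seq_len(n_families)) {
        if (runif(1) < p_loss[g]) {
          events[[length(events) + 1L]] <- tibble(genome = gid, family = f,
                                                  event = "loss")
          next
        }
        n_copies <- 1L + (runif(1) < p_duplication)
        if (n_copies > 1L) {
          events[[length(events) + 1L]] <- tibble(genome = gid, family = f,
                                                  event = "duplication")
        }
        for (dummy in seq_len(n_copies)) {
          copy_count[f] <- copy_count[f] + 1L
          cnum <- copy_count[f]
          s <- fam_seq[f]
          if (sub_rate > 0) {
            ch <- strsplit(s, "")[[1]]
            hit <- which(runif(length(ch)) < sub_rate)
            for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
            if (length(hit)) {
              events[[length(events) + 1L]] <- tibble(
                genome = gid, family = f,
                event = sprintf("substitutions:%d", length(hit)))
            }
            s <- paste(ch, collapse = "")
          }
          strand <- if (runif(1) < p_inversion) "-" else "+"
          if (strand == "-") {
            events[[length(events) + 1L]] <- tibble(genome = gid, family = f,
                                                    event = "inversion")
          }
          eL <- guard(permL[[f]], cnum); eR <- guard(permR[[f]], cnum)
          if (fissioned[f] && split_in[g, f]) {
            split_count[f] <- split_count[f] + 1L
            eCR <- guard(permCutR[[f]], split_count[f])
            eCL <- guard(permCutL[[f]], split_count[f])
            p1 <- substr(s, 1L, cut_at[f])
            p2 <- substr(s, cut_at[f] + 1L, nchar(s))
            u1 <- if (strand == "+") {
              list(seq = p1, lchar = eL, rchar = eCR)
            } else {
              list(seq = revcomp_chr(p1), lchar = comp_base(eCR), rchar = comp_base(eL))
            }
            u2 <- if (strand == "+") {
              list(seq = p2, lchar = eCL, rchar = eR)
            } else {
              list(seq = revcomp_chr(p2), lchar = comp_base(eR), rchar = comp_base(eCL))
            }
            units[[length(units) + 1L]] <- c(u1, list(family = f, piece = 1L,
                                                      copy = cnum, strand = strand))
            units[[length(units) + 1L]] <- c(u2, list(family = f, piece = 2L,
                                                      copy = cnum, strand = strand))
            events[[length(events) + 1L]] <- tibble(genome = gid, family = f,
                                                    event = sprintf("fission:%d", cut_at[f]))
          } else {
            u <- if (strand == "+") {
              list(seq = s, lchar = eL, rchar = eR)
            } else {
              list(seq = revcomp_chr(s), lchar = comp_base(eR), rchar = comp_base(eL))
            }
            units[[length(units) + 1L]] <- c(u, list(family = f, piece = 0L,
                                                     copy = cnum, strand = strand))
          }
        }
      }
      plan[[gid]] <- if (length(units)) units[sample.int(length(units))] else units
    }

    # a fission boundary only exists as evidence if some surviving copy
    # was physically split; otherwise the family stays whole
    fission_realized <- vapply(seq_len(n_families), function(f) {
      any(vapply(plan, function(us) {
        any(vapply(us, function(u) u$family == f && u$piece > 0L, logical(1)))
      }, logical(1)))
    }, logical(1))

    # pass 2: assemble genomes with guarded spacers, record truth
    blocks <- list(); genome_rows <- list()
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("g%d", g)
      units <- plan[[gid]]
      spacer <- function(first_char, last_char) {
        n <- sample(spacer_len[1]:spacer_len[2], 1L)
        s <- random_dna(n)
        paste0(first_char %||% substr(s, 1L, 1L),
               substr(s, 2L, n - 1L),
               last_char %||% substr(s, n, n))
      }
      seq_parts <- character(0); pos <- 0L
      push <- function(s) {
        seq_parts[[length(seq_parts) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      for (i in seq_along(units)) {
        u <- units[[i]]
        prev_r <- if (i > 1L) units[[i - 1L]]$rchar else NULL
        push(spacer(prev_r, u$lchar))
        st <- pos
        push(u$seq)
        f <- u$family
        if (u$piece == 0L && fission_realized[f]) {
          # unsplit copy of a fissioned family: the planted boundary
          # still exists, as two adjacent truth segments
          len <- nchar(u$seq); fc <- cut_at[f]
          if (u$strand == "+") {
            b1 <- c(st, st + fc); b2 <- c(st + fc, st + len)
          } else {
            b2 <- c(st, st + len - fc); b1 <- c(st + len - fc, st + len)
          }
          blocks[[length(blocks) + 1L]] <- tibble(
            family = f, piece = 1L, copy = u$copy, genome = gid,
            start = b1[1], end = b1[2], strand = u$strand)
          blocks[[length(blocks) + 1L]] <- tibble(
            family = f, piece = 2L, copy = u$copy, genome = gid,
            start = b2[1], end = b2[2], strand = u$strand)
        } else {
          blocks[[length(blocks) + 1L]] <- tibble(
            family = f, piece = u$piece, copy = u$copy, genome = gid,
            start = st, end = pos, strand = u$strand)
        }
      }
      last_r <- if (length(units)) units[[length(units)]]$rchar else NULL
      push(spacer(last_r, NULL))
      gseq <- paste(seq_parts, collapse = "")
      if (!is.null(genome_budget) && nchar(gseq) > genome_budget) {
        abort(sprintf("genome %s (%d bp) exceeds the genome budget (%d bp)",
                      gid, nchar(gseq), genome_budget))
      }
      genome_rows[[length(genome_rows) + 1L]] <- tibble(
        genome = gid, sequence = gseq, length = nchar(gseq))
    }
    truth <- structure(list(
      blocks = if (length(blocks)) bind_rows(blocks) else
        tibble(family = integer(), piece = integer(), copy = integer(),
               genome = character(), start = integer(), end = integer(),
               strand = character()),
      events = if (length(events)) bind_rows(events) else
        tibble(genome = character(), family = integer(), event = character()),
      params = list(n_genomes = n_genomes, n_families = n_families,
                    block_len = block_len, sub_rate = sub_rate,
                    p_inversion = p_inversion, p_duplication = p_duplication,
                    p_loss = p_loss, p_fission = p_fission,
                    fissioned = fissioned, fission_realized = fission_realized,
                    cut_at = cut_at, split_in = split_in)
    ), class = "planted_truth")
    list(genomes = bind_rows(genome_rows), truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d planted segment(s), %d family/piece group(s)\n",
              nrow(x$blocks),
              nrow(unique(x$blocks[, c("family", "piece")]))))
  invisible(x)
}

#' Write a planted fixture to disk
#'
#' FASTA genomes, a JSON truth file, and a BED of planted blocks.
#'
#' @param fixture Output of [simulate_genomes()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genomes(fixture$genomes, file.path(dir, paste0(name, ".fasta")))
  truth <- fixture$truth
  jsonlite::write_json(
    list(blocks = truth$blocks, events = truth$events,
         params = truth$params[setdiff(names(truth$params), "split_in")]),
    file.path(dir, paste0(name, ".truth.json")),
    auto_unbox = TRUE, digits = NA)
  b <- truth$blocks
  write_features_bed(
    tibble(genome = b$genome, start = b$start, end = b$end,
           name = sprintf("fam%d.%d.%d%s", b$family, b$piece, b$copy, b$strand)),
    file.path(dir, paste0(name, ".blocks.bed")))
  invisible(dir)
}

#' Expected homology partition of a planted truth
#'
#' Converts the event log into the partition the pipeline should
#' recover: one group per (family, piece) -- a fission splits a family
#' into two groups in every genome, and a duplicated copy contributes a
#' second member from its genome to the same group.  Groups with a
#' single member carry no alignment evidence and are dropped (a block
#' surviving in one copy only is not part of any homology group).
#'
#' @param truth A `planted_truth`.
#' @return A partition tibble in [mhg_delineate()]'s schema.
#' @export
truth_partition <- function(truth) {
  b <- truth$blocks
  empty <- new_mhg_partition(tibble(mhg_id = integer(), genome = character(),
                                    start = integer(), end = integer(),
                                    strand = character()), pileup = NULL)
  if (nrow(b) == 0L) return(empty)
  key <- paste(b$family, b$piece, sep = ".")
  groups <- split(seq_len(nrow(b)), key)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) return(empty)
  out <- bind_rows(lapply(seq_along(groups), function(i) {
    m <- b[groups[[i]], , drop = FALSE]
    m <- m[order(m$genome, m$start), , drop = FALSE]
    if (m$strand[1] == "-") m$strand <- ifelse(m$strand == "+", "-", "+")
    tibble(mhg_id = i, genome = m$genome,
           start = as.integer(m$start), end = as.integer(m$end),
           strand = m$strand)
  }))
  new_mhg_partition(out, pileup = NULL)
}
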