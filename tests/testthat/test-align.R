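test_that("gapless BLAST rows parse with all-ones bit arrays", {
  p <- write_tmp_lines("g1\tg2\t1\t4\t11\t14\t50\tACGT\tACGT", ".tsv")
  al <- read_blast_pairs(p)
  expect_equal(al$query_start, 0L)
  expect_equal(al$query_end, 4L)
  expect_equal(al$subject_start, 10L)
  expect_equal(al$subject_end, 14L)
  expect_equal(al$orientation, "same")
  expect_equal(al$query_bits[[1]], rep(1L, 4))
  expect_equal(al$subject_bits[[1]], rep(1L, 4))
})

test_that("gap columns become 0 bits, scanned column by column", {
  p <- write_tmp_lines("g1\tg2\t1\t4\t1\t5\t40\tAC-GT\tACAGT", ".tsv")
  al <- read_blast_pairs(p)
  expect_equal(al$query_bits[[1]], c(1L, 1L, 0L, 1L, 1L))
  expect_equal(al$subject_bits[[1]], rep(1L, 5))
})

test_that("reverse-strand hits convert to + coordinates with orientation=opposite", {
  p <- write_tmp_lines("g1\tg2\t1\t4\t14\t11\t50\tACGT\tACGT", ".tsv")
  al <- read_blast_pairs(p)
  expect_equal(al$orientation, "opposite")
  expect_equal(al$subject_start, 10L)
  expect_equal(al$subject_end, 14L)
})

test_that("malformed rows are rejected", {
  # aligned strings of unequal length
  p <- write_tmp_lines("g1\tg2\t1\t4\t1\t4\t50\tACGT\tACG", ".tsv")
  expect_error(read_blast_pairs(p), "length|disagrees")
  # residue count inconsistent with coordinates
  p2 <- write_tmp_lines("g1\tg2\t1\t5\t1\t4\t50\tACGT\tACGT", ".tsv")
  expect_error(read_blast_pairs(p2), "disagrees")
})

test_that("parse then re-serialize reproduces rows bit-exactly", {
  rows <- c("g1\tg2\t1\t4\t11\t14\t50\tACGT\tACGT",
            "g1\tg2\t1\t4\t1\t5\t40\tAC-GT\tACAGT",
            "g1\tg3\t5\t10\t24\t19\t33\tAAC-CGT\tAACTCG-")
  p <- write_tmp_lines(rows, ".tsv")
  al <- read_blast_pairs(p)
  p2 <- tempfile(fileext = ".tsv")
  write_blast_pairs(al, p2)
  expect_equal(read_blast_pairs(p2), al)
})

test_that("relative bit-score filtering keeps the boundary and drops self hits", {
  al <- dplyr::bind_rows(
    make_alignment("g1", 0, 50, "g2", 0, 50, bitscore = 50),
    make_alignment("g1", 0, 100, "g2", 0, 100, bitscore = 100),
    make_alignment("g1", 0, 1000, "g1", 0, 1000, bitscore = 1000)  # trivial self
  )
  ms <- c(g1 = 1000)
  kept <- filter_alignments(al, ms, fraction = 0.1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$bitscore, 100)
  expect_error(filter_alignments(al, c(g2 = 1), fraction = 0.1), "g1")
  expect_error(filter_alignments(al, ms, fraction = 0), "fraction")
})

test_that("max_self_bitscore is the per-genome maximum and rejects bad input", {
  al <- dplyr::bind_rows(
    make_alignment("g1", 0, 10, "g1", 0, 10, bitscore = 1000),
    make_alignment("g1", 0, 5, "g1", 20, 25, bitscore = 52),
    make_alignment("g2", 0, 5, "g2", 10, 15, bitscore = 48)
  )
  expect_equal(unname(max_self_bitscore(al)[c("g1", "g2")]), c(1000, 48))
  expect_error(max_self_bitscore(al[0, ]), "no self")
  cross <- make_alignment("g1", 0, 5, "g2", 0, 5)
  expect_error(max_self_bitscore(cross), "self")
})

test_that("the built-in aligner finds the self repeat in ACGTACGT", {
  g <- tibble::tibble(genome = "a", sequence = "ACGTACGT", length = 8L)
  al <- align_local(g, score_floor = 8, word_size = 4)
  # trivial full-length self hit present (the max-score reference)
  triv <- al[al$query_start == 0 & al$query_end == 8 &
               al$subject_start == 0 & al$orientation == "same", ]
  expect_equal(nrow(triv), 1L)
  expect_equal(triv$bitscore, 16)
  # offset-4 repeat
  rep4 <- al[al$query_start == 0 & al$query_end == 4 &
               al$subject_start == 4 & al$orientation == "same", ]
  expect_equal(nrow(rep4), 1L)
})

test_that("planted identical blocks yield exactly one cross-genome alignment", {
  set.seed(5)
  block <- random_dna(200)
  g <- tibble::tibble(
    genome = c("a", "b"),
    sequence = c(paste0("C", random_dna(99), "A", block, "C", random_dna(99)),
                 paste0("G", random_dna(79), "G", block, "T", random_dna(119))),
    length = 0L)
  g$length <- nchar(g$sequence)
  al <- align_local(g)
  cross <- al[al$query_genome != al$subject_genome, ]
  expect_equal(nrow(cross), 1L)
  expect_equal(cross$query_end - cross$query_start, 200L)
  expect_equal(cross$orientation, "same")
  expect_equal(substr(g$sequence[1], cross$query_start + 1, cross$query_end), block)
  expect_equal(substr(g$sequence[2], cross$subject_start + 1, cross$subject_end), block)
})

test_that("a reverse-complemented planted block is found as orientation=opposite", {
  set.seed(6)
  block <- random_dna(150)
  g <- tibble::tibble(
    genome = c("a", "b"),
    sequence = c(paste0("A", random_dna(60), "A", block, "A", random_dna(60)),
                 paste0("C", random_dna(50), "C", rc(block), "C", random_dna(70))),
    length = 0L)
  g$length <- nchar(g$sequence)
  al <- align_local(g)
  cross <- al[al$query_genome != al$subject_genome, ]
  expect_equal(nrow(cross), 1L)
  expect_equal(cross$orientation, "opposite")
  expect_equal(cross$query_end - cross$query_start, 150L)
})

test_that("every computed alignment satisfies the bit-array invariants", {
  fx <- simulate_genomes(n_genomes = 3, n_families = 3, block_len = 150,
                         p_inversion = 0.3, p_duplication = 0.3,
                         spacer_len = c(60, 100), seed = 11)
  al <- align_local(fx$genomes)
  expect_gt(nrow(al), 3)
  # validate_alignments() would abort otherwise; spot-check the gapless law
  for (i in seq_len(nrow(al))) {
    expect_equal(sum(al$query_bits[[i]]), al$query_end[i] - al$query_start[i])
    expect_equal(sum(al$subject_bits[[i]]), al$subject_end[i] - al$subject_start[i])
    expect_equal(length(al$query_bits[[i]]),
                 al$query_end[i] - al$query_start[i])
  }
})
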