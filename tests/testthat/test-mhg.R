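test_that("breakpoint mapping: gapless offset, gapped column walk, boundaries", {
  # gapless: identity offset
  al <- make_alignment("q", 100, 150, "s", 200, 250)
  expect_equal(map_breakpoint(al, "query", 120), 220)
  expect_equal(map_breakpoint(al, "query", 100), 200)  # start -> start
  expect_equal(map_breakpoint(al, "query", 150), 250)
  # gapped: query_bits 11011, subject_bits 11111
  alg <- make_alignment("q", 10, 14, "s", 20, 25,
                        qbits = c(1L, 1L, 0L, 1L, 1L), sbits = rep(1L, 5))
  expect_equal(map_breakpoint(alg, "query", 12), 22)
  expect_equal(map_breakpoint(alg, "subject", 22), 12)
  # gap run on the destination side: leftmost placement
  alh <- make_alignment("q", 0, 5, "s", 50, 53,
                        qbits = rep(1L, 5), sbits = c(1L, 1L, 0L, 0L, 1L))
  expect_equal(map_breakpoint(alh, "query", 2), 52)
  expect_equal(map_breakpoint(alh, "query", 3), 52)
  expect_equal(map_breakpoint(alh, "query", 4), 52)
  # out of range
  expect_error(map_breakpoint(al, "query", 99), "outside")
})

test_that("opposite-orientation mapping reflects from the destination end", {
  al <- make_alignment("q", 0, 10, "s", 100, 110, orientation = "opposite")
  expect_equal(map_breakpoint(al, "query", 0), 110)
  expect_equal(map_breakpoint(al, "query", 10), 100)
  expect_equal(map_breakpoint(al, "query", 3), 107)
  expect_equal(map_breakpoint(al, "subject", 107), 3)
})

test_that("breakpoint round trip is the identity on match columns", {
  set.seed(7)
  for (i in 1:25) {
    L <- sample(5:30, 1)
    b <- random_bits(L)
    qs <- sample(0:50, 1); ss <- sample(0:50, 1)
    orient <- sample(c("same", "opposite"), 1)
    al <- make_alignment("q", qs, qs + sum(b$q), "s", ss, ss + sum(b$s),
                         orientation = orient, qbits = b$q, sbits = b$s)
    # positions whose preceding query residue sits in a match column
    match_cols <- which(b$q == 1L & b$s == 1L)
    for (c in match_cols) {
      pos <- qs + sum(b$q[seq_len(c)])
      there <- map_breakpoint(al, "query", pos)
      back <- map_breakpoint(al, "subject", there)
      expect_equal(back, pos)
    }
    # segment start always round-trips
    expect_equal(map_breakpoint(al, "subject", map_breakpoint(al, "query", qs)), qs)
  }
})

test_that("single-edge traversal yields a merged pair plus overhang singletons", {
  al <- make_alignment("g1", 10, 30, "g2", 5, 25)
  al2 <- make_alignment("g2", 0, 40, "g3", 0, 40)  # widens the g2 node
  # single alignment: pure two-member group
  p <- mhg_delineate(al)
  expect_equal(attr(p, "n_mhgs"), 1L)
  expect_equal(nrow(p), 2L)
  # overhangs: alignment covering part of an already wider node
  both <- dplyr::bind_rows(al2, al)
  p2 <- mhg_delineate(both)
  # g1[10,30) aligns into g2[5,25), which aligns fully to g3
  # -> one group {g1, g2, g3 pieces} plus flanking {g2,g3} pieces
  expect_equal(attr(p2, "n_mhgs"), 3L)
  mid <- p2[p2$mhg_id == unique(p2$mhg_id[p2$genome == "g1"]), ]
  expect_setequal(mid$genome, c("g1", "g2", "g3"))
  # per-genome coverage equals the pile-up cover
  pl <- attr(p2, "pileup")
  for (g in unique(pl$genome)) {
    expect_equal(sum(p2$end[p2$genome == g] - p2$start[p2$genome == g]),
                 sum(pl$end[pl$genome == g] - pl$start[pl$genome == g]))
  }
})

test_that("a tandem repeat self-alignment becomes one two-member group", {
  al <- make_alignment("g1", 0, 4, "g1", 4, 8, bitscore = 8)
  p <- mhg_delineate(al)
  expect_equal(attr(p, "n_mhgs"), 1L)
  expect_equal(nrow(p), 2L)
  expect_equal(p$start, c(0L, 4L))
  expect_equal(p$end, c(4L, 8L))
})

test_that("an overlapping self-alignment chains all copies into one group", {
  # [0,10) vs [5,15): transitive 5-periodic repeat -> three 5 bp members
  al <- make_alignment("g1", 0, 10, "g1", 5, 15, bitscore = 20)
  p <- mhg_delineate(al)
  expect_equal(attr(p, "n_mhgs"), 1L)
  expect_equal(nrow(p), 3L)
  expect_equal(p$start, c(0L, 5L, 10L))
})

test_that("merging via an opposite-orientation alignment flips strands", {
  al <- make_alignment("g1", 0, 10, "g2", 50, 60, orientation = "opposite")
  p <- mhg_delineate(al)
  expect_equal(nrow(p), 2L)
  expect_setequal(p$strand, c("+", "-"))
  # group frame is canonical: first member +
  expect_equal(p$strand[1], "+")
})

test_that("partition and merge bookkeeping splits members at propagated cuts", {
  # A[0,20)=B[0,20), then C aligns to B[8,20): cut at 8 propagates to A
  al <- dplyr::bind_rows(
    make_alignment("A", 0, 20, "B", 0, 20),
    make_alignment("B", 8, 20, "C", 0, 12)
  )
  p <- mhg_delineate(al)
  expect_equal(attr(p, "n_mhgs"), 2L)
  left <- p[p$mhg_id == 1, ]
  expect_setequal(paste0(left$genome, ":", left$start, "-", left$end),
                  c("A:0-8", "B:0-8"))
  right <- p[p$mhg_id == 2, ]
  expect_setequal(paste0(right$genome, ":", right$start, "-", right$end),
                  c("A:8-20", "B:8-20", "C:0-12"))
})

test_that("cuts propagate through gapped alignments by residue counting", {
  # A[0,6) aligned to B[0,5) with a gap in B after column 2;
  # C aligns to B[2,5): the cut at B=2 must land at A=2 (leftmost)
  al <- dplyr::bind_rows(
    make_alignment("A", 0, 6, "B", 0, 5,
                   qbits = rep(1L, 6), sbits = c(1L, 1L, 0L, 1L, 1L, 1L)),
    make_alignment("B", 2, 5, "C", 0, 3)
  )
  p <- mhg_delineate(al)
  a_cuts <- sort(p$start[p$genome == "A"])
  expect_equal(a_cuts, c(0L, 2L))
  b_right <- p[p$genome == "B" & p$start == 2, ]
  c_row <- p[p$genome == "C", ]
  expect_equal(b_right$mhg_id, c_row$mhg_id)
})

test_that("planted fixtures with fission are recovered boundary-for-boundary", {
  for (seed in c(31, 32, 33)) {
    fx <- simulate_genomes(n_genomes = 4, n_families = 4, block_len = 250,
                           p_fission = 0.6, p_inversion = 0.3,
                           spacer_len = c(80, 140), seed = seed)
    res <- fixture_pipeline(fx$genomes, mismatch = -1e6)
    expect_identical(canonical_partition(res$partition),
                     canonical_partition(truth_partition(fx$truth)))
  }
})

test_that("a duplicated block yields two members from one genome in one group", {
  fx <- simulate_genomes(n_genomes = 2, n_families = 2, block_len = 200,
                         p_duplication = 1, spacer_len = c(80, 140), seed = 41)
  res <- fixture_pipeline(fx$genomes, mismatch = -1e6)
  p <- res$partition
  expect_identical(canonical_partition(p),
                   canonical_partition(truth_partition(fx$truth)))
  per_group_genome <- table(p$mhg_id, p$genome)
  expect_true(any(per_group_genome > 1))
})

test_that("delineation is deterministic, including ids and file output", {
  fx <- simulate_genomes(n_genomes = 3, n_families = 3, block_len = 200,
                         p_fission = 0.5, spacer_len = c(60, 120), seed = 55)
  r1 <- fixture_pipeline(fx$genomes)
  r2 <- fixture_pipeline(fx$genomes)
  expect_identical(tidy(r1$partition), tidy(r2$partition))
  f1 <- tempfile(); f2 <- tempfile()
  write_mhg_tsv(r1$partition, f1)
  write_mhg_tsv(r2$partition, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reverse-complementing one genome reflects its members and strands", {
  fx <- simulate_genomes(n_genomes = 3, n_families = 3, block_len = 200,
                         spacer_len = c(60, 120), seed = 61)
  p1 <- fixture_pipeline(fx$genomes, mismatch = -1e6)$partition
  g2 <- fx$genomes
  flipped <- "g2"
  L <- g2$length[g2$genome == flipped]
  g2$sequence[g2$genome == flipped] <- rc(g2$sequence[g2$genome == flipped])
  p2 <- fixture_pipeline(g2, mismatch = -1e6)$partition
  # reflect the flipped genome's members back and flip their strands
  p2r <- tidy(p2)
  sel <- p2r$genome == flipped
  ns <- L - p2r$end[sel]; ne <- L - p2r$start[sel]
  p2r$start[sel] <- ns; p2r$end[sel] <- ne
  p2r$strand[sel] <- ifelse(p2r$strand[sel] == "+", "-", "+")
  expect_identical(canonical_partition(p2r), canonical_partition(p1))
})

test_that("empty input gives an empty partition; TSV round trip preserves groups", {
  empty <- mhg_delineate(make_alignment("a", 0, 1, "b", 0, 1)[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_mhgs"), 0L)
  fx <- simulate_genomes(n_genomes = 3, n_families = 2, block_len = 150,
                         spacer_len = c(50, 80), seed = 71)
  p <- fixture_pipeline(fx$genomes)$partition
  f <- tempfile()
  write_mhg_tsv(p, f, config_hash = "abc")
  p2 <- read_mhg_tsv(f)
  expect_identical(canonical_partition(p), canonical_partition(p2))
})

test_that("pipeline equals the transitive-closure oracle on mixed fixtures", {
  for (seed in c(81, 82)) {
    fx <- simulate_genomes(n_genomes = 4, n_families = 4, block_len = 220,
                           p_fission = 0.4, p_inversion = 0.3, p_duplication = 0.3,
                           spacer_len = c(80, 130), seed = seed)
    res <- fixture_pipeline(fx$genomes)
    orc <- transitive_homology_partition(fx$genomes, res$alignments)
    expect_identical(canonical_partition(res$partition),
                     canonical_partition(orc))
  }
})
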