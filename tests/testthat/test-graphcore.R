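test_that("pile-up unions strictly overlapping segments and keeps abutments", {
  al <- dplyr::bind_rows(
    make_alignment("g1", 0, 50, "g2", 0, 50),
    make_alignment("g1", 30, 80, "g2", 100, 150)
  )
  r <- pile_up(al)
  g1 <- r[r$genome == "g1", ]
  expect_equal(g1$start, 0L)
  expect_equal(g1$end, 80L)
  # abutting but not overlapping
  al2 <- dplyr::bind_rows(
    make_alignment("g1", 0, 10, "g2", 0, 10),
    make_alignment("g1", 10, 20, "g2", 100, 110)
  )
  g1b <- pile_up(al2)
  g1b <- g1b[g1b$genome == "g1", ]
  expect_equal(g1b$start, c(0L, 10L))
  expect_equal(g1b$end, c(10L, 20L))
})

test_that("pile-up matches a per-base union oracle", {
  segs <- list(c(0, 5), c(3, 9), c(20, 30), c(25, 40), c(50, 60))
  al <- dplyr::bind_rows(lapply(segs, function(s) {
    make_alignment("g1", s[1], s[2], "gX", s[1] + 100, s[2] + 100)
  }))
  r <- pile_up(al)
  g1 <- r[r$genome == "g1", ]
  expect_equal(g1$start, c(0L, 20L, 50L))
  expect_equal(g1$end, c(9L, 40L, 60L))
  # randomized property: total range length equals the per-base cover
  set.seed(99)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    st <- sample(0:200, n, replace = TRUE)
    en <- st + sample(1:40, n, replace = TRUE)
    al <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      make_alignment("g", st[j], en[j], "h", 500 + st[j], 500 + en[j])
    }))
    r <- pile_up(al)
    rg <- r[r$genome == "g", ]
    covered <- rep(FALSE, 300)
    for (j in seq_len(n)) covered[(st[j] + 1):en[j]] <- TRUE
    expect_equal(sum(rg$end - rg$start), sum(covered))
    # ranges must be disjoint and sorted
    if (nrow(rg) > 1) expect_true(all(rg$start[-1] >= rg$end[-nrow(rg)]))
  }
})

test_that("graph construction connects containing nodes, allowing self loops", {
  al <- dplyr::bind_rows(
    make_alignment("g1", 0, 50, "g2", 0, 50),
    make_alignment("g1", 10, 30, "g1", 35, 55)   # self loop after union
  )
  r <- pile_up(al)
  gr <- build_alignment_graph(r, al)
  expect_s3_class(gr, "alignment_graph")
  expect_equal(nrow(gr$edges), 2L)
  # the self-overlapping alignment lands inside one g1 node
  self <- gr$edges[2, ]
  expect_equal(self$node_a, self$node_b)
  # empty graph
  empty <- pile_up(al[0, ])
  expect_equal(nrow(empty), 0L)
  # two genomes one alignment
  al1 <- make_alignment("g1", 0, 10, "g2", 5, 15)
  g1 <- build_alignment_graph(pile_up(al1), al1)
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)
})

test_that("connected components partition nodes deterministically", {
  al <- dplyr::bind_rows(
    make_alignment("g1", 0, 10, "g2", 0, 10),
    make_alignment("g3", 0, 10, "g4", 0, 10)
  )
  n <- alignment_components(build_alignment_graph(pile_up(al), al))
  expect_equal(length(unique(n$component)), 2L)
  # chain A-B, B-C is one component
  al2 <- dplyr::bind_rows(
    make_alignment("g1", 0, 10, "g2", 0, 10),
    make_alignment("g2", 0, 10, "g3", 0, 10)
  )
  n2 <- alignment_components(build_alignment_graph(pile_up(al2), al2))
  expect_equal(unique(n2$component), 1L)
})

test_that("two independent planted families give two components matching truth", {
  fx <- simulate_genomes(n_genomes = 3, n_families = 2, block_len = 200,
                         spacer_len = c(60, 100), seed = 13)
  al <- align_local(fx$genomes)
  selfs <- al[al$query_genome == al$subject_genome, ]
  flt <- filter_alignments(al, max_self_bitscore(selfs), fraction = 0.01)
  nodes <- alignment_components(build_alignment_graph(pile_up(flt), flt))
  expect_equal(max(nodes$component), 2L)
  # each component's nodes correspond to one planted family
  truth <- fx$truth$blocks
  for (cmp in 1:2) {
    nd <- nodes[nodes$component == cmp, ]
    fams <- unique(vapply(seq_len(nrow(nd)), function(i) {
      hit <- truth$genome == nd$genome[i] & truth$start < nd$end[i] &
        truth$end > nd$start[i]
      unique(truth$family[hit])
    }, integer(1)))
    expect_length(fams, 1L)
  }
})

test_that("node ranges conserve the per-base alignment cover", {
  fx <- simulate_genomes(n_genomes = 3, n_families = 3, block_len = 150,
                         p_duplication = 0.5, spacer_len = c(60, 100), seed = 21)
  al <- align_local(fx$genomes)
  selfs <- al[al$query_genome == al$subject_genome, ]
  flt <- filter_alignments(al, max_self_bitscore(selfs), fraction = 0.01)
  ranges <- pile_up(flt)
  segs <- dplyr::bind_rows(
    tibble::tibble(genome = flt$query_genome, start = flt$query_start, end = flt$query_end),
    tibble::tibble(genome = flt$subject_genome, start = flt$subject_start, end = flt$subject_end)
  )
  for (g in unique(ranges$genome)) {
    r <- ranges[ranges$genome == g, ]
    s <- segs[segs$genome == g, ]
    len <- max(s$end)
    cov <- rep(FALSE, len)
    for (i in seq_len(nrow(s))) cov[(s$start[i] + 1):s$end[i]] <- TRUE
    expect_equal(sum(r$end - r$start), sum(cov))
  }
})
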