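test_that("newick reading and writing round-trips topology and lengths", {
  p <- write_tmp_lines("((A:1,B:1):1,(C:1,D:1):1);", ".nwk")
  tr <- read_trees(p)
  expect_length(tr, 1L)
  expect_equal(sort(tr[[1]]$tip.label), c("A", "B", "C", "D"))
  # 19-tip round trip preserves all splits
  big <- random_base_tree(19, 0.05, seed = 2)
  f <- tempfile(fileext = ".nwk")
  write_trees(big, f)
  back <- read_trees(f)[[1]]
  expect_identical(tree_bipartitions(back), tree_bipartitions(big))
  bad <- write_tmp_lines("((A:1,B:1):1,(C:1,D:1:1);", ".nwk")
  expect_error(read_trees(bad), "malformed")
})

test_that("bipartitions are canonical bitmasks over the universe", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  b1 <- tree_bipartitions(t1, c("A", "B", "C", "D"))
  expect_equal(as.character(b1), "1100")
  # same split written the other way round normalizes identically
  t2 <- ape::read.tree(text = "((C,D),(A,B));")
  expect_equal(as.character(tree_bipartitions(t2, c("A", "B", "C", "D"))),
               "1100")
  # embedding a subset tree in a larger universe keeps absent taxa at 0
  b3 <- tree_bipartitions(t1, c("A", "B", "C", "D", "E"))
  expect_equal(as.character(b3), "11000")
  expect_error(tree_bipartitions(t1, c("A", "B", "C")), "outside")
})

test_that("a 5-tip caterpillar yields the exhaustive set of nontrivial splits", {
  t5 <- ape::read.tree(text = "((((A,B),C),D),E);")
  b <- tree_bipartitions(ape::unroot(t5), c("A", "B", "C", "D", "E"))
  expect_length(b, 2L)           # n - 3 internal edges
  expect_setequal(as.character(b), c("11000", "11100"))
})

test_that("RF distance: identical, single NNI, and maximally different trees", {
  t1 <- random_base_tree(19, 0.05, seed = 5)
  expect_equal(rf_distance(t1, t1), list(raw = 0L, normalized = 0))
  t2 <- random_nni(t1, seed = 9)
  r <- rf_distance(t1, t2)
  expect_equal(r$raw, 2L)
  expect_equal(r$normalized, 2 / (2 * 16))
  # maximally different 6-tip caterpillars share no splits
  c1 <- ape::unroot(ape::read.tree(text = "(((((A,B),C),D),E),F);"))
  c2 <- ape::unroot(ape::read.tree(text = "(((((A,D),F),B),E),C);"))
  expect_equal(rf_distance(c1, c2)$normalized, 1)
  expect_error(rf_distance(t1, c1), "tip set")
})

test_that("RF distance agrees with an independent implementation and is a metric", {
  set.seed(11)
  trees <- replicate(6, ape::unroot(ape::rtree(8)), simplify = FALSE)
  for (i in 1:5) for (j in (i + 1):6) {
    mine <- rf_distance(trees[[i]], trees[[j]])$raw
    ref <- phangorn::RF.dist(trees[[i]], trees[[j]])
    expect_equal(mine, as.integer(ref))
    expect_equal(mine, rf_distance(trees[[j]], trees[[i]])$raw)  # symmetry
  }
  # triangle inequality
  for (i in 1:4) {
    d_ab <- rf_distance(trees[[i]], trees[[i + 1]])$raw
    d_bc <- rf_distance(trees[[i + 1]], trees[[i + 2]])$raw
    d_ac <- rf_distance(trees[[i]], trees[[i + 2]])$raw
    expect_lte(d_ac, d_ab + d_bc)
  }
})

test_that("NJ recovers a well-separated split and handles degenerate input", {
  t4 <- ape::read.tree(text = "((A:0.05,B:0.05):0.3,(C:0.05,D:0.05):0.3);")
  msa <- simulate_alignment(ape::unroot(t4), 2000, seed = 3)
  tr <- nj_tree(msa)
  expect_equal(as.character(tree_bipartitions(tr, c("A", "B", "C", "D"))), "1100")
  # identical sequences: star-like, all branch lengths ~0
  msa0 <- matrix(rep(strsplit("ACGTACGTAC", "")[[1]], 4), nrow = 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  tr0 <- nj_tree(msa0)
  expect_true(all(tr0$edge.length < 1e-9))
  expect_error(nj_tree(msa0[1:3, ]), "at least 4")
  expect_equal(bootstrap_trees(msa, B = 0), list())
  # fixed seed makes bootstraps reproducible
  b1 <- bootstrap_trees(msa, B = 3, seed = 5)
  b2 <- bootstrap_trees(msa, B = 3, seed = 5)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
})

test_that("informative-group filtering applies the three rules exactly", {
  p <- dplyr::bind_rows(
    tibble::tibble(mhg_id = 1L, genome = c("A", "A", "B", "C")),   # duplicate genome
    tibble::tibble(mhg_id = 2L, genome = c("A", "B", "C")),        # only 3 members
    tibble::tibble(mhg_id = 3L, genome = c("A", "B", "C", "D")),   # short branch
    tibble::tibble(mhg_id = 4L, genome = c("A", "B", "C", "D"))    # boundary branch
  )
  mk <- function(len) {
    tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
    tr <- ape::unroot(tr)
    n <- length(tr$tip.label)
    tr$edge.length[tr$edge[, 2] > n] <- len
    tr
  }
  trees <- list(`3` = mk(0.0004), `4` = mk(0.0005))
  out <- filter_informative(p, trees)
  expect_equal(out$informative, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$max_copies_per_genome[1], 2L)
  expect_equal(out$n_members[2], 3L)
  expect_equal(out$min_internal_branch[3], 0.0004)
})

test_that("split support counts bootstrap frequencies per source", {
  t_ab <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_ac <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  marker_boots <- c(rep(list(t_ab), 4), list(t_ac))        # 0.8 / 0.2
  mhg_boots <- list(m1 = rep(list(t_ab), 5),               # 1.0
                    m2 = rep(list(t_ac), 5))               # split AB absent
  ss <- split_support(marker_boots, mhg_boots)
  m1 <- ss[ss$mhg_id == "m1", ]
  expect_equal(m1$marker_support[m1$split == "A,B"], 0.8)
  expect_equal(m1$mhg_support[m1$split == "A,B"], 1.0)
  m2 <- ss[ss$mhg_id == "m2", ]
  expect_equal(m2$mhg_support[m2$split == "A,B"], 0)
  expect_equal(m2$marker_support[m2$split == "A,C"], 0.2)
  # pairs sharing fewer than 4 taxa contribute nothing
  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  ss2 <- split_support(marker_boots, list(m3 = rep(list(t3), 2)))
  expect_equal(nrow(ss2), 0L)
})

test_that("bipartition normalization is idempotent under tip reordering", {
  set.seed(31)
  for (i in 1:8) {
    tr <- ape::unroot(ape::rtree(7))
    u <- sort(tr$tip.label)
    b1 <- tree_bipartitions(tr, u)
    tr2 <- ape::read.tree(text = ape::write.tree(ape::rotate(tr, sample(8:11, 1))))
    b2 <- tree_bipartitions(tr2, u)
    expect_identical(as.character(b1), as.character(b2))
  }
})
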