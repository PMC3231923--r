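test_that("K2P distance matches the hand formula on worked pairs", {
  expect_equal(k2pDistance("AAAA", "AAAA")$d, 0, tolerance = 1e-12)
  # one transition in four sites: P = 1/4, Q = 0
  k_ts <- k2pDistance("AAAA", "AGAA")
  expect_equal(k_ts$d, -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(k_ts$d, 0.34657, tolerance = 1e-4)
  # one transversion in four sites: P = 0, Q = 1/4:
  # d = -1/2 ln(0.75) - 1/4 ln(0.5)
  k_tv <- k2pDistance("AAAA", "ACAA")
  expect_equal(k_tv$d, -0.5 * log(0.75) - 0.25 * log(0.5),
               tolerance = 1e-12)
  expect_equal(k_tv$d, 0.3171278, tolerance = 1e-6)
  expect_identical(k_ts$n_sites, 4L)
})

test_that("K2P distance agrees with the ape reference implementation", {
  set.seed(10)
  for (rep in 1:10) {
    # rows diverge moderately from a shared ancestor (independent
    # uniform rows would be saturated by construction)
    root <- sample(c("a", "c", "g", "t"), 120, replace = TRUE)
    m <- do.call(rbind, lapply(1:3, function(i) {
      x <- root
      mut <- sample(120, 25)
      x[mut] <- sample(c("a", "c", "g", "t"), 25, replace = TRUE)
      x
    }))
    dimnames(m) <- list(c("A", "B", "C"), NULL)
    ours <- k2pDistanceMatrix(toupper(m))
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(ours[lower.tri(ours)], ref[lower.tri(ref)],
                 tolerance = 1e-9)
  }
})

test_that("K2P applies pairwise deletion and reports saturation", {
  k <- k2pDistance("A-GANA", "AAGACA")
  expect_identical(k$n_sites, 4L)   # gap and N columns dropped
  expect_error(k2pDistance("ACGT", "GTAC", pair_label = "x vs y"),
               "saturated.*x vs y")
  expect_error(k2pDistance("----", "ACGT"), "zero valid sites")
})

test_that("NJ solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl["A"]), 1, tolerance = 1e-9)
  expect_equal(unname(bl["B"]), 1, tolerance = 1e-9)
  expect_equal(unname(bl["C"]), 3, tolerance = 1e-9)
})

test_that("NJ recovers the topology of random additive matrices", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(ref)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- njTree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
    # branch lengths are reproduced too: path distances match input
    got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_equal(got, D, tolerance = 1e-6)
  }
})

test_that("our NJ and ape::nj give the same topology on noisy input", {
  set.seed(5)
  for (rep in 1:5) {
    tr0 <- ape::rtree(6, br = function(k) runif(k, 0.05, 0.3))
    msa <- evolveAlignment(tr0, root_len = 400, seed = 600 + rep)
    D <- k2pDistanceMatrix(msa)
    expect_equal(
      as.numeric(ape::dist.topo(njTree(D), ape::nj(as.dist(D)))), 0)
  }
})

test_that("a star matrix yields zero-length internal branches", {
  n <- 5
  d <- matrix(2, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(d) <- 0
  tr <- njTree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-9))
})

test_that("NJ refuses asymmetric input", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d2 <- matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(njTree(d2), "symmetric")
  expect_error(njTree(d), "3 taxa")
})

test_that("bootstrap supports are reproducible and bounded", {
  msa <- evolveAlignment(ape::rtree(5, br = function(k) runif(k, 0.05, 0.3)),
                         root_len = 300, seed = 40)
  b1 <- bootstrapSupport(msa, reps = 25, seed = 99)
  b2 <- bootstrapSupport(msa, reps = 25, seed = 99)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  # a single replicate forces supports into {0, 100}
  b3 <- bootstrapSupport(msa, reps = 1, seed = 7)
  expect_true(all(b3$supports %in% c(0, 100)))
})

test_that("a strongly supported split gets near-unanimous support", {
  # two pairs of identical rows, the pairs 30% divergent: the AB|CD
  # split is unambiguous at every resampled column
  set.seed(12)
  left <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  right <- strsplit(left, "")[[1]]
  flip <- sample(1000, 300)
  swap <- c(A = "G", C = "T", G = "A", T = "C")
  right[flip] <- swap[right[flip]]
  right <- paste(right, collapse = "")
  msa <- c(A = left, B = left, C = right, D = right)
  b <- bootstrapSupport(msa, reps = 100, seed = 3)
  expect_gte(max(b$supports), 99)
})

test_that("newick output round-trips and rejects empty trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*\\);$")
  back <- ape::read.tree(path)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  # idempotent: write -> read -> write gives the same text
  path2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(back, path2)
  expect_identical(readLines(path2), txt)
  expect_error(writeNewick(NULL, path), "phylo")
})

test_that("distances estimated from simulated alignments hit the truth", {
  hits <- 0L
  for (s in 1:10) {
    msa <- evolveAlignment("(A:0.1,B:0.1);", root_len = 10000,
                           kappa = 2, seed = 2000 + s)
    k <- k2pDistance(msa[["A"]], msa[["B"]])
    if (abs(k$d - 0.2) <= 3 * k$se) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
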