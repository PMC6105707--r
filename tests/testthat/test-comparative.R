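test_that("k-mer distance is zero on identity, capped on disjoint sets", {
  s <- strrep("ACGGTTACAGGCTTAACGGT", 5)
  expect_equal(kmer_distance(s, s), 0)
  expect_equal(kmer_distance(strrep("A", 40), strrep("C", 40)), 1)
})

test_that("k-mer distance matches set enumeration on small sequences", {
  set.seed(18)
  for (i in 1:10) {
    a <- random_seq(60, gc = 0.5)
    b <- random_seq(60, gc = 0.5)
    k <- 15L
    canon <- function(s) {
      n <- nchar(s)
      f <- substring(s, 1:(n - k + 1L), k:n)
      r <- vapply(f, oracle_revcomp, "")
      unique(ifelse(f <= r, f, r))
    }
    ka <- canon(a); kb <- canon(b)
    j <- length(intersect(ka, kb)) / length(union(ka, kb))
    expected <- if (j == 0) 1 else if (j == 1) 0 else
      min(1, -(1 / k) * log(2 * j / (1 + j)))
    expect_equal(kmer_distance(a, b, k = k), expected)
    expect_equal(kmer_distance(a, b), kmer_distance(b, a))
  }
  expect_error(kmer_distance("ACGT", "ACGT", k = 15L), "shorter")
})

test_that("3-taxon NJ reproduces the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- ape::read.tree(text = nj_tree(dm))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("additive matrices are inverted exactly", {
  nwk <- "((a:2,b:3):1,c:4,d:5);"
  ref <- ape::read.tree(text = nwk)
  dm <- ape::cophenetic.phylo(ref)
  tr <- ape::read.tree(text = nj_tree(dm))
  got <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(got, dm, tolerance = 1e-8)
  # property: random additive 5-7 taxon trees round-trip through NJ
  set.seed(19)
  for (i in 1:10) {
    n <- sample(5:7, 1L)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
    dmr <- ape::cophenetic.phylo(rt)
    tr2 <- ape::read.tree(text = nj_tree(dmr))
    got2 <- ape::cophenetic.phylo(tr2)[rownames(dmr), colnames(dmr)]
    expect_equal(got2, dmr, tolerance = 1e-6)
  }
})

test_that("NJ input validation and clamping behave as documented", {
  bad <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
  # triangle violation forces a negative branch length
  dm <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- nj_tree(dm), "clamped")
  expect_true(all(ape::read.tree(text = tr)$edge.length >= 0))
})

test_that("dot plots of a genome against itself and its reverse complement", {
  set.seed(20)
  s <- random_seq(2000, gc = 0.4)
  self <- dotplot_segments(s, s, w = 20)
  fwd <- self[self$orientation == "forward", ]
  expect_true(any(fwd$x_start == 0 & fwd$length == 2000))
  cov <- sum(fwd$length[fwd$x_start == fwd$y_start])
  expect_gte(cov, 2000)   # full main diagonal coverage
  rc <- dotplot_segments(s, oracle_revcomp(s), w = 20)
  rev <- rc[rc$orientation == "reverse", ]
  expect_true(any(rev$x_start == 0 & rev$y_start == 0 & rev$length == 2000))
})

test_that("a single SNV splits the diagonal into two abutting segments", {
  set.seed(22)
  s1 <- random_seq(1000, gc = 0.4)
  p <- 500L  # 1-based
  s2 <- s1
  old <- substr(s2, p, p)
  substr(s2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  seg <- dotplot_segments(s1, s2, w = 20)
  seg <- seg[seg$orientation == "forward" & seg$x_start == seg$y_start, ]
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$x_start, c(0L, p))
  expect_equal(seg$length, c(p - 1L, 1000L - p))
  # every segment re-extracts to identical substrings
  for (i in 1:2)
    expect_equal(substr(s1, seg$x_start[i] + 1L, seg$x_start[i] + seg$length[i]),
                 substr(s2, seg$y_start[i] + 1L, seg$y_start[i] + seg$length[i]))
})

test_that("related archetypes cluster away from an unrelated outgroup", {
  coh <- generate_cohort(n = 8, n_archetypes = 8, snv_rate = 1e-4, seed = 2)
  og <- generate_genome(genome_spec(seed = 60001), id = "outgroup")
  gs <- c(coh$genomes, list(og$genome))
  dm <- kmer_distance_matrix(gs)
  expect_true(isSymmetric(unname(dm)))
  expect_true(all(diag(dm) == 0))
  ingroup <- dm[1:8, 1:8][upper.tri(dm[1:8, 1:8])]
  expect_lt(max(ingroup), min(dm[9, 1:8]))
  nwk <- suppressWarnings(nj_tree(dm))
  tr <- ape::read.tree(text = nwk)
  rooted <- ape::root(tr, outgroup = "outgroup", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(
    rooted, vapply(coh$genomes, function(g) g$id, "")))
})
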