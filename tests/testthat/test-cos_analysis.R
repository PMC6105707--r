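test_that("the default synthetic genome has exactly one 11-nt cos site at the origin", {
  res <- default_genome_fixture()
  cos <- find_cos_site(res$genome)
  expect_length(cos$all_hits, 1L)
  expect_equal(cos$cos_start, 0L)
  expect_equal(cos$cos_end - cos$cos_start, 11L)
  expect_equal(cos$cos_seq, "CACAAAGGACT")
})

test_that("a genome without the motif yields no cos site", {
  set.seed(8)
  g <- phage_genome("r", paste0(strrep("AC", 500)))
  expect_null(find_cos_site(g))
})

test_that("a cos motif split across the linear ends is found via the circular view", {
  set.seed(9)
  motif <- "CACAAAGGACT"
  mid <- random_seq(400, gc = 0.3)
  # 6 nt at the end, 5 nt at the start
  seq <- paste0(substr(motif, 7, 11), mid, substr(motif, 1, 6))
  while (length(oracle_find(paste0(seq, seq), motif)) != 1L) {
    mid <- random_seq(400, gc = 0.3)
    seq <- paste0(substr(motif, 7, 11), mid, substr(motif, 1, 6))
  }
  g <- phage_genome("split", seq)
  cos <- find_cos_site(g)
  expect_equal(cos$cos_start, nchar(seq) - 6L)
  expect_equal(cos$cos_seq, motif)
  # oracle: scan of seq + seq
  expect_equal(cos$cos_start,
               oracle_find(paste0(seq, seq), motif)[1L])
})

test_that("cos search is strand-consistent", {
  res <- default_genome_fixture()
  g <- res$genome
  grc <- phage_genome("rc", revcomp(g$seq))
  cos <- find_cos_site(g)
  cosrc <- find_cos_site(grc, motif = revcomp("CACAAAGGACT"))
  n <- nchar(g$seq)
  expect_equal(sort((n - (cosrc$all_hits + 11L)) %% n), sort(cos$all_hits))
})

test_that("planted inverted repeats are recovered with exact coordinates", {
  res <- default_genome_fixture()
  g <- res$genome
  cos <- find_cos_site(g)
  irs <- find_inverted_repeats(g, cos)
  f <- g$features
  left <- f[f$kind == "inverted_repeat" & f$label == "IR_left", ]
  right <- f[f$kind == "inverted_repeat" & f$label == "IR_right", ]
  hit <- irs$left_start == left$start & irs$right_start == right$start
  expect_true(any(hit))
  expect_equal(irs$mismatches[hit], 0L)
  expect_equal(irs$arm_len[hit], 10L)
})

test_that("IR detection equals a brute-force oracle on a clean toy window", {
  arm <- "ACGTTGCAAC"
  seq <- paste0(strrep("A", 60), arm, strrep("A", 20), "CACAAAGGACT",
                strrep("A", 25), oracle_revcomp(arm), strrep("A", 60))
  g <- phage_genome("toy", seq, topology = "circular")
  cos <- find_cos_site(g)
  irs <- find_inverted_repeats(g, cos, arm_len = 10L, window = 60L,
                               max_mismatch = 0L)
  # oracle: enumerate every arm pair in the window
  n <- nchar(seq)
  win_l <- (cos$cos_start - 60L):(cos$cos_start - 10L)
  win_r <- cos$cos_end:(cos$cos_end + 50L)
  pairs <- 0L
  for (a in win_l) for (b in win_r) {
    la <- substr(seq, a + 1L, a + 10L)
    rb <- substr(seq, b + 1L, b + 10L)
    if (oracle_revcomp(la) == rb) pairs <- pairs + 1L
  }
  # poly-A filler cannot pair with itself, so only the planted pair exists
  expect_equal(pairs, 1L)
  expect_equal(nrow(irs), 1L)
  expect_equal(irs$left_start, 60L)
  expect_equal(irs$right_start, cos$cos_end + 25L)
})

test_that("a window with no complementary arms yields no IR pairs", {
  seq <- paste0(strrep("A", 100), "CACAAAGGACT", strrep("A", 100))
  g <- phage_genome("noarm", seq, topology = "circular")
  cos <- find_cos_site(g)
  irs <- find_inverted_repeats(g, cos, window = 80L, max_mismatch = 0L)
  expect_equal(nrow(irs), 0L)
})

test_that("direct repeats are labelled D1..D6 in order and match a regex oracle", {
  res <- default_genome_fixture()
  g <- res$genome
  cos <- find_cos_site(g)
  drs <- find_direct_repeats(g, cos)
  expect_equal(drs$label, paste0("D", 1:6))
  planted <- g$features[g$features$kind == "direct_repeat", ]
  expect_equal(sort(drs$start), sort(planted$start))
  # every reported coordinate re-extracts to the motif
  for (i in seq_len(nrow(drs)))
    expect_equal(substr(g$seq, drs$start[i] + 1L, drs$end[i]), "AATCT")
  # regex-count oracle over random windows
  set.seed(10)
  for (r in 1:25) {
    s <- random_seq(300, gc = 0.4)
    gg <- phage_genome("w", paste0(s, "CACAAAGGACT", random_seq(300, gc = 0.4)),
                       topology = "circular")
    cc <- find_cos_site(gg)
    got <- nrow(find_direct_repeats(gg, cc, window = 200L))
    win <- substr(gg$seq, cc$cos_start - 200L + 1L, cc$cos_end + 200L)
    exp <- length(gregexpr("(?=AATCT)", win, perl = TRUE)[[1]])
    if (gregexpr("(?=AATCT)", win, perl = TRUE)[[1]][1] == -1L) exp <- 0L
    expect_equal(got, exp)
  }
})

test_that("terminase sites: R1/R3 complete, R2 partial and overlapping D6", {
  res <- default_genome_fixture()
  g <- res$genome
  cos <- find_cos_site(g)
  drs <- find_direct_repeats(g, cos)
  ts <- map_terminase_sites(g, cos, default_terminase_motifs(), drs = drs)
  expect_true(ts$complete[ts$label == "R1"])
  expect_true(ts$complete[ts$label == "R3"])
  expect_false(ts$complete[ts$label == "R2"])
  expect_equal(ts$truncated_dr[ts$label == "R2"], "D6")
  expect_error(map_terminase_sites(g, cos, list()), "configuration")
})

test_that("absent terminase motifs come back incomplete with low matched fraction", {
  seq <- paste0(strrep("AC", 150), "CACAAAGGACT", strrep("AC", 150))
  g <- phage_genome("bare", seq, topology = "circular")
  cos <- find_cos_site(g)
  ts <- map_terminase_sites(g, cos, default_terminase_motifs())
  expect_true(all(!ts$complete))
  expect_true(all(ts$matched_fraction < 1))
})
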