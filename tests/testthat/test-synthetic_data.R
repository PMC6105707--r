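test_that("generation is byte-identical under a fixed seed", {
  a <- generate_genome(genome_spec(seed = 3, length = 29500L))
  b <- generate_genome(genome_spec(seed = 3, length = 29500L))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$features, b$truth$features)
  c <- generate_genome(genome_spec(seed = 8, length = 29500L))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("requested genome length and GC are realized", {
  res <- default_genome_fixture()
  L <- nchar(res$genome$seq)
  expect_gte(L, 29300L); expect_lte(L, 30200L)
  gc <- gc_content(res$genome$seq) / 100
  expect_gte(gc, 0.342); expect_lte(gc, 0.352)
  res2 <- generate_genome(genome_spec(seed = 5, gc = 0.40, length = 29400L))
  expect_equal(nchar(res2$genome$seq), 29400L)
  expect_lt(abs(gc_content(res2$genome$seq) / 100 - 0.40), 0.005)
  expect_error(genome_spec(gc = 0.7), "GC")
})

test_that("every planted feature is literally present in the sequence", {
  res <- default_genome_fixture()
  g <- res$genome
  f <- g$features
  for (i in seq_len(nrow(f))) {
    sub <- substr(g$seq, f$start[i] + 1L, f$end[i])
    ok <- switch(f$kind[i],
      cos = sub == "CACAAAGGACT",
      direct_repeat = startsWith(sub, "AATCT"),
      terminase_site = sub == default_terminase_motifs()[[f$label[i]]],
      primer_site = if (f$strand[i] == "+")
        sub == default_primer_pairs()$`936`$fwd
      else sub == revcomp(default_primer_pairs()$`936`$rev),
      orf = substr(sub, 1, 3) %in% c("ATG") ||
        f$label[i] == "tpeX",
      TRUE)
    expect_true(ok, info = paste(f$kind[i], f$label[i]))
  }
  # inverted repeat arms are reverse complements of each other
  ir <- f[f$kind == "inverted_repeat", ]
  arms <- substring(g$seq, ir$start + 1L, ir$end)
  expect_equal(revcomp(arms[ir$label == "IR_left"]),
               arms[ir$label == "IR_right"])
})

test_that("planted ORFs translate cleanly with correct terminators", {
  res <- default_genome_fixture()
  g <- res$genome
  orfs <- res$truth$orfs
  for (i in seq_len(nrow(orfs))) {
    if (orfs$label[i] == "tpeX") next
    body <- substr(g$seq, orfs$start[i] + 1L, orfs$end[i])
    expect_equal(nchar(body) %% 3L, 0L)
    aa <- strsplit(phagechar:::translate_dna(body), "")[[1]]
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("cohort genomes differ from their archetype only at recorded SNVs", {
  coh <- generate_cohort(n = 10, n_archetypes = 3, snv_rate = 1e-4, seed = 4)
  for (i in seq_along(coh$genomes)) {
    iso <- coh$genomes[[i]]
    arch <- coh$truth$archetypes[[
      as.integer(sub("arch", "", coh$truth$labels[[iso$id]]))]]
    a <- strsplit(iso$seq, "")[[1]]
    b <- strsplit(arch$seq, "")[[1]]
    expect_equal(which(a != b), coh$truth$snvs[[i]])
  }
})

test_that("zero SNV rate reproduces archetypes; one archetype gives one label", {
  coh <- generate_cohort(n = 6, n_archetypes = 3, snv_rate = 0, seed = 9)
  for (i in seq_along(coh$genomes)) {
    arch <- coh$truth$archetypes[[
      as.integer(sub("arch", "", coh$truth$labels[[coh$genomes[[i]]$id]]))]]
    expect_identical(coh$genomes[[i]]$seq, arch$seq)
  }
  one <- generate_cohort(n = 4, n_archetypes = 1, snv_rate = 1e-4, seed = 9)
  expect_length(unique(unname(one$truth$labels)), 1L)
})

test_that("cohort truth labels partition a 90-genome cohort into 8 classes", {
  coh <- cohort90_fixture()
  expect_length(coh$genomes, 90L)
  expect_equal(length(unique(unname(coh$truth$labels))), 8L)
  expect_true(all(table(coh$truth$labels) >= 1L))
})

test_that("planted enzyme sites appear at the requested positions", {
  L <- 29500L
  spec <- genome_spec(seed = 11, length = L,
                      enzyme_sites = list(EcoRI = c(L - 150L, L - 100L)))
  res <- generate_genome(spec, id = "planted")
  expect_equal(substr(res$genome$seq, L - 149L, L - 144L), "GAATTC")
  expect_equal(substr(res$genome$seq, L - 99L, L - 94L), "GAATTC")
  rs <- res$genome$features
  expect_equal(sort(rs$start[rs$kind == "restriction_site"]),
               c(L - 150L, L - 100L))
  # a site colliding with the cos block is an immediate spec error
  bad <- genome_spec(seed = 11, length = L,
                     enzyme_sites = list(EcoRI = 2L))
  expect_error(generate_genome(bad), "spec error")
})
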