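# Shared fixtures: the default synthetic genome is expensive enough to
# build once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_genome_fixture <- function() {
  if (is.null(.fixture_env$res))
    .fixture_env$res <- generate_genome(genome_spec(seed = 1))
  .fixture_env$res
}

# The 90-isolate / 8-archetype cohort under the reference seed, cached
# because both the cohort tests and the restriction-typing checks use it.
cohort90_fixture <- function() {
  if (is.null(.fixture_env$cohort90))
    .fixture_env$cohort90 <- generate_cohort(n = 90L, n_archetypes = 8L,
                                             snv_rate = 1e-4, seed = 1L)
  .fixture_env$cohort90
}

# A small toy genome carrying a shifty-stop construct with known
# arithmetic: a 33-codon upstream ORF ending CCC, TAG, then 12 +1-frame
# sense codons and a stop, so the fused product is 33 + 12 = 45 aa.
shifty_toy <- function() {
  upstream <- paste0("ATG", strrep("GCT", 31), "CCC", "TAG")
  post <- paste0("A", strrep("GCA", 11), "TAA")
  seq <- paste0("ACGACG", "TAA", upstream, post, "ACGTACGT")
  phage_genome("toy_shift", seq)
}
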