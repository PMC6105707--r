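---
title: "Characterizing 936-type dairy phage genomes in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing 936-type dairy phage genomes in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagechar)
```

## Scope and model organisms

Virulent 936-type *Siphoviridae* phages of *Lactococcus lactis* are the
dominant cause of dairy fermentation failures. Their genomes are linear
cos-ended dsDNA of roughly 29.3--30.2 kb with GC around 34.6--34.9%,
organized into three same-strand transcription regions (late, early,
middle reading along the genome from the cos cut). `phagechar` implements
the computational side of a standard characterization workflow for such
isolates:

* RFLP typing: in-silico restriction digestion with cohesive-end
  handling, gel-aware band calling, a band-pattern distance and
  single-linkage grouping into restriction types;
* multiplex PCR typing with 936- and c2-specific primer pairs;
* genome statistics, ORF calling and transcription-region partitioning;
* mapping of the packaging elements around the cos site (inverted
  repeats, AATCT direct repeats, terminase binding sites);
* detection and simulation of the +1 "shifty stop" frameshift that fuses
  the major tail protein (MTP) with the downstream tail protein
  extension (TpeX);
* one-step growth parameter estimation (latent period, burst time,
  burst size);
* alignment-free k-mer distances, neighbour-joining trees and dot-plot
  synteny segments.

A synthetic genome generator plants all of these features with recorded
ground truth, so every stage is testable without external downloads.

## Coordinate and topology conventions

All in-memory coordinates are 0-based half-open; all emitted tables are
1-based inclusive (GenBank style), and the conversion is bijective.
Genomes with topology `linear_cos` anchor position 0 at the first base 3'
of the cos cut on the top strand, i.e. the sequence begins with the cos
11-mer. Scanning functions (`find_cos_site`, `in_silico_pcr`, the window
extraction around cos) use the circular view of such genomes, so motifs
and amplicons spanning the join are found. Ambiguity codes are rejected
rather than masked: every downstream scan is an exact-word scan over
ACGT, and silently masked bases would bias restriction-site and repeat
counts.

## The synthetic generator

`generate_genome()` assembles a genome from a `genome_spec()`. The
defaults *are* the study conditions the package is tested under:
length drawn uniformly from 29,300--30,200 bp, GC 0.347, cos motif
`CACAAAGGACT`, 10-bp inverted-repeat arms flanking cos (the left arm sits
at the very end of the linear sequence and wraps), six AATCT direct
repeats, terminase motifs R1 and R3 planted complete and R2 planted only
as its 11-nt AATCT-prefixed truncation (so the last direct repeat doubles
as a truncated R2), a 55-ORF late/early/middle region plan
(27/23/5), and the 936-typing primer pair planted at 179-bp amplicon
spacing. The region counts and the one fixed 483-nt middle ORF mirror the
annotation profile of sequenced 936-type genomes (53--57 ORFs, a handful
of small middle-region genes).

Key construction choices:

* **Background and codons.** Intergenic filler is i.i.d. with base
  probabilities set by the target GC. ORF bodies are random sense codons;
  because excluding the AT-rich stop codons biases composition, the codon
  sampler's input GC is adjusted by root finding so the *realized* codon
  GC matches the request. After assembly a repair pass flips bases in
  intergenic filler (never in planted features, never within 240 bp of
  cos) until the genome GC is on target; the realized value stays within
  0.5 percentage points of the request.
* **Exact ORF recovery.** Each planted ORF is preceded by an in-frame TAA
  in the last 3 nt of its gap, so the ORF caller's
  "most upstream in-segment start" rule recovers planted coordinates
  exactly. The one designed exception is TpeX: its reading frame runs
  through the upstream mtp body, so its called start may extend upstream
  of the planted ATG -- mirroring the start-assignment ambiguity real
  annotations show for this gene -- and tests assert only its terminator.
* **The shifty-stop construct.** The mtp ORF is 540 nt (a 179-aa
  product) ending `CCC TAG`. Translation is modelled as incorporating
  proline at CCC and resuming one nucleotide into the TAG (the first
  post-shift codon starts at the A), a register isolated in one function
  so the alternative (+1 from the T) is a one-line change. The construct
  supplies 341 post-shift sense codons before the first +1-frame stop,
  so the simulated fusion is 179 + 341 = 520 aa, the length expected for
  the MTP--TpeX fusion of 936-type phages. Other planted ORFs never end
  `CCC TAG` (the generator resamples such terminators), keeping the mtp
  the unique candidate.
* **Region partitioning.** The three regions are separated by planned
  400 bp and 350 bp gaps while intra-region gaps stay at most 80 bp, so
  splitting the coding-strand ORF chain at its two largest intergenic
  gaps -- the only sequence-intrinsic surrogate for annotation-derived
  region calls -- reproduces the plan. Ties break at the earliest gap.
* **Sanitation.** The cos window (240 bp each side) is resampled until it
  contains exactly the planted AATCT occurrences and a single cos motif;
  assembly is verified afterwards (single circular cos occurrence, exact
  direct-repeat count, intact shifty stop, unique 179-bp amplicon) and
  rerun under a derived seed in the rare case a junction effect slips
  through.

`generate_cohort()` models a collection of related dairy isolates: one
ancestral genome, `n_archetypes` lineages diverged from it, and `n`
isolates. Archetype lineages differ by intergenic substitutions
(`archetype_div`, default 1% over permitted positions) and by
*restriction-site layout*: each archetype knocks out a random subset of
the ancestor's EcoRV sites and plants a few new ones in intergenic
filler. Layout differences, not point divergence, are what separate
restriction types on a gel, and the generator verifies that all archetype
band-pattern distances exceed the grouping threshold (regenerating up to
100 times) so that cohort-level typing claims are reproducible by
construction rather than by luck. Isolate-level SNVs (default rate
1e-4/bp) avoid planted feature footprints and pass a windowed
site-neutrality check against all registered enzymes, so isolates of one
archetype digest identically; an option (`mask_features = FALSE`) allows
leaky mutation for robustness studies. Because real cohort studies do
not report per-group isolate counts, class sizes are drawn uniformly
after guaranteeing one isolate per archetype.

The generator does **not** model realistic codon usage, promoters,
terminators, or evolution along a phylogeny; archetype knockout
substitutions may fall inside ORF bodies (as real inter-strain variation
does). Passing tests therefore demonstrate correctness of the analysis
logic under controlled conditions, not performance on real sequencing
data -- real genomes bring annotation noise, repeat structure and
enzyme-site statistics the generator only approximates.

## RFLP typing

`digest()` cuts at recognition-site start + cut offset on the top strand
(EcoRI `G^AATTC`, EcoRV `GAT^ATC`, HindIII `A^AGCTT`; palindromic type II
enzymes, so both strand nicks collapse to one cut). `dissociated` mode
models formamide-treated samples whose annealed cohesive ends have been
separated: n sites give n+1 fragments. `cohesive` mode joins the two
terminal fragments, as untreated cos ends do on a gel, giving n fragments
-- conservation of total length holds in both modes, and cohesive
digestion is rotation-invariant (a circular-digestion property used in
the tests).

`to_bands()` models a 0.7% agarose gel: fragments under `min_size`
(default 200 bp; the true visibility limit is gel- and stain-dependent,
so this is a flag) are dropped, and fragments within a ratio tolerance
(`|ln(s1/s2)| <= ln(1 + rel_tol)`, default 5%) co-migrate into one band
at their mean. `pattern_distance()` greedily matches size-sorted band
lists under the same ratio test and returns the Dice-style dissimilarity
`1 - 2m/(|b1|+|b2|)`. Greedy matching keeps the distance deterministic
and cheap at gel-realistic band counts; it is symmetric and zero on
identical lists but not guaranteed to satisfy the triangle inequality,
which single-linkage grouping does not require. `group_patterns()` takes
connected components under a distance threshold (default 0.1). The
threshold is a declared free parameter: visual gel comparison has no
stated tolerance, and the generator's archetype-distinctness check is
what makes the default reliable on synthetic cohorts.

## PCR typing

`in_silico_pcr()` requires exact identity over each primer's 3'-terminal
5 bases (polymerase extension needs a matched 3' end -- the classical
clamp rule, adopted because no mismatch model is published for these
reagents) and at most 2 mismatches elsewhere, both configurable. Both
template orientations are scanned, products up to 5 kb are reported, and
product length is the standard amplicon size (5' end of one primer
footprint to 5' end of the other, inclusive). Multiplexing is modelled as
independent single-pair reactions without primer competition.
`classify_phage_type()` maps amplicon presence to a label
(`936` / `c2` / `mixed` / `untyped`); the c2 call is presence-based only,
as no c2 product size is asserted anywhere in the package.

## ORF calling and annotation statistics

`call_orfs()` is a deliberately minimal deterministic caller: each of the
six frames is split at stop codons and every stop-bounded segment whose
ORF (from the most upstream in-segment ATG/GTG/TTG through the stop)
reaches 90 nt is reported. There is no ribosome-binding-site or coding
model, so counts differ from annotation-pipeline outputs; summary tables
report this caller's counts and make no claim of equality with published
gene counts. The 90-nt default admits the small middle-region genes while
suppressing most noise ORFs. `count_tmds()` uses the standard
Kyte--Doolittle window of 19 residues with a 1.6 mean-hydropathy
threshold (the usual transmembrane heuristic, stated explicitly because
holin classification depends on it); three merged hydrophobic runs
classify a holin as class I.

## cos-region mapping

`find_cos_site()` is exact by default because the cos 11-mer is
sequence-identical across 936-type phages; a mismatch tolerance is
exposed for exploratory scans. `find_inverted_repeats()` enumerates all
arm pairs (left arm ending before cos, right arm after, each within a
200-bp window) whose reverse-complement match has at most 1 mismatch --
the published descriptions do not state whether real arms are exact, so 1
is a documented guess exposed as a flag. Overlapping redundant pairs are
pruned to the best-scoring one (fewest mismatches, then smallest span),
and results sort by distance to cos. Terminase binding sites are supplied
via configuration only: their sequences are genome-family-specific and
not published alongside the repeat descriptions, so the package defaults
are the synthetic generator's own planted motifs
(`default_terminase_motifs()`), with R2's truncation relationship to the
last direct repeat reproduced by planting only its AATCT-prefixed head.

## Frameshift simulation

`find_shifty_stops()` nominates coding-strand ORFs terminating
`CCC TAG` with a +1-frame stop within 3 kb downstream; only TAG
terminators qualify because the signal is specifically CCC followed by
an amber stop. `simulate_frameshift()` translates through the proline,
shifts +1, and translates to the next in-frame stop. The post-shift
register (+1 lands on the A of TAG) is a modelling decision validated
against the 520-aa fusion the synthetic construct encodes; the function
isolating it makes the alternative register a one-line change, and
whether the initiator methionine is counted is fixed by the arithmetic
of the construct (it is).

## One-step growth estimation

Titers span orders of magnitude, so the three-phase model (flat,
log-linear rise, flat) is fitted in log10 space; linear-space least
squares would be dominated by the plateau. Breakpoints are restricted to
observed sampling times (the assay samples every 3 min), making the
search an exhaustive, exactly reproducible grid scan; ties break toward
the earliest breakpoint pair. The pre-rise mean excludes the sample at
the first breakpoint and the plateau mean includes everything from the
second breakpoint on. Burst size is deliberately *not* the fitted
amplitude: it is the classical ratio of mean plateau titer to mean
pre-rise titer, matching how the assay is analysed at the bench. A curve
whose titers never exceed twice the initial level is rejected as flat,
and any breakpoint pair leaving fewer than two points in a flat phase is
skipped as degenerate. On noiseless simulated curves with on-grid
breakpoints, recovery is exact; under 5% multiplicative noise, 100
replicates at the fastest published parameter set (burst 148, latent 15
min, burst time 25 min) keep the median burst-size error under 10% and
the median latent-period error within one sampling interval.

## Comparative genomics

`kmer_distance()` uses canonical 15-mers (lexicographic minimum of word
and reverse complement, making the distance strand-neutral) and the Mash
transform `-(1/k) ln(2J/(1+J))` of the Jaccard similarity, capped at 1.
`nj_tree()` is classical neighbour joining with lowest-index tie-breaking
and zero-clamped negative branch lengths, emitting Newick. NJ on
alignment-free distances replaces external
multiple-alignment/maximum-likelihood engines deliberately: the package's
phylogenetic claims are limited to clade recovery on synthetic truth
(related archetypes versus an unrelated outgroup), not to branch support,
and BLAST-style identity percentages are out of scope because k-mer
distances are not comparable to alignment identities.
`dotplot_segments()` reports maximal exact matches of at least 20 bp in
both orientations via shared-word anchoring on diagonals; a single
substitution splits the main diagonal into two abutting segments, which
is exactly how disturbed-synteny regions present in dot plots.

## Problem sizes used in the test suite

The suite regenerates everything from code: one default genome shared
across tests, a 90-isolate/8-archetype cohort for typing, 50 seeded
genomes for cos-feature recovery, 200 random digests against a naive
oracle, 100 noisy growth replicates, and 100 seeded archetype+outgroup
cohorts for clade recovery. These sizes reproduce the cohort scale of a
real isolate survey while keeping the whole suite re-runnable from
scratch in minutes on one core.

## Known limitations

* The ORF caller's start assignment (maximal upstream extension) differs
  from RBS-aware annotation pipelines; gene counts are caller-dependent.
* `pattern_distance` is a semimetric; grouping relies on single linkage,
  which tolerates that but can chain through intermediate patterns.
* Real terminase-site sequences must be supplied by the user; the
  defaults only describe the synthetic genomes.
* PCR simulation ignores melting temperature, degenerate bases and
  primer competition.
* The generator's archetype model (site knockouts plus planted sites
  over a shared ancestor) reproduces restriction-type structure but not
  the mosaic recombination real phage cohorts show.
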