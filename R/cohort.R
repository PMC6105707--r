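# Cohort generation: a common ancestral genome, archetype lineages with
# distinct restriction-site layouts, and isolate-level variation -- plus
# one-step growth curve simulation.

# Substitution positions allowed for mutation: outside every planted
# feature footprint and outside the cos window at the genome ends.
allowed_positions <- function(genome, zone = 260L) {
  L <- nchar(genome$seq)
  mask <- rep(TRUE, L)                 # index = 1-based position
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    a <- max(1L, f$start[i] + 1L); b <- min(L, f$end[i])
    if (a <= b) mask[a:b] <- FALSE
  }
  mask[seq_len(min(zone, L))] <- FALSE
  mask[seq.int(max(1L, L - zone + 1L), L)] <- FALSE
  which(mask)
}

# Apply `n_snv` substitutions at positions drawn from `allowed`;
# `neutral` additionally enforces restriction-site neutrality.
mutate_seq <- function(seq, allowed, n_snv, neutral = FALSE,
                       enzymes = default_enzymes()) {
  n_snv <- min(n_snv, length(allowed))
  if (n_snv == 0L) return(list(seq = seq, snvs = integer(0)))
  b <- strsplit(seq, "")[[1]]
  if (!neutral) {
    pos <- sample(allowed, n_snv)
    alt <- vapply(b[pos], function(r) sample(setdiff(DNA_BASES, r), 1L), "")
    b[pos] <- alt
    return(list(seq = paste(b, collapse = ""), snvs = sort(pos)))
  }
  placed <- integer(0)
  pool <- allowed
  tries <- 0L
  while (length(placed) < n_snv && length(pool) > 0L && tries < n_snv * 60L) {
    tries <- tries + 1L
    i <- sample.int(length(pool), 1L)
    pos <- pool[i]
    alt <- sample(setdiff(DNA_BASES, b[pos]), 1L)
    old <- b[pos]
    b[pos] <- alt
    a0 <- max(1L, pos - 5L); b0 <- min(length(b), pos + 5L)
    win_new <- paste(b[a0:b0], collapse = "")
    b[pos] <- old
    win_old <- paste(b[a0:b0], collapse = "")
    ok <- all(vapply(enzymes, function(e)
      length(find_exact(win_old, e$site)) == length(find_exact(win_new, e$site)),
      logical(1)))
    if (ok) {
      b[pos] <- alt
      placed <- c(placed, pos)
      pool <- pool[-i]
    }
  }
  list(seq = paste(b, collapse = ""), snvs = sort(placed))
}

#' Generate a cohort of related synthetic genomes
#'
#' Emulates a collection of dairy-plant phage isolates: one ancestral
#' genome is generated from `spec`; `n_archetypes` archetype lineages
#' diverge from it by intergenic substitutions plus a small
#' archetype-specific set of planted EcoRV sites (recorded as
#' `restriction_site` features); each of the `n` isolates is a copy of
#' one archetype carrying isolate-level SNVs. Isolate SNVs avoid every
#' planted feature footprint and (by a windowed site-neutrality check)
#' never create or destroy a recognition site of the default enzymes, so
#' restriction-type identity within an archetype is exact. The generator
#' verifies that all archetype EcoRV band patterns are mutually farther
#' apart than `distinct_threshold` and regenerates the archetype set
#' (up to 100 attempts) otherwise.
#'
#' @param n Number of isolates.
#' @param n_archetypes Number of archetype lineages (`n >=
#'   n_archetypes >= 1`).
#' @param snv_rate Per-bp isolate substitution probability
#'   (default 1e-4).
#' @param seed Integer seed.
#' @param spec [genome_spec()] for the ancestral genome.
#' @param archetype_div Per-bp archetype divergence from the ancestor
#'   (default 0.01, applied over permitted intergenic positions).
#' @param extra_sites Range of archetype-specific planted EcoRV sites
#'   (default 2-5).
#' @param distinct_threshold Minimum pairwise archetype band-pattern
#'   distance (default 0.1, the grouping threshold).
#' @param mask_features Mask planted feature footprints from isolate SNVs
#'   (default TRUE; FALSE allows leaky mutation for robustness studies).
#' @return List: `genomes` (n [phage_genome()]s, ids `iso001`...),
#'   `truth` with `labels` (archetype label per isolate), `archetypes`
#'   (list of archetype genomes), `base`, `snvs`.
#' @export
generate_cohort <- function(n = 90L, n_archetypes = 8L, snv_rate = 1e-4,
                            seed = 1L, spec = genome_spec(),
                            archetype_div = 0.01, extra_sites = 2:5,
                            distinct_threshold = 0.1,
                            mask_features = TRUE) {
  if (n < n_archetypes || n_archetypes < 1L)
    stop("need n >= n_archetypes >= 1", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(2^20, 4L)
  spec$seed <- seeds[1L]
  base <- generate_genome(spec, id = "ancestor")
  L <- nchar(base$genome$seq)
  allowed <- allowed_positions(base$genome)
  enzymes <- default_enzymes()

  # archetypes: divergence + planted EcoRV layouts, verified distinct
  archetypes <- NULL
  for (attempt in 1:100) {
    set.seed(seeds[2L] + attempt)
    anc_sites <- find_exact(base$genome$seq, enzymes$EcoRV$site)  # 0-based
    cand <- lapply(seq_len(n_archetypes), function(a) {
      n_div <- stats::rbinom(1L, L, archetype_div)
      mut <- mutate_seq(base$genome$seq, allowed, n_div, neutral = FALSE)
      s <- mut$seq
      feats <- base$genome$features
      site <- enzymes$EcoRV$site
      # archetype-specific layout: knock out a subset of ancestral sites
      # (merging their flanking fragments) and plant a few new ones
      surviving <- anc_sites[vapply(anc_sites, function(p)
        substr(s, p + 1L, p + nchar(site)) == site, logical(1))]
      n_ko <- min(length(surviving), sample(1:3, 1L))
      ko <- if (n_ko > 0L) sample(surviving, n_ko) else integer(0)
      for (p in ko) {
        # disrupt the middle of the recognition word
        cur <- substr(s, p + 4L, p + 4L)
        substr(s, p + 4L, p + 4L) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
      n_extra <- if (length(extra_sites) == 1L) extra_sites else
        sample(extra_sites, 1L)
      spots <- allowed[allowed <= L - nchar(site)]
      planted <- integer(0)
      while (length(planted) < n_extra && length(spots) > 0L) {
        p <- spots[sample.int(length(spots), 1L)]
        span <- p:(p + nchar(site) - 1L)
        if (all(span %in% allowed) &&
            !any(abs(planted - p) < nchar(site) + 2L)) {
          substr(s, p, p + nchar(site) - 1L) <- site
          planted <- c(planted, p)
        }
        spots <- setdiff(spots, p)
      }
      feats <- rbind_features(feats, feature_table(
        rep("restriction_site", length(planted)), planted - 1L,
        planted - 1L + nchar(site), rep("*", length(planted)),
        rep("EcoRV", length(planted))))
      phage_genome(sprintf("arch%02d", a), s, topology = "linear_cos",
                   features = feats,
                   provenance = sprintf("archetype %d (cohort seed %d)",
                                        a, seed))
    })
    if (n_archetypes == 1L) { archetypes <- cand; break }
    pats <- lapply(cand, digest, enzyme = "EcoRV", end_mode = "dissociated")
    dists <- utils::combn(length(cand), 2L, function(ij)
      pattern_distance(pats[[ij[1L]]], pats[[ij[2L]]]))
    if (all(dists > distinct_threshold)) {
      archetypes <- cand
      break
    }
  }
  if (is.null(archetypes))
    stop("generation error: could not build ", n_archetypes,
         " archetypes with distinct restriction patterns in 100 attempts",
         call. = FALSE)

  # isolates: one per archetype first, the rest drawn uniformly
  set.seed(seeds[3L])
  labels <- c(seq_len(n_archetypes),
              sample.int(n_archetypes, n - n_archetypes, replace = TRUE))
  genomes <- vector("list", n)
  snvs <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- archetypes[[labels[i]]]
    iso_allowed <- if (mask_features) allowed_positions(arch) else
      seq_len(nchar(arch$seq))
    n_snv <- stats::rbinom(1L, L, snv_rate)
    mut <- mutate_seq(arch$seq, iso_allowed, n_snv, neutral = TRUE,
                      enzymes = enzymes)
    genomes[[i]] <- phage_genome(sprintf("iso%03d", i), mut$seq,
                                 topology = "linear_cos",
                                 features = arch$features,
                                 provenance = sprintf("isolate of arch%02d",
                                                      labels[i]))
    snvs[[i]] <- mut$snvs
  }
  list(genomes = genomes,
       truth = list(labels = stats::setNames(paste0("arch",
                                                    sprintf("%02d", labels)),
                                             vapply(genomes, function(g) g$id, "")),
                    archetypes = archetypes, base = base, snvs = snvs,
                    seed = seed))
}

#' Simulate a one-step growth curve
#'
#' Piecewise model of a synchronized infection cycle sampled every `dt`
#' minutes: titer stays at `n0` (the initially infected cells, whose
#' eventual lysis each registers as one plaque) until the latent period
#' ends, rises log-linearly to `n0 * burst_size` at the burst time, and
#' plateaus thereafter. Multiplicative lognormal noise (sdlog =
#' `noise_sd`) is applied pointwise.
#'
#' @param latent Latent period, minutes.
#' @param burst_time Burst (plateau-onset) time, minutes
#'   (`latent < burst_time <= t_max`).
#' @param burst_size Particles released per infected cell (>= 1).
#' @param n0 Initial infected cells per ml (default 1e5).
#' @param dt Sampling interval in minutes (default 3, the classical
#'   assay's interval).
#' @param t_max End of sampling (default `burst_time + 15`).
#' @param noise_sd Lognormal sdlog of multiplicative noise (default 0.05;
#'   0 gives the noiseless curve).
#' @param seed Integer seed.
#' @return A [growth_curve()].
#' @export
simulate_growth_curve <- function(latent, burst_time, burst_size, n0 = 1e5,
                                  dt = 3, t_max = burst_time + 15,
                                  noise_sd = 0.05, seed = 1L) {
  if (n0 <= 0 || burst_size <= 0)
    stop("parameter error: n0 and burst_size must be positive",
         call. = FALSE)
  if (!(latent < burst_time && burst_time <= t_max))
    stop("parameter error: need latent < burst_time <= t_max",
         call. = FALSE)
  times <- seq(0, t_max, by = dt)
  frac <- pmin(1, pmax(0, (times - latent) / (burst_time - latent)))
  titers <- n0 * burst_size^frac
  if (noise_sd > 0) {
    set.seed(seed)
    titers <- titers * stats::rlnorm(length(titers), 0, noise_sd)
  }
  growth_curve(times, titers, n0 = NULL)
}
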