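# In-silico restriction digestion with cohesive-end handling, gel-aware
# band patterns, a band-pattern distance and single-linkage grouping into
# restriction types.

#' Digest a genome in silico
#'
#' Cut positions are recognition-site starts plus the enzyme's cut offset
#' on the top strand (type II palindromic enzymes: the two strand nicks
#' collapse to one double-strand cut). Two cohesive-end modes reproduce
#' the band difference that formamide treatment removes on a gel:
#' `dissociated` treats the genome as a true linear molecule (cos ends
#' apart; n sites give n+1 fragments), `cohesive` joins the two terminal
#' fragments as the annealed cos ends do (circular digestion; n >= 1 sites
#' give n fragments).
#'
#' @param genome A [phage_genome()].
#' @param enzyme An [enzyme_def()] or the name of a default enzyme.
#' @param end_mode `"dissociated"` or `"cohesive"`.
#' @return A `restriction_pattern`: genome_id, enzyme, end_mode,
#'   `fragments` (integer multiset of sizes, unordered), `n_sites`.
#' @export
digest <- function(genome, enzyme = "EcoRV",
                   end_mode = c("dissociated", "cohesive")) {
  end_mode <- match.arg(end_mode)
  if (is.character(enzyme)) {
    reg <- default_enzymes()
    if (!enzyme %in% names(reg))
      stop("enzyme not registered: ", enzyme, call. = FALSE)
    enzyme <- reg[[enzyme]]
  }
  n <- nchar(genome$seq)
  if (n == 0L) stop("zero-length genome", call. = FALSE)
  sites <- find_exact(genome$seq, enzyme$site)
  cuts <- sort(sites + enzyme$cut_offset)
  cuts <- cuts[cuts > 0L & cuts < n]
  if (end_mode == "dissociated") {
    fragments <- diff(c(0L, cuts, n))
  } else {
    if (length(cuts) == 0L) {
      fragments <- n
    } else {
      inner <- diff(cuts)
      joined <- (n - cuts[length(cuts)]) + cuts[1L]  # terminal fragments fused
      fragments <- c(joined, inner)
    }
  }
  structure(list(genome_id = genome$id, enzyme = enzyme$name,
                 end_mode = end_mode,
                 fragments = as.integer(fragments),
                 n_sites = length(cuts)),
            class = "restriction_pattern")
}

#' @export
print.restriction_pattern <- function(x, ...) {
  cat(sprintf("<restriction_pattern> %s x %s (%s): %d fragments [%s]\n",
              x$genome_id, x$enzyme, x$end_mode, length(x$fragments),
              paste(sort(x$fragments, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Convert a fragment multiset into visible gel bands
#'
#' Models what is resolvable on a 0.7% agarose gel: fragments below
#' `min_size` are dropped (run off or too faint) and fragments that
#' co-migrate -- sizes within the ratio test
#' `|ln(s1/s2)| <= ln(1 + rel_tol)` -- are merged into one band at their
#' mean size.
#'
#' @param pattern A `restriction_pattern` from [digest()], or a numeric
#'   vector of fragment sizes.
#' @param min_size Smallest visible fragment in bp (default 200).
#' @param rel_tol Relative co-migration tolerance (default 0.05).
#' @return Numeric vector of band sizes, descending.
#' @export
to_bands <- function(pattern, min_size = 200, rel_tol = 0.05) {
  sizes <- if (inherits(pattern, "restriction_pattern"))
    pattern$fragments else pattern
  sizes <- sort(sizes[sizes >= min_size], decreasing = TRUE)
  if (length(sizes) <= 1L) return(as.numeric(sizes))
  bands <- numeric(0)
  group <- sizes[1L]
  for (s in sizes[-1L]) {
    if (abs(log(group[length(group)] / s)) <= log(1 + rel_tol)) {
      group <- c(group, s)
    } else {
      bands <- c(bands, mean(group))
      group <- s
    }
  }
  c(bands, mean(group))
}

#' Distance between two band patterns
#'
#' Greedy size-sorted matching of band lists under the co-migration ratio
#' test, then a Dice-style dissimilarity `1 - 2m / (|b1| + |b2|)` where `m`
#' is the number of matched bands. Symmetric and zero on identical lists;
#' the triangle inequality is not guaranteed (greedy matching), so this is
#' a semimetric.
#'
#' @param p1,p2 `restriction_pattern`s (same enzyme and end mode) or band
#'   vectors.
#' @param rel_tol Ratio tolerance for two bands to match (default 0.05).
#' @param min_size Passed to [to_bands()] when patterns are supplied.
#' @return Distance in `[0, 1]`.
#' @export
pattern_distance <- function(p1, p2, rel_tol = 0.05, min_size = 200) {
  if (inherits(p1, "restriction_pattern") &&
      inherits(p2, "restriction_pattern")) {
    if (p1$enzyme != p2$enzyme || p1$end_mode != p2$end_mode)
      stop("patterns from different enzymes or end modes are not comparable",
           call. = FALSE)
    b1 <- to_bands(p1, min_size, rel_tol)
    b2 <- to_bands(p2, min_size, rel_tol)
  } else {
    b1 <- sort(as.numeric(p1), decreasing = TRUE)
    b2 <- sort(as.numeric(p2), decreasing = TRUE)
  }
  if (length(b1) == 0L && length(b2) == 0L) return(0)
  m <- 0L; i <- 1L; j <- 1L
  tol <- log(1 + rel_tol)
  while (i <= length(b1) && j <= length(b2)) {
    if (abs(log(b1[i] / b2[j])) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (b1[i] > b2[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  1 - 2 * m / (length(b1) + length(b2))
}

#' Group restriction patterns into restriction types
#'
#' Single-linkage grouping: patterns are nodes, edges connect pairs at
#' distance <= `threshold`, groups are the connected components. Group
#' labels (`G1`, `G2`, ...) are assigned in order of each group's first
#' member, so the result is deterministic given the input order.
#'
#' @param patterns List of `restriction_pattern`s sharing enzyme/end mode.
#' @param threshold Linkage distance threshold (default 0.1).
#' @param rel_tol,min_size Band-calling parameters, see [to_bands()].
#' @return Data frame: genome_id, group (factor-free character labels).
#' @export
group_patterns <- function(patterns, threshold = 0.1, rel_tol = 0.05,
                           min_size = 200) {
  stopifnot(length(patterns) >= 1L)
  n <- length(patterns)
  bands <- lapply(patterns, to_bands, min_size = min_size, rel_tol = rel_tol)
  # union-find over pairs within threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d <- pattern_distance(bands[[i]], bands[[j]], rel_tol = rel_tol)
      if (d <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  labels <- paste0("G", as.integer(factor(roots, levels = unique(roots))))
  data.frame(genome_id = vapply(patterns, function(p)
    if (inherits(p, "restriction_pattern")) p$genome_id else "", ""),
    group = labels, stringsAsFactors = FALSE)
}

#' Full RFLP typing of a set of genomes
#'
#' Convenience wrapper: digest every genome, call bands, group.
#'
#' @param genomes List of [phage_genome()]s.
#' @param enzyme,end_mode See [digest()].
#' @param threshold,min_size,rel_tol See [group_patterns()].
#' @return List with `patterns`, `groups` (data frame), `n_groups`.
#' @export
rflp_type <- function(genomes, enzyme = "EcoRV", end_mode = "dissociated",
                      threshold = 0.1, min_size = 200, rel_tol = 0.05) {
  patterns <- lapply(genomes, digest, enzyme = enzyme, end_mode = end_mode)
  groups <- group_patterns(patterns, threshold = threshold,
                           rel_tol = rel_tol, min_size = min_size)
  list(patterns = patterns, groups = groups,
       n_groups = length(unique(groups$group)))
}
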