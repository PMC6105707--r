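# In-silico multiplex PCR typing with 936- and c2-specific primer pairs.

# Binding sites of a primer whose 3' end points rightward on `template`
# (i.e. the primer sequence read 5'->3' matches the template top strand).
# A site requires exact identity over the 3'-terminal `clamp_len` bases
# and at most `max_mismatch` mismatches elsewhere. 0-based starts.
plus_sites <- function(template, primer, max_mismatch, clamp_len) {
  k <- nchar(primer)
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                max.mismatch = max_mismatch)
  starts <- BiocGenerics::start(m) - 1L
  if (length(starts) == 0L) return(integer(0))
  clamp <- substr(primer, k - clamp_len + 1L, k)
  starts[vapply(starts, function(s)
    substr(template, s + k - clamp_len + 1L, s + k) == clamp, logical(1))]
}

# Binding sites of a primer on the bottom strand (3' end points leftward):
# its reverse complement is searched on the top strand and the 3' clamp
# corresponds to the first `clamp_len` bases of that match. 0-based starts
# of the footprint on the top strand.
minus_sites <- function(template, primer, max_mismatch, clamp_len) {
  rc <- revcomp(primer)
  k <- nchar(rc)
  m <- Biostrings::matchPattern(rc, Biostrings::DNAString(template),
                                max.mismatch = max_mismatch)
  starts <- BiocGenerics::start(m) - 1L
  if (length(starts) == 0L) return(integer(0))
  clamp <- substr(rc, 1L, clamp_len)
  starts[vapply(starts, function(s)
    substr(template, s + 1L, s + clamp_len) == clamp, logical(1))]
}

#' In-silico PCR with one primer pair
#'
#' Binding requires exact identity over the 3'-terminal `clamp_len` bases
#' of each primer (extension needs a matched 3' end) and at most
#' `max_mismatch` mismatches over the rest. Both template orientations are
#' considered (either primer may sit on the top strand). Every convergent
#' arrangement with product length up to `max_product` is reported;
#' product length runs from the 5' end of one primer's binding site to the
#' 5' end of the other's, inclusive (standard amplicon size). On
#' `linear_cos` templates the circular view is used, so products spanning
#' the cos join are found.
#'
#' @param genome A [phage_genome()].
#' @param pair A [primer_pair()].
#' @param max_mismatch Non-clamp mismatches tolerated per primer
#'   (default 2).
#' @param clamp_len Exact 3' clamp length (default 5).
#' @param max_product Largest product reported in bp (default 5000).
#' @return Data frame: pair, fwd_pos, rev_pos (0-based footprint starts on
#'   the top strand, modulo genome length), length, fwd_mismatches,
#'   rev_mismatches, orientation (`"+"` when the forward primer sits on
#'   the top strand).
#' @export
in_silico_pcr <- function(genome, pair, max_mismatch = 2L, clamp_len = 5L,
                          max_product = 5000L) {
  if (nchar(pair$fwd) < clamp_len || nchar(pair$rev) < clamp_len)
    stop("primer shorter than the 3' clamp", call. = FALSE)
  seq <- genome$seq
  n <- nchar(seq)
  circular <- genome$topology == "linear_cos"
  ext <- min(max_product, n)
  template <- if (circular) paste0(seq, substr(seq, 1L, ext)) else seq
  empty <- data.frame(pair = character(), fwd_pos = integer(),
                      rev_pos = integer(), length = integer(),
                      fwd_mismatches = integer(),
                      rev_mismatches = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  one_orientation <- function(plusP, minusP, orientation) {
    kp <- nchar(plusP); km <- nchar(minusP)
    ph <- plus_sites(template, plusP, max_mismatch, clamp_len)
    ph <- ph[ph < n]
    mh <- minus_sites(template, minusP, max_mismatch, clamp_len)
    rows <- empty
    for (f in ph) {
      for (r in mh[mh >= f]) {
        len <- (r + km) - f
        if (len >= kp + km && len <= max_product && len <= n) {
          pm <- hamming(substr(template, f + 1L, f + kp), plusP)
          mm <- hamming(substr(template, r + 1L, r + km), revcomp(minusP))
          if (orientation == "+") {
            row <- data.frame(pair = pair$name, fwd_pos = f %% n,
                              rev_pos = r %% n, length = len,
                              fwd_mismatches = pm, rev_mismatches = mm,
                              orientation = orientation,
                              stringsAsFactors = FALSE)
          } else {
            row <- data.frame(pair = pair$name, fwd_pos = r %% n,
                              rev_pos = f %% n, length = len,
                              fwd_mismatches = mm, rev_mismatches = pm,
                              orientation = orientation,
                              stringsAsFactors = FALSE)
          }
          rows <- rbind(rows, row)
        }
      }
    }
    rows
  }
  out <- rbind(one_orientation(pair$fwd, pair$rev, "+"),
               one_orientation(pair$rev, pair$fwd, "-"))
  unique(out)
}

#' Classify a phage by multiplex PCR
#'
#' Runs [in_silico_pcr()] for each configured pair (independent reactions,
#' no competition model) and calls the type from amplicon presence.
#'
#' @param genome A [phage_genome()].
#' @param pairs Named list of [primer_pair()]s
#'   (default [default_primer_pairs()], the 936 and c2 pairs).
#' @param ... Passed to [in_silico_pcr()].
#' @return List with `label` (one pair's expected type, `"mixed"` when
#'   several types amplify, `"untyped"` when none) and `amplicons` (data
#'   frame of all products).
#' @export
classify_phage_type <- function(genome, pairs = default_primer_pairs(), ...) {
  if (length(pairs) == 0L) stop("no primer pairs configured", call. = FALSE)
  amps <- do.call(rbind, c(lapply(pairs, in_silico_pcr, genome = genome, ...),
                           list(make.row.names = FALSE)))
  hit <- vapply(pairs, function(p) any(amps$pair == p$name), logical(1))
  hit_types <- unique(vapply(pairs[hit], function(p) p$expected_type, ""))
  label <- if (length(hit_types) == 0L) "untyped"
           else if (length(hit_types) > 1L) "mixed"
           else hit_types
  list(label = label, amplicons = amps)
}
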