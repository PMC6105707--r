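# Location of the cos site and mapping of its surrounding packaging
# elements: flanking inverted repeats, AATCT direct repeats and putative
# terminase binding sites.

#' Locate the cos site
#'
#' Scans the top strand for the 11-mer cohesive-end motif. For topology
#' `linear_cos` the circular view is used, so a motif split across the two
#' genome ends is still detected. The search is exact by default because
#' the cos site is sequence-identical across 936-type phages.
#'
#' @param genome A [phage_genome()].
#' @param motif cos motif (default the 936-type 11-mer `CACAAAGGACT`).
#' @param max_mismatch Allowed mismatches (default 0).
#' @return A `cos_region` list (`cos_start`, `cos_end`, `cos_seq`, plus
#'   empty slots for repeats to be filled by the mapping functions), or
#'   `NULL` when the motif is absent. With several occurrences, all are
#'   returned in `all_hits` with a warning and the first is used.
#' @export
find_cos_site <- function(genome, motif = "CACAAAGGACT", max_mismatch = 0L) {
  seq <- genome$seq
  n <- nchar(seq)
  k <- nchar(motif)
  if (max_mismatch == 0L) {
    hits <- if (genome$topology == "linear_cos")
      find_exact_circular(seq, motif) else find_exact(seq, motif)
  } else {
    ext <- if (genome$topology == "linear_cos")
      paste0(seq, substr(seq, 1L, k - 1L)) else seq
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(ext),
                                  max.mismatch = max_mismatch)
    hits <- BiocGenerics::start(m) - 1L
    hits <- sort(unique(hits[hits < n]))
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L)
    warning(sprintf("%s: %d cos motif occurrences found; using the first",
                    genome$id, length(hits)))
  structure(list(cos_start = hits[1L], cos_end = hits[1L] + k,
                 cos_seq = circ_substr(seq, hits[1L], hits[1L] + k),
                 all_hits = hits, irs = NULL, drs = NULL,
                 terminase_sites = NULL),
            class = "cos_region")
}

# Extract the circular window around cos and return its genome offset.
cos_window <- function(genome, cos, window) {
  n <- nchar(genome$seq)
  w_start <- cos$cos_start - window
  w_end <- cos$cos_end + window
  if (genome$topology != "linear_cos") {
    if (w_start < 0L || w_end > n) {
      warning("window exceeds genome; clipped")
      w_start <- max(0L, w_start); w_end <- min(n, w_end)
    }
    list(seq = substr(genome$seq, w_start + 1L, w_end), offset = w_start)
  } else {
    if (w_end - w_start > n) {
      warning("window exceeds genome; clipped")
      w_start <- cos$cos_start - (n - (cos$cos_end - cos$cos_start)) %/% 2L
      w_end <- w_start + n
    }
    list(seq = circ_substr(genome$seq, w_start, w_end), offset = w_start)
  }
}

# Map a window-local 0-based coordinate back to genome space.
unwrap_pos <- function(pos, offset, n) ((pos + offset) %% n + n) %% n

#' Find inverted repeats flanking the cos site
#'
#' Exhaustive scan for arm pairs of length `arm_len` where the left arm
#' ends before `cos_start`, the right arm starts after `cos_end` (both
#' within `window` bp of cos, circular view for `linear_cos` genomes), and
#' the reverse complement of the left arm matches the right arm with at
#' most `max_mismatch` mismatches. Overlapping redundant pairs are pruned:
#' within a cluster of pairs whose arms overlap, only the pair with fewest
#' mismatches (then smallest span) is kept. Results are sorted by total
#' arm distance to cos.
#'
#' @param genome A [phage_genome()].
#' @param cos A `cos_region` from [find_cos_site()].
#' @param arm_len Arm length in bp (default 10).
#' @param window Search window on each side of cos in bp (default 200).
#' @param max_mismatch Allowed mismatches between revcomp(left) and right
#'   (default 1).
#' @return Data frame: left_start, left_end, right_start, right_end
#'   (0-based half-open genome coordinates, possibly wrapped), arm_len,
#'   mismatches, dist_to_cos.
#' @export
find_inverted_repeats <- function(genome, cos, arm_len = 10L, window = 200L,
                                  max_mismatch = 1L) {
  n <- nchar(genome$seq)
  win <- cos_window(genome, cos, window)
  w <- win$seq
  cos_local <- cos$cos_start - win$offset
  if (genome$topology == "linear_cos") cos_local <- (cos_local %% n + n) %% n
  cos_len <- cos$cos_end - cos$cos_start
  # candidate arm start positions (window-local, 0-based)
  left_starts <- 0:(cos_local - arm_len)
  left_starts <- left_starts[left_starts >= 0L]
  right_starts <- (cos_local + cos_len):(nchar(w) - arm_len)
  right_starts <- right_starts[right_starts <= nchar(w) - arm_len]
  if (length(left_starts) == 0L || length(right_starts) == 0L)
    return(ir_frame())
  left_arms <- substring(w, left_starts + 1L, left_starts + arm_len)
  right_arms <- substring(w, right_starts + 1L, right_starts + arm_len)
  left_rc <- revcomp(left_arms)
  rows <- list()
  # pairwise mismatch counts via per-position character comparison
  rc_mat <- do.call(rbind, strsplit(left_rc, ""))
  ra_mat <- do.call(rbind, strsplit(right_arms, ""))
  for (i in seq_along(left_starts)) {
    mm <- colSums(t(ra_mat) != rc_mat[i, ])
    ok <- which(mm <= max_mismatch)
    for (j in ok) {
      rows[[length(rows) + 1L]] <- c(left_starts[i], right_starts[j], mm[j])
    }
  }
  if (length(rows) == 0L) return(ir_frame())
  m <- do.call(rbind, rows)
  ls <- m[, 1L]; rs <- m[, 2L]; mm <- m[, 3L]
  dist <- (cos_local - (ls + arm_len)) + (rs - (cos_local + cos_len))
  span <- rs + arm_len - ls
  df <- data.frame(l = ls, r = rs, mm = mm, dist = dist, span = span)
  df <- df[order(df$mm, df$span, df$dist), , drop = FALSE]
  # prune overlapping redundant pairs: keep best per overlap cluster
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ov <- FALSE
    if (any(keep)) {
      k <- df[keep, , drop = FALSE]
      ov <- any(pmax(k$l, df$l[i]) < pmin(k$l + arm_len, df$l[i] + arm_len) &
                pmax(k$r, df$r[i]) < pmin(k$r + arm_len, df$r[i] + arm_len))
    }
    if (!ov) keep[i] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$dist), , drop = FALSE]
  out <- ir_frame(
    left_start = unwrap_pos(df$l, win$offset, n),
    right_start = unwrap_pos(df$r, win$offset, n),
    arm_len = arm_len, mismatches = df$mm, dist_to_cos = df$dist)
  out
}

ir_frame <- function(left_start = integer(), right_start = integer(),
                     arm_len = integer(), mismatches = integer(),
                     dist_to_cos = integer()) {
  k <- if (length(left_start)) arm_len else integer()
  data.frame(left_start = as.integer(left_start),
             left_end = as.integer(left_start + k),
             right_start = as.integer(right_start),
             right_end = as.integer(right_start + k),
             arm_len = as.integer(rep(arm_len, length(left_start))),
             mismatches = as.integer(mismatches),
             dist_to_cos = as.integer(dist_to_cos),
             stringsAsFactors = FALSE)
}

#' Find direct repeats near the cos site
#'
#' Exact occurrences of `motif` within `window` bp of the cos site
#' (circular view for `linear_cos`), labelled D1..Dn in positional order
#' along the window.
#'
#' @inheritParams find_inverted_repeats
#' @param motif Direct-repeat motif (default `AATCT`).
#' @return Data frame: label, start, end (0-based half-open genome
#'   coordinates).
#' @export
find_direct_repeats <- function(genome, cos, motif = "AATCT",
                                window = 200L) {
  n <- nchar(genome$seq)
  win <- cos_window(genome, cos, window)
  hits <- find_exact(win$seq, motif)
  if (length(hits) == 0L)
    return(data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(label = paste0("D", seq_along(hits)),
             start = unwrap_pos(hits, win$offset, n),
             end = unwrap_pos(hits, win$offset, n) + nchar(motif),
             stringsAsFactors = FALSE)
}

#' Map putative terminase binding sites around cos
#'
#' For each supplied motif the best (fewest-mismatch) sliding-window match
#' in the cos window is reported with its matched fraction; a site is
#' `complete` when the matched fraction reaches `min_complete_fraction`.
#' Direct repeats whose coordinates fall inside a partial site match are
#' annotated as truncated versions of that site (the relationship between
#' the last direct repeat and a truncated R2 in 936-type genomes).
#'
#' @inheritParams find_inverted_repeats
#' @param site_motifs Named character vector or list, label -> DNA motif
#'   (labels conventionally R1, R2, R3). The motifs are not hard-coded:
#'   they must come from configuration (for synthetic genomes, the
#'   generator's own planted motifs, [default_terminase_motifs()]).
#' @param drs Optional direct-repeat table from [find_direct_repeats()]
#'   used for the truncation annotation.
#' @param min_complete_fraction Matched fraction required to call a site
#'   complete (default 1.0).
#' @return Data frame: label, start, end, matched_fraction, complete,
#'   truncated_dr (label of a DR inside a partial match, else NA).
#' @export
map_terminase_sites <- function(genome, cos, site_motifs,
                                drs = NULL, window = 200L,
                                min_complete_fraction = 1.0) {
  if (length(site_motifs) == 0L)
    stop("configuration error: no terminase site motifs supplied",
         call. = FALSE)
  n <- nchar(genome$seq)
  win <- cos_window(genome, cos, window)
  w <- win$seq
  wc <- strsplit(w, "")[[1]]
  rows <- lapply(names(site_motifs), function(lab) {
    motif <- toupper(site_motifs[[lab]])
    k <- nchar(motif)
    mc <- strsplit(motif, "")[[1]]
    starts <- 0:(nchar(w) - k)
    mm <- vapply(starts, function(s) sum(wc[(s + 1L):(s + k)] != mc), 0L)
    best <- which.min(mm)
    frac <- (k - mm[best]) / k
    data.frame(label = lab, start = unwrap_pos(starts[best], win$offset, n),
               end = unwrap_pos(starts[best], win$offset, n) + k,
               matched_fraction = frac,
               complete = frac >= min_complete_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$truncated_dr <- NA_character_
  if (!is.null(drs) && nrow(drs) > 0L) {
    for (i in seq_len(nrow(out))) {
      if (out$complete[i]) next
      inside <- drs$start >= out$start[i] & drs$end <= out$end[i]
      if (any(inside)) out$truncated_dr[i] <- drs$label[which(inside)[1L]]
    }
  }
  out
}
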