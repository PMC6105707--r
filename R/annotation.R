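# Genome statistics, ORF calling, transcription-region partitioning and
# transmembrane-domain counting for holin classification.

#' GC content of a DNA string
#'
#' @param seq Non-empty DNA string (or [phage_genome()]).
#' @return Percent GC, `100 * (G + C) / length`. Use `round(x, 1)` for the
#'   1-decimal convention of genome summary tables.
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "phage_genome")) seq <- seq$seq
  assert_acgt(seq)
  b <- strsplit(seq, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' AT content of a DNA string (complement of [gc_content()])
#' @inheritParams gc_content
#' @return Percent AT.
#' @export
at_content <- function(seq) 100 - gc_content(seq)

#' Call open reading frames
#'
#' Minimal deterministic six-frame caller: each reading frame is split at
#' stop codons; every stop-bounded segment whose ORF (from the most
#' upstream in-segment start codon through the terminating stop, inclusive)
#' reaches `min_orf_len` is reported. No ribosome-binding-site model is
#' applied, so starts are always extended maximally upstream.
#'
#' @param genome A [phage_genome()] or DNA string.
#' @param min_orf_len Minimum ORF length in nt, stop codon included
#'   (default 90).
#' @param start_codons Allowed start codons (default ATG, GTG, TTG).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data frame of ORF calls with 0-based half-open top-strand
#'   coordinates (`start`, `end`), `strand`, `frame` (0-2 on the coding
#'   strand), `length_nt` (stop included) and `protein` (stop excluded),
#'   ordered by `(start, strand)`.
#' @export
call_orfs <- function(genome, min_orf_len = 90L,
                      start_codons = c("ATG", "GTG", "TTG"),
                      both_strands = TRUE) {
  seq <- if (inherits(genome, "phage_genome")) genome$seq else toupper(genome)
  assert_acgt(seq)
  n <- nchar(seq)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      cod <- codons_of(s, from = frame)
      if (length(cod) == 0L) next
      stops <- which(cod %in% STOP_CODONS)
      seg_begin <- 1L  # codon index where the current segment starts
      for (st in stops) {
        if (st > seg_begin) {
          starts_in <- which(cod[seg_begin:(st - 1L)] %in% start_codons)
          if (length(starts_in) > 0L) {
            c0 <- seg_begin + starts_in[1L] - 1L  # most upstream start
            len_nt <- (st - c0 + 1L) * 3L
            if (len_nt >= min_orf_len) {
              a <- frame + (c0 - 1L) * 3L           # 0-based on strand s
              b <- frame + st * 3L
              if (strand == "+") {
                start <- a; end <- b
              } else {
                start <- n - b; end <- n - a
              }
              prot <- paste(translate_codons(cod[c0:(st - 1L)]), collapse = "")
              rows[[length(rows) + 1L]] <- data.frame(
                start = start, end = end, strand = strand, frame = frame,
                length_nt = len_nt, protein = prot,
                stringsAsFactors = FALSE)
            }
          }
        }
        seg_begin <- st + 1L
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_nt = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition the coding-strand ORF chain into transcription regions
#'
#' cos-ended 936-type genomes carry all genes on one strand in three
#' same-orientation transcription regions; reading along the genome from
#' the cos cut (position 0) the order is late, early, middle, with cos
#' sitting between the middle- and late-expressed genes across the join.
#' The coding-strand ORF chain is split at its two largest intergenic gaps
#' (ties broken by the earliest gap position) and blocks are labelled
#' late/early/middle in genome order.
#'
#' @param genome A [phage_genome()] with topology `linear_cos`.
#' @param orfs ORF data frame (as from [call_orfs()] or a planted truth
#'   set) with columns start, end, strand.
#' @return List with `blocks` (data frame: label, from, to, n_orfs,
#'   start, end), `orf_labels` (region label per coding-strand ORF), and
#'   `coding_strand`.
#' @export
partition_regions <- function(genome, orfs) {
  if (inherits(genome, "phage_genome") && genome$topology != "linear_cos")
    stop("partition_regions requires a linear_cos genome", call. = FALSE)
  strands <- table(orfs$strand)
  coding <- names(strands)[which.max(strands)]
  o <- orfs[orfs$strand == coding, , drop = FALSE]
  o <- o[order(o$start), , drop = FALSE]
  if (nrow(o) < 3L)
    stop("partition error: need at least 3 ORFs on the coding strand",
         call. = FALSE)
  gaps <- o$start[-1L] - o$end[-nrow(o)]  # gap i sits after ORF i
  ord <- order(-gaps, seq_along(gaps))    # largest first, earliest on ties
  cut_after <- sort(ord[1:2])
  bounds <- c(0L, cut_after, nrow(o))
  labels <- c("late", "early", "middle")
  blocks <- do.call(rbind, lapply(1:3, function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    data.frame(label = labels[i], from = idx[1L], to = idx[length(idx)],
               n_orfs = length(idx), start = o$start[idx[1L]],
               end = o$end[idx[length(idx)]], stringsAsFactors = FALSE)
  }))
  orf_labels <- rep(labels, times = blocks$n_orfs)
  list(blocks = blocks, orf_labels = orf_labels, coding_strand = coding,
       orfs = o)
}

# Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count predicted transmembrane domains in a protein
#'
#' Sliding-window mean Kyte-Doolittle hydropathy; maximal runs of window
#' positions at or above the threshold are merged and the number of merged
#' runs is returned. Windows whose start positions are contiguous or
#' overlapping belong to the same run.
#'
#' @param protein Amino-acid string (one-letter codes).
#' @param window Window length in residues (default 19).
#' @param threshold Mean hydropathy threshold (default 1.6).
#' @return Integer count of predicted transmembrane segments.
#' @export
count_tmds <- function(protein, window = 19L, threshold = 1.6) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) < window)
    stop("protein shorter than the hydropathy window", call. = FALSE)
  h <- KD_HYDROPATHY[aa]
  if (anyNA(h)) stop("unknown amino-acid code in protein", call. = FALSE)
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):length(cs)] - cs[1:(length(cs) - window)]) / window
  hot <- means >= threshold
  if (!any(hot)) return(0L)
  # runs of consecutive hot window-start positions; overlapping windows
  # (starts closer than `window`) merge into one segment
  pos <- which(hot)
  breaks <- which(diff(pos) > window)
  length(breaks) + 1L
}

#' Classify a holin by transmembrane-domain count
#'
#' @inheritParams count_tmds
#' @return `"class I"` for 3 TMDs, `"class II"` for 2, `"class III"` for 1,
#'   otherwise `"unclassified"`.
#' @export
classify_holin <- function(protein, window = 19L, threshold = 1.6) {
  n <- count_tmds(protein, window, threshold)
  switch(as.character(n), `3` = "class I", `2` = "class II",
         `1` = "class III", "unclassified")
}

#' One-row genome summary (length, GC, ORF count)
#'
#' @param genome A [phage_genome()].
#' @param ... Passed to [call_orfs()].
#' @return Data frame with id, length_bp, gc_percent, n_orfs.
#' @export
genome_summary <- function(genome, ...) {
  orfs <- call_orfs(genome, ...)
  data.frame(id = genome$id, length_bp = nchar(genome$seq),
             gc_percent = round(gc_content(genome$seq), 1),
             n_orfs = nrow(orfs), stringsAsFactors = FALSE)
}
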