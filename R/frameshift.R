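# Detection of the CCC.TAG "shifty stop" at the 3' end of the major tail
# protein gene and simulation of the +1 translational frameshift that
# fuses MTP with the downstream tail protein extension (TpeX).

#' Find shifty-stop frameshift candidates
#'
#' A candidate is a coding-strand ORF whose last sense codon is `CCC` and
#' whose terminator is `TAG` (the CCC.UAG shifty-stop signal), provided a
#' stop codon exists in the +1 frame within `scan_limit` nt downstream --
#' otherwise the simulated read-through would run off the template.
#'
#' @param genome A [phage_genome()].
#' @param orfs ORF table from [call_orfs()] (or a planted truth set with
#'   the same columns).
#' @param scan_limit How far past the shifty stop to look for the +1-frame
#'   terminator, in nt (default 3000).
#' @param region Optional region partition from [partition_regions()];
#'   when supplied, only late-region ORFs are scanned (the MTP gene sits
#'   in the late transcription region).
#' @return Data frame of candidates: orf_start, orf_end, strand,
#'   shifty_codon_pos (0-based start of the CCC), stop_pos (start of the
#'   TAG), downstream_stop_pos (start of the +1-frame terminator).
#' @export
find_shifty_stops <- function(genome, orfs, scan_limit = 3000L,
                              region = NULL) {
  seq <- genome$seq
  n <- nchar(seq)
  o <- orfs[orfs$strand == "+", , drop = FALSE]
  if (!is.null(region)) {
    keep <- region$orf_labels == "late"
    ro <- region$orfs[keep, , drop = FALSE]
    o <- o[paste(o$start, o$end) %in% paste(ro$start, ro$end), , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(o))) {
    a <- o$start[i]; b <- o$end[i]
    stop_codon <- substr(seq, b - 2L, b)           # terminator
    last_sense <- substr(seq, b - 5L, b - 3L)      # codon before it
    if (stop_codon != "TAG" || last_sense != "CCC") next
    # +1 frame: first post-shift codon starts one nt into the TAG
    shift_from <- b - 2L  # 0-based: TAG occupies [b-3, b); A is at b-2
    ds <- downstream_plus1_stop(seq, shift_from, scan_limit)
    if (is.na(ds)) next
    rows[[length(rows) + 1L]] <- data.frame(
      orf_start = a, orf_end = b, strand = "+",
      shifty_codon_pos = b - 6L, stop_pos = b - 3L,
      downstream_stop_pos = ds, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(orf_start = integer(), orf_end = integer(),
                      strand = character(), shifty_codon_pos = integer(),
                      stop_pos = integer(), downstream_stop_pos = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$orf_start), , drop = FALSE]
}

# 0-based start of the first stop codon in the frame anchored at
# `from` (0-based), scanning at most `scan_limit` nt; NA if none.
downstream_plus1_stop <- function(seq, from, scan_limit) {
  n <- nchar(seq)
  last <- min(n, from + scan_limit)
  starts <- seq.int(from + 1L, last - 2L, by = 3L)
  if (length(starts) == 0L) return(NA_integer_)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]] - 1L
}

#' Simulate the +1 translational frameshift at a shifty stop
#'
#' Models the ribosome incorporating proline at the CCC codon and resuming
#' translation one nucleotide downstream of the CCC/TAG junction (the
#' first post-shift codon begins at the A of the TAG), continuing to the
#' next in-frame stop (exclusive). The post-shift register is isolated
#' here so the alternative convention (+1 from the T) is a one-line
#' change.
#'
#' @param genome A [phage_genome()].
#' @param candidate One row of the [find_shifty_stops()] table.
#' @return A `frameshift_fusion` list: `candidate`, `fused_protein`,
#'   `fused_len` (residues), `upstream_len`, `extension_len`.
#' @export
simulate_frameshift <- function(genome, candidate) {
  seq <- genome$seq
  a <- candidate$orf_start; b <- candidate$orf_end
  if (substr(seq, b - 2L, b) != "TAG" || substr(seq, b - 5L, b - 3L) != "CCC")
    stop("not a shifty-stop candidate: ORF must end CCC TAG", call. = FALSE)
  upstream <- translate_dna(substr(seq, a + 1L, b - 3L))  # through the Pro
  shift_from <- b - 2L
  ds <- candidate$downstream_stop_pos
  if (is.na(ds) || ds <= shift_from)
    stop("no in-frame stop downstream of the shift within the scan limit",
         call. = FALSE)
  extension <- translate_dna(substr(seq, shift_from + 1L, ds))
  fused <- paste0(upstream, extension)
  if (grepl("*", fused, fixed = TRUE))
    stop("internal stop in fused product; candidate is inconsistent",
         call. = FALSE)
  structure(list(candidate = candidate, fused_protein = fused,
                 fused_len = nchar(fused), upstream_len = nchar(upstream),
                 extension_len = nchar(extension)),
            class = "frameshift_fusion")
}

#' @export
print.frameshift_fusion <- function(x, ...) {
  cat(sprintf(
    "<frameshift_fusion> ORF [%d,%d) + shift: %d aa = %d (MTP) + %d (TpeX extension)\n",
    x$candidate$orf_start, x$candidate$orf_end, x$fused_len,
    x$upstream_len, x$extension_len))
  invisible(x)
}
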