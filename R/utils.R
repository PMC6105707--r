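# Internal string/sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over ACGT.
#' @return Character vector of the same length, reverse-complemented.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA string; error names the offending record.
assert_acgt <- function(seq, id = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(sprintf("%s: sequence must be a non-empty string", id), call. = FALSE)
  bad <- gsub("[ACGT]", "", seq)
  if (nchar(bad) > 0L)
    stop(sprintf(
      "%s: alphabet error, sequence contains non-ACGT characters (e.g. '%s'); ambiguity codes are rejected",
      id, substr(bad, 1L, 1L)), call. = FALSE)
  invisible(TRUE)
}

# Circular substring extraction: 0-based half-open [start, end) with wrap.
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  width <- end - start
  if (width < 0L) stop("circ_substr: end before start")
  if (width > n) stop("circ_substr: window longer than sequence")
  start <- ((start %% n) + n) %% n
  start1 <- start + 1L
  if (start + width <= n) return(substr(seq, start1, start + width))
  paste0(substr(seq, start1, n), substr(seq, 1L, start + width - n))
}

# Extract codons from a DNA string starting at 0-based offset.
codons_of <- function(seq, from = 0L) {
  n <- nchar(seq)
  starts <- seq.int(from + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L || starts[1] > n - 2L) return(character(0))
  substring(seq, starts, starts + 2L)
}

# Translate a vector of codons with the standard code ('*' = stop).
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

# Translate a DNA string (length divisible by 3) to protein, stop as '*'.
translate_dna <- function(seq) {
  paste(translate_codons(codons_of(seq)), collapse = "")
}

# All 0-based start positions of exact occurrences of `motif` in `seq`
# (linear scan; overlapping hits included).
find_exact <- function(seq, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  BiocGenerics::start(hits) - 1L
}

# 0-based starts of `motif` occurrences in the circular view of `seq`:
# positions in [0, nchar(seq)), matches may wrap across the join.
find_exact_circular <- function(seq, motif) {
  n <- nchar(seq)
  k <- nchar(motif)
  if (k > n) return(integer(0))
  ext <- paste0(seq, substr(seq, 1L, k - 1L))
  pos <- find_exact(ext, motif)
  sort(unique(pos[pos < n]))
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
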