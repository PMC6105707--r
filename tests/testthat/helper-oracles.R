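# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate (base-R string
# scanning instead of Biostrings, direct enumeration instead of the
# package's algorithms).

# All 0-based occurrence starts of `motif` in `seq` (overlapping), via
# base-R scanning.
oracle_find <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (k > n) return(integer(0))
  starts <- 1:(n - k + 1L)
  which(substring(seq, starts, starts + k - 1L) == motif) - 1L
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Naive scan-and-split digestion.
oracle_digest <- function(seq, site, cut_offset, mode = "dissociated") {
  n <- nchar(seq)
  cuts <- oracle_find(seq, site) + cut_offset
  cuts <- sort(cuts[cuts > 0 & cuts < n])
  if (mode == "dissociated") return(diff(c(0L, cuts, n)))
  if (length(cuts) == 0L) return(n)
  c((n - cuts[length(cuts)]) + cuts[1L], diff(cuts))
}

# Exhaustive six-frame ORF scan: for every stop codon, the leftmost
# in-segment start codon reaching it.
oracle_orfs <- function(seq, min_len = 90L,
                        starts = c("ATG", "GTG", "TTG")) {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      idx <- seq.int(frame + 1L, n - 2L, by = 3L)
      if (length(idx) == 0L) next
      cods <- substring(s, idx, idx + 2L)
      prev_stop <- 0L
      for (ci in seq_along(cods)) {
        if (cods[ci] %in% c("TAA", "TAG", "TGA")) {
          seg <- if (ci > prev_stop + 1L) (prev_stop + 1L):(ci - 1L) else
            integer(0)
          hit <- seg[cods[seg] %in% starts]
          if (length(hit) > 0L) {
            c0 <- hit[1L]
            len <- (ci - c0 + 1L) * 3L
            if (len >= min_len) {
              a <- frame + (c0 - 1L) * 3L
              b <- frame + ci * 3L
              if (strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
              out[[length(out) + 1L]] <- c(a, b,
                                           if (strand == "+") 1L else -1L)
            }
          }
          prev_stop <- ci
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L],
             strand = ifelse(m[, 3L] > 0, "+", "-"))
}

# Transitive closure grouping oracle over a distance matrix.
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

random_seq <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
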