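# Alignment-free comparative genomics: canonical k-mer (Mash-style)
# distances, neighbour-joining trees, and exact-match dot-plot segments.

# Canonical k-mer set of a sequence: for every k-mer the lexicographic
# minimum of the k-mer and its reverse complement, made unique.
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("genome shorter than k", call. = FALSE)
  starts <- 1:(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rc <- revcomp(seq)
  rck <- rev(substring(rc, starts, starts + k - 1L))  # aligned to fwd
  unique(ifelse(fwd <= rck, fwd, rck))
}

#' Mash-style k-mer distance between two genomes
#'
#' Jaccard similarity `J` of canonical k-mer sets, converted to an
#' evolutionary distance with the Mash formulation
#' `d = -(1/k) * ln(2J / (1 + J))`; 0 for identical k-mer sets, capped at
#' 1.0 (and defined as the cap when `J = 0`).
#'
#' @param g1,g2 [phage_genome()]s or DNA strings.
#' @param k Word size (default 15).
#' @return Distance in `[0, 1]`.
#' @export
kmer_distance <- function(g1, g2, k = 15L) {
  s1 <- if (inherits(g1, "phage_genome")) g1$seq else toupper(g1)
  s2 <- if (inherits(g2, "phage_genome")) g2$seq else toupper(g2)
  k1 <- canonical_kmers(s1, k)
  k2 <- canonical_kmers(s2, k)
  inter <- length(intersect(k1, k2))
  uni <- length(k1) + length(k2) - inter
  j <- inter / uni
  if (j == 0) return(1.0)
  if (j == 1) return(0.0)
  min(1.0, -(1 / k) * log(2 * j / (1 + j)))
}

#' Pairwise k-mer distance matrix
#'
#' @param genomes Named list of [phage_genome()]s.
#' @param k Word size (default 15).
#' @return Symmetric matrix with zero diagonal, dimnames = genome ids.
#' @export
kmer_distance_matrix <- function(genomes, k = 15L) {
  ids <- vapply(genomes, function(g) g$id, "")
  sets <- lapply(genomes, function(g) canonical_kmers(g$seq, k))
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(sets[[i]]) + length(sets[[j]]) - inter
    jac <- inter / uni
    dij <- if (jac == 0) 1.0 else if (jac == 1) 0.0 else
      min(1.0, -(1 / k) * log(2 * jac / (1 + jac)))
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical neighbour joining with deterministic tie-breaking (the
#' lowest-index pair wins when Q values tie). Negative branch lengths are
#' clamped to zero with a warning. Output is a Newick string with branch
#' lengths; the tree is unrooted (trifurcating root node).
#'
#' @param dm Symmetric numeric matrix with zero diagonal and dimnames
#'   giving taxon ids (>= 3 taxa).
#' @return Newick string, terminated by `;`.
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  ids <- rownames(dm) %||% paste0("t", seq_len(n))
  labels <- ids            # current node labels (Newick subtrees)
  d <- unname(dm)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among minima: scan column-major over i < j
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (ii in 1:(m - 1L)) for (jj in (ii + 1L):m) {
      if (q[ii, jj] < qmin - 1e-12) { qmin <- q[ii, jj]; best <- c(ii, jj) }
    }
    i <- best[1L]; j <- best[2L]
    vi <- clamp(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_label <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], vi, labels[j], vj)
    dnew <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    labels <- c(labels[keep], new_label)
    d <- d2
  }
  # three nodes left: closed-form branch lengths
  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  if (clamped) warning("negative branch length(s) clamped to 0")
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          labels[1], va, labels[2], vb, labels[3], vc)
}

#' Exact-match dot-plot segments between two genomes
#'
#' Maximal exact-match segments of length >= `w` between `g1` (x axis) and
#' `g2` (y axis), in forward and reverse-complement orientation, found by
#' shared-word anchoring: every shared `w`-word is an anchor, anchors on a
#' common (anti)diagonal with consecutive offsets coalesce into one
#' maximal segment.
#'
#' @param g1,g2 [phage_genome()]s or DNA strings.
#' @param w Word size / minimum segment length (default 20).
#' @return Data frame: x_start, y_start (0-based), length, orientation
#'   (`"forward"` or `"reverse"`), sorted by x_start. For reverse
#'   segments, y_start is the segment's lowest g2 coordinate; the matched
#'   g2 substring is the reverse complement of the g1 substring.
#' @export
dotplot_segments <- function(g1, g2, w = 20L) {
  s1 <- if (inherits(g1, "phage_genome")) g1$seq else toupper(g1)
  s2 <- if (inherits(g2, "phage_genome")) g2$seq else toupper(g2)
  if (nchar(s1) < w || nchar(s2) < w) stop("genome shorter than w",
                                           call. = FALSE)
  fwd <- anchor_segments(s1, s2, w)
  if (nrow(fwd) > 0L) fwd$orientation <- "forward"
  rcs2 <- revcomp(s2)
  rev <- anchor_segments(s1, rcs2, w)
  if (nrow(rev) > 0L) {
    # map y back from revcomp(g2) coordinates to g2 coordinates
    n2 <- nchar(s2)
    rev$y_start <- n2 - (rev$y_start + rev$length)
    rev$orientation <- "reverse"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0L)
    return(data.frame(x_start = integer(), y_start = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$x_start, out$y_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared-word anchoring on the forward orientation of two strings.
# Returns maximal runs of diagonal-consecutive anchors as segments with
# 0-based x_start/y_start and length (>= w).
anchor_segments <- function(s1, s2, w) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  w1 <- substring(s1, 1:(n1 - w + 1L), w:(n1))
  w2 <- substring(s2, 1:(n2 - w + 1L), w:(n2))
  idx2 <- split(seq_along(w2), w2)
  shared <- which(w1 %in% names(idx2))
  if (length(shared) == 0L)
    return(data.frame(x_start = integer(), y_start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  js_list <- idx2[w1[shared]]
  ys <- unlist(js_list, use.names = FALSE)
  xs <- rep.int(shared, lengths(js_list))
  diagv <- xs - ys
  ord <- order(diagv, xs)
  xs <- xs[ord]; ys <- ys[ord]; diagv <- diagv[ord]
  newrun <- c(TRUE, diff(diagv) != 0L | diff(xs) != 1L)
  runid <- cumsum(newrun)
  firsts <- which(newrun)
  lens <- tabulate(runid)
  data.frame(x_start = xs[firsts] - 1L, y_start = ys[firsts] - 1L,
             length = lens + w - 1L, stringsAsFactors = FALSE)
}
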