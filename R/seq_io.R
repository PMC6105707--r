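# Sequence containers, FASTA and feature-table I/O, enzyme/primer
# registries and run configuration.
#
# Coordinate convention: all coordinates held in memory are 0-based
# half-open [start, end); all tables written to disk are 1-based inclusive
# (GenBank style). For topology "linear_cos", position 0 is the first base
# 3' of the cos cut on the top strand, i.e. the genome string begins at the
# cos site.

FEATURE_KINDS <- c("orf", "cos", "inverted_repeat", "direct_repeat",
                   "terminase_site", "primer_site", "restriction_site",
                   "region")

#' Construct a phage genome object
#'
#' A `phage_genome` is the basic sequence container used throughout the
#' package: a linear dsDNA sequence (stored as its top strand) with
#' optional feature annotations. Genomes of cos-ended phages use topology
#' `"linear_cos"`, whose circular view (ends joined at the cos cut) is
#' respected by the scanning functions.
#'
#' @param id Genome identifier.
#' @param seq DNA string over A/C/G/T (upper-cased on input; ambiguity
#'   codes are rejected).
#' @param topology `"linear_cos"` (default) or `"circular"`.
#' @param features Feature data frame as returned by [feature_table()].
#' @param provenance Free-text provenance note.
#' @return An object of class `phage_genome`.
#' @export
phage_genome <- function(id, seq, topology = c("linear_cos", "circular"),
                         features = feature_table(), provenance = "") {
  topology <- match.arg(topology)
  seq <- toupper(seq)
  assert_acgt(seq, id = id)
  stopifnot(is.data.frame(features))
  g <- structure(
    list(id = as.character(id), seq = seq, topology = topology,
         features = features, provenance = provenance),
    class = "phage_genome")
  validate_features(g)
  g
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %d bp, topology=%s, GC=%.1f%%, %d features\n",
              x$id, nchar(x$seq), x$topology, gc_content(x$seq),
              nrow(x$features)))
  invisible(x)
}

#' @export
length.phage_genome <- function(x) nchar(x$seq)

#' Create (or validate) a feature table
#'
#' Features are stored as a data frame with 0-based half-open coordinates.
#' `label` carries the element name (e.g. `D1`, `R2`, `mtp`, `late`) and
#' `attrs` an optional `key=value;...` string of qualifiers.
#'
#' @param kind Feature kind, one of `r paste(FEATURE_KINDS, collapse=", ")`.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"`, or `"*"` where strand is not meaningful.
#' @param label Element label.
#' @param attrs Optional qualifier string `key=value;key2=value2`.
#' @return A data frame of class `feature_table`.
#' @export
feature_table <- function(kind = character(), start = integer(),
                          end = integer(), strand = character(),
                          label = character(), attrs = character()) {
  n <- length(kind)
  if (length(strand) == 0L && n > 0L) strand <- rep("*", n)
  if (length(label) == 0L && n > 0L) label <- rep("", n)
  if (length(attrs) == 0L && n > 0L) attrs <- rep("", n)
  df <- data.frame(kind = as.character(kind), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   label = as.character(label), attrs = as.character(attrs),
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

rbind_features <- function(...) {
  dfs <- Filter(function(d) nrow(d) > 0L, list(...))
  if (length(dfs) == 0L) return(feature_table())
  out <- do.call(rbind, lapply(dfs, function(d) as.data.frame(d)))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

validate_features <- function(genome) {
  f <- genome$features
  if (nrow(f) == 0L) return(invisible(TRUE))
  bad <- !(f$kind %in% FEATURE_KINDS)
  if (any(bad))
    stop("unknown feature kind(s): ", paste(unique(f$kind[bad]), collapse = ", "),
         call. = FALSE)
  n <- nchar(genome$seq)
  if (any(f$start < 0L | f$start >= f$end | f$end > n))
    stop(genome$id, ": feature coordinates out of range", call. = FALSE)
  orfish <- f$kind %in% c("orf", "primer_site")
  if (any(orfish & !(f$strand %in% c("+", "-"))))
    stop(genome$id, ": orf/primer_site features require strand + or -",
         call. = FALSE)
  reg <- f$kind == "region"
  if (any(reg & !(f$label %in% c("late", "early", "middle"))))
    stop(genome$id, ": region labels must be late/early/middle", call. = FALSE)
  invisible(TRUE)
}

#' Read phage genomes from a FASTA file
#'
#' @param path FASTA file. Sequences are upper-cased; any character outside
#'   A/C/G/T (including IUPAC ambiguity codes) raises an error naming the
#'   record.
#' @param topology Topology assigned to every record (default
#'   `"linear_cos"`).
#' @return List of [phage_genome()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, topology = "linear_cos") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    phage_genome(ids[i], as.character(set[[i]]), topology = topology,
                 provenance = paste0("read from ", basename(path)))
  })
}

#' Write phage genomes to a FASTA file
#'
#' @param genomes A `phage_genome` or list of them.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "phage_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$seq, ""))
  names(set) <- vapply(genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a genome's feature table (1-based inclusive coordinates)
#'
#' Emits a tab-delimited table with GenBank-style 1-based inclusive
#' coordinates; [read_feature_table()] is its exact inverse.
#'
#' @param genome A [phage_genome()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(genome, path) {
  f <- as.data.frame(genome$features)
  out <- data.frame(seq_id = rep(genome$id, nrow(f)),
                    kind = f$kind,
                    start = f$start + 1L,   # 1-based inclusive
                    end = f$end,            # half-open end == inclusive end
                    strand = f$strand, label = f$label, attrs = f$attrs,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write feature table to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Tab-delimited feature table with 1-based inclusive
#'   coordinates.
#' @return A [feature_table()] (0-based half-open coordinates).
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (nrow(raw) == 0L) return(feature_table())
  feature_table(kind = raw$kind,
                start = as.integer(raw$start) - 1L,
                end = as.integer(raw$end),
                strand = raw$strand, label = raw$label, attrs = raw$attrs)
}

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param site Exact recognition site over A/C/G/T (no ambiguity codes).
#' @param cut_offset Cut position within the site on the top strand,
#'   in `[0, nchar(site)]`.
#' @return An `enzyme_def` list.
#' @export
enzyme_def <- function(name, site, cut_offset) {
  site <- toupper(site)
  assert_acgt(site, id = name)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme_def")
}

#' Default enzyme registry
#'
#' The three 6-cutters used for RFLP typing of lactococcal phage DNA:
#' EcoRI (G^AATTC), EcoRV (GAT^ATC), HindIII (A^AGCTT).
#'
#' @return Named list of [enzyme_def()] objects.
#' @export
default_enzymes <- function() {
  list(EcoRI   = enzyme_def("EcoRI", "GAATTC", 1L),
       EcoRV   = enzyme_def("EcoRV", "GATATC", 3L),
       HindIII = enzyme_def("HindIII", "AAGCTT", 1L))
}

#' PCR primer pair definition
#'
#' @param name Pair name.
#' @param fwd,rev Primer sequences, 5'->3', each at least 15 nt.
#' @param expected_type Phage-type label the pair diagnoses.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(name, fwd, rev, expected_type = name) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  assert_acgt(fwd, id = paste0(name, " fwd"))
  assert_acgt(rev, id = paste0(name, " rev"))
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  structure(list(name = name, fwd = fwd, rev = rev,
                 expected_type = expected_type),
            class = "primer_pair")
}

#' Default multiplex-typing primer pairs
#'
#' The 936-type-specific pair (179-bp product on 936-type genomes) and the
#' c2-type-specific pair used for multiplex PCR classification of
#' lactococcal phages.
#'
#' @return Named list of [primer_pair()] objects.
#' @export
default_primer_pairs <- function() {
  list(`936` = primer_pair("936", "TCAATGGAAGACCAAGCGGA",
                           "GTAGGAGACCAACCCAAGCC", "936"),
       c2 = primer_pair("c2", "CAGGTGTAAAAGTTCGAGAACT",
                        "CAGATAATGCACCTGAATCA", "c2"))
}

config_defaults <- function() {
  list(enzyme = "EcoRV", end_mode = "dissociated", min_size = 200,
       rel_tol = 0.05, group_threshold = 0.1, cos_motif = "CACAAAGGACT",
       min_orf_len = 90, kmer = 15, max_mismatch_pcr = 2, clamp_len = 5,
       max_product = 5000, seed = 1)
}

#' Load a run configuration
#'
#' Reads a flat `key = value` file; keys not present fall back to
#' documented defaults, and the effective configuration is reported via
#' `message()`. Unknown keys raise an error suggesting the nearest valid
#' key.
#'
#' @param path Config file, or `NULL` for pure defaults. Lines starting
#'   with `#` and blank lines are ignored.
#' @param quiet Suppress the effective-config message.
#' @return Named list of effective settings.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nchar(lines) > 0L & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: '", ln, "'", call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) {
        dist <- utils::adist(key, names(cfg))
        hint <- names(cfg)[which.min(dist)]
        stop(sprintf(
          "unknown config key '%s' (did you mean '%s'?); valid keys: %s",
          key, hint, paste(names(cfg), collapse = ", ")), call. = FALSE)
      }
      cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    }
  }
  if (!quiet)
    message("effective config: ",
            paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  cfg
}
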