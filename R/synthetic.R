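# Synthetic 936-like genome generator. Produces cos-anchored linear dsDNA
# genomes with the canonical feature layout -- cos 11-mer at position 0,
# flanking 10-bp inverted repeats (the left arm wraps to the genome end),
# AATCT direct repeats and terminase-site motifs next to cos, three
# same-strand transcription regions (late, early, middle in genome order
# from the cos cut), an mtp ORF ending in a CCC.TAG shifty stop with a
# +1-frame TpeX ORF downstream, planted primer binding sites and optional
# planted restriction sites -- together with a truth set recording every
# planted feature, so each downstream analysis can be validated against
# known coordinates.

#' Default synthetic terminase-site motifs
#'
#' Terminase binding sites near cos are genome-specific; real R1-R3
#' sequences must be supplied through configuration. These synthetic
#' motifs are the ones planted by [generate_genome()]: R1 and R3 are
#' planted complete, R2 only as its 11-nt AATCT-prefixed truncation (so
#' the last direct repeat doubles as a truncated R2, as in real 936-type
#' cos regions).
#'
#' @return Named character vector (R1, R2, R3).
#' @export
default_terminase_motifs <- function() {
  c(R1 = "GGTACGATTGACCGTA",
    R2 = "AATCTGGTGACGACCA",
    R3 = "CCGTTAGACGGATTGA")
}

R2_PLANTED_PREFIX <- 11L  # nt of R2 planted (starts with AATCT = D6)

#' Specification for one synthetic genome
#'
#' Defaults emulate sequenced 936-type dairy phage genomes: 29.3-30.2 kb
#' linear cos-ended dsDNA, GC about 34.7%, one CACAAAGGACT cos 11-mer,
#' 10-bp flanking inverted repeats, 6 AATCT direct repeats, a
#' late/early/middle region plan totalling 55 ORFs (all on the plus
#' strand), a 179-aa MTP ORF terminating in a CCC.TAG shifty stop whose
#' simulated +1 read-through yields a 520-aa fusion, and the 936-typing
#' primer pair planted at 179-bp amplicon spacing.
#'
#' @param length Genome length in bp; `NULL` draws uniformly from
#'   29300-30200.
#' @param gc Target GC fraction (default 0.347; accepted range 0.25-0.6).
#' @param cos_motif cos 11-mer.
#' @param ir_len Inverted-repeat arm length (default 10).
#' @param n_direct_repeats Number of AATCT repeats including the truncated
#'   R2 prefix (default 6).
#' @param region_plan Named integer vector of ORF counts
#'   (late, early, middle); the late count includes the mtp, tpeX and
#'   holin genes.
#' @param shifty_stop Plant the CCC.TAG shifty stop and +1-frame TpeX ORF
#'   (default TRUE; FALSE gives the mtp a plain TAA terminator).
#' @param primer_sites List of `list(pair = primer_pair, amplicon = bp)`
#'   to plant (default: the 936 pair at 179 bp).
#' @param enzyme_sites Named list, enzyme name -> integer vector of
#'   0-based positions at which to plant recognition sites.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = NULL, gc = 0.347,
                        cos_motif = "CACAAAGGACT", ir_len = 10L,
                        n_direct_repeats = 6L,
                        region_plan = c(late = 27L, early = 23L, middle = 5L),
                        shifty_stop = TRUE,
                        primer_sites = list(list(pair = default_primer_pairs()$`936`,
                                                 amplicon = 179L)),
                        enzyme_sites = list(), seed = 1L) {
  if (gc < 0.25 || gc > 0.6)
    stop("spec error: requested GC outside [0.25, 0.6]", call. = FALSE)
  if (!all(c("late", "early", "middle") %in% names(region_plan)))
    stop("region_plan needs late, early and middle counts", call. = FALSE)
  if (region_plan[["late"]] < 5L || region_plan[["middle"]] < 1L ||
      region_plan[["early"]] < 1L)
    stop("spec error: region plan too small (late needs >= 5 ORFs)",
         call. = FALSE)
  structure(list(length = length, gc = gc, cos_motif = toupper(cos_motif),
                 ir_len = as.integer(ir_len),
                 n_direct_repeats = as.integer(n_direct_repeats),
                 region_plan = region_plan, shifty_stop = isTRUE(shifty_stop),
                 primer_sites = primer_sites, enzyme_sites = enzyme_sites,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# --- codon machinery -------------------------------------------------------

# Base probabilities at GC fraction g (A=T, G=C).
base_probs <- function(g) c(A = (1 - g) / 2, C = g / 2, G = g / 2,
                            T = (1 - g) / 2)

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Sense-codon sampling distribution whose *realized* GC matches the target
# despite the exclusion of stop codons (which are AT-rich): the input GC of
# the i.i.d. base model is adjusted by root finding.
sense_codon_probs <- function(target_gc) {
  codons <- all_codons()
  mat <- do.call(rbind, strsplit(codons, ""))
  gc_cnt <- rowSums(mat == "G" | mat == "C")
  sense <- !(codons %in% STOP_CODONS)
  probs_at <- function(g) {
    p <- base_probs(g)
    cp <- p[mat[, 1]] * p[mat[, 2]] * p[mat[, 3]]
    cp[!sense] <- 0
    cp / sum(cp)
  }
  g_adj <- stats::uniroot(function(g) sum(probs_at(g) * gc_cnt / 3) - target_gc,
                          c(0.1, 0.7), tol = 1e-6)$root
  cp <- probs_at(g_adj)
  stats::setNames(cp[sense], codons[sense])
}

sample_codons <- function(n, codon_probs) {
  if (n == 0L) return(character(0))
  sample(names(codon_probs), n, replace = TRUE, prob = codon_probs)
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs(gc)),
        collapse = "")
}

# Reverse-translate a protein with uniformly sampled synonymous codons.
reverse_translate <- function(protein) {
  inv <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- inv[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# --- genome assembly -------------------------------------------------------

#' Generate one synthetic 936-like genome with ground truth
#'
#' See [genome_spec()] for the layout. Generation is deterministic given
#' the spec (including its seed). The realized GC is brought within 0.5
#' percentage points of the request by flipping bases in intergenic filler
#' only; planted features are never touched. The assembled genome is
#' verified (single cos occurrence, exactly `n_direct_repeats` AATCT
#' occurrences inside the cos window, intact shifty stop, unique primer
#' sites) and reassembled under a derived seed in the rare case a check
#' fails.
#'
#' @param spec A [genome_spec()].
#' @param id Genome identifier (default `"syn1"`).
#' @return List with `genome` (a [phage_genome()] carrying the planted
#'   features) and `truth` (planted feature table, region plan, realized
#'   GC, expected fused MTP-TpeX length, holin protein, ORF table).
#' @export
generate_genome <- function(spec = genome_spec(), id = "syn1") {
  for (attempt in 0:49) {
    set.seed(spec$seed + 7919L * attempt)
    res <- tryCatch(assemble_genome(spec, id), error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("spec error", conditionMessage(res), fixed = TRUE))
        stop(res)   # infeasible specs do not become feasible on retry
      next
    }
    if (verify_genome(res, spec)) return(res)
  }
  stop("generation error: could not assemble a genome satisfying the spec ",
       "in 50 attempts", call. = FALSE)
}

assemble_genome <- function(spec, id) {
  L <- spec$length %||% sample(29300:30200, 1L)
  gc <- spec$gc
  cosm <- spec$cos_motif
  rp <- spec$region_plan
  n_late <- rp[["late"]]; n_early <- rp[["early"]]; n_mid <- rp[["middle"]]

  # -- special late-region genes ----------------------------------------
  mtp_idx <- max(2L, floor(n_late * 0.6))        # mtp position within late
  tpex_idx <- mtp_idx + 1L                       # tpeX directly downstream
  holin_idx <- n_late                             # lysis gene ends the region
  MTP_LEN <- 540L     # 179 codons + stop -> 179-aa MTP
  TPEX_LEN <- 1020L   # +1 ORF body; fused product 179 + 341 = 520 aa
  HOLIN_PROT <- holin_protein_template()
  HOLIN_LEN <- (nchar(HOLIN_PROT) + 1L) * 3L

  codon_probs <- sense_codon_probs(gc)

  draw_len <- function(n, lo = 150L, hi = 600L, hi2 = 1500L) {
    long <- stats::runif(n) < 0.15
    len <- ifelse(long, sample(seq(600L, hi2, 3L), n, TRUE),
                  sample(seq(lo, hi, 3L), n, TRUE))
    as.integer(len)
  }

  # -- ORF length plan (redraw until the length budget closes) -----------
  cos_block <- build_cos_block(spec, gc)
  INTER1 <- 400L; INTER2 <- 350L
  LATE_START <- 240L
  TRAIL_MIN <- 240L
  MIN_GAP <- 12L; MAX_GAP <- 80L
  ok_plan <- FALSE
  for (try_i in 1:100) {
    late_len <- draw_len(n_late)
    late_len[mtp_idx] <- MTP_LEN
    late_len[tpex_idx] <- TPEX_LEN
    late_len[holin_idx] <- HOLIN_LEN
    early_len <- draw_len(n_early)
    mid_len <- draw_len(n_mid, lo = 150L, hi = 300L, hi2 = 300L)
    mid_len[1L] <- 483L
    all_len <- c(late_len, early_len, mid_len)
    n_orfs <- length(all_len)
    # a within-region gap (with its in-frame TAA) precedes every ORF except
    # the first of each region (front filler / inter-region gaps serve
    # there) and tpeX (contiguous +1 construct, 4 nt spacer)
    n_gaps <- n_orfs - 4L
    fixed <- LATE_START + sum(all_len) + 4L + INTER1 + INTER2 +
      TRAIL_MIN + spec$ir_len
    slack <- L - fixed - MIN_GAP * n_gaps
    if (slack >= 0L) { ok_plan <- TRUE; break }
  }
  if (!ok_plan)
    stop("spec error: planted features exceed the requested genome length",
         call. = FALSE)

  # distribute slack over within-region gaps (cap MAX_GAP), rest trailing
  gap_len <- rep(MIN_GAP, n_gaps)
  if (slack > 0L && n_gaps > 0L) {
    add <- stats::rmultinom(1L, slack, rep(1, n_gaps))[, 1L]
    add <- pmin(add, MAX_GAP - MIN_GAP)
    gap_len <- gap_len + add
    slack <- slack - sum(add)
  }
  trail_len <- TRAIL_MIN + slack

  # -- assembly ----------------------------------------------------------
  pieces <- character(0)
  mutable <- list()   # (start, end) 0-based half-open filler windows
  feats <- list()
  offset <- 0L
  emit <- function(s, mut = FALSE) {
    pieces[[length(pieces) + 1L]] <<- s
    if (mut && nchar(s) > 0L)
      mutable[[length(mutable) + 1L]] <<- c(offset, offset + nchar(s))
    offset <<- offset + nchar(s)
  }
  feat <- function(kind, start, end, strand = "*", label = "", attrs = "") {
    feats[[length(feats) + 1L]] <<- feature_table(kind, start, end, strand,
                                                  label, attrs)
  }

  # cos block (positions 0 .. nchar(block))
  emit(cos_block$seq)
  for (i in seq_len(nrow(cos_block$features)))
    feats[[length(feats) + 1L]] <- cos_block$features[i, , drop = FALSE]

  # front filler up to the late region (part of the sanitized cos window)
  front <- LATE_START - offset
  emit(sanitized_filler(front - 3L, gc, forbid = c("AATCT", cosm)))
  emit("TAA")

  gap_i <- 0L
  orf_meta <- list()
  plant_orf <- function(len, region, label, body = NULL) {
    start <- offset
    if (is.null(body)) {
      n_sense <- len %/% 3L - 2L
      cods <- sample_codons(n_sense, codon_probs)
      stopc <- sample(STOP_CODONS, 1L)
      if (length(cods) > 0L && cods[n_sense] == "CCC" && stopc == "TAG")
        stopc <- "TAA"   # reserve the shifty stop for the mtp
      body <- paste0("ATG", paste(cods, collapse = ""), stopc)
    }
    stopifnot(nchar(body) == len)
    emit(body)
    feat("orf", start, start + len, "+", label,
         paste0("region=", region))
    orf_meta[[length(orf_meta) + 1L]] <<- data.frame(
      start = start, end = start + len, strand = "+", label = label,
      region = region, stringsAsFactors = FALSE)
  }
  plant_gap <- function() {
    gap_i <<- gap_i + 1L
    emit(random_dna(gap_len[gap_i] - 3L, gc), mut = TRUE)
    emit("TAA")
  }

  region_names <- rep(c("late", "early", "middle"),
                      times = c(n_late, n_early, n_mid))
  lens <- all_len
  region_bounds <- list()
  k <- 0L
  for (r in c("late", "early", "middle")) {
    n_r <- rp[[r]]
    r_start <- NA_integer_
    for (i in seq_len(n_r)) {
      k <- k + 1L
      if (r == "late" && i == tpex_idx) {
        # the +1-frame TpeX construct is contiguous with the mtp
        plant_tpex(spec, gc, codon_probs, emit, feat, orf_meta_add = function(df)
          orf_meta[[length(orf_meta) + 1L]] <<- df, offset_get = function() offset,
          tpex_len = TPEX_LEN)
        next
      }
      if (!(r == "late" && i == 1L) &&
          !(r == "early" && i == 1L) && !(r == "middle" && i == 1L))
        plant_gap()
      if (r == "early" && i == 1L) {
        # late->early gap hosts the planted primer amplicon
        plant_inter_gap(INTER1, spec, gc, emit, feat, offset_get = function() offset)
      }
      if (r == "middle" && i == 1L)
        plant_inter_gap(INTER2, NULL, gc, emit, feat, offset_get = function() offset)
      if (is.na(r_start)) r_start <- offset
      label <- if (r == "late" && i == mtp_idx) "mtp"
               else if (r == "late" && i == holin_idx) "holin"
               else sprintf("orf_%s_%02d", r, i)
      body <- NULL
      if (r == "late" && i == mtp_idx)
        body <- mtp_body(MTP_LEN, codon_probs, spec$shifty_stop)
      if (r == "late" && i == holin_idx)
        body <- holin_body(HOLIN_PROT)
      plant_orf(lens[k], r, label, body)
    }
    region_bounds[[r]] <- c(r_start, offset)
    feat("region", r_start, offset, "+", r)
  }

  # trailing filler: last 230 bp belong to the sanitized cos window
  loose <- trail_len - 230L
  if (loose > 0L) emit(random_dna(loose, gc), mut = TRUE)
  emit(sanitized_filler(min(trail_len, 230L), gc,
                        forbid = c("AATCT", cosm)))
  # left inverted-repeat arm at the very end of the genome (wraps to cos)
  emit(cos_block$left_arm)
  feat("inverted_repeat", offset - spec$ir_len, offset, "*", "IR_left")
  stopifnot(offset == L)

  seq <- paste(pieces, collapse = "")

  # planted restriction sites (overwrite filler at requested positions)
  feats_df <- do.call(rbind_features, feats)
  if (length(spec$enzyme_sites) > 0L) {
    reg <- default_enzymes()
    for (nm in names(spec$enzyme_sites)) {
      site <- reg[[nm]]$site
      for (p in spec$enzyme_sites[[nm]]) {
        if (any(feats_df$start < p + nchar(site) & feats_df$end > p))
          stop("spec error: planted enzyme site overlaps a feature",
               call. = FALSE)
        substr(seq, p + 1L, p + nchar(site)) <- site
        feats_df <- rbind_features(feats_df, feature_table(
          "restriction_site", p, p + nchar(site), "*", nm))
      }
    }
  }

  # GC repair within mutable filler, away from the cos window
  mut_pos <- mutable_positions(mutable, L)
  seq <- repair_gc(seq, gc, mut_pos)

  genome <- phage_genome(id, seq, topology = "linear_cos",
                         features = feats_df,
                         provenance = sprintf("synthetic (seed %d)", spec$seed))
  orfs <- do.call(rbind, orf_meta)
  truth <- list(features = feats_df, orfs = orfs,
                region_plan = spec$region_plan,
                gc_target = gc, gc_realized = gc_content(seq) / 100,
                fused_len = if (spec$shifty_stop) 520L else NA_integer_,
                holin_protein = HOLIN_PROT,
                terminase_motifs = default_terminase_motifs(),
                seed = spec$seed)
  list(genome = genome, truth = truth)
}

# hydrophilic / 3x hydrophobic-block holin template (class I: 3 TMDs)
holin_protein_template <- function() {
  hydrophobic <- strrep("L", 19)
  hydrophilic <- function(n) strrep("D", n)
  paste0("M", hydrophilic(8), hydrophobic, hydrophilic(12), hydrophobic,
         hydrophilic(12), hydrophobic, hydrophilic(8))
}

holin_body <- function(protein) {
  paste0(reverse_translate(protein), "TAA")
}

# mtp body: 179 sense codons ending in CCC, TAG terminator (shifty stop);
# or a plain TAA terminator when the shifty stop is disabled.
mtp_body <- function(len, codon_probs, shifty) {
  n_sense <- len %/% 3L - 3L   # codons between ATG and the final CCC
  cods <- sample_codons(n_sense, codon_probs)
  if (shifty) paste0("ATG", paste(cods, collapse = ""), "CCC", "TAG")
  else paste0("ATG", paste(cods, collapse = ""), "CCC", "TAA")
}

# Plant the +1-frame TpeX construct immediately after the mtp TAG.
# Post-shift reading begins at the A of the TAG; the construct supplies
# 341 sense codons in that frame (AGx + one linker codon + the 339-codon
# TpeX ORF) and then its stop, giving a 520-aa fused product.
plant_tpex <- function(spec, gc, codon_probs, emit, feat, orf_meta_add,
                       offset_get, tpex_len) {
  x <- sample(DNA_BASES, 1L)                 # completes the AGx codon
  linker <- sample_codons(1L, codon_probs)
  start <- offset_get() + 4L
  n_sense <- tpex_len %/% 3L - 2L
  cods <- sample_codons(n_sense, codon_probs)
  stopc <- "TAA"
  if (!spec$shifty_stop) {
    # no special construct: plant an ordinary ORF after a 4-nt spacer
    emit(paste0(x, linker))
    emit(paste0("ATG", paste(cods, collapse = ""), stopc))
    feat("orf", start, start + tpex_len, "+", "tpeX",
         "region=late;plus1=no")
    orf_meta_add(data.frame(start = start, end = start + tpex_len,
                            strand = "+", label = "tpeX", region = "late",
                            stringsAsFactors = FALSE))
    return(invisible(NULL))
  }
  body <- paste0("ATG", paste(cods, collapse = ""), stopc)
  emit(paste0(x, linker))
  emit(body)
  feat("orf", start, start + tpex_len, "+", "tpeX",
       "region=late;plus1=yes;recover=approx")
  orf_meta_add(data.frame(start = start, end = start + tpex_len,
                          strand = "+", label = "tpeX", region = "late",
                          stringsAsFactors = FALSE))
  invisible(NULL)
}

# Inter-region gap; when `spec` is given its primer amplicons are planted
# inside (fwd site + insert + revcomp(rev site)), and the gap ends with
# the in-frame TAA of the next region's first ORF.
plant_inter_gap <- function(total, spec, gc, emit, feat, offset_get) {
  consumed <- 0L
  if (!is.null(spec) && length(spec$primer_sites) > 0L) {
    lead <- 100L
    emit(random_dna(lead, gc), mut = TRUE)
    consumed <- consumed + lead
    for (ps in spec$primer_sites) {
      pair <- ps$pair; amp <- ps$amplicon
      kf <- nchar(pair$fwd); kr <- nchar(pair$rev)
      insert <- amp - kf - kr
      if (insert < 0L) stop("spec error: amplicon shorter than primers",
                            call. = FALSE)
      p0 <- offset_get()
      emit(pair$fwd)
      emit(random_dna(insert, gc))
      emit(revcomp(pair$rev))
      feat("primer_site", p0, p0 + kf, "+", pair$name,
           paste0("role=fwd;amplicon=", amp))
      feat("primer_site", p0 + amp - kr, p0 + amp, "-", pair$name,
           paste0("role=rev;amplicon=", amp))
      consumed <- consumed + amp
    }
  }
  rest <- total - consumed - 3L
  if (rest < 0L) stop("spec error: inter-region gap cannot hold the amplicon",
                      call. = FALSE)
  emit(random_dna(rest, gc), mut = TRUE)
  emit("TAA")
  invisible(NULL)
}

# Random filler guaranteed to contain none of the forbidden motifs.
sanitized_filler <- function(n, gc, forbid) {
  if (n <= 0L) return("")
  for (i in 1:200) {
    s <- random_dna(n, gc)
    if (!any(vapply(forbid, function(m) grepl(m, s, fixed = TRUE),
                    logical(1))))
      return(s)
  }
  stop("could not sanitize filler", call. = FALSE)
}

# cos block: cos 11-mer at local position 0, then R1, D1-D5, the
# truncated R2 (whose AATCT prefix is D6), R3 and the right IR arm.
# Also draws the left IR arm (planted at the genome end by the caller).
build_cos_block <- function(spec, gc) {
  motifs <- default_terminase_motifs()
  cosm <- spec$cos_motif
  dr <- "AATCT"
  for (i in 1:200) {
    arm <- random_dna(spec$ir_len, gc)
    if (grepl(dr, arm, fixed = TRUE) || grepl(dr, revcomp(arm), fixed = TRUE))
      next
    feats <- list(); parts <- character(0); off <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; off <<- off + nchar(s) }
    fadd <- function(kind, start, end, label, attrs = "")
      feats[[length(feats) + 1L]] <<- feature_table(kind, start, end, "*",
                                                    label, attrs)
    add(cosm); fadd("cos", 0L, nchar(cosm), "cos")
    add(random_dna(8L, gc))
    fadd("terminase_site", off, off + nchar(motifs["R1"]), "R1",
         "complete=true")
    add(motifs[["R1"]])
    add(random_dna(4L, gc))
    n_plain <- spec$n_direct_repeats - 1L
    for (d in seq_len(n_plain)) {
      fadd("direct_repeat", off, off + nchar(dr), paste0("D", d))
      add(dr)
      add(random_dna(4L, gc))
    }
    # truncated R2: its AATCT prefix is the last direct repeat
    r2 <- motifs[["R2"]]
    r2p <- substr(r2, 1L, R2_PLANTED_PREFIX)
    fadd("direct_repeat", off, off + nchar(dr),
         paste0("D", spec$n_direct_repeats), "truncated_terminase=R2")
    add(r2p)
    # force the unplanted R2 tail to mismatch so the site stays partial
    tail <- strsplit(substr(r2, R2_PLANTED_PREFIX + 1L, nchar(r2)), "")[[1]]
    add(paste(vapply(tail, function(b) sample(setdiff(DNA_BASES, b), 1L), ""),
              collapse = ""))
    add(random_dna(3L, gc))
    fadd("terminase_site", off, off + nchar(motifs["R3"]), "R3",
         "complete=true")
    add(motifs[["R3"]])
    add(random_dna(4L, gc))
    fadd("inverted_repeat", off, off + spec$ir_len, "IR_right")
    add(revcomp(arm))
    block <- paste(parts, collapse = "")
    # the block must contain exactly the planted motif occurrences
    n_dr <- length(find_exact(block, dr))
    n_cos <- length(find_exact(block, cosm))
    if (n_dr == spec$n_direct_repeats && n_cos == 1L)
      return(list(seq = block, features = do.call(rbind_features, feats),
                  left_arm = arm))
  }
  stop("could not assemble a clean cos block", call. = FALSE)
}

mutable_positions <- function(mutable, L, zone = 240L) {
  if (length(mutable) == 0L) return(integer(0))
  pos <- unlist(lapply(mutable, function(iv) seq.int(iv[1L] + 1L, iv[2L])))
  pos[pos > zone & pos <= L - zone]   # 1-based, outside the cos window
}

# Flip filler bases (AT <-> GC) until the realized GC is on target.
repair_gc <- function(seq, target, mut_pos) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  need <- round(target * L) - sum(b %in% c("G", "C"))
  if (need == 0L || length(mut_pos) == 0L) return(seq)
  if (need > 0L) {
    cand <- mut_pos[b[mut_pos] %in% c("A", "T")]
    take <- utils::head(sample(cand, length(cand)), need)
    b[take] <- sample(c("G", "C"), length(take), replace = TRUE)
  } else {
    cand <- mut_pos[b[mut_pos] %in% c("G", "C")]
    take <- utils::head(sample(cand, length(cand)), -need)
    b[take] <- sample(c("A", "T"), length(take), replace = TRUE)
  }
  paste(b, collapse = "")
}

# Post-assembly verification of the planted layout.
verify_genome <- function(res, spec) {
  g <- res$genome; seq <- g$seq; L <- nchar(seq)
  if (length(find_exact_circular(seq, spec$cos_motif)) != 1L) return(FALSE)
  win <- paste0(substr(seq, L - 239L, L), substr(seq, 1L, 240L))
  if (length(find_exact(win, "AATCT")) != spec$n_direct_repeats)
    return(FALSE)
  if (spec$shifty_stop) {
    mtp <- res$truth$orfs[res$truth$orfs$label == "mtp", ]
    b <- mtp$end
    if (substr(seq, b - 5L, b) != "CCCTAG") return(FALSE)
    ds <- downstream_plus1_stop(seq, b - 2L, 3000L)
    tpex <- res$truth$orfs[res$truth$orfs$label == "tpeX", ]
    if (is.na(ds) || ds != tpex$end - 3L) return(FALSE)
  }
  for (ps in spec$primer_sites) {
    amps <- in_silico_pcr(g, ps$pair)
    if (nrow(amps) != 1L || amps$length != ps$amplicon) return(FALSE)
  }
  TRUE
}
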