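# Deterministic synthetic genomes with planted retroposition products.
#
# A planted insertion reproduces the anatomy of an internally primed TPRT
# product on the top strand (element orientation):
#
#   ...flank [TT] [TSD] [source RNA 1..breakpoint] [gap] [TSD'] flank...
#
# where the two nt ahead of the 5' TSD copy plus the TSD start follow the
# target-site motif, and -- when a priming length is requested -- the
# downstream TSD copy begins with the consensus sequence beyond the
# breakpoint (the integration site's bottom strand is then complementary to
# the annealed RNA). Minus-strand plants reverse-complement the whole
# cassette; the TSD copies stay direct repeats on the chromosome.

#' Specification of one planted insertion
#'
#' @param rna source RNA name (must exist in the generator's RNA library).
#' @param truncation 1-based breakpoint: last consensus position retroposed.
#' @param tsd_len TSD length in nt.
#' @param tsd_mut substitutions applied to the downstream TSD copy.
#' @param motif IUPAC target-site pattern; first two symbols are the
#'   dinucleotide 5' of the TSD, the rest seed the TSD start.
#' @param priming requested complementarity length between integration site
#'   and RNA beyond the breakpoint (<= 20 and <= `tsd_len`; forces the
#'   downstream flank to begin with the consensus continuation).
#' @param strand `"+"` or `"-"`.
#' @param gap_3p nt of spacer between the element terminus and the
#'   downstream TSD copy.
#' @param overhang_5p consensus nt missing at the element 5' end.
#' @param decoy_class `"none"` for a conforming insertion, or one of
#'   `"short"`, `"tailed"`, `"interrupted"`, `"low_tsd_identity"`,
#'   `"duplicated"` for a planted rule violation.
#' @return a one-row tibble.
#' @export
plant_spec <- function(rna, truncation, tsd_len = 12L, tsd_mut = 0L,
                       motif = "TTWAAAAWW", priming = 0L, strand = "+",
                       gap_3p = 0L, overhang_5p = 0L, decoy_class = "none") {
  stopifnot(priming <= 20L, strand %in% c("+", "-"))
  decoy_class <- match.arg(decoy_class,
    c("none", "short", "tailed", "interrupted", "low_tsd_identity", "duplicated"))
  tibble::tibble(
    rna = rna, truncation = as.integer(truncation),
    tsd_len = as.integer(tsd_len), tsd_mut = as.integer(tsd_mut),
    motif = motif, priming = as.integer(priming), strand = strand,
    gap_3p = as.integer(gap_3p), overhang_5p = as.integer(overhang_5p),
    decoy_class = decoy_class)
}

#' Apply exact substitution mutations to a sequence
#'
#' Exactly `n` substitutions at distinct positions, never to the original
#' base; deterministic for a given seed.
#'
#' @param seq DNA string.
#' @param n number of substitutions (`<= nchar(seq)`).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return the mutated string.
#' @export
#' @examples
#' mutate_seq("ACGTACGTACGT", 3, seed = 1)
mutate_seq <- function(seq, n, seed = NULL) {
  if (n > nchar(seq)) stop("cannot place ", n, " substitutions in ", nchar(seq), " nt")
  if (!is.null(seed)) {
    return(with_rng_seed(seed, mutate_seq(seq, n)))
  }
  if (n == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# run code with a locally seeded RNG, restoring the caller's stream
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# a base different from each of the given bases (used to break accidental
# complementarity extensions)
different_base <- function(...) {
  avoid <- unlist(list(...))
  sample(setdiff(DNA_BASES, avoid), 1L)
}

# build the cassette (element orientation) and its truth metadata
build_cassette <- function(spec, rna_seq) {
  rna_len <- nchar(rna_seq)
  bp <- spec$truncation
  if (bp < 1L || bp > rna_len) stop("truncation point outside source RNA")

  motif_seq <- sample_iupac(spec$motif)
  up2 <- substr(motif_seq, 1, 2)
  motif_tsd <- substr(motif_seq, 3, nchar(motif_seq))

  beyond <- substr(rna_seq, bp + 1L, rna_len)
  if (spec$priming > 0L) {
    if (spec$priming > spec$tsd_len) stop("priming length exceeds TSD length")
    if (spec$priming > nchar(beyond)) stop("priming length exceeds remaining consensus")
    core <- substr(beyond, 1, spec$priming)
    fill_len <- spec$tsd_len - spec$priming
    fill <- if (fill_len > 0) {
      nxt <- if (nchar(beyond) > spec$priming) {
        substr(beyond, spec$priming + 1L, spec$priming + 1L)
      } else ""
      paste0(different_base(nxt), random_dna(fill_len - 1L))
    } else ""
    tsd <- paste0(core, fill)
  } else {
    seed_part <- substr(motif_tsd, 1, min(nchar(motif_tsd), spec$tsd_len))
    fill <- random_dna(spec$tsd_len - nchar(seed_part))
    tsd <- paste0(seed_part, fill)
  }

  body <- substr(rna_seq, 1L + spec$overhang_5p, bp)
  if (spec$decoy_class == "tailed") {
    body <- substr(rna_seq, 1L + spec$overhang_5p, rna_len)
  }
  tail <- if (spec$decoy_class == "tailed") strrep("A", 20L) else ""
  # spacer boundaries must not extend the TSD alignment: its first base breaks
  # complementarity with the consensus continuation, its last base differs from
  # the base immediately 5' of the upstream TSD copy (else the local aligner
  # would absorb it into the duplication)
  up2_last <- substr(up2, nchar(up2), nchar(up2))
  spacer <- if (spec$gap_3p == 1L) {
    different_base(substr(beyond, 1, 1), up2_last)
  } else if (spec$gap_3p > 1L) {
    paste0(different_base(substr(beyond, 1, 1)),
           random_dna(spec$gap_3p - 2L),
           different_base(up2_last))
  } else ""

  tsd_right <- if (spec$tsd_mut == 0L) {
    tsd
  } else if (spec$decoy_class == "low_tsd_identity") {
    # substitutions on a fixed every-3rd-position grid: no sub-block of the
    # mutated pair can satisfy both the TSD length floor and the identity
    # threshold, so the rejection is deterministic
    if (3L * spec$tsd_mut > spec$tsd_len) {
      stop("tsd_mut too large for grid placement on a ", spec$tsd_len, " nt TSD")
    }
    chars <- strsplit(tsd, "", fixed = TRUE)[[1]]
    for (p in 3L * seq_len(spec$tsd_mut)) chars[p] <- different_base(chars[p])
    paste(chars, collapse = "")
  } else {
    mutate_seq(tsd, spec$tsd_mut)
  }

  if (spec$decoy_class == "interrupted") {
    k <- max(1L, bp %/% 2L)
    part1 <- substr(body, 1, k - spec$overhang_5p)
    part2 <- substr(body, k - spec$overhang_5p + 1L, nchar(body))
    interruptor <- random_dna(100L)
    cassette <- paste0(up2, tsd, part1, interruptor, part2, tail, spacer, tsd_right)
    segments <- list(
      c(off = nchar(up2) + nchar(tsd), len = nchar(part1),
        r_start = 1L + spec$overhang_5p, r_end = k),
      c(off = nchar(up2) + nchar(tsd) + nchar(part1) + nchar(interruptor),
        len = nchar(part2), r_start = k + 1L, r_end = bp))
  } else {
    cassette <- paste0(up2, tsd, body, tail, spacer, tsd_right)
    r_end <- if (spec$decoy_class == "tailed") rna_len else bp
    segments <- list(
      c(off = nchar(up2) + nchar(tsd), len = nchar(body),
        r_start = 1L + spec$overhang_5p, r_end = r_end))
  }
  list(cassette = cassette, segments = segments, tsd = tsd,
       realized_priming = min(20L, common_prefix_len(
         paste0(tail, spacer, tsd_right), beyond)))
}

#' Generate a synthetic genome with planted insertions and ground truth
#'
#' Produces an i.i.d. background sequence with the requested GC content,
#' plants each specified insertion with at least `spacing` nt between
#' cassettes, and emits the idealized RepeatMasker-style hit table a masking
#' run would produce together with a machine-readable truth record per
#' plant. Identical seeds give byte-identical output.
#'
#' @param specs tibble of [plant_spec()] rows (may be empty).
#' @param rna_library tibble from [read_rna_library()].
#' @param background_length total genome length in nt.
#' @param gc background GC fraction (human-like default 0.41).
#' @param seed integer seed.
#' @param spacing minimal background separation between cassettes.
#' @param noisy perturb hit query boundaries by up to +/-3 nt (annotation
#'   robustness mode).
#' @return list with `genome` (tibble `name`, `seq`), `hits` (RepeatMasker
#'   hit tibble, see [read_rmout()]) and `truth` (one row per planted
#'   element: locus, spec fields, realized priming, `expected_outcome`).
#' @export
generate_genome <- function(specs, rna_library, background_length = 2e6,
                            gc = 0.41, seed = 1L, spacing = 200L,
                            noisy = FALSE) {
  with_rng_seed(seed, {
    generate_genome_impl(specs, rna_library, as.integer(background_length),
                         gc, as.integer(spacing), noisy)
  })
}

generate_genome_impl <- function(specs, rna_library, background_length, gc,
                                 spacing, noisy) {
  chrom <- "synth1"
  if (is.null(specs) || nrow(specs) == 0L) {
    return(list(
      genome = tibble::tibble(name = chrom, seq = random_dna(background_length, gc)),
      hits = empty_hits(),
      truth = tibble::tibble()))
  }

  # build cassettes; a duplicated plant contributes two placements sharing
  # sequence (cassette plus flanks, so TSD + 100 nt flanks are identical)
  placements <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    rna <- rna_library[rna_library$name == spec$rna, ]
    if (nrow(rna) != 1) stop("source RNA '", spec$rna, "' not in library")
    built <- build_cassette(spec, rna$seq)
    rna_len <- nchar(rna$seq)
    rna_class <- if ("class" %in% names(rna_library)) rna$class else "Unknown"
    if (spec$decoy_class == "duplicated") {
      flank_l <- random_dna(120L); flank_r <- random_dna(120L)
      unit <- paste0(flank_l, built$cassette, flank_r)
      for (copy in 1:2) {
        placements[[length(placements) + 1L]] <- list(
          spec_idx = i, spec = spec, seq = unit, built = built,
          cass_off = nchar(flank_l), rna_len = rna_len, rna_class = rna_class,
          copy = copy)
      }
    } else {
      placements[[length(placements) + 1L]] <- list(
        spec_idx = i, spec = spec, seq = built$cassette, built = built,
        cass_off = 0L, rna_len = rna_len, rna_class = rna_class, copy = 1L)
    }
  }

  total_insert <- sum(vapply(placements, function(p) nchar(p$seq), numeric(1)))
  n_chunks <- length(placements) + 1L
  chunk <- (background_length - total_insert) %/% n_chunks
  if (chunk < spacing) {
    stop("background too short: plants would be closer than ", spacing, " nt")
  }

  pieces <- character(0)
  pos <- 0L
  hits <- list(); truth <- list()
  rm_id <- 0L
  for (p in placements) {
    bg <- random_dna(chunk, gc)
    pieces <- c(pieces, bg); pos <- pos + chunk
    start_of_unit <- pos + 1L

    spec <- p$spec; built <- p$built
    orient <- spec$strand
    unit_len <- nchar(p$seq)
    # minus-strand plants: the whole unit is reverse-complemented in place;
    # TSD copies remain direct repeats on the top strand
    pieces <- c(pieces, if (orient == "-") revcomp(p$seq) else p$seq)
    rm_id <- rm_id + 1L

    seg_rows <- list()
    for (s in built$segments) {
      # unit-local span of the segment in element orientation
      u1 <- p$cass_off + s[["off"]] + 1L
      u2 <- p$cass_off + s[["off"]] + s[["len"]]
      if (orient == "-") {
        tmp <- u1
        u1 <- unit_len - u2 + 1L
        u2 <- unit_len - tmp + 1L
      }
      seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
        sw_score = 8L * s[["len"]], divergence_pct = 0, deletion_pct = 0,
        insertion_pct = 0, query_name = chrom,
        query_start = as.integer(start_of_unit + u1 - 1L),
        query_end = as.integer(start_of_unit + u2 - 1L),
        query_left = 0L, strand = orient, repeat_name = spec$rna,
        repeat_class = p$rna_class,
        repeat_start = as.integer(s[["r_start"]]),
        repeat_end = as.integer(s[["r_end"]]),
        repeat_left = as.integer(p$rna_len - s[["r_end"]]),
        rm_id = rm_id)
    }
    seg_tbl <- dplyr::bind_rows(seg_rows)
    hits[[length(hits) + 1L]] <- seg_tbl

    expected <- switch(spec$decoy_class,
      none = "accept",
      short = "reject:min_element_len",
      tailed = "reject:min_3p_truncation",
      interrupted = "reject:interrupted",
      low_tsd_identity = "reject:tsd",
      duplicated = if (p$copy == 1L) "accept" else "duplicate")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      chrom = chrom, start = min(seg_tbl$query_start),
      end = max(seg_tbl$query_end), rna = spec$rna,
      truncation = spec$truncation, tsd_len = spec$tsd_len,
      tsd_mut = spec$tsd_mut, tsd_seq = built$tsd, motif = spec$motif,
      priming = built$realized_priming, strand = spec$strand,
      gap_3p = spec$gap_3p, overhang_5p = spec$overhang_5p,
      decoy_class = spec$decoy_class, rm_id = rm_id,
      expected_outcome = expected)
    pos <- pos + unit_len
  }
  remainder <- background_length - pos
  pieces <- c(pieces, random_dna(remainder, gc))
  genome_seq <- paste(pieces, collapse = "")

  hits_tbl <- dplyr::bind_rows(hits)
  hits_tbl$query_left <- nchar(genome_seq) - hits_tbl$query_end
  truth_tbl <- dplyr::bind_rows(truth)

  if (noisy) {
    delta_s <- sample(-3:3, nrow(hits_tbl), replace = TRUE)
    delta_e <- sample(-3:3, nrow(hits_tbl), replace = TRUE)
    hits_tbl$query_start <- pmax(1L, hits_tbl$query_start + delta_s)
    hits_tbl$query_end <- pmin(nchar(genome_seq),
                               pmax(hits_tbl$query_start, hits_tbl$query_end + delta_e))
  }

  list(genome = tibble::tibble(name = chrom, seq = genome_seq),
       hits = hits_tbl, truth = truth_tbl)
}
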