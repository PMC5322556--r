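# Position frequency matrices, logos, and breakpoint/endpoint statistics.

new_pfm <- function(counts, present, n_sequences) {
  structure(list(counts = counts, present = present,
                 n_sequences = n_sequences, width = ncol(counts)),
            class = "pfm")
}

# accumulate sequences (possibly shorter than width) into a PFM; position i of
# each string fills column offset + i
build_pfm <- function(strings, width, offsets = 0L) {
  counts <- matrix(0L, 4, width, dimnames = list(DNA_BASES, NULL))
  present <- integer(width)
  offsets <- rep_len(offsets, length(strings))
  for (k in seq_along(strings)) {
    chars <- strsplit(strings[k], "", fixed = TRUE)[[1]]
    for (i in seq_along(chars)) {
      col <- offsets[k] + i
      if (col < 1L || col > width) next
      if (chars[i] %in% DNA_BASES) {
        counts[chars[i], col] <- counts[chars[i], col] + 1L
        present[col] <- present[col] + 1L
      }
    }
  }
  new_pfm(counts, present, length(strings))
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix:", x$width, "positions,",
      x$n_sequences, "sequences\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a position frequency matrix
#' @param x a `pfm`.
#' @param ... unused.
#' @return tibble with `position`, `base`, `count`, `present`, `freq`.
#' @export
tidy.pfm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), each = 4L),
    base = rep(DNA_BASES, x$width),
    count = as.integer(x$counts),
    present = rep(x$present, each = 4L)
  ) |>
    dplyr::mutate(freq = ifelse(.data$present > 0, .data$count / .data$present, NA_real_))
}

#' Insertion target-site position frequency matrix
#'
#' Builds the target-site motif matrix from the 2 nt immediately upstream of
#' the 5' TSD copy plus the TSD itself, read on the genomic strand of the
#' insertion (element orientation). Only candidates with 100% identical TSD
#' copies enter the matrix; shorter TSDs are right-padded and counted only
#' where present. Positions 1-2 are the upstream dinucleotide (the `TT` of
#' the TT/WAAAAWW consensus), position 3 onward the TSD.
#'
#' @param candidates accepted candidate tibble (see [screen_genome()]).
#' @param genome tibble from [read_fasta()].
#' @return a `pfm` object.
#' @export
target_site_matrix <- function(candidates, genome) {
  cands <- candidates[!is.na(candidates$tsd_identity) &
                        candidates$tsd_identity == 100, ]
  if (!nrow(cands)) stop("no candidates with perfect TSDs")
  site <- vapply(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    seq <- chrom_seq(genome, cand$chrom)
    if (cand$strand == "+") {
      up2 <- subseq_clip(seq, cand$tsd_left_start - 2L, cand$tsd_left_start - 1L)
      tsd <- subseq_clip(seq, cand$tsd_left_start, cand$tsd_left_end)
    } else {
      up2 <- revcomp(subseq_clip(seq, cand$tsd_right_end + 1L, cand$tsd_right_end + 2L))
      tsd <- revcomp(subseq_clip(seq, cand$tsd_right_start, cand$tsd_right_end))
    }
    paste0(stringr::str_pad(up2, 2, side = "left", pad = "N"), tsd)
  }, character(1))
  build_pfm(site, width = 2L + max(nchar(site) - 2L))
}

#' Breakpoint sequence-context position frequency matrix
#'
#' Counts source-RNA nucleotides around each candidate's breakpoint: columns
#' 1-5 are consensus positions `bp-4 .. bp` (the breakpoint occupying column
#' 5), columns 6-10 are `bp+1 .. bp+5`. Positions outside the RNA are skipped
#' for that sequence.
#'
#' @param candidates accepted candidate tibble.
#' @param rna_library tibble from [read_rna_library()].
#' @return a `pfm` of width 10.
#' @export
breakpoint_context_matrix <- function(candidates, rna_library) {
  if (!nrow(candidates)) stop("no candidates")
  width <- 10L
  counts <- matrix(0L, 4, width, dimnames = list(DNA_BASES, NULL))
  present <- integer(width)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    rna <- rna_library[rna_library$name == cand$source_rna, ]
    if (nrow(rna) != 1) stop("source RNA '", cand$source_rna, "' not in library")
    bp <- cand$breakpoint
    if (is.na(bp) || bp < 1 || bp > nchar(rna$seq)) {
      stop("breakpoint outside source RNA for candidate ", i)
    }
    pos <- (bp - 4L):(bp + 5L)
    for (col in seq_len(width)) {
      p <- pos[col]
      if (p < 1L || p > nchar(rna$seq)) next
      base <- substr(rna$seq, p, p)
      if (base %in% DNA_BASES) {
        counts[base, col] <- counts[base, col] + 1L
        present[col] <- present[col] + 1L
      }
    }
  }
  new_pfm(counts, present, nrow(candidates))
}

#' Information-content sequence logo values
#'
#' Per position, information content `IC = 2 - H` bits where `H` is the
#' Shannon entropy of the base frequencies (log base 2, no small-sample
#' correction); each base's letter height is `freq x IC`.
#'
#' @param pfm a `pfm` object.
#' @return tibble with `position`, `base`, `freq`, `ic`, `height`.
#' @export
#' @examples
#' # a deterministic column has IC = 2 bits
information_logo <- function(pfm) {
  if (pfm$n_sequences <= 0) stop("empty position frequency matrix")
  per_pos <- lapply(seq_len(pfm$width), function(col) {
    n <- pfm$present[col]
    if (n == 0L) {
      return(tibble::tibble(position = col, base = DNA_BASES, freq = 0,
                            ic = 0, height = 0))
    }
    p <- pfm$counts[, col] / n
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic <- 2 - h
    tibble::tibble(position = col, base = DNA_BASES, freq = unname(p),
                   ic = ic, height = unname(p) * ic)
  })
  dplyr::bind_rows(per_pos)
}

#' Priming-length distribution
#'
#' Distribution of the complementarity length between the integration site
#' and the source RNA beyond the breakpoint (the `X` of the TT/WAAAAWWX
#' target-site consensus).
#'
#' @param candidates accepted candidate tibble with `priming_length`.
#' @return list with `histogram` (tibble `priming_length`, `n`), `min`, `max`.
#' @export
priming_length_distribution <- function(candidates) {
  pl <- candidates$priming_length
  pl <- pl[!is.na(pl)]
  if (!length(pl)) stop("no candidates with priming lengths")
  hist <- dplyr::count(tibble::tibble(priming_length = pl), .data$priming_length)
  list(histogram = hist, min = min(pl), max = max(pl))
}

#' Breakpoint (truncation-point) histogram for one source RNA
#'
#' Counts candidate breakpoints per consensus position. When the RNA carries
#' a dot-bracket structure, each position is labelled paired/unpaired and the
#' unpaired fraction of all truncations is reported (truncation hotspots fall
#' into loops and other single-stranded regions).
#'
#' @param candidates accepted candidate tibble (only rows matching
#'   `rna$name` are used).
#' @param rna one-row tibble from [read_rna_library()].
#' @return a `breakpoint_histogram`: list with `rna`, `counts` (tibble
#'   `position`, `count`, `paired`), `n_candidates`, `unpaired_fraction`
#'   (`NA` without structure).
#' @export
breakpoint_histogram <- function(candidates, rna) {
  stopifnot(nrow(rna) == 1)
  len <- nchar(rna$seq)
  paired <- rep(NA, len)
  if (!is.na(rna$structure)) {
    if (nchar(rna$structure) != len) {
      stop("structure length does not match sequence length for '", rna$name, "'")
    }
    paired <- structure_paired(rna$structure)
  }
  bps <- candidates$breakpoint[candidates$source_rna == rna$name]
  bps <- bps[!is.na(bps)]
  if (any(bps < 1 | bps > len)) stop("breakpoint outside consensus length")
  counts <- tabulate(bps, nbins = len)
  unpaired_fraction <- if (all(is.na(paired)) || !length(bps)) NA_real_ else
    sum(!paired[bps]) / length(bps)
  structure(
    list(rna = rna$name,
         counts = tibble::tibble(position = seq_len(len), count = counts,
                                 paired = paired),
         n_candidates = length(bps),
         unpaired_fraction = unpaired_fraction),
    class = "breakpoint_histogram")
}

#' @export
print.breakpoint_histogram <- function(x, ...) {
  cat("Breakpoint histogram for", x$rna, "-", x$n_candidates, "candidates\n")
  if (!is.na(x$unpaired_fraction)) {
    cat(sprintf("  unpaired fraction of truncations: %.3f\n", x$unpaired_fraction))
  }
  invisible(x)
}

#' Endpoint frequencies of cDNA alignments
#'
#' For transcriptome evidence of truncated RNAs: among alignments to a source
#' RNA, only those starting at consensus position 1 are considered, and their
#' endpoint positions are counted.
#'
#' @param cdna_alignments tibble with columns `name` (source RNA), `start`,
#'   `end` (1-based inclusive consensus coordinates).
#' @return tibble with `name`, `end`, `n`.
#' @export
endpoint_frequencies <- function(cdna_alignments) {
  full5 <- cdna_alignments[cdna_alignments$start == 1L, ]
  if (!nrow(full5)) {
    return(tibble::tibble(name = character(), end = integer(), n = integer()))
  }
  dplyr::count(full5, .data$name, .data$end)
}

#' Per-gigabase density
#'
#' Normalizes an element count by genome length to elements per gigabase.
#'
#' @param count number of elements.
#' @param genome_length genome length in nt (> 0).
#' @return tibble with `count`, `genome_length`, `per_gb` (raw) and
#'   `per_gb_rounded` (nearest integer).
#' @export
#' @examples
#' per_gigabase(555, 2.861e9)$per_gb_rounded  # 194
per_gigabase <- function(count, genome_length) {
  if (any(genome_length <= 0)) stop("genome length must be > 0")
  per_gb <- count * 1e9 / genome_length
  tibble::tibble(count = count, genome_length = genome_length,
                 per_gb = per_gb, per_gb_rounded = round(per_gb))
}
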