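# Per-hit classification: the ordered rule cascade of the tailless screen.

candidate_schema <- function() {
  tibble::tibble(
    source_rna = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), breakpoint = integer(),
    tsd_len = integer(), tsd_identity = numeric(),
    tsd_left_start = integer(), tsd_left_end = integer(),
    tsd_right_start = integer(), tsd_right_end = integer(),
    target_identity = numeric(), overhang_5p = integer(), gap_3p = integer(),
    priming_length = integer(), rm_id = integer(),
    duplicate_of = character(), accepted = logical(),
    failed_rule = character(), value = numeric()
  )
}

reject_row <- function(hit, rule, value) {
  tibble::tibble(
    source_rna = hit$repeat_name, chrom = hit$query_name,
    start = hit$query_start, end = hit$query_end, strand = hit$strand,
    breakpoint = NA_integer_, tsd_len = NA_integer_, tsd_identity = NA_real_,
    tsd_left_start = NA_integer_, tsd_left_end = NA_integer_,
    tsd_right_start = NA_integer_, tsd_right_end = NA_integer_,
    target_identity = NA_real_, overhang_5p = NA_integer_,
    gap_3p = NA_integer_, priming_length = NA_integer_, rm_id = hit$rm_id,
    duplicate_of = NA_character_, accepted = FALSE,
    failed_rule = rule, value = as.numeric(value)
  )
}

# genomic hit sequence in element (source-RNA) orientation
hit_sequence <- function(hit, genome) {
  seq <- subseq_clip(chrom_seq(genome, hit$query_name), hit$query_start, hit$query_end)
  if (hit$strand == "-") revcomp(seq) else seq
}

# sequence immediately 3' of the element terminus, element orientation
downstream_flank <- function(hit, genome, n) {
  seq <- chrom_seq(genome, hit$query_name)
  if (hit$strand == "+") {
    subseq_clip(seq, hit$query_end + 1L, hit$query_end + n)
  } else {
    revcomp(subseq_clip(seq, hit$query_start - n, hit$query_start - 1L))
  }
}

#' Classify one masked hit as a tailless candidate or a rejection
#'
#' Applies the ordered rule cascade: (1) 5' completeness (at most
#' `max_5p_overhang` consensus nt missing at the 5' end, relaxed to
#' `trna_5p_slack` for tRNAs); (2) 3' truncation of at least
#' `min_3p_truncation` nt; (3) global alignment of the genomic hit against
#' its source-RNA consensus segment, identity strictly greater than
#' `min_target_identity`; (4) a flanking TSD ([find_tsds()]) with at most
#' `max_gap_3p` nt between element terminus and downstream copy; (5) element
#' length (last retroposed consensus position) of at least `min_element_len`.
#' On success the breakpoint (last consensus position covered by the global
#' alignment, 1-based) and the priming length (exact complementarity between
#' the integration site and the source RNA beyond the breakpoint, capped at
#' 20 nt) are computed.
#'
#' Minus-strand hits are reverse-complemented into RNA orientation before
#' alignment; TSD spans are reported in genomic orientation.
#'
#' @param hit one-row tibble from [read_rmout()].
#' @param rna one-row tibble from [read_rna_library()] matching
#'   `hit$repeat_name`.
#' @param genome tibble from [read_fasta()].
#' @param cfg a [filter_config()].
#' @param relaxed_trna use the relaxed 5' slack (precursor allowance).
#' @return a one-row tibble; `accepted` is `TRUE` for a candidate, otherwise
#'   `failed_rule` names the first violated rule and `value` the measured
#'   quantity.
#' @export
classify_candidate <- function(hit, rna, genome, cfg = filter_config(),
                               relaxed_trna = FALSE) {
  if (is.null(rna) || nrow(rna) != 1 || rna$name != hit$repeat_name) {
    stop("source RNA '", hit$repeat_name, "' not resolved in the RNA library")
  }
  rna_len <- nchar(rna$seq)

  # (1) 5' completeness
  overhang_5p <- hit$repeat_start - 1L
  slack <- if (relaxed_trna) cfg$trna_5p_slack else cfg$max_5p_overhang
  if (overhang_5p > slack) return(reject_row(hit, "max_5p_overhang", overhang_5p))

  # (2) 3' truncation
  if (hit$repeat_left < cfg$min_3p_truncation) {
    return(reject_row(hit, "min_3p_truncation", hit$repeat_left))
  }

  # (3) identity to the source-RNA consensus (global alignment)
  hseq <- hit_sequence(hit, genome)
  rseg <- substr(rna$seq, hit$repeat_start, min(hit$repeat_end, rna_len))
  if (!nzchar(hseq) || !nzchar(rseg)) {
    return(reject_row(hit, "min_target_identity", 0))
  }
  aln <- needleman_wunsch(hseq, rseg, consensus_scheme())
  if (aln$identity_pct <= 100 * cfg$min_target_identity) {
    return(reject_row(hit, "min_target_identity", aln$identity_pct))
  }

  # (4) TSD with bounded 3' gap
  tsd <- find_tsds(hit, genome, cfg)
  if (is.null(tsd)) return(reject_row(hit, "tsd", NA))
  if (tsd$gap_3p > cfg$max_gap_3p) return(reject_row(hit, "max_gap_3p", tsd$gap_3p))

  # (5) element length: last consensus position covered by the alignment
  states <- strsplit(aln$states, "", fixed = TRUE)[[1]]
  trailing_unmatched <- match(FALSE, rev(states) == "A", nomatch = length(states) + 1L) - 1L
  breakpoint <- hit$repeat_start - 1L + nchar(rseg) - trailing_unmatched
  if (breakpoint < cfg$min_element_len) {
    return(reject_row(hit, "min_element_len", breakpoint))
  }

  # priming: exact match between the downstream integration site (element
  # orientation, top strand -- equivalently complementarity of the bottom
  # strand to the RNA) and the consensus beyond the breakpoint
  flank <- downstream_flank(hit, genome, 20L)
  beyond <- substr(rna$seq, breakpoint + 1L, min(breakpoint + 20L, rna_len))
  priming <- min(20L, common_prefix_len(flank, beyond))

  tibble::tibble(
    source_rna = hit$repeat_name, chrom = hit$query_name,
    start = hit$query_start, end = hit$query_end, strand = hit$strand,
    breakpoint = as.integer(breakpoint),
    tsd_len = tsd$tsd_len, tsd_identity = tsd$tsd_identity,
    tsd_left_start = tsd$tsd_left_start, tsd_left_end = tsd$tsd_left_end,
    tsd_right_start = tsd$tsd_right_start, tsd_right_end = tsd$tsd_right_end,
    target_identity = aln$identity_pct, overhang_5p = overhang_5p,
    gap_3p = tsd$gap_3p, priming_length = as.integer(priming),
    rm_id = hit$rm_id, duplicate_of = NA_character_, accepted = TRUE,
    failed_rule = NA_character_, value = NA_real_
  )
}
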