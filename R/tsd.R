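# TSD detection around a masked hit.
#
# All work happens in "element orientation": for a minus-strand hit the
# flanking windows are reverse-complemented so that the 5' flank always
# precedes the element. TSD copies are direct repeats on the chromosome, so
# reverse-complementing both windows preserves their relationship. Reported
# spans are genomic (left_* is the copy 5' of the element on the chromosome).

# fetch the sequence for a hit's chromosome
chrom_seq <- function(genome, name) {
  i <- match(name, genome$name)
  if (is.na(i)) stop("query sequence '", name, "' not found in genome")
  genome$seq[i]
}

#' Find the target site duplication flanking a masked hit
#'
#' Aligns the 5' flanking window of a hit against its 3' flanking window with
#' the local TSD scoring scheme ([tsd_scheme()]); a TSD is reported when the
#' aligned block has length `tsd_min_len..tsd_max_len` and identity at least
#' `tsd_min_identity`. Windows are `tsd_search_window` nt long, clipped at
#' contig ends; `end_overlap` lets the downstream window reach into the
#' element's 3' end (the priming-site overlap used by the census).
#'
#' @param hit a one-row tibble as produced by [read_rmout()].
#' @param genome a tibble of sequences from [read_fasta()].
#' @param cfg a [filter_config()].
#' @param end_overlap nt of allowed overlap of the downstream window with the
#'   element's 3' end (default 0).
#' @return a one-row tibble (`tsd_len`, `tsd_identity`, `gap_3p`, genomic
#'   spans of both copies, element-oriented copy sequences) or `NULL` when no
#'   qualifying TSD exists.
#' @export
find_tsds <- function(hit, genome, cfg = filter_config(), end_overlap = 0L) {
  seq <- chrom_seq(genome, hit$query_name)
  L <- nchar(seq)
  if (hit$query_start < 1 || hit$query_end > L) {
    stop("hit lies outside its query sequence")
  }
  W <- cfg$tsd_search_window
  qs <- hit$query_start; qe <- hit$query_end

  if (hit$strand == "+") {
    up_g <- c(max(1L, qs - W), qs - 1L)
    down_g <- c(max(1L, qe + 1L - end_overlap), min(L, qe + W))
    up_seq <- subseq_clip(seq, up_g[1], up_g[2])
    down_seq <- subseq_clip(seq, down_g[1], down_g[2])
  } else {
    up_g <- c(qe + 1L, min(L, qe + W))
    down_g <- c(max(1L, qs - W), min(L, qs - 1L + end_overlap))
    up_seq <- revcomp(subseq_clip(seq, up_g[1], up_g[2]))
    down_seq <- revcomp(subseq_clip(seq, down_g[1], down_g[2]))
  }
  if (!nzchar(up_seq) || !nzchar(down_seq)) return(NULL)

  aln <- smith_waterman(up_seq, down_seq, tsd_scheme())
  if (aln$score <= 0 || aln$n_columns < cfg$tsd_min_len ||
      aln$n_columns > cfg$tsd_max_len ||
      aln$identity_pct < 100 * cfg$tsd_min_identity) {
    return(NULL)
  }

  # map window spans back to genomic coordinates
  if (hit$strand == "+") {
    left_span <- c(up_g[1] + aln$a_start - 1L, up_g[1] + aln$a_end - 1L)
    right_span <- c(down_g[1] + aln$b_start - 1L, down_g[1] + aln$b_end - 1L)
  } else {
    # windows were reverse-complemented: position p maps to g_end - p + 1;
    # the element-5' copy sits genomically right of the element
    right_span <- c(up_g[2] - aln$a_end + 1L, up_g[2] - aln$a_start + 1L)
    left_span <- c(down_g[2] - aln$b_end + 1L, down_g[2] - aln$b_start + 1L)
  }
  # nt between the element 3' terminus and the downstream TSD copy start
  gap_3p <- aln$b_start - 1L - as.integer(end_overlap)

  tibble::tibble(
    tsd_len = aln$n_columns,
    tsd_identity = aln$identity_pct,
    gap_3p = max(0L, gap_3p),
    tsd_left_start = left_span[1], tsd_left_end = left_span[2],
    tsd_right_start = right_span[1], tsd_right_end = right_span[2],
    tsd_5p_seq = substr(up_seq, aln$a_start, aln$a_end),
    tsd_3p_seq = substr(down_seq, aln$b_start, aln$b_end)
  )
}
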