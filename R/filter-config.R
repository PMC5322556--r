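#' Filter thresholds of the tailless screen
#'
#' Every numeric threshold of the cascade in one place. The defaults are the
#' screen's published operating point:
#'
#' * `max_5p_overhang` (5 nt): a hit must be 5'-(almost) complete, at most
#'   this many consensus nucleotides missing/overhanging at the 5' end.
#' * `min_3p_truncation` (10 nt): at least this many consensus nucleotides
#'   missing at the 3' end ("tailless").
#' * `tsd_min_len`/`tsd_max_len` (8/35 nt): accepted TSD length range.
#' * `tsd_min_identity` (0.70): minimum TSD pair identity (inclusive).
#' * `min_target_identity` (0.69): identity of the hit to its source-RNA
#'   consensus must *exceed* this (strictly greater, "more than 69%").
#' * `max_gap_3p` (15 nt): allowed gap between the 3' element terminus and
#'   the start of the downstream TSD copy.
#' * `min_element_len` (30 nt): minimal length of a tailless retropseudogene.
#' * `trna_5p_slack` (20 nt): relaxed 5' allowance for tRNA-derived hits
#'   (precursor sequences may precede the mature tRNA).
#' * `dup_flank_len` (100 nt) / `dup_min_identity` (0.70): a genomic
#'   duplication is called when TSDs plus ~100-nt flanks are >= 70% identical.
#' * `tsd_search_window` (50 nt): how far each flank is scanned for TSD
#'   copies; covers the 35 nt maximal TSD plus the 15 nt gap allowance.
#'
#' @param max_5p_overhang,min_3p_truncation,tsd_min_len,tsd_max_len,max_gap_3p,min_element_len,trna_5p_slack,dup_flank_len,tsd_search_window lengths in nt.
#' @param tsd_min_identity,min_target_identity,dup_min_identity fractions in `[0, 1]`.
#' @return a validated `filter_config` list.
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$tsd_min_len
filter_config <- function(max_5p_overhang = 5L, min_3p_truncation = 10L,
                          tsd_min_len = 8L, tsd_max_len = 35L,
                          tsd_min_identity = 0.70, min_target_identity = 0.69,
                          max_gap_3p = 15L, min_element_len = 30L,
                          trna_5p_slack = 20L, dup_flank_len = 100L,
                          dup_min_identity = 0.70, tsd_search_window = 50L) {
  cfg <- list(
    max_5p_overhang = as.integer(max_5p_overhang),
    min_3p_truncation = as.integer(min_3p_truncation),
    tsd_min_len = as.integer(tsd_min_len), tsd_max_len = as.integer(tsd_max_len),
    tsd_min_identity = tsd_min_identity,
    min_target_identity = min_target_identity,
    max_gap_3p = as.integer(max_gap_3p),
    min_element_len = as.integer(min_element_len),
    trna_5p_slack = as.integer(trna_5p_slack),
    dup_flank_len = as.integer(dup_flank_len),
    dup_min_identity = dup_min_identity,
    tsd_search_window = as.integer(tsd_search_window)
  )
  lens <- cfg[c("max_5p_overhang", "min_3p_truncation", "tsd_min_len",
                "tsd_max_len", "max_gap_3p", "min_element_len", "trna_5p_slack",
                "dup_flank_len", "tsd_search_window")]
  if (any(unlist(lens) < 0)) stop("all lengths must be >= 0")
  if (cfg$tsd_min_len > cfg$tsd_max_len) stop("tsd_min_len must be <= tsd_max_len")
  fracs <- unlist(cfg[c("tsd_min_identity", "min_target_identity", "dup_min_identity")])
  if (any(fracs < 0 | fracs > 1)) stop("identity thresholds must be fractions in [0, 1]")
  structure(cfg, class = "filter_config")
}
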