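#' Census of elements by 5'/3' completeness
#'
#' Classifies TSD-confirmed repeat hits into four mutually exclusive
#' categories. The 5' end is *full* when at most `slack_5p` consensus nt are
#' missing (the boundary case of exactly `slack_5p` counts as full) and
#' *truncated* otherwise; the 3' end is *full* when at most `slack_3p` nt are
#' missing and *tailless* when at least `min_3p_tailless` are. With the
#' defaults (5/9/10) the two 3' rules partition all hits. Only hits with a
#' confirmed TSD are censused: length 8-35 nt, identity >= 70%, with the
#' downstream search window allowed to overlap the element's 3' end by up to
#' `end_overlap` nt (the priming site).
#'
#' @param rm_hits tibble from [read_rmout()].
#' @param genome tibble from [read_fasta()].
#' @param cfg a [filter_config()] (TSD length/identity bounds and window).
#' @param slack_5p,slack_3p,min_3p_tailless,end_overlap census rule bounds in nt.
#' @return an `element_census` object; [tidy()] gives the per-hit label
#'   table, [glance()] the category counts (`n_full_length`,
#'   `n_5p_truncated_3p_full`, `n_5p_full_3p_tailless`,
#'   `n_5p_and_3p_truncated`, `n_no_tsd`).
#' @export
census_elements <- function(rm_hits, genome, cfg = filter_config(),
                            slack_5p = 5L, slack_3p = 9L, min_3p_tailless = 10L,
                            end_overlap = 20L) {
  label_one <- function(i) {
    hit <- rm_hits[i, ]
    tsd <- find_tsds(hit, genome, cfg, end_overlap = end_overlap)
    if (is.null(tsd)) return("no_tsd")
    p5_full <- (hit$repeat_start - 1L) <= slack_5p
    p3_full <- hit$repeat_left <= slack_3p
    p3_tailless <- hit$repeat_left >= min_3p_tailless
    if (p5_full && p3_full) "full_length"
    else if (!p5_full && p3_full) "5p_truncated_3p_full"
    else if (p5_full && p3_tailless) "5p_full_3p_tailless"
    else "5p_and_3p_truncated"
  }
  labels <- if (nrow(rm_hits)) {
    vapply(seq_len(nrow(rm_hits)), label_one, character(1))
  } else character(0)

  out <- dplyr::select(rm_hits, "query_name", "query_start", "query_end",
                       "strand", "repeat_name", "repeat_start", "repeat_end",
                       "repeat_left", "rm_id")
  out$category <- labels
  structure(list(labels = out), class = "element_census")
}

#' @rdname census_elements
#' @param x an `element_census` object.
#' @param ... unused.
#' @export
tidy.element_census <- function(x, ...) x$labels

#' @rdname census_elements
#' @export
glance.element_census <- function(x, ...) {
  n <- function(cat) sum(x$labels$category == cat)
  tibble::tibble(
    n_full_length = n("full_length"),
    n_5p_truncated_3p_full = n("5p_truncated_3p_full"),
    n_5p_full_3p_tailless = n("5p_full_3p_tailless"),
    n_5p_and_3p_truncated = n("5p_and_3p_truncated"),
    n_no_tsd = n("no_tsd")
  )
}

#' @export
print.element_census <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Select uninterrupted full-length elements
#'
#' Potentially active full-length elements (e.g. L1 and HAL1): uninterrupted
#' hits (unique repeat ID) with at most `max_end_slack` nt of nonmatching
#' sequence at each of the 5' and 3' consensus ends.
#'
#' @param rm_hits tibble from [read_rmout()].
#' @param max_end_slack nt of allowed nonmatching sequence per end.
#' @return the qualifying subset of `rm_hits`.
#' @export
find_full_length <- function(rm_hits, max_end_slack = 20L) {
  kept <- exclude_interrupted(rm_hits)$kept
  kept[(kept$repeat_start - 1L) <= max_end_slack &
         kept$repeat_left <= max_end_slack, ]
}
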