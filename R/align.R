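#' Alignment scoring schemes
#'
#' `scoring_scheme()` bundles the parameters of a pairwise alignment scoring
#' model. `tsd_scheme()` is the local (Smith-Waterman) scheme used for TSD
#' identification: match +8, mismatch -17, gap penalty -25 (a single gap
#' penalty, i.e. linear gaps: `gap_open == gap_extend`). `consensus_scheme()`
#' is the global (Needleman-Wunsch) scheme used to align a genomic hit to its
#' source-RNA consensus: match +7, mismatch -5, gap opening -25, gap
#' extension -3. A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' By default any pairing involving `N` scores 0. A full 5x5 substitution
#' table over `A,C,G,T,N` (e.g. from [read_score_matrix()]) can replace the
#' match/mismatch scores.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open score of the first column of a gap (must be <= 0).
#' @param gap_extend score of each further gap column (gap_open <= gap_extend <= 0).
#' @param matrix optional symmetric 5x5 integer matrix over `A,C,G,T,N`.
#' @return a `scoring_scheme` list.
#' @export
#' @examples
#' tsd_scheme()
#' scoring_scheme(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
scoring_scheme <- function(match, mismatch, gap_open, gap_extend = gap_open,
                           matrix = NULL) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0)
  if (!is.null(matrix)) {
    stopifnot(is.matrix(matrix), nrow(matrix) == 5, ncol(matrix) == 5)
    if (!isTRUE(all.equal(unname(matrix), unname(t(matrix))))) {
      stop("substitution matrix must be symmetric")
    }
    storage.mode(matrix) <- "integer"
  }
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         matrix = matrix),
    class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
tsd_scheme <- function(matrix = NULL) {
  scoring_scheme(match = 8, mismatch = -17, gap_open = -25, gap_extend = -25,
                 matrix = matrix)
}

#' @rdname scoring_scheme
#' @export
consensus_scheme <- function(matrix = NULL) {
  scoring_scheme(match = 7, mismatch = -5, gap_open = -25, gap_extend = -3,
                 matrix = matrix)
}

new_alignment <- function(raw, local) {
  states <- strsplit(raw$states, "", fixed = TRUE)[[1]]
  ncol <- length(states)
  nmatch <- sum(states == "M")
  structure(
    list(score = raw$score,
         a_start = raw$a_start, a_end = raw$a_end,
         b_start = raw$b_start, b_end = raw$b_end,
         states = raw$states,
         n_columns = ncol, n_matches = nmatch,
         identity_pct = if (ncol) 100 * nmatch / ncol else 0,
         local = local),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(if (x$local) "Local" else "Global", "alignment: score", x$score,
      sprintf("identity %.1f%% over %d columns\n", x$identity_pct, x$n_columns),
      sprintf("a[%d..%d] ~ b[%d..%d]\n", x$a_start, x$a_end, x$b_start, x$b_end))
  invisible(x)
}

check_align_input <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("alignment inputs must be single non-empty strings")
  }
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    stop("alignment inputs must be uppercase DNA over {A,C,G,T,N}")
  }
}

#' Smith-Waterman local alignment
#'
#' Exact local alignment by dynamic programming under a [scoring_scheme()].
#' Returns the maximal-scoring local alignment; among equal-scoring optima the
#' one with the smallest end coordinate in `a`, then in `b`, is reported.
#' When no positive-scoring pairing exists the result is the empty alignment
#' (score 0, zero-length spans).
#'
#' @param a,b uppercase DNA strings.
#' @param scheme a [scoring_scheme()]; defaults to the TSD screen's scheme.
#' @return a `pairwise_alignment`: `score`, 1-based inclusive spans
#'   `a_start..a_end` / `b_start..b_end`, a column `states` string over
#'   `M` (match), `X` (mismatch), `A` (gap in a), `B` (gap in b), and
#'   `identity_pct` = matches / aligned columns x 100.
#' @export
#' @examples
#' smith_waterman("ACGT", "ACGT")$score  # 32
smith_waterman <- function(a, b, scheme = tsd_scheme()) {
  check_align_input(a, b)
  raw <- .gotoh_align(a, b, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend,
                      local = TRUE, matrix = scheme$matrix)
  new_alignment(raw, local = TRUE)
}

#' Needleman-Wunsch global alignment
#'
#' Exact global alignment with affine gaps: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @inheritParams smith_waterman
#' @param scheme a [scoring_scheme()]; defaults to the consensus-alignment
#'   scheme.
#' @return a `pairwise_alignment` (see [smith_waterman()]); spans always cover
#'   both inputs fully.
#' @export
#' @examples
#' needleman_wunsch("ACGT", "ACGT")$score  # 28
needleman_wunsch <- function(a, b, scheme = consensus_scheme()) {
  check_align_input(a, b)
  raw <- .gotoh_align(a, b, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend,
                      local = FALSE, matrix = scheme$matrix)
  new_alignment(raw, local = FALSE)
}
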