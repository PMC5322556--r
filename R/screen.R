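#' Exclude interrupted elements
#'
#' Elements split by a later insertion appear as several RepeatMasker hits
#' sharing one repeat-specific ID; such fragments masquerade as truncated
#' elements and are removed wholesale.
#'
#' @param hits tibble from [read_rmout()].
#' @return a list with tibbles `kept` (unique `rm_id`) and `excluded` (every
#'   hit whose `rm_id` occurs more than once), input order preserved.
#' @export
exclude_interrupted <- function(hits) {
  if (!nrow(hits)) return(list(kept = hits, excluded = hits))
  dup_ids <- unique(hits$rm_id[duplicated(hits$rm_id)])
  is_dup <- hits$rm_id %in% dup_ids
  list(kept = hits[!is_dup, ], excluded = hits[is_dup, ])
}

#' Collapse same-region hits and remove genomic duplications
#'
#' Two passes: (1) candidates whose genomic loci overlap (e.g. the same locus
#' matched by several tRNA consensuses) are collapsed to the one with the
#' highest consensus identity, ties going to the leftmost locus; (2) each
#' remaining pair is compared by Smith-Waterman over the concatenation of
#' both TSD copies with `dup_flank_len` nt of flanking sequence on each side;
#' when the aligned matches cover at least `dup_min_identity` of the longer
#' region, the later-coordinate member is marked as a duplication of the
#' earlier one and moved off the primary list.
#'
#' @param cands accepted candidate tibble (see [classify_candidate()]).
#' @param genome tibble from [read_fasta()].
#' @param cfg a [filter_config()].
#' @return list with tibbles `primary` (sorted by locus, `duplicate_of` `NA`)
#'   and `duplicates` (`duplicate_of` = `chrom:start-end` of the retained
#'   copy).
#' @export
deduplicate <- function(cands, genome, cfg = filter_config()) {
  if (!nrow(cands)) return(list(primary = cands, duplicates = cands[0, ]))
  cands <- dplyr::arrange(cands, .data$chrom, .data$start, .data$end)

  # pass 1: collapse overlapping loci
  keep <- rep(TRUE, nrow(cands))
  grp <- integer(nrow(cands))
  gid <- 0L; last_chrom <- ""; last_end <- -1L
  for (i in seq_len(nrow(cands))) {
    if (cands$chrom[i] != last_chrom || cands$start[i] > last_end) {
      gid <- gid + 1L
      last_chrom <- cands$chrom[i]; last_end <- cands$end[i]
    } else {
      last_end <- max(last_end, cands$end[i])
    }
    grp[i] <- gid
  }
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      best <- idx[order(-cands$target_identity[idx], cands$start[idx], cands$end[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  cands <- cands[keep, ]

  # pass 2: genomic duplications via TSD + flank comparison
  n <- nrow(cands)
  dup_of <- rep(NA_character_, n)
  if (n > 1L) {
    regions <- vapply(seq_len(n), function(i) dup_region(cands[i, ], genome, cfg),
                      character(1))
    for (i in seq_len(n - 1L)) {
      if (!is.na(dup_of[i])) next
      for (j in seq((i + 1L), n)) {
        if (!is.na(dup_of[j])) next
        aln <- smith_waterman(regions[i], regions[j], tsd_scheme())
        cov_identity <- aln$n_matches / max(nchar(regions[i]), nchar(regions[j]))
        if (cov_identity >= cfg$dup_min_identity) {
          dup_of[j] <- sprintf("%s:%d-%d", cands$chrom[i], cands$start[i], cands$end[i])
        }
      }
    }
  }
  dups <- cands[!is.na(dup_of), ]
  dups$duplicate_of <- dup_of[!is.na(dup_of)]
  list(primary = cands[is.na(dup_of), ], duplicates = dups)
}

# TSD copies plus dup_flank_len nt of outside flank on each side, concatenated
dup_region <- function(cand, genome, cfg) {
  seq <- chrom_seq(genome, cand$chrom)
  left <- subseq_clip(seq, cand$tsd_left_start - cfg$dup_flank_len, cand$tsd_left_end)
  right <- subseq_clip(seq, cand$tsd_right_start, cand$tsd_right_end + cfg$dup_flank_len)
  paste0(left, right)
}

#' Flag hits followed by simple repeats or low-complexity runs
#'
#' Used to search for oligoadenylated (tailed) forms: a hit is flagged when a
#' `Simple_repeat` or `Low_complexity` annotation begins within `window` nt
#' after the hit's 3' end (strand-aware).
#'
#' @param hits tibble from [read_rmout()].
#' @param annotations tibble with columns `query_name`, `start`, `end`,
#'   `class`.
#' @param window nt of allowed gap between element end and annotation start.
#' @return the flagged subset of `hits`.
#' @export
flag_oligoadenylated <- function(hits, annotations, window = 5L) {
  if (!nrow(hits)) return(hits)
  ann <- annotations[annotations$class %in% c("Simple_repeat", "Low_complexity"), ]
  flagged <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    a <- ann[ann$query_name == h$query_name, ]
    if (!nrow(a)) return(FALSE)
    gap <- if (h$strand == "+") a$start - h$query_end - 1L else h$query_start - a$end - 1L
    any(gap >= 0L & gap <= window)
  }, logical(1))
  hits[flagged, ]
}

#' Screen a genome for tailless retropseudogenes
#'
#' The full cascade: interrupted-element exclusion, per-hit classification
#' (with the relaxed 5' slack for hits whose `repeat_class` matches
#' `relaxed_classes`), and deduplication of same-region hits and genomic
#' duplications.
#'
#' @param genome tibble from [read_fasta()].
#' @param rm_hits tibble from [read_rmout()].
#' @param rna_library tibble from [read_rna_library()].
#' @param cfg a [filter_config()].
#' @param relaxed_classes repeat classes screened with the relaxed tRNA mode
#'   (matched against `repeat_class` by substring, e.g. `"tRNA"` matches
#'   `"tRNA/..."`).
#' @return a `tailless_screen` object: list with `candidates` (accepted,
#'   deduplicated, locus-sorted), `duplicates`, `rejections` and
#'   `excluded_interrupted` tibbles plus the `config`. [tidy()] returns the
#'   candidate tibble, [glance()] one row of per-stage counts.
#' @export
screen_genome <- function(genome, rm_hits, rna_library, cfg = filter_config(),
                          relaxed_classes = "tRNA") {
  parts <- exclude_interrupted(rm_hits)
  kept <- parts$kept

  rows <- purrr::map(seq_len(nrow(kept)), function(i) {
    hit <- kept[i, ]
    rna <- rna_library[rna_library$name == hit$repeat_name, ]
    relaxed <- any(vapply(relaxed_classes, function(cl)
      grepl(cl, hit$repeat_class, fixed = TRUE), logical(1)))
    classify_candidate(hit, rna, genome, cfg, relaxed_trna = relaxed)
  })
  classified <- if (length(rows)) dplyr::bind_rows(rows) else candidate_schema()

  accepted <- classified[classified$accepted, ]
  rejections <- classified[!classified$accepted, ]
  dedup <- deduplicate(accepted, genome, cfg)

  structure(
    list(candidates = dedup$primary, duplicates = dedup$duplicates,
         rejections = rejections, excluded_interrupted = parts$excluded,
         config = cfg),
    class = "tailless_screen")
}

#' @export
print.tailless_screen <- function(x, ...) {
  cat("Tailless retropseudogene screen\n",
      "  candidates: ", nrow(x$candidates), "\n",
      "  genomic duplications: ", nrow(x$duplicates), "\n",
      "  rejections: ", nrow(x$rejections), "\n",
      "  interrupted hits excluded: ", nrow(x$excluded_interrupted), "\n", sep = "")
  invisible(x)
}

#' @rdname screen_genome
#' @param x a `tailless_screen` object.
#' @param ... unused.
#' @export
tidy.tailless_screen <- function(x, ...) {
  dplyr::select(x$candidates, -"accepted", -"failed_rule", -"value")
}

#' @rdname screen_genome
#' @export
glance.tailless_screen <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_duplicates = nrow(x$duplicates),
    n_rejected = nrow(x$rejections),
    n_interrupted_excluded = nrow(x$excluded_interrupted)
  )
}

#' Rejection table of a screen
#'
#' @param screen a `tailless_screen` object.
#' @return tibble with `chrom`, `start`, `end`, `failed_rule`, `value`.
#' @export
rejections <- function(screen) {
  dplyr::select(screen$rejections, "chrom", "start", "end", "failed_rule", "value")
}
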