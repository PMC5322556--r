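# Deterministic in-code fixtures: a small RNA-gene library (5S rRNA-like,
# tRNA-like, U2-like) with a hand-built valid secondary structure for the
# 5S-like gene, plus convenience builders for hand-crafted genomes and hits.

rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# structure: two stems with loops and single-stranded tails, length 120
r5s_structure <- function() {
  paste0(strrep("(", 15), strrep(".", 20), strrep(")", 15),
         strrep(".", 15), strrep("(", 10), strrep(".", 10), strrep(")", 10),
         strrep(".", 25))
}

fixture_rna_library <- function() {
  tibble::tibble(
    name = c("r5S", "tRNA-Ala", "U2"),
    seq = c(rand_seq(120, 101), rand_seq(72, 102), rand_seq(190, 103)),
    length = c(120L, 72L, 190L),
    structure = c(r5s_structure(), NA_character_, NA_character_),
    class = c("rRNA/5S", "tRNA/Ala", "snRNA/U2")
  )
}

# genome with one hand-planted insertion: [bg][pre2][tsd][insert][gap][tsd2][bg]
# returns the genome tibble plus the hit row describing the insert
hand_genome <- function(insert, tsd, tsd2 = tsd, pre2 = "TT", gap = "",
                        repeat_name = "r5S", repeat_start = 1L,
                        repeat_end = nchar(insert), repeat_left = 10L,
                        strand = "+", bg_seed = 500, bg = 80L) {
  left_bg <- rand_seq(bg, bg_seed)
  right_bg <- rand_seq(bg, bg_seed + 1L)
  top <- paste0(left_bg, pre2, tsd, insert, gap, tsd2, right_bg)
  qs <- nchar(left_bg) + nchar(pre2) + nchar(tsd) + 1L
  qe <- qs + nchar(insert) - 1L
  if (strand == "-") {
    L <- nchar(top)
    top <- revcomp(top)
    tmp <- qs
    qs <- L - qe + 1L
    qe <- L - tmp + 1L
  }
  genome <- tibble::tibble(name = "chrT", seq = top)
  hit <- tibble::tibble(
    sw_score = 8L * nchar(insert), divergence_pct = 0, deletion_pct = 0,
    insertion_pct = 0, query_name = "chrT", query_start = qs, query_end = qe,
    query_left = nchar(genome$seq) - qe, strand = strand,
    repeat_name = repeat_name, repeat_class = "rRNA/5S",
    repeat_start = as.integer(repeat_start), repeat_end = as.integer(repeat_end),
    repeat_left = as.integer(repeat_left), rm_id = 1L)
  list(genome = genome, hit = hit)
}

# random hit table for round-trip tests (one-decimal percentages: the .out
# dialect prints one decimal)
random_hits <- function(n, seed) {
  withr::with_seed(seed, {
    start <- sample.int(1e6, n)
    len <- sample(50:500, n, replace = TRUE)
    rs <- sample.int(50, n)
    re <- rs + sample(30:200, n, replace = TRUE)
    tibble::tibble(
      sw_score = sample.int(5000, n),
      divergence_pct = round(stats::runif(n, 0, 30), 1),
      deletion_pct = round(stats::runif(n, 0, 10), 1),
      insertion_pct = round(stats::runif(n, 0, 10), 1),
      query_name = sample(c("chr1", "chr2"), n, replace = TRUE),
      query_start = start, query_end = start + len,
      query_left = sample.int(1e5, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      repeat_name = sample(c("r5S", "U2", "tRNA-Ala"), n, replace = TRUE),
      repeat_class = sample(c("rRNA/5S", "snRNA/U2"), n, replace = TRUE),
      repeat_start = rs, repeat_end = re,
      repeat_left = sample.int(100, n), rm_id = seq_len(n))
  })
}

# a mixed plant set: n_ok conforming insertions plus the standard 20-decoy mix
standard_plant_set <- function(lib, n_ok = 50L) {
  rnas <- c("r5S", "tRNA-Ala", "U2")
  lens <- setNames(lib$length, lib$name)
  ok <- purrr::map_dfr(seq_len(n_ok), function(i) {
    rna <- rnas[(i %% 3L) + 1L]
    # breakpoints leave >= 10 nt truncated and >= 30 nt of element
    bp <- 30L + (i * 7L) %% (lens[[rna]] - 45L)
    plant_spec(rna, truncation = bp,
               tsd_len = 10L + (i %% 12L),
               priming = min(bp %% 18L, 10L + (i %% 12L), lens[[rna]] - bp - 1L),
               strand = if (i %% 2L == 0L) "+" else "-",
               overhang_5p = if (rna == "tRNA-Ala" && i %% 5L == 0L) 15L else 0L,
               gap_3p = if (i %% 7L == 0L) 5L else 0L)
  })
  decoys <- dplyr::bind_rows(
    purrr::map_dfr(1:5, function(i) plant_spec("r5S", truncation = 20L + i,
                                               decoy_class = "short")),
    purrr::map_dfr(1:5, function(i) plant_spec("U2", truncation = 190L,
                                               decoy_class = "tailed")),
    purrr::map_dfr(1:4, function(i) plant_spec("U2", truncation = 80L + 10L * i,
                                               decoy_class = "interrupted")),
    purrr::map_dfr(1:4, function(i) plant_spec("r5S", truncation = 60L + 5L * i,
                                               tsd_len = 12L, tsd_mut = 4L,
                                               decoy_class = "low_tsd_identity")),
    purrr::map_dfr(1:2, function(i) plant_spec("r5S", truncation = 90L,
                                               decoy_class = "duplicated"))
  )
  dplyr::bind_rows(ok, decoys)
}
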