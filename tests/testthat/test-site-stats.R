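# Motif matrices, logos, priming lengths, breakpoint and endpoint statistics.

lib <- fixture_rna_library()
r5s <- lib[lib$name == "r5S", ]

# accepted candidates from a simulation, without deduplication (classification
# only) -- convenient for motif statistics on many plants
classified_candidates <- function(sim) {
  kept <- exclude_interrupted(sim$hits)$kept
  rows <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    hit <- kept[i, ]
    classify_candidate(hit, lib[lib$name == hit$repeat_name, ], sim$genome,
                       relaxed_trna = grepl("tRNA", hit$repeat_class))
  })
  rows[rows$accepted, ]
}

test_that("uniform target sites give flat frequencies at the binomial scale", {
  specs <- purrr::map_dfr(1:150, function(i)
    plant_spec("r5S", truncation = 60, tsd_len = 12, motif = "NNNNNNNNN"))
  sim <- generate_genome(specs, lib, background_length = 80000, seed = 81)
  cands <- classified_candidates(sim)
  expect_gt(nrow(cands), 100)
  pfm <- target_site_matrix(cands, sim$genome)
  t1 <- tidy(pfm)
  # three binomial standard errors around 0.25 for fully-counted columns
  full <- t1[t1$present >= 0.9 * pfm$n_sequences, ]
  se <- sqrt(0.25 * 0.75 / pfm$n_sequences)
  expect_true(all(abs(full$freq - 0.25) < 3.5 * se))
})

test_that("deterministic target sites give frequency-1 letters", {
  # all sites literally TT | GATCCAGTTACG
  tsd <- "GATCCAGTTACG"
  insert <- substr(r5s$seq, 1, 60)
  hg <- hand_genome(insert, tsd)
  cand <- classify_candidate(hg$hit, r5s, hg$genome)
  expect_true(cand$accepted)
  pfm <- target_site_matrix(cand, hg$genome)
  logo <- information_logo(pfm)
  expected <- strsplit(paste0("TT", tsd), "", fixed = TRUE)[[1]]
  argmax <- tidy(pfm) |>
    dplyr::group_by(position) |>
    dplyr::slice_max(freq, n = 1) |>
    dplyr::pull(base)
  expect_equal(argmax, expected)
  expect_true(all(logo$ic[logo$freq == 1] == 2))
})

test_that("only candidates with perfect TSDs enter the target-site matrix", {
  tsd <- "GATCCAGTTACG"
  mut <- "GATCTAGTTACG"  # one substitution: identity 11/12
  insert <- substr(r5s$seq, 1, 60)
  clean <- classify_candidate(hand_genome(insert, tsd)$hit,
                              r5s, hand_genome(insert, tsd)$genome)
  degraded_hg <- hand_genome(insert, tsd, tsd2 = mut, bg_seed = 510)
  degraded <- classify_candidate(degraded_hg$hit, r5s, degraded_hg$genome)
  expect_true(degraded$accepted)
  expect_lt(degraded$tsd_identity, 100)
  hg <- hand_genome(insert, tsd)
  pfm <- target_site_matrix(dplyr::bind_rows(clean, degraded), hg$genome)
  expect_equal(pfm$n_sequences, 1L)
  expect_error(target_site_matrix(degraded, hg$genome), "perfect TSDs")
})

test_that("breakpoint context columns surround the breakpoint, with boundary skips", {
  cand <- tibble::tibble(source_rna = "r5S", breakpoint = 60L)
  pfm <- breakpoint_context_matrix(cand, lib)
  expect_equal(pfm$width, 10L)
  window <- strsplit(substr(r5s$seq, 56, 65), "", fixed = TRUE)[[1]]
  for (col in 1:10) {
    expect_equal(sum(pfm$counts[, col]), 1L)
    expect_equal(unname(pfm$counts[window[col], col]), 1L)
  }
  # breakpoint at position 3: positions -1 and 0 (columns 1-2) are skipped
  edge <- breakpoint_context_matrix(tibble::tibble(source_rna = "r5S",
                                                   breakpoint = 3L), lib)
  expect_equal(edge$present, c(0L, 0L, rep(1L, 8L)))
})

test_that("information content follows the hand-computed entropies", {
  # a column with frequencies (.5, .25, .125, .125): IC = 2 - 1.75 bits
  counts <- matrix(c(4L, 2L, 1L, 1L), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  mixed <- structure(list(counts = counts, present = 8L, n_sequences = 8L,
                          width = 1L), class = "pfm")
  logo <- information_logo(mixed)
  expect_equal(unique(logo$ic), 0.25)
  expect_equal(logo$height[logo$base == "A"], 0.5 * 0.25)

  uniform <- structure(list(counts = matrix(c(2L, 2L, 2L, 2L), 4,
                                            dimnames = list(c("A","C","G","T"), NULL)),
                            present = 8L, n_sequences = 8L, width = 1L),
                       class = "pfm")
  expect_equal(unique(information_logo(uniform)$ic), 0)

  single <- structure(list(counts = matrix(c(8L, 0L, 0L, 0L), 4,
                                           dimnames = list(c("A","C","G","T"), NULL)),
                           present = 8L, n_sequences = 8L, width = 1L),
                      class = "pfm")
  slogo <- information_logo(single)
  expect_equal(unique(slogo$ic), 2)
  expect_equal(slogo$height[slogo$base == "A"], 2)
})

test_that("priming-length summaries cover planted ranges", {
  expect_equal(priming_length_distribution(
    tibble::tibble(priming_length = c(0L, 0L, 4L)))[c("min", "max")],
    list(min = 0L, max = 4L))
  expect_error(priming_length_distribution(tibble::tibble(priming_length = integer())),
               "no candidates")

  specs <- purrr::map_dfr(2:18, function(p)
    plant_spec("r5S", truncation = 80, tsd_len = 20, priming = p))
  sim <- generate_genome(specs, lib, background_length = 20000, seed = 82)
  cands <- classified_candidates(sim)
  expect_equal(nrow(cands), 17)
  dist <- priming_length_distribution(cands)
  expect_equal(dist$min, 2L)
  expect_equal(dist$max, 18L)
})

test_that("breakpoint histograms count truncations and read the structure", {
  cands <- tibble::tibble(source_rna = "r5S", breakpoint = c(60L, 60L, 100L))
  bh <- breakpoint_histogram(cands, r5s)
  expect_equal(bh$counts$count[60], 2L)
  expect_equal(bh$counts$count[100], 1L)
  expect_equal(sum(bh$counts$count), 3L)
  # positions 60 and 100 are dots in the fixture structure
  expect_equal(bh$unpaired_fraction, 1)

  paired_pos <- which(structure_paired(r5s$structure))[1]
  bh2 <- breakpoint_histogram(tibble::tibble(source_rna = "r5S",
                                             breakpoint = paired_pos), r5s)
  expect_equal(bh2$unpaired_fraction, 0)

  bad <- r5s; bad$structure <- "((..))"
  expect_error(breakpoint_histogram(cands, bad), "length")
})

test_that("endpoint counting keeps only 5'-complete alignments", {
  aln <- tibble::tibble(name = c("r5S", "r5S", "r5S", "U2"),
                        start = c(1L, 2L, 1L, 1L),
                        end = c(60L, 60L, 90L, 100L))
  freq <- endpoint_frequencies(aln)
  expect_equal(freq$n[freq$name == "r5S" & freq$end == 60], 1L)
  expect_equal(freq$n[freq$name == "r5S" & freq$end == 90], 1L)
  expect_equal(freq$n[freq$name == "U2"], 1L)
  expect_equal(nrow(endpoint_frequencies(aln[0, ])), 0)
  # one-line filter-and-count oracle on a random set
  withr::with_seed(83, {
    rnd <- tibble::tibble(name = "X", start = sample(1:3, 50, TRUE),
                          end = sample(50:52, 50, TRUE))
    freq2 <- endpoint_frequencies(rnd)
    oracle <- table(rnd$end[rnd$start == 1])
    expect_equal(setNames(freq2$n, freq2$end), setNames(as.integer(oracle),
                                                        names(oracle)))
  })
})

test_that("per-gigabase densities normalize and round as printed", {
  expect_equal(per_gigabase(100, 1e9)$per_gb, 100)
  expect_equal(per_gigabase(0, 5e8)$per_gb, 0)
  expect_equal(per_gigabase(555, 2.861e9)$per_gb_rounded, 194)
  expect_error(per_gigabase(10, 0), "> 0")
})
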