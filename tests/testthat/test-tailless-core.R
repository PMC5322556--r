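# The filter cascade: TSD detection, per-hit classification, interruption
# exclusion, deduplication, oligo(A) flagging, and the orchestrated screen.

lib <- fixture_rna_library()
r5s <- lib[lib$name == "r5S", ]
cfg <- filter_config()

test_that("a planted perfect 12 nt duplication is found with its span", {
  tsd <- "GATCCAGTTACG"
  insert <- substr(r5s$seq, 1, 60)
  hg <- hand_genome(insert, tsd)
  found <- find_tsds(hg$hit, hg$genome, cfg)
  expect_equal(found$tsd_len, 12L)
  expect_equal(found$tsd_identity, 100)
  expect_equal(found$gap_3p, 0L)
  # spans: left copy immediately 5' of the element, right copy 3' of it
  expect_equal(found$tsd_left_end, hg$hit$query_start - 1L)
  expect_equal(found$tsd_right_start, hg$hit$query_end + 1L)
  expect_equal(found$tsd_5p_seq, tsd)
})

test_that("TSD length and identity floors are enforced", {
  insert <- substr(r5s$seq, 1, 60)
  # 7 nt: one below the floor
  short <- hand_genome(insert, "GATCCAG")
  expect_null(find_tsds(short$hit, short$genome, cfg))
  # 12 nt pair degraded to 67% identity by scattered substitutions: below
  # the 70% floor, and no sub-block reaches both the length floor and the
  # identity floor
  mutated <- hand_genome(insert, "GATCCAGTTACG", tsd2 = "GAACCTGATACC")
  expect_null(find_tsds(mutated$hit, mutated$genome, cfg))
})

test_that("TSDs are recovered on minus-strand hits with genomic spans", {
  tsd <- "GATCCAGTTACG"
  insert <- substr(r5s$seq, 1, 60)
  hg <- hand_genome(insert, tsd, strand = "-")
  found <- find_tsds(hg$hit, hg$genome, cfg)
  expect_equal(found$tsd_len, 12L)
  expect_equal(found$tsd_identity, 100)
  # left span still genomically 5' of the hit
  expect_lt(found$tsd_left_end, hg$hit$query_start)
  expect_gt(found$tsd_right_start, hg$hit$query_end)
})

test_that("a hit outside the genome bounds is an error", {
  hg <- hand_genome(substr(r5s$seq, 1, 60), "GATCCAGTTACG")
  bad <- hg$hit
  bad$query_end <- nchar(hg$genome$seq) + 50L
  expect_error(find_tsds(bad, hg$genome, cfg), "outside")
})

test_that("the cascade accepts a clean truncated copy and reports its anatomy", {
  sim <- generate_genome(plant_spec("r5S", truncation = 60, tsd_len = 12,
                                    priming = 4),
                         lib, background_length = 5000, seed = 3)
  res <- classify_candidate(sim$hits[1, ], r5s, sim$genome, cfg)
  expect_true(res$accepted)
  expect_equal(res$breakpoint, 60L)
  expect_equal(res$tsd_len, 12L)
  expect_equal(res$priming_length, 4L)
  expect_equal(res$overhang_5p, 0L)
  expect_equal(res$gap_3p, 0L)
  expect_equal(res$target_identity, 100)
})

test_that("each cascade rule rejects with its own name, in order", {
  # too short an element
  sim <- generate_genome(plant_spec("r5S", truncation = 25, decoy_class = "short"),
                         lib, background_length = 5000, seed = 4)
  res <- classify_candidate(sim$hits[1, ], r5s, sim$genome, cfg)
  expect_false(res$accepted)
  expect_equal(res$failed_rule, "min_element_len")
  expect_equal(res$value, 25)

  # truncated by only 5 nt
  sim <- generate_genome(plant_spec("r5S", truncation = 115), lib,
                         background_length = 5000, seed = 5)
  res <- classify_candidate(sim$hits[1, ], r5s, sim$genome, cfg)
  expect_equal(res$failed_rule, "min_3p_truncation")
  expect_equal(res$value, 5)

  # 5' overhang beyond the default slack
  sim <- generate_genome(plant_spec("r5S", truncation = 80, overhang_5p = 6),
                         lib, background_length = 5000, seed = 6)
  res <- classify_candidate(sim$hits[1, ], r5s, sim$genome, cfg)
  expect_equal(res$failed_rule, "max_5p_overhang")
  expect_equal(res$value, 6)

  # unknown source RNA is an error, not a rejection
  sim <- generate_genome(plant_spec("r5S", truncation = 60), lib,
                         background_length = 5000, seed = 7)
  expect_error(classify_candidate(sim$hits[1, ], lib[lib$name == "U2", ],
                                  sim$genome, cfg), "not resolved")
})

test_that("relaxed tRNA mode widens only the 5' rule", {
  sim <- generate_genome(plant_spec("tRNA-Ala", truncation = 55, overhang_5p = 15),
                         lib, background_length = 5000, seed = 8)
  trna <- lib[lib$name == "tRNA-Ala", ]
  strict <- classify_candidate(sim$hits[1, ], trna, sim$genome, cfg)
  relaxed <- classify_candidate(sim$hits[1, ], trna, sim$genome, cfg,
                                relaxed_trna = TRUE)
  expect_equal(strict$failed_rule, "max_5p_overhang")
  expect_true(relaxed$accepted)
  expect_equal(relaxed$breakpoint, 55L)
})

test_that("interrupted-element exclusion partitions by repeat ID", {
  hits <- random_hits(10, 41)
  hits$rm_id <- c(1L, 2L, 3L, 3L, 4L, 5L, 3L, 6L, 7L, 8L)
  parts <- exclude_interrupted(hits)
  expect_equal(nrow(parts$kept), 7)
  expect_equal(nrow(parts$excluded), 3)
  expect_true(all(parts$excluded$rm_id == 3L))
  expect_equal(nrow(parts$kept) + nrow(parts$excluded), nrow(hits))
  # all-unique input excludes nothing
  parts2 <- exclude_interrupted(random_hits(5, 42))
  expect_equal(nrow(parts2$excluded), 0)
})

test_that("overlapping loci collapse to the highest consensus identity", {
  sim <- generate_genome(plant_spec("r5S", truncation = 60), lib,
                         background_length = 5000, seed = 9)
  cand <- classify_candidate(sim$hits[1, ], r5s, sim$genome, cfg)
  rival <- cand
  rival$source_rna <- "tRNA-Ala"
  rival$target_identity <- 80
  out <- deduplicate(dplyr::bind_rows(cand, rival), sim$genome, cfg)
  expect_equal(nrow(out$primary), 1)
  expect_equal(out$primary$source_rna, "r5S")
  expect_equal(nrow(out$duplicates), 0)
})

test_that("planted segmental duplications are flagged, unrelated loci are not", {
  sim <- generate_genome(
    dplyr::bind_rows(plant_spec("r5S", truncation = 90, decoy_class = "duplicated"),
                     plant_spec("U2", truncation = 100)),
    lib, background_length = 20000, seed = 10)
  scr <- screen_genome(sim$genome, sim$hits, lib, cfg)
  expect_equal(nrow(scr$candidates), 2)  # one r5S survivor + the U2 locus
  expect_equal(nrow(scr$duplicates), 1)
  expect_match(scr$duplicates$duplicate_of, "^synth1:")
})

test_that("oligo(A)-adjacency flagging is class- and window-aware", {
  hits <- random_hits(1, 51)
  hits$query_name <- "chr1"; hits$query_start <- 900L; hits$query_end <- 1000L
  hits$strand <- "+"
  ann <- tibble::tibble(query_name = "chr1", start = 1002L, end = 1020L,
                        class = "Simple_repeat")
  expect_equal(nrow(flag_oligoadenylated(hits, ann, window = 5L)), 1)
  # too far
  ann$start <- 1010L
  expect_equal(nrow(flag_oligoadenylated(hits, ann, window = 5L)), 0)
  # wrong class
  ann$start <- 1002L; ann$class <- "LINE/L1"
  expect_equal(nrow(flag_oligoadenylated(hits, ann, window = 5L)), 0)
  # minus strand: the 3' end is the genomic start
  hits$strand <- "-"
  ann <- tibble::tibble(query_name = "chr1", start = 870L, end = 897L,
                        class = "Low_complexity")
  expect_equal(nrow(flag_oligoadenylated(hits, ann, window = 5L)), 1)
})

test_that("the screen is deterministic and its accepted set obeys every bound", {
  sim <- generate_genome(standard_plant_set(lib, n_ok = 12L), lib,
                         background_length = 3e5, seed = 11)
  scr1 <- screen_genome(sim$genome, sim$hits, lib, cfg)
  scr2 <- screen_genome(sim$genome, sim$hits, lib, cfg)
  expect_identical(scr1$candidates, scr2$candidates)
  expect_identical(rejections(scr1), rejections(scr2))

  cand <- scr1$candidates
  expect_true(all(cand$tsd_len >= cfg$tsd_min_len & cand$tsd_len <= cfg$tsd_max_len))
  expect_true(all(cand$tsd_identity >= 100 * cfg$tsd_min_identity))
  expect_true(all(cand$target_identity > 100 * cfg$min_target_identity))
  expect_true(all(cand$gap_3p <= cfg$max_gap_3p))
  expect_true(all(cand$breakpoint >= cfg$min_element_len))
  expect_true(all(cand$overhang_5p <= cfg$trna_5p_slack))
  expect_true(all(cand$priming_length <= 20))
  # empty input gives empty output
  scr0 <- screen_genome(sim$genome, sim$hits[0, ], lib, cfg)
  expect_equal(nrow(scr0$candidates), 0)
  expect_equal(nrow(scr0$rejections), 0)
})

test_that("tightening any single threshold never gains candidates", {
  sim <- generate_genome(standard_plant_set(lib, n_ok = 12L), lib,
                         background_length = 3e5, seed = 12)
  base_n <- nrow(screen_genome(sim$genome, sim$hits, lib, cfg)$candidates)
  tighter <- list(
    filter_config(min_element_len = 60),
    filter_config(tsd_min_identity = 0.9),
    filter_config(max_5p_overhang = 2, trna_5p_slack = 2),
    filter_config(min_3p_truncation = 30),
    filter_config(max_gap_3p = 2),
    filter_config(min_target_identity = 0.95),
    filter_config(tsd_min_len = 14, tsd_max_len = 20))
  for (tcfg in tighter) {
    expect_lte(nrow(screen_genome(sim$genome, sim$hits, lib, tcfg)$candidates),
               base_n)
  }
})
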