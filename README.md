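# taillessr

Detection and analysis of **tailless retropseudogenes** — genomic copies of
cellular RNAs (tRNAs, 5S rRNA, U2 and other snRNAs, 7SK, mRNAs) that are
3′-truncated, carry **no oligo(A) tail**, and are flanked by target site
duplications (TSDs). They arise when the LINE1 (L1) machinery, instead of
engaging an RNA's polyadenylated 3′ end, primes target-primed reverse
transcription (TPRT) **internally** at an A-rich, usually single-stranded
region of the template. The tell-tale anatomy of such an insertion on the
chromosome is

```
5'-...TT | [TSD] [RNA 5'──────breakpoint] (gap ≤ 15 nt) [TSD'] ...-3'
         └ insertion-site consensus TT/WAAAAWW·X(0–17): the first bases of
           the duplication are complementary (bottom strand) to the RNA
           just beyond the breakpoint — the "priming length" X
```

The package is aimed at genome biologists studying retrotransposition: it
takes a RepeatMasker annotation of a genome masked against a user-supplied
RNA library and applies a TSD-anchored filter cascade to extract clean
insertions, then characterises them (insertion-site logos, breakpoint
hotspots vs. RNA secondary structure, priming-length distributions, element
censuses, per-gigabase densities) and maps presence/absence patterns onto a
species tree. A deterministic synthetic-genome generator with planted ground
truth makes every stage testable without a real genome.

## The screen

A masked hit becomes a candidate only if it passes, in order:

1. **5′ completeness** — at most 5 nt of consensus missing at the 5′ end
   (20 nt for tRNAs, whose precursors carry leader sequences);
2. **3′ truncation** — at least 10 nt of consensus missing ("tailless");
3. **consensus identity** — global Needleman–Wunsch alignment (match +7,
   mismatch −5, gap open −25, gap extend −3) of the hit to its source RNA,
   identity strictly above 69%;
4. **TSD** — local Smith–Waterman alignment (match +8, mismatch −17, gap
   −25) of the flanking windows finds an 8–35 nt duplication of ≥ 70%
   identity, starting at most 15 nt after the element terminus;
5. **length** — at least 30 nt of retroposed consensus.

Interrupted elements (several hits sharing one RepeatMasker ID) are excluded
up front; same-region multiple hits and genomic duplications (TSD + ~100 nt
flanks ≥ 70% identical) are collapsed at the end.

## Worked example

```r
library(taillessr)

set.seed(1)
lib <- tibble::tibble(                         # a one-gene RNA library
  name = "r5S", seq = paste(sample(c("A","C","G","T"), 120, TRUE), collapse = ""),
  length = 120L, structure = NA_character_, class = "rRNA/5S")

specs <- dplyr::bind_rows(                     # three plants, one decoy
  plant_spec("r5S", truncation = 60, tsd_len = 12, priming = 4),
  plant_spec("r5S", truncation = 70, tsd_len = 15, strand = "-"),
  plant_spec("r5S", truncation = 25, decoy_class = "short"))

sim <- generate_genome(specs, lib, background_length = 50000, seed = 7)
scr <- screen_genome(sim$genome, sim$hits, lib)
scr
#> Tailless retropseudogene screen
#>   candidates: 2
#>   genomic duplications: 0
#>   rejections: 1
#>   interrupted hits excluded: 0

tidy(scr)[, c("start", "end", "strand", "breakpoint", "tsd_len", "priming_length")]
#>   start   end strand breakpoint tsd_len priming_length
#> 1 12455 12514      +         60      12              4
#> 2 24982 25051      -         70      15              0

rejections(scr)
#>    chrom start   end     failed_rule value
#> 1 synth1 37523 37547 min_element_len    25
```

Both conforming insertions are recovered with their planted anatomy — the
breakpoint (last retroposed consensus position), TSD length, and the
priming-length complementarity — while the 25 nt plant is rejected by the
30 nt length rule. Downstream, `target_site_matrix()` + `information_logo()`
build the insertion-site logo, `breakpoint_histogram()` relates truncation
hotspots to secondary structure, `census_elements()` tabulates 5′/3′
completeness classes, and `branch_counts()` assigns presence/absence
patterns to branches of a species tree (`autoplot()` methods plot each).

A command-line front end for all stages ships at `inst/cli/tailless.R`
(subcommands `screen`, `census`, `logos`, `breakpoints`, `branches`,
`synthgen`).

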