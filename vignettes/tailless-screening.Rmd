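---
title: "Screening genomes for tailless retropseudogenes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for tailless retropseudogenes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taillessr)
```

## The insertion model

LINE1-mediated target-primed reverse transcription (TPRT) normally engages
an RNA's oligo(A) tail: the L1 endonuclease nicks the bottom strand of the
chromosomal target (consensus `TT/AAAA`), the exposed 3′-OH anneals to the
poly(A) stretch and primes reverse transcription, and a staggered
second-strand nick leaves 8–35 nt target site duplications (TSDs) flanking
the new copy. The same machinery can instead anneal to an A-rich *internal*
stretch of almost any cellular RNA. The product is then a **tailless
retropseudogene**: a 5′-complete but 3′-truncated copy with no oligo(A)
tail, whose insertion site reads `TT/WAAAAWW·X(0–17)` — the first bases of
the duplicated target are complementary (on the bottom strand) to the RNA
immediately beyond the truncation point. We call the last retroposed
consensus position the **breakpoint** and the length of that exact
complementarity the **priming length**.

This package implements the complete desk pipeline around that model: a
filter cascade that extracts clean insertions from repeat annotations, the
statistics that characterise them, a presence/absence branch assigner, and
a generator of synthetic genomes with planted ground truth.

## The cascade and its thresholds

All thresholds live in one object, `filter_config()`. Defaults are the
screen's operating point; each is an ordinary argument so sensitivity
analyses are one-liners.

| rule | default | meaning |
|---|---|---|
| `max_5p_overhang` | 5 nt | 5′-(almost) complete: consensus start ≤ 6 |
| `trna_5p_slack` | 20 nt | relaxed 5′ rule for tRNAs (precursor leaders) |
| `min_3p_truncation` | 10 nt | consensus missing at the 3′ end ("tailless") |
| `min_target_identity` | 0.69 (exclusive) | global identity to the consensus, strictly `> 69%` |
| `tsd_min_len`, `tsd_max_len` | 8, 35 nt | accepted TSD length range |
| `tsd_min_identity` | 0.70 (inclusive) | TSD pair identity, `>= 70%` |
| `max_gap_3p` | 15 nt | gap between element terminus and downstream TSD copy |
| `min_element_len` | 30 nt | minimal breakpoint position |
| `dup_flank_len`, `dup_min_identity` | 100 nt, 0.70 | genomic-duplication call on TSD + flanks |
| `tsd_search_window` | 50 nt | flank scan width: max TSD (35) + max gap (15) |

Note the deliberate asymmetry between the two identity rules: the
consensus-identity rule is *strictly greater than* 69%, the TSD rule *at
least* 70%. The rules are applied in a fixed order (5′ completeness, 3′
truncation, consensus identity, TSD + gap, length), and a rejected hit
records the first rule it failed together with the measured value, so every
decision is auditable.

Two aligners back the cascade, both exact dynamic programs (Rcpp):

* **TSD detection** uses local Smith–Waterman with match +8, mismatch −17,
  gap −25. A single printed gap penalty is modelled as linear gaps
  (`gap_open == gap_extend`). The windows are the `tsd_search_window` nt
  immediately flanking the hit, reverse-complemented into element
  orientation for minus-strand hits (TSD copies are direct repeats on the
  chromosome, so this preserves their relationship).
* **Consensus identity** uses global Needleman–Wunsch with match +7,
  mismatch −5, gap open −25, gap extend −3. Affine convention: a gap of
  length $L$ costs $open + (L-1) \cdot extend$, i.e. the opening score
  covers the first gapped column. This convention is part of the contract
  and shared by the test oracles.

Identity is matches over aligned columns. By default any pairing involving
`N` scores 0; a full 5×5 substitution table (EMBOSS-style file via
`read_score_matrix()`) can replace the match/mismatch model, which is the
hook for restoring bespoke substitution tables.

Tie-breaking is pinned down for reproducibility: among equal-scoring local
optima the alignment with the smallest end coordinate in the first, then
the second sequence is reported; traceback prefers substitution columns,
then gaps in the second sequence.

## Conventions worth stating

* **Coordinates are 1-based inclusive everywhere**, the native convention
  of both R and the RepeatMasker `.out` format; conversion happens only in
  parsers/writers (there is none to do for `.out`). Minus-strand `.out`
  lines have their consensus triple reordered at parse so `repeat_start <=
  repeat_end` always refers to consensus orientation.
* **Breakpoint** = last consensus position covered by the global alignment
  (trailing consensus positions aligned against gaps do not count), 1-based
  in the source RNA.
* **Priming length** is measured as the exact common prefix of the genomic
  sequence immediately 3′ of the element (element orientation, top strand)
  and the consensus beyond the breakpoint — equivalent to bottom-strand
  complementarity with the annealed RNA — capped at 20 nt, with no
  mismatches allowed. Exactness keeps the quantity well defined.
* **Breakpoint context matrices** are 10 columns wide: columns 1–5 are
  consensus positions `bp−4 … bp` (the breakpoint occupies column 5),
  columns 6–10 are `bp+1 … bp+5`. Positions outside the RNA are skipped per
  sequence and the per-column coverage is tracked explicitly.
* **Census boundary**: the 5′ rules "at most 5 nt" (full) and "at least
  5 nt" (truncated) overlap at exactly 5; the boundary case is assigned to
  5′-full so that "at most 5" stays literally true. The 3′ rules (≤ 9 full,
  ≥ 10 tailless) partition cleanly.
* **Logo information content** uses $IC = 2 - H$ bits with Shannon entropy
  in log base 2 and *no small-sample correction* — exactly reproducible and
  independent of rendering conventions. Letter height is frequency × IC.
* **Duplication calls** compare, by Smith–Waterman, the concatenation of
  both TSD copies with 100 nt of outside flank each; identity is computed
  as aligned matches over the longer region (coverage-corrected), since a
  bare local-alignment identity would be ~100% for any chance seed match.
* **Dot-bracket structures**: `.` is unpaired, any of `()[]{}<>` paired;
  pseudoknot letter codes are rejected rather than misread.

## Branch assignment

Presence/absence patterns are mapped onto a fixed rooted species tree under
the Dollo assumption (one insertion event, no precise excision): a locus is
assigned to the unique branch — terminal or internal, never the root —
whose descendant leaf set is exactly the set of present species. `M`
(missing) states are tolerated up to `max_missing`, which defaults to 0 to
mirror the "clear presence/absence boundaries only" selection; with missing
tolerance several branches can fit and the locus is reported ambiguous
rather than guessed. Loci present in a designated outgroup are treated as
uninformative and left unassigned. Fractions are percentages of assigned
loci, rounded to integers. A reference primate topology over the species
usually available in whole-genome alignments (tree shrew outgroup) ships in
`inst/extdata/primates.nwk` with named internal branches.

## What the synthetic genomes emulate — and what they do not

`generate_genome()` plants, on an i.i.d. background of configurable GC
content (default 0.41, a mammalian-like value), cassettes of the form
`[TT][TSD][RNA 1..bp][gap][TSD′]` in element orientation, reverse-
complementing whole cassettes for minus-strand plants. The target-site
dinucleotide and the TSD seed follow an IUPAC motif (default `TTWAAAAWW`);
when a priming length $p$ is requested the TSD instead begins with the
consensus continuation beyond the breakpoint, and the base after position
$p$ is forced to differ so the realized priming is exactly $p$. Decoy
classes plant single-rule violations (too short, oligo(A)-tailed
full-length, interrupted elements sharing a repeat ID, TSDs degraded below
the identity floor, segmental duplications of an accepted locus), and every
plant carries a machine-readable truth record. Identical seeds give
byte-identical output, and generation restores the caller's RNG stream.

Degraded-TSD decoys place their substitutions on a fixed every-3rd-position
grid. Random placement would occasionally leave a clean sub-block that
passes both the 8 nt length floor and the 70% identity floor — the local
aligner would then legitimately report that sub-block — whereas the grid
guarantees no qualifying sub-alignment exists, making the planted outcome
derivable from the spec alone.

The generator deliberately does **not** model indel evolution, CpG
hypermutation, nested repeats, or annotation noise beyond an optional ±3 nt
boundary jitter; backgrounds have no repeat structure. Passing tests on
synthetic genomes therefore demonstrate the correctness of the cascade's
logic and geometry (including strand handling and truth recovery), not
robustness to the full messiness of real repeat annotations, and the
package makes no attempt to reproduce genome-scale counts that depend on
real assemblies and masking libraries.

One knowable artefact is worth naming: flanking windows of real (or
simulated) sequence occasionally contain a chance duplication-like block
that outscores a planted degraded TSD. The hit is still rejected, but the
proximate rule can then be the gap bound rather than the TSD rule, since
the cascade evaluates the single maximal-scoring flank alignment — the
faithful behaviour for a screen built on one local alignment per locus.

## Problem sizes and verification

The test suite validates the aligners against layered independent oracles
(full enumeration of all alignments at tiny lengths; independently written
plain-R dynamic programs on 500 random pairs of length ≤ 15 local / ≤ 12
global), exercises both sides of every threshold boundary, and runs the
whole screen on seeded synthetic genomes — 2 Mb with 50 conforming plants
and 20 single-rule decoys for the end-to-end recall/rejection check, 1,000
planted sites for target-site consensus recovery, 300 loop-biased
breakpoints (80% unpaired) for the structure-context property. These sizes
give tight binomial error bars while keeping a full run in well under two
minutes; `scripts/acceptance.R` recomputes the same quantities from scratch
at any seed.

## Known limitations

* The consensus-building step for species lacking curated RNA gene models
  is out of scope: the RNA library is an input.
* Producing presence/absence matrices from whole-genome alignments is out
  of scope: the matrix is an input contract, the assigner consumes it.
* The screen inherits the single-best-alignment behaviour described above;
  a multi-candidate TSD search would change rule attribution in rare
  corner cases but not acceptance decisions in any case we constructed.
* `.out` parsing targets the classic 15-column dialect (a trailing overlap
  `*` is tolerated); exotic column variants are not validated.
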