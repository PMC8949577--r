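---
title: "Consolidating enChIP-Seq peak lists: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating enChIP-Seq peak lists: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enchipr)
```

## The inference problem

enChIP-Seq tags a genomic locus with a dCas9/gRNA complex, pulls the locus
down with its cross-linked partners, and sequences the co-purified DNA.
After MACS peak calling against input DNA, each sample yields a peak list
in which true interaction partners of the target locus are mixed with
CRISPR off-target binding sites and sample-specific noise. The consolidation
logic in this package rests on two assumptions:

* **off-target sites reproduce in negative controls** (enChIP without a
  gRNA, or with an irrelevant gRNA), so any peak overlapping a
  negative-control peak is discarded; and
* **true partners reproduce across independent gRNAs** tiling the same
  locus, so only peaks found in every on-target sample are kept.

Both assumptions are approximations. Off-target repertoires depend on the
gRNA sequence, so a no-gRNA control does not capture gRNA-specific
off-targets — using several distinct on-target gRNAs is what protects
against those, since two different gRNAs rarely share an off-target site.
Conversely, a genuine partner can be lost whenever any single gRNA sample
fails to call it (peak-calling sensitivity, not biology, then sets recall).

## The two-step procedure

For each on-target gRNA sample $g$ with parsed peak set $P_g$, negative
sets $N_1,\dots,N_k$, and target-locus coordinates $T$:

**Step 1.**
$S_g = \{\, p \in P_g : p \text{ overlaps no peak of } N_1 \cup \dots \cup N_k,\;
\mathrm{tags}(p) \ge \tfrac{q}{100}\,\mathrm{tags}(t_g),\;
\mathrm{FE}(p) \ge f \,\}$,
where $t_g$ is the target peak of sample $g$ (the highest-tag peak of
$P_g$ overlapping $T$), $q$ is the tag percentage and $f$ the minimum fold
enrichment. Peaks overlapping $T$ itself are then removed from $S_g$.

**Step 2.** With a designated base sample $b$:
$C = \{\, p \in S_b : p \text{ overlaps} \ge 1 \text{ peak of every other } S_g \,\}$.

All results are the base file's records verbatim; the package never emits
merged or intersected coordinates, so every reported peak can be traced to
a row of an input file.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `tag_percent` | 5 (%) | tag criterion relative to the target peak; a peak carrying 5% of the target's tags can be read as an interacting ratio of 5%. `NULL` disables. |
| `fold_enrichment_min` | 10 (fold over input) | minimum enrichment; inclusive, so exactly 10 passes. `NULL` disables. |
| `min_overlap_bp` | 1 (bp) | shared bases required for two closed intervals to count as overlapping. 1 means any overlap, including a single boundary base. |
| `base` | first-listed gRNA | whose records the common set reports. |
| `exclude_target` | `TRUE` | drop peaks overlapping the target locus from each specific set. |

The defaults for `tag_percent` and `fold_enrichment_min` are the criteria
used in the 5′HS5 study that motivated this design; they are stringent
relative to typical ChIP-Seq practice because enChIP enrichment at a true
partner is expected to be strong. `min_overlap_bp` defaults to 1 because
the required overlap extent is genuinely unspecified in the source
procedure; it is exposed as a parameter rather than hard-coded.

### Design choices where the design was open

* **Base-centric AND.** With more than two gRNA files, a base peak is kept
  if it overlaps each other file *individually*; the stricter variant —
  some single genomic stretch covered by every file simultaneously — is
  available as `extract_common(..., mutual = TRUE)`. The base-centric
  reading matches the per-comparison-set workflow; the mutual variant is
  provided because the two differ exactly when a wide base peak touches
  disjoint partners, which users may want to exclude.
* **Per-file 5% referent.** The relative tag threshold is resolved against
  each gRNA file's own target peak, not one designated file's: every
  enChIP experiment has its own pull-down efficiency, and the tag count of
  the target peak is the natural per-sample normalizer.
* **Eliminate, then filter.** Step 1 removes off-targets before applying
  the tag/fold-enrichment criteria. For ≥-type criteria the order cannot
  change the result (both are row-wise predicates combined by AND); the
  fixed order exists so that stage counts are well-defined and
  reproducible.
* **Target-peak exclusion.** The target-locus peak is present in every
  positive sample, absent from negatives, and passes both filters by
  construction, so it would always appear as a "common peak". Since the
  analysis asks what interacts *with* the locus, `run_workflow()` drops
  peaks overlapping the target locus from each specific set (disable with
  `exclude_target = FALSE`).
* **Target-peak lookup by coordinates.** The target peak is located by
  interval overlap with user-supplied locus coordinates, with the
  highest-tag overlapping peak as referent and leftmost start breaking
  ties. Locating it by peak identifier would tie the package to one MACS
  version's naming.
* **Duplicates.** Identical duplicate rows are preserved by the parser
  (input fidelity) and deduplicated once, in `run_workflow()` results, so
  no peak is double-reported.

## Numerical and format conventions

* Coordinates are **1-based closed** intervals throughout, matching the
  MACS `peaks.xls` dialect; two peaks overlap iff
  $\min(e_1,e_2) - \max(s_1,s_2) + 1 \ge$ `min_overlap_bp`. Only BED export
  converts to 0-based half-open (`start - 1`), covering the same bases.
* `length` is treated as derived: files writing the `end − start` dialect
  are accepted, with the value recomputed as `end − start + 1` and a
  warning rather than a failure.
* Chromosome names are compared as exact strings after whitespace
  trimming. `read_macs_peaks(normalize_chrom = TRUE)` opts into adding a
  `chr` prefix; it is off by default because silent renaming can create
  false overlaps between files using different conventions.
* Equality filtering (`=`) is exact for tag counts (integers) and uses an
  absolute tolerance of $10^{-6}$ for fold enrichment, which is a printed
  decimal.
* The resolved relative threshold ($q/100 \times$ target tags) is **not**
  rounded to an integer; comparisons use the real value. Rounding would
  demand an arbitrary floor/ceiling choice and change results near the
  boundary.
* Empty peak sets are legal everywhere: an empty negative set eliminates
  nothing, and zero survivors at any stage is a reported outcome, not an
  error.
* Overlap queries run on `GenomicRanges::findOverlaps()`; the test suite
  checks the algebra against an independent all-pairs brute-force oracle
  written in plain arithmetic.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_experiment()` plants four peak categories on a genome
of three 10-Mb chromosomes (peaks 200–2000 bp wide, placed on a slot grid
that guarantees pairwise non-overlap):

* a **target peak** in every positive file (1000 tags, fold enrichment 50);
* **common peaks** in all positive files, absent from negatives, with tags
  uniform on 20–200 and fold enrichment uniform on 5–20 — ranges that
  straddle the default thresholds (50 tags, fold enrichment 10), so every
  generated scenario exercises both filter outcomes;
* **decoys** unique to one file; and
* **off-targets** shared by all positive and all negative files.

Everything is deterministic given the seed, and generated files are
byte-identical across runs.

This fixture makes recovery exact by construction: categories never
overlap, common peaks carry identical coordinates and scores in every
file, and off-targets appear identically in the negatives. Real data break
all three idealizations — peak boundaries shift between samples, the same
interaction is called with different tag counts per gRNA, and off-target
repertoires are partly gRNA-specific. Passing the recovery tests therefore
demonstrates that the set algebra, thresholds and bookkeeping are correct,
not that the biological error rates on real data are zero. Boundary-shift
robustness is governed by `min_overlap_bp`, which the synthetic fixture
does not stress beyond the oracle tests' randomized intervals.

## Problem sizes used by the test suite

The randomized oracle comparisons use up to 200 peaks per file over 3
chromosomes (1000 instances); workflow recovery runs 100 seeded scenarios
with 2–4 gRNA files, 1–2 negatives, and up to ~50 peaks per file; the
acceptance script repeats the same measurements at 250 and 60 instances.
These sizes were chosen so the full validation runs comfortably on a
laptop; the algorithms themselves are indexed interval queries and scale
to full-genome MACS output (tens of thousands of peaks) without
modification.

## Known limitations

* MACS2 `narrowPeak`/`broadPeak` files are not parsed natively; convert to
  the tab layout first (columns: chr, start, end, length, summit, tags,
  −10·log10 p-value, fold enrichment, FDR%).
* Filtering is implemented for tag number and fold enrichment only — the
  two fields the consolidation criteria use; p-value/FDR columns are
  parsed and exported but not filterable.
* No statistical assessment of overlap significance (e.g. permutation
  tests) is attempted: the output is a deterministic set consolidation,
  and confidence comes from the multi-gRNA, multi-control experimental
  design itself.
* Peaks are never merged; if a consensus interval across samples is
  needed, export to BED and use a range-merging tool downstream.
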