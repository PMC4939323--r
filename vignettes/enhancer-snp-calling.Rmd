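---
title: "Calling enhancer SNPs from GWAS and paired histone-mark coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling enhancer SNPs from GWAS and paired histone-mark coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Genome-wide association studies report *lead* SNPs, but the causal variant
at a locus can be any SNP in strong linkage disequilibrium (LD) with the
lead, and most of these sit in noncoding DNA. One mechanistic hypothesis
is regulatory: a variant inside an **enhancer** can alter the expression
of a target gene, sometimes over a large genomic distance. `enhsnp` turns
that hypothesis into a screening pipeline with four stages.

**Lead filtering.** A catalog of lead associations is filtered to
p < 10⁻⁵ (strict inequality), optionally per cohort. The packaged
liver-cancer catalog has 45 entries, 26 from the CHB cohort and 19 from
JPT; all pass the cut.

**LD expansion.** Each lead is widened to the proxies linked to it by a
pairwise LD record with r² > 0.8 (strict). Expansion is one hop only —
lead to proxy, never proxy to proxy — because pairwise proxy lists are
conventionally defined against the lead, and it is population-matched by
default (a CHB lead only consumes CHB LD records; `match_population =
FALSE` pools them). A proxy reachable from several leads is kept once
with its maximum-r² provenance; leads are always retained, even with no
proxies.

**Enhancer calling.** Enhancer chromatin carries strong H3K4me1 and
comparatively weak H3K4me3 (promoters show the reverse). For each mark we
count per-base read coverage, scale each track to reads-per-million (RPM)
of its own library, and compute the per-base statistic

$$v(x) = \log_2 \frac{\mathrm{me1}'(x) + c}{\mathrm{me3}'(x) + c},$$

with pseudocount $c = 1$. Enhancer regions are maximal runs of positions
with $v(x) > 1.2$ (strict); runs separated by at most `merge_gap` bp can
be merged, and merged runs spanning fewer than `min_length` bp discarded.

**Mapping and annotation.** Candidate SNPs falling inside a called region
(half-open containment, `start <= pos < end`, BED convention throughout)
are the enhancer SNPs. They are then joined by exact rsID match against a
regulatory-variant annotation table carrying, per SNP, a regulatory-
evidence flag, a distal-regulation flag, chromatin-state labels, related
regulatory elements, and distal target-gene links. On the packaged
reference tables the 22 loci yield 14 regulatory SNPs, 9 of them with
distal target-gene links.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `p_max` | 1e-5 | p-value | conventional suggestive GWAS threshold; strict `<` |
| `r2_min` | 0.8 | r² | conventional strong-LD cutoff; strict `>` |
| `ratio_threshold` | 1.2 | log₂ units | the calling rule's cutoff; strict `>` |
| `pseudocount` | 1 | depth units | Laplace offset; keeps the ratio finite at zero H3K4me3 |
| `normalize` | on | — | the two marks are independently sequenced libraries; RPM puts them on one scale |
| `bin_width` | 1 | bp | per-position coverage; larger bins trade resolution for speed |
| `min_length` | 1 | bp | literal per-position rule; larger values suppress fragment-scale noise |
| `merge_gap` | 0 | bp | no gap bridging by default |

Strandedness is ignored for coverage (histone ChIP fragments are
unstranded); SNP strand is carried as metadata only. Chromosome labels
are normalized to the `chr` prefix at parse time so catalog-style (`1`)
and BED-style (`chr1`) inputs join correctly.

The pseudocount is added after RPM scaling, as a constant in scaled-depth
units. Two numerical consequences are worth knowing. First, where neither
mark has any reads the statistic is exactly 0, so unsequenced territory is
never called. Second, because RPM scaling multiplies raw depths by
10⁶/library-size, the pseudocount's relative weight shrinks as libraries
grow — with deep libraries the rule approaches the pure ratio.

## What the simulator emulates

`simulate_reads()` generates the paired tracks the caller consumes. Read
starts follow a homogeneous Poisson process with rate
`background_depth / read_length` per bp, multiplied inside planted
enhancer intervals by the mark's enrichment (`me1_enrichment` > 1;
`me3_enrichment` ≤ 1). Reads have fixed length, are unpaired and
error-free, and the expected per-base coverage is therefore exactly
`background_depth` outside and `background_depth × enrichment` inside
planted intervals — which is what the depth-law test checks against a
brute-force pileup oracle. An optional `windows` field restricts read
emission to analysis windows, so planted intervals can sit at realistic
hundred-megabase coordinates while the read count stays small.

Deliberately *not* emulated: PCR duplicates, mappability and GC bias,
fragment-size distributions, chromatin input controls, and replicate
structure. Passing tests on this generator therefore demonstrate the
correctness of the pipeline's arithmetic and region logic under a clean
counting model — not robustness to the artifacts of real ChIP-seq, which
would call for a dedicated peak caller with background modeling (out of
scope here by design: the ratio rule *is* the method).

`simulate_ld_table()` emits a star-shaped LD graph (each proxy linked to
one lead, r² uniform in configurable bounds) with the proxies above 0.8
recorded as truth; `simulate_decoy_snps()` places single-base loci at
least two read lengths clear of every planted interval.

## The packaged demo: geometry and choices

`demo_pipeline()` wires the packaged tables and the simulator into a full
run whose planted signal covers the 22 packaged loci:

* **Planted intervals** are the loci padded ±600 bp and merged (20
  disjoint intervals; nearby loci share one interval). Sequenced windows
  extend 2 kb beyond each planted interval.
* **Background breadth**: each of the six chromosomes also gets a 500 kb
  background-only sequenced window. This is not decoration — genome-wide,
  enhancers are a tiny fraction of the territory, so the me1 and me3
  library sizes are nearly equal. With too little simulated background
  the me1 library (which contains the enriched reads) inflates, RPM
  scaling deflates the me1 track relative to me3, and the ratio margin
  inside planted intervals erodes until regions fragment.
* **Decoys** (50, the demo's candidate negatives) are placed in windows a
  further 10 kb out, with no read coverage; the statistic there is
  exactly 0 and the rule never calls them. Specificity inside *sequenced*
  background is governed by noise excursions of the per-base statistic
  (at depth 5, measured excursions reach ~175 bp and cover well under 1%
  of background bases) and is asserted separately by the planted-recovery
  test below.
* **Minimum span**: the demo calls with `min_length = 100` (two read
  lengths). At a mean depth of 5 the per-base rule produces
  fragment-scale noise excursions in background and occasional short
  dips inside genuine regions; requiring two read lengths of contiguous
  enrichment removes the former without splitting the latter. All other
  parameters are the pipeline defaults.
* **Synthetic LD**: every candidate (locus or decoy) is linked to a
  packaged lead of its own population with r² drawn in 0.85–0.99, so the
  LD stage passes all of them through; lead loci without coordinates of
  their own take coordinates from the candidate BED.

The demo asserts the reference counts end to end: 45 leads → 113
candidate members → exactly the 22 packaged loci mapped (no decoy) → 14
regulatory, 9 distal.

## Planted-region recovery

At the demo's signal settings (me1 enrichment 8, me3 enrichment 1,
background depth 5, pseudocount 1, threshold 1.2, `min_length` 100) the
caller recovers ≥ 90% of planted bases while calling ≤ 1% of background
bases on a 400 kb whole-chromosome simulation — both asserted at a fixed
seed in the test suite. The recovered fraction is bounded away from 100%
by edge taper: coverage ramps over one read length at each planted
boundary, so a called region starts a few tens of bp inside the planted
edge.

## Degenerate inputs and tie-breaks

* All three cutoffs are strict inequalities; a value exactly at a cutoff
  is excluded (tested at the boundary for each stage).
* Zero-coverage positions are well-defined via the pseudocount; an
  all-zero chromosome yields no regions.
* Reads extending past a chromosome end are clipped with a warning;
  reads on unknown chromosomes are an error at coverage time, while
  candidate SNPs on chromosomes absent from the coverage data are set
  aside in a skipped-records file rather than failing the run.
* A SNP listed under two populations is kept as two records keyed by
  (rsID, population); LD expansion unions their proxies.
* Gene links with no annotated gene symbol keep their Ensembl id and an
  empty symbol — they still count as distal-regulation evidence.
* `validate_snps()` is permutation-invariant and its counts always
  satisfy distal ≤ regulatory ≤ annotated ≤ input.

## Problem sizes

The shipped tests and the acceptance script run the simulator at
desk scale: ~320,000 50 bp reads per track per demo run (3.1 Mb of
sequenced windows at mean depth 5), 400 kb single-chromosome
simulations for the recovery and depth-law properties, and 200-instance
randomized equivalence sweeps against brute-force oracles for interval
intersection and run calling. A demo run takes a few seconds on one CPU.

## Known limitations

* The ratio rule has no statistical background model: no enrichment
  p-values, no input subtraction, no replicate reconciliation. It is a
  faithful implementation of a simple screening rule, with `min_length` /
  `merge_gap` as its only shape refinements.
* LD expansion consumes precomputed pairwise r² tables; it does not
  compute r² from genotypes or handle D′.
* Annotation is a local-table join by exact rsID; no live database
  queries, no fuzzy matching, no liftover across genome builds.
* The per-base rule's specificity depends on sequencing depth; at low
  depth, fragment-scale noise excursions are expected and a nonzero
  `min_length` is advisable.
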