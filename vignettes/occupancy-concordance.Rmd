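---
title: "Comparing ChIP-Seq occupancy across datasets: methods and design"
author: "peakconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ChIP-Seq occupancy across datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakconcord)
```

## The problem

A recurring question in regulatory genomics is whether two or more ChIP-Seq
experiments — say, an antibody against an endogenous chromatin factor and
FLAG-tag pulldowns of ectopically expressed wild-type and mutant versions of
the same factor — report the *same* genomic occupancy. Naive comparison of
called peak lists is misleading: peak calling applies a hard significance
threshold, so a site sitting just below threshold in one dataset "disappears"
from its list even when the underlying read enrichment is nearly identical.
`peakconcord` implements a concordance analysis that works at the level of
read counts over merged peak regions, asking how many regions remain
dataset-specific once a bounded fold-difference in (depth-normalized) tag
counts is tolerated, together with the surrounding stages such an analysis
needs: read filtering, peak selection, summit detection, TSS annotation,
cross-species comparison, and gene-set enrichment.

## Coordinates and data model

All genomic intervals are 0-based half-open `[start, end)` (the BED
convention) everywhere inside the package; GTF input is converted on read.
A "±N bp" window around a point `p` means the closed range `[p − N, p + N]`,
stored half-open as `[p − N, p + N + 1)`, so a ±150 bp summit window is 301
bp wide. The TSS of a gene body `[start, end)` is `start` on the `+` strand
and `end − 1` on the `−` strand — the last base of the half-open interval,
forced by the storage convention. A *tag* is an aligned read reduced to
chromosome, 5′ position, and strand.

## Read filtering

`filter_tags()` groups tags by (chromosome, strand, 5′ position), retains at
most `max_per_start = 2` tags per group, and *censors* — removes entirely —
groups with more than `censor_above = 7` tags, reporting every censored
position. Two readings of the underlying rules were open:

* **Does the duplicate key pool strands?** We key on (chrom, strand,
  position). Reads on opposite strands at one coordinate come from distinct
  fragments, and separating them is standard ChIP-Seq deduplication
  practice.
* **Does censoring remove or cap?** We remove. A position carrying more
  than seven identical reads is best explained as a PCR amplification
  artifact; keeping two of its reads would let every artifact through at
  the cap. The contrast between the "maximum of two" clause and the
  separate "censored" clause suggests two different actions.

The filter's report satisfies the conservation identity
`n_input = n_retained + n_duplicates_removed + n_censored`, which the
pipeline manifest audits end-to-end.

## The stand-in peak caller

External peak callers are supported via file ingestion (narrowPeak or the
documented TSV dialect). So the pipeline also runs end-to-end with no
external software, `call_peaks()` provides a deliberately simple
sliding-window caller: windows of 300 bp every 100 bp are tested by an
upper-tail Poisson p-value against
`λ = max(genome-wide rate × window, control count × depth ratio)`,
overlapping significant windows are merged, and each peak's FDR is the
*sample-swap* empirical estimate — the number of control-vs-treatment peaks
at least as significant divided by the number of treatment peaks at least as
significant, as a step function of p, clipped to [0, 1]. This preserves the
meaning of an empirical, caller-defined FDR at desk scale without
reimplementing any particular tool (no fragment-shift model, no local-λ
hierarchy, no broad calls). Two selection filters follow, and apply equally
to ingested peaks:

* `exclude_by_control()` drops peaks with **strictly more than 100** tag 5′
  ends from *any* control library inside the peak interval, counting raw
  (unnormalized) filtered tags — the threshold is stated as an absolute
  count, and the filter precedes peak calling in pipeline order.
* `filter_fdr()` keeps peaks with FDR **≤ 0.001** (inclusive).

## Merging and fold-tolerance concordance

`merge_peak_sets()` pools the FDR-selected intervals of all datasets and
forms the connected components of their per-base union; book-ended
intervals (`[a,b)` then `[b,c)`) belong to one component, a one-base gap
separates. Each merged region records which datasets contributed a peak.
`region_counts()` then fills, for *every* dataset, the number of tag 5′ ends
in the region scaled by `normalization_factor(library_size)` — i.e. tags per
20 million usable reads. Normalization matters because libraries differ in
depth, and an unnormalized fold comparison would confound enrichment with
sequencing depth.

The tolerance rule, `fold_membership()`, is the heart of the comparison: a
dataset *d* is called present in a region at tolerance `k` when

```
counts[d] >= max(counts) / k
```

Regions where all counts are zero fall back to their contributing datasets.
The published phrasing ("allowing a k-fold difference in read counts") does
not pin down an exact predicate — pairwise ratios do not give a well-defined
per-dataset presence call for a three-set Venn, whereas thresholding against
the maximum does, is monotone in `k` by construction (membership at `k` is a
subset of membership at `k′ ≥ k`), and reproduces the qualitative behaviour
of progressively greater overlap at larger tolerance. The rule is isolated
behind this single function so an alternative reading can be swapped in.
`venn_partition()` tallies regions by their exact membership subset; cell
counts always sum to the region count.

## Summits

`compute_summits()` pools the filtered tags of all datasets (reads, not
normalized rates — pooling operates on reads), elongates each to 200 bp in
read direction, and takes the position of highest overlap. Fixed-length
elongation guarantees coverage plateaus, so a tie-break is needed: we take
the midpoint of the *leftmost* maximal plateau,
`floor((plateau_start + plateau_end − 1) / 2)`, which is deterministic and
stable. Zero-coverage regions are flagged and given the region midpoint.
`summit_windows()` exports ±150 bp windows (301 bp) around summits, clipped
at chromosome bounds, ready for FASTA extraction and motif tools.

## Annotation, cross-species comparison, enrichment

A peak associates with a gene when the peak interval intersects the closed
TSS ± 1250 bp window (`associate_peaks_tss()`); association is
many-to-many. `classify_locations()` makes the location categories
exclusive by priority — TSS-proximal beats intragenic beats intergenic — so
the breakdown always conserves the peak count; the published category
percentages may have used overlapping bookkeeping, which the priority rule
resolves. `bound_genes()` applies set semantics (a gene with several peaks
counts once) and is monotone in the window half-width. The cross-species
comparison uses ±10 kb windows (the resolution at which the second species'
bound-gene list is defined) and tallies one-to-one ortholog pairs by
boundness in either or both species; bound genes with no one-to-one partner
are counted as species-specific, not dropped.

`tss_metaprofile()` averages elongated-tag coverage over TSS ± 2500 bp in
25 bp bins (both configurable; the window and bin width of the published
average-coverage figure are not stated — these defaults show the
TSS-centred shape at readable resolution), orienting by strand so positive
offsets are downstream, weighting each base by the genes whose window
survives clipping at the chromosome start, and scaling to 20 million reads.
The profile is *exactly* invariant under duplicating every tag while
doubling the library size, a property the tests assert bit-for-bit.

`fisher_enrichment()` is the one-sided Fisher exact test: upper-tail
hypergeometric probability of the overlap between the bound list and each
gene set within the universe, with Benjamini–Hochberg correction across the
tested sets. Only enrichment (not depletion) is tested, matching how such
pathway results are reported. The default universe is the genes carrying at
least one gene-set annotation (`gene_universe(mode = "annotated")`),
configurable to all annotated genes; the exact universe used in the
original pathway analysis is not stated, so both are exposed.

## The synthetic-data generator

`simulation_design()` / `simulate_chipseq()` generate a complete study —
tag libraries, controls, gene models, ortholog map, genome sequence, and
truth tables — with the statistical structure the pipeline assumes:

* **Background** tags from a homogeneous Poisson process (default 0.004
  tags/bp per dataset over a 1 Mb two-chromosome genome, comparable to the
  genome-wide density of a ~20 M-read mammalian library at desk scale).
* **Planted peaks** (default 120, 80% inside TSS ± 1250 bp windows): each
  contributes `Poisson(peak_depth × fold)` tags per dataset. Tag 5′ ends
  are drawn uniformly over the 200 bp elongation distance upstream of the
  summit on `+` (downstream on `−`) — mean shift of half the elongation
  distance per strand — plus Gaussian fragment-length jitter (sd 20 bp).
  This mirrors real ChIP fragment geometry: fragments of roughly the
  elongation length cover the site and are sequenced from either end, so
  the elongated pileup is triangular with its apex at the true summit,
  which is precisely why elongate-and-argmax is the right summit
  estimator. (A fixed ±100 bp shift would instead produce a ~200 bp flat
  top whose argmax is pure noise.)
* **Concordance classes**: shared peaks carry per-dataset folds
  (1, 1.2, 0.9) — within 1.5× of each other — while discordant peaks
  (default 20%) drop one dataset 8-fold (fold 0.125). These are the effect
  sizes the fold-tolerance rule is meant to separate at `k = 2`.
* **PCR-duplicate bursts**: each background tag seeds, with probability
  0.02, a burst of 10 identical-position reads — above the censoring
  threshold, so the filter must remove them; truth records every burst.
* **Controls**: background-only libraries, the first of which carries
  `control_hotspots` artifact positions of 150 identical-position tags
  (>100, the exclusion threshold). Note an instructive interaction: because
  the pipeline filters control libraries before counting, single-position
  hotspots are already removed by censoring — the two defences overlap.
  The >100-tag exclusion matters for *dispersed* control enrichment, which
  the exclusion tests exercise with constructed fixtures.
* **Second species**: a configurable fraction (0.7) of genes get a
  one-to-one ortholog; orthologs of bound genes are bound with
  probability 0.7 versus 0.1 otherwise, plus 20 species-specific bound
  genes.

All draws flow through the single design seed, so identical designs are
byte-identical — the pipeline's determinism tests rest on this.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: mappability structure and alignability gaps,
GC/chromatin accessibility bias in background rates, fragment-size
distributions beyond a fixed mean, copy-number variation (a major source of
real control-exclusion events), and isoform-level TSS multiplicity.
Conclusions about those failure modes need real libraries.

## Problem sizes and numerical choices

The test suite runs the full pipeline on 0.25–1 Mb genomes with 15–120
planted peaks and 50–200 genes, ten seeds per property, sizes chosen so the
whole suite completes in well under a minute while keeping ≥ 100 pooled
tags per peak where summit precision is asserted. Counting uses
`findInterval` on sorted positions; coverage uses difference arrays;
interval overlap and merging go through `IRanges`/`GenomicRanges` with an
explicit conversion between half-open and 1-based closed coordinates
confined to two helper functions. Fisher p-values use `stats::phyper`,
BH uses `stats::p.adjust`; both are cross-checked in the tests against
independent summation and hand-applied step-up oracles. TSV writers render
doubles with `%.17g` so every reader/writer pair round-trips bit-exactly.

One property we deliberately do *not* claim: BH adjustment is not
idempotent (applying it to already-adjusted values can increase them), so
the tests assert monotonicity, permutation equivariance, `q ≥ p`, and
agreement with the hand oracle instead.

## Known limitations

The stand-in caller is plumbing, not a MACS replacement: no fragment-length
estimation, no local background hierarchy, and its empirical FDR requires a
control library. The fold-membership rule is one defensible reading of a
verbally specified comparison. Gene models carry a single TSS per gene.
Cross-species comparison consumes a bound-gene list for the second species
rather than re-running the pipeline on its tags.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(out_dir = "pipeline_out",
                  design = simulation_design(seed = 1))
manifest <- run_pipeline(cfg)
names(manifest$stages)
```
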