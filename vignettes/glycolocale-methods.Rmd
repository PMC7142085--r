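---
title: "Methods: locale analysis of N-glycosylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locale analysis of N-glycosylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedures, the tunable parameters,
the synthetic-data generator, and the numerical and design choices behind
`glycolocale`. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The scientific question and the data model

N-linked glycans are conjugated to asparagines inside the sequon N(X−P)S/T:
an Asn, followed by any residue except proline (whose pyrrolidine ring kinks
the backbone and blocks conjugation), followed by Ser or Thr. Many
post-translational modifications concentrate in intrinsically disordered
regions; the question here is whether N-glycosites do the opposite —
concentrate in ordered sequence — and, if so, what distinguishes the residue
neighborhoods around them from ordered and disordered sequence at large.

The package treats disorder as an *input annotation*: per-protein intervals
(1-based, inclusive), typically exported from a disorder meta-predictor.
How per-residue disorder scores were thresholded into intervals, and any
minimum stretch length, are properties of the upstream predictor; the
package accepts the intervals as given. Every residue position then carries
a binary locale, `ORDERED` or `DISORDERED`.

Coordinates are 1-based throughout — in the input files (the UniProt
convention), in every output table, and internally. Internally this matches
R's native indexing and the IRanges/Biostrings convention, so no coordinate
conversion exists anywhere in the package; overlap and merge arithmetic on
intervals is delegated to `IRanges::reduce()`. Overlapping or adjacent
disorder intervals are merged with a warning rather than rejected, because
meta-predictor exports commonly overlap.

Sequences may contain `X` (unknown residue). `X` is accepted in records but
excluded from every composition count, with the dropped count reported.

## Windows

An *N-glycosite neighborhood* is the 11-residue window centered on a
glycosylated Asn (5 residues each side). Glycosites closer than 5 residues
to a terminus are skipped, not truncated, so all windows are the same
length and directly comparable; skipped counts are reported. A window may
span an order/disorder boundary: it keeps the locale of its central Asn and
records its *locale purity* (fraction of window residues sharing that
locale). Boundary-spanning neighborhoods are retained because there is no
principled reason to discard them; the purity column lets a user filter
them out.

*Control windows* are 11-residue stretches that (i) are locale-pure,
(ii) contain no glycosite, and (iii) do not intersect any glycosite
neighborhood span. One control per class per protein is sampled uniformly
among all eligible starts (`controls_per_protein` raises this for power
studies). Proteins lacking an eligible window for a class — e.g. no
disordered run of length 11 — contribute an `NA` and drop out of paired
analyses for that class. The sampler is seed-deterministic, and its
eligible-start set is verified in the tests against a brute-force scan of
every start position.

## Paired metrics and the Wilcoxon test

All locale metrics are computed per protein so that the ordered and
disordered values of the same protein form a matched pair: glycosite
occurrence fractions (ordered + disordered = 1), Asn/Ser/Thr percentages,
sequon density per 100 residues, and the fraction of a region's asparagines
that sit at a sequon N. Sequon abundance is deliberately emitted under two
denominators — per 100 residues of the region, and per Asn of the region —
because "relative proportion of sequons" is ambiguous between the two;
they answer slightly different questions and both are reported.

Pairs with a missing member are dropped (preserving the matched design) and
zero differences are dropped per the Wilcoxon convention. The exact null
distribution is used when the effective n is ≤ 25 and the absolute
differences are tie-free; otherwise the normal approximation with tie
correction and continuity correction. The implementation wraps
`stats::wilcox.test()`; the test suite verifies the exact branch against a
full 2^n enumeration of sign assignments up to n = 10, and descriptive
summaries report NA-aware mean, median and SEM (sample SD over √n).

## Composition and property enrichment

Neighborhood and control windows are pooled into residue pools (the residue,
not the window, is the resampling unit, mirroring how composition-profiling
tools operate; a window-level bootstrap can be had by resampling the window
table before pooling). For amino acid *a* with query fraction `Cq(a)` and
background fraction `Cb(a)`, the fractional difference is
`D(a) = (Cq(a) − Cb(a)) / Cb(a)`, `NA` if `Cb(a) = 0 < Cq(a)`, `0` if both
are zero.

Significance uses a bootstrap of `D`: both pools are resampled with
replacement at their observed sizes (implemented as multinomial draws, which
is exact and fast), `D` recomputed each iteration, and the observed `D`
tested against a standard normal via `z = D / SE_bootstrap`, two-sided.
The default is 10,000 iterations; the per-amino-acid family applies a
Bonferroni divisor of 20, property-scale families a divisor equal to the
number of scales tested. An optional label-permutation p-value
(`permutation_enrichment()`) provides an independent cross-check; the test
suite verifies the two are strongly rank-correlated on null data. Pools
under 20 residues trigger an instability warning but are still computed.

The calibration test in the acceptance suite draws both pools iid from one
composition (2,000 residues each) and checks the uncorrected rejection rate
at α = 0.05 over 500 runs. With 500 runs the binomial standard error is
~0.01, so a single amino acid's empirical rate can stray outside a ±0.02
band by chance even at perfect calibration; the suite therefore asserts the
*mean* per-amino-acid rate within [0.03, 0.07] and each individual amino
acid within 3 binomial SEs of 0.05.

Property scales (aromaticity, polarity, charge at pH 7, hydropathy,
flexibility, surface exposure, β-sheet and coil/turn frequency, disorder and
order propensity, bulkiness) ship as an editable TSV
(`inst/extdata/property_scales.tsv`). Each scale's provenance note names the
literature scale it mirrors (Kyte–Doolittle hydropathy, Zimmerman bulkiness
and polarity, Chou–Fasman propensities, a TOP-IDP-style disorder ranking,
a sign-flipped Janin transfer energy for exposure, Bhaskaran–Ponnuswamy
flexibility). These are explicit, swappable stand-ins chosen by property
name — different conventions can be dropped in by editing the TSV or passing
an alternative table. The sequon-X property classes derive from the same
tables: hydrophobic = positive Kyte–Doolittle hydropathy, bulky = upper half
of the bulkiness scale, acidic {D,E}, basic {K,R,H},
small {G,A,S,C,T,P,N,D}, hydrophilic = complement of hydrophobic. Note that
under the Kyte–Doolittle definition tryptophan is *not* hydrophobic
(KD −0.9) although it is bulky; users preferring a set-based hydrophobicity
convention can pass their own class table to `classify_x()`.

## Conservation

Ortholog alignments carry a designated reference (human) row; analysis
positions are defined on the ungapped reference and mapped to alignment
columns through `ref_map`. Column conservation is Shannon entropy in bits,
`H = −Σ p_i log2 p_i` over column symbol frequencies. The default gap
policy treats the gap as a 21st symbol (bound log2 21); the alternative
drops gapped rows (bound log2 20, `NA` for all-gap columns). Both policies
are exposed because alignment-variability servers differ on this point, and
the choice is recorded in output headers. Mean entropies are reported for
neighborhoods, both control classes, and the full protein length, since a
neighborhood can sensibly be compared either to matched 11-mers or to the
whole protein.

The evolutionary-trace rank is the classic integer trace: internal tree
nodes sorted by distance from the root define partition levels 1..L; at
level k the leaves fall into groups, and a column's rank is the smallest
level at which every group is monomorphic (gap distinct). Invariant columns
get rank 1; a column with a distinct residue per leaf gets rank = number of
leaves. Ties in node depth are broken by node number — deterministic, and
only reachable with zero-length branches. Unrooted input trees are
midpoint-rooted with a warning. The implementation is verified against an
independent graph-components oracle (delete the activated nodes, take
component leaf sets) on random 6-leaf trees.

## The synthetic generator

The generator emulates the *structure* of an annotated glycoprotein cohort,
not protein evolution:

* **Architecture** — alternating ordered/disordered segments; ordered
  segment lengths uniform on [30, 80], disordered lengths the same draw
  scaled by `f/(1−f)` for target disordered fraction `f` (default 0.35,
  a typical extracellular-protein disorder load). Protein lengths uniform
  on [300, 600].
* **Composition** — residues drawn iid per segment from two 20-vectors:
  the disordered composition up-weights P, E, S, R, Q, N, M (disorder-
  associated, long-side-chain residues) plus K and D; the ordered
  composition up-weights W, F, Y, I, L, V, C. Simple documented multipliers
  on a uniform base, normalized; a χ² goodness-of-fit test in the suite
  confirms realized segment composition matches the parameters.
* **Glycosites** — 1-5 per protein, each placed in an ordered segment with
  probability `p_glycosite_ordered` (default 0.8, so the default cohort
  reproduces the ordered-enrichment regime). Sites are planted by rewriting
  an in-segment tripeptide to N-X-S/T (X ≠ P drawn from the segment
  composition), at least 6 residues from each terminus and 11 residues
  apart, so every planted site is a canonical sequon with a full, cleanly
  attributable neighborhood. Forced-infeasible placements (e.g. bias 1.0
  with no ordered segment) retry a bounded number of times, then error.
* **Orthologs** — chimp, mouse, chicken rows derive from the reference by
  iid per-site substitutions with probability `branch_scaling × rate`, where
  the rate is region-specific (defaults: neighborhood 0.02, other ordered
  0.05, disordered 0.2 substitutions/site/lineage) and replacements are
  redrawn from the segment composition excluding the current residue. No
  indels, so alignments are gapless and `ref_map` is the identity — entropy
  attribution is unambiguous. The topology is fixed and ultrametric,
  (((human, chimp), mouse), chicken), with relative divergences 0.5/1.5/3.0.
  This is composition-resampling, not an empirical substitution matrix: only
  rank and entropy *contrasts* between regions are needed, not realistic
  phylogenetics.

All randomness flows from one cohort seed through per-protein subseeds
(drawn once via `sample.int`), so any single protein is reproducible in
isolation and identical seeds give byte-identical cohort files.

What passing tests on this generator do **not** show: real disorder
annotations are noisy threshold calls, real glycosites are sometimes
annotated off-sequon (the QC report counts these instead of erroring), real
neighborhoods overlap and straddle boundaries more messily, and real
ortholog alignments contain indels and rate heterogeneity beyond two region
classes. The generator establishes correctness of the machinery, not
biological realism.

## Problem sizes

The test suite runs cohorts of 10-200 proteins; the unbiased-generator
size check uses 200 replicate cohorts of 200 proteins and the entropy
contrast 100 cohorts of 100 proteins, both at protein lengths 150-300 (the
contrast and the test size are insensitive to length, and shorter proteins
keep the full suite under ~5 minutes). Bootstrap calibration uses 1,000
iterations per run across 500 runs; real analyses default to 10,000
iterations. `scripts/acceptance.R` uses a 150-protein cohort at the default
lengths with 10,000 bootstrap iterations.

## Known limitations

* The ordered/disordered dichotomy ignores disorder probability; partially
  disordered windows are only flagged via locale purity.
* The bootstrap z-test assumes approximate normality of `D`; for very rare
  residues in small pools the permutation cross-check is the safer tool.
* Property scales are stand-ins selected by property name, not recovered
  tables from any specific prior analysis; conclusions about individual
  scales depend on that choice.
* The integer evolutionary trace ignores within-group residue similarity
  (no real-valued weighting) and the 4-taxon default tree gives ranks a
  coarse 1-4 range.
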