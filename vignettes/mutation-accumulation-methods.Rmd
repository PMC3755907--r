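---
title: "Models and methods behind the mapipe mutation-accumulation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mapipe mutation-accumulation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapipe)
```

## The experiment the package models

In a mutation-accumulation (MA) assay a haploid strain is passaged through
repeated single-colony bottlenecks, so that selection is largely
neutralised and spontaneous mutations accumulate at their intrinsic rate;
whole-genome sequencing of the end point then reveals every fixed
mutation. In mismatch-repair (MMR) deficient yeast (`msh2` loss of
function) the dominant mutational mechanism is replication slippage at
tandem repeats: the per-base-pair mutation rate rises by two orders of
magnitude, and the spectrum is dominated by single-unit insertions and
deletions at homopolymeric runs and at di-/trinucleotide microsatellites,
with strong class-specific direction biases (deletions at homopolymers,
insertions at (AT)n dinucleotides).

`mapipe` re-implements the downstream analysis of such an experiment as a
reusable pipeline: repeat census, mutation classification, rate and
spectrum estimation, bias/proximity statistics, and Luria-Delbrück
fluctuation-assay estimators. Because the raw sequencing data of the kind
of study this models is generally not redistributable, the package also
contains a first-class synthetic-data generator that produces every input
the pipeline consumes, plus small plain-text fixtures holding published
genome-wide count tables for the reporting layer.

## Repeat census

`find_repeats()` reports every *maximal perfect* tandem repeat with unit
length 1–4. Coordinates are 0-based half-open throughout the package
(1-based only at the VCF boundary), so `end - start = unit_len * n_units`
holds exactly. Three conventions matter:

* **Thresholds.** Homopolymers are censused from 3 bp and larger units
  from 3 full units (both configurable). Mutations have been observed at
  4 bp runs and 3-unit microsatellites, so the census deliberately extends
  one length class below observed mutability to provide denominators.
* **Overlap resolution.** A region that is perfect under several unit
  lengths is reported once, under the smallest unit: the unit of a
  reported locus must be *primitive* ("ATATAT" is an AT repeat, never an
  AA-like 1-mer nor a 3-mer). Partially overlapping repeats of genuinely
  different units are all reported. Where a repeat stretch admits several
  phases (e.g. a 5 bp "CACAC" stretch), the leftmost full-unit placement
  is reported.
* **Motif classes.** Units are pooled over strands and rotations into
  classes labelled `X/complement(X)` ("A/T", "GT/CA", "AAC/TTG", ...).
  No single base ordering reproduces all the conventional labels, so the
  representative is the lexicographically smallest member of the
  rotation/reverse-complement closure with three conventional overrides
  (GT, GA and ATG classes). Note one consequence of full
  rotation+reverse-complement collapse: AAT-type and ATT-type
  trinucleotides are a single class, because revcomp(AAT) = ATT.

`nearest_neighbor_distances()` gives each locus its minimum end-to-start
gap to any other locus on the chromosome (0 for touching or overlapping
loci, `NA` for a chromosome with a single locus). These distances feed the
proximity analysis.

## Mutation classification

Substitutions collapse onto six strand-symmetric classes (G:C>A:T,
A:T>G:C, G:C>T:A, G:C>C:G, A:T>T:A, A:T>C:G) and transition/transversion
status. Indels are first left-aligned against the reference (the VCF
normalisation; positions inside a repeat are otherwise ambiguous), then
assigned to a repeat locus when the breakpoint touches the locus interval
(gap 0) and the inserted/deleted sequence is a whole number of unit copies
up to rotation; when several loci qualify the longest wins, ties broken
leftmost. A multi-unit indel counts as one event with a signed
`units_changed`.

Two filters mirror standard MA practice: `remove_shared_mutations()`
drops any identical variant present in three or more lineages (such
variants almost certainly pre-date the founding of the lines), and
`filter_span_coverage()` keeps an indel only when at least three reads
span the full repeat in both sample and ancestor — modelled here as
explicit per-call spanning-read counts.

`detect_boundary_shift()` flags substitutions at the junction of two
repeats (gap ≤ 1 bp) whose mutant sequence re-decomposes as one repeat
extended by one unit and its neighbour contracted by one — the signature
of a double slippage event rather than a polymerase substitution error.
The detector re-scans a 20 bp window on each side with relaxed minimum
sizes (2 bp / 2 units), so a contracted run is still recognisable; a
partner contracted below two units is not detected, which we accept as a
conservative bound.

## Rates, spectra and regime fits

Rates are events over opportunity. For per-bp rates the opportunity is
`lineages x generations x callable genome size`; the default callable
size, 1.216e7 bp, is the value implied by the published per-lineage rates
and event counts, and absolute-rate checks carry a ±3% tolerance owned by
that derivation. Generations default to 170 per lineage. Confidence
intervals on event counts are exact Poisson (Garwood), i.e.
`qchisq(a/2, 2k)/2` to `qchisq(1-a/2, 2k+2)/2` scaled by the opportunity.

Length-stratified rates use `L` = run length in bp for homopolymers and
unit count for larger microsatellites. `fit_regimes()` fits ordinary
least squares of `log10(rate)` on `L` over 3–8 (reported as
`fold_per_unit = 10^slope`) and a linear fit of rate on `L` for `L >= 9`.
Zero-rate lengths are excluded from the log fit and reported; a regime
with too few informative lengths is marked unavailable rather than
extrapolated. Rows with repeat span ≥ 14 bp are flagged as potential
underestimates: short-read indel detection degrades once reads must span
long repeats, which the simulator reproduces as parametric dropout.

Spectrum tables use the six-category layout (deletions/insertions at
homopolymers, transitions, transversions, insertions/deletions at larger
microsatellites) with percentages of the grand total. Report rounding
follows the field's tables: two significant figures for rates, integers
for fold inductions, one decimal for percentages.

## Bias, proximity and spectrum-comparison statistics

The insertion/deletion bias test is a Pearson chi-square against a 50:50
split, df = 1, **without** Yates continuity correction — the correction
must be absent to reproduce the conventional p-values from small count
tables (e.g. 10/28 gives p = 3.5e-3). Classes with fewer than five events
are computed but flagged low-n.

The proximity statistic is a two-sample Kolmogorov–Smirnov D between
nearest-repeat distances of mutated loci and of all loci, computed as the
exact supremum over the pooled support; the p-value is the asymptotic
Smirnov series evaluated at
`(sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D` with
`ne = n1*n2/(n1+n2)` — the same form MATLAB's `kstest2` uses, appropriate
because repeat censuses provide thousands of distances. Ties are handled
by the right-continuous ECDF convention on integer bp gaps.

`compare_spectra()` is a Monte-Carlo Fisher-type exact test for 2 x k
category tables: the p-value is the probability, over
margin-preserving tables sampled with `r2dtable`, of a table no more
likely than the observed one under the multivariate hypergeometric law
(10^5 tables by default, seed mandatory). On 2 x 2 tables it converges to
the closed-form Fisher exact p; a chi-square p is reported alongside.

## Fluctuation analysis

`ld_pmf()` implements the standard recursion for the Luria–Delbrück
mutant-count distribution: `p0 = exp(-m)`,
`p_k = (m/k) sum_{j<k} p_j/(k-j+1)`. Two estimators sit on top:

* `p0_estimate()`: `m = -log(zero fraction)`, per-division rate
  `m/n_final`, with a Clopper–Pearson interval on the zero fraction
  propagated through `-log`. It requires at least one zero culture and
  refuses otherwise (directing to the MLE).
* `mss_mle()`: maximises the full likelihood by derivative-free search on
  `log m` over [1e-6, 1e3] (relative tolerance 1e-6 on m). Jackpot counts
  above 1000 are lumped into a single tail class; the tail above that
  point holds only about `m/1000` of the probability mass, and lumping
  keeps the quadratic recursion cheap. The 95% interval uses the standard
  normal approximation on `ln m` with
  `sigma = 1.225 m^-0.315 / sqrt(cultures)`.

The per-division rate is defined as `m / n_final` (with
`n_final >> n_initial` the number of divisions is approximately
`n_final`). Plating efficiency and phenotypic lag are not modelled.

The forward oracle, `simulate_fluctuation()`, grows each culture through
its `n_final - n_initial` successive divisions with per-division mutation
probability; a clone founded at population size `N` expands
deterministically to `floor(n_final/N)`. The asynchronous formulation is
deliberate: it yields the classic clone-size law `P(k) = 1/(k(k+1))` and
matches `ld_pmf` to total-variation distance well below 0.01 at m = 1,
whereas synchronous whole-population doubling would force clone sizes
onto powers of two and differ from the Luria–Delbrück distribution by
TVD ≈ 0.1 — a lattice artifact, not an estimator defect.

## The synthetic-data generator

`sim_config()` defaults describe a reduced-scale MA experiment: a 1 Mb
genome in four unequal chromosomes at GC 0.38, 16 lineages, 170
generations, substitutions at 4.8e-9 per bp per generation, and the
class-specific deletion biases (A/T 0.93, C/G 0.74, AT/TA 0.37, GT/CA
0.65). The genome background is i.i.d., which already supplies short
repeats in genome-like, geometrically decreasing abundance; the embedded
`repeat_spec` (~300 loci) tops up the long tail (7–8-unit runs, long
dinucleotide arrays, 14–15 bp runs for dropout behaviour) that a 1 Mb
random sequence lacks. Embedded loci have their flanking bases fixed so
each is exactly maximal: the census of the emitted genome always contains
the truth list at exact coordinates.

Slippage rates follow the observed length dependence: rate
`base * fold^(L-3)` up to 8 units (defaults `base = 2e-7` per repeat per
generation, `fold = 4`), then linear growth (`+0.5` of the 8-unit rate
per extra unit), capped at 0.05 per generation. The base rate is a scale
choice for a 1 Mb genome: it gives hundreds of slippage events across the
3–8-unit range — enough to estimate the fold-per-unit — while keeping the
per-locus cumulative event probability low, so each locus almost always
carries at most one event per lineage, matching both the accumulation
model's assumption and the regime real genomes are in. Loci whose nearest
repeat lies within 3 bp get a configurable rate multiplier (default 3),
emulating the elevated mutability of repeat-dense neighbourhoods; a
`cluster_fraction` of embedded repeats is placed with a companion
homopolymer 0–3 bp away so that such neighbourhoods exist.

The lineage simulator is the neutral accumulation model: every mutation
fixes in the single bottlenecked survivor; selection during
inter-bottleneck expansion is ignored, so the bottleneck interval is
metadata only. Loci with non-negligible expected event counts are stepped
generation by generation (the rate tracks the drifting length); for the
vast low-rate remainder the per-lineage event count is drawn in one
Poisson step at the reference length, exact up to the vanishing
probability of a same-locus second hit. Emitted VCFs contain one
anchored, left-aligned record per locus whose net length changed, so
multiple partially cancelling events at one locus appear — as they would
to a variant caller — as a single net indel. De novo repeat creation by
substitutions is ignored for rate accounting. Per-lineage RNG streams are
derived from the master seed by fixed offsets, making each lineage
independently reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: read-level errors and alignment artifacts
(dropout is parametric, not read-based), non-uniform base composition and
chromatin or replication-timing structure, selection, aneuploidy, and
interrupted or compound repeats.

## Problem sizes and determinism

The shipped test-suite and acceptance checks use: 25 random 600 bp and
100 random 2 kb sequences for scanner/oracle equivalence; 1e6 simulated
cultures for the distribution cross-check; 200 replicate fluctuation
experiments of 48–96 cultures for estimator recovery; and 20 independent
end-to-end replicates of the full 1 Mb / 16-lineage / 170-generation
design for parameter recovery (about half a minute on one core). Every
simulation takes an explicit seed and is reproducible bit for bit from
(seed, configuration).

## Known limitations

* Perfect repeats only; interrupted or compound microsatellites are out
  of scope, and tetranucleotides, though censused, are excluded from rate
  curves by default for sparsity.
* The boundary-shift detector requires both partner repeats to remain at
  ≥ 2 units in the mutant decomposition.
* The MSS confidence interval is a normal approximation on `ln m`; for
  very small culture counts a likelihood-ratio interval would be wider.
* `spectrum_table()` counts only indels assigned to a repeat locus in its
  microsatellite categories; unassigned indels (rare in MMR-deficient
  spectra) are reported as an attribute, not a category.
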