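---
title: "Methods: models, calibrations and design choices in mitophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibrations and design choices in mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

mitophylo implements the analysis chain of a mitogenome phylogeography
survey: variant scoring, haplogroup tree construction, motif-based
classification, ρ-statistic dating, skyline post-processing and spatial
frequency interpolation. This vignette records the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the package's synthetic benchmarks do and do not demonstrate.

## Variant scoring and nomenclature

Sequences are assumed pre-aligned to reference coordinates — the universal
convention for human mtDNA, where positions are named against a standard
reference (rCRS or RSRS). The scorer is a per-site comparison over the
sequenced intervals: `N` on either side skips the site (this also handles
the spacer placeholder at position 3107 of the rCRS, which is stored as
`N`), an alignment gap in the sample becomes a deletion, and any ambiguity
code other than `N` is rejected rather than guessed. Insertions cannot be
expressed in fixed reference coordinates, so they are accepted only as
pre-encoded labels (`573.1C`), never inferred.

Labels follow PhyloTree conventions exactly: uppercase derived allele =
transition, lowercase = transversion, `.k` suffix = k-th inserted base,
`d` = deletion. The parser enforces consistency between the case of the
derived allele and the substitution class implied by the allele pair, and
the formatter is its exact inverse on canonical labels (property-tested
over random labels). Heteroplasmy codes are rejected: a population survey
scores fixed differences.

Which reference anchors a motif table is deliberately a *parameter*: the
reference (sequence, length, partition annotation) is always supplied by
the user or the simulator, never embedded. Real surveys score against both
rCRS and RSRS; the package takes no position on which, it simply scores
against whatever `reference_system` it is given.

The partition annotation (control region, rRNA+tRNA, codon positions 1–3,
other) must tile the genome. Coding positions are labelled by codon
position, which lets `classify_variant` reconstruct the codon around any
coding site and decide synonymy by translating reference and mutated codon
under the vertebrate mitochondrial code. Synonymy is defined only for
substitutions in coding partitions; everywhere else it is `NA`.

## Tree construction

Published haplogroup trees are curated by hand. The builder formalises
that curation as a deterministic, reproducible rule:

* Every distinct variant label is a binary character with a carrier set.
* Characters carried by all samples form the root motif (the edge into the
  root clade).
* If the remaining carrier sets are laminar (pairwise nested or disjoint),
  the result is the **unique perfect phylogeny**: one edge per character
  group, polytomies preserved as they are — a basal polytomy is reported
  as such, never arbitrarily resolved into bifurcations.
* Under conflict, characters are placed greedily in order of descending
  site weight, then descending carrier count (ties by position, then
  label): a later character whose carrier set straddles already-placed
  blocks is fragmented across them, i.e. it **recurs** as a repeat event
  on several edges. This mirrors the curator's instinct that the rarer or
  hypermutable character is the homoplasic one.

The `weights` argument is the hook for hotspot knowledge: down-weighting
notoriously recurrent control-region sites (152, 16309, …) makes them lose
conflicts against stable coding characters. The weight table is
configuration, not canon — published curation rules live in the curators'
heads and in references we do not reproduce, so the package exposes the
mechanism and leaves the numbers to the user (default: weight 1
everywhere).

Parsimony lengths are computed per site with Hartigan's algorithm, which
is exact on multifurcating rooted trees (the Fitch two-pass is its binary
special case), and summed over sites. The test suite checks it against
exhaustive enumeration of internal state assignments on all instances up
to 7 leaves, and against an independent phylogenetics library. A greedy
tree's realised length is minimal for single-conflict instances (verified
against all rooted 5-taxon topologies) and never below the
perfect-phylogeny lower bound; with many overlapping conflicts it is a
heuristic, as any non-exhaustive method must be.

Clade naming follows the field's convention: the root name's children take
letters when the parent name ends in a digit and digits otherwise, ordered
by descending subtree size, then lowest defining position. Partial
profiles are accepted by the builder but count as non-carriers at sites
they do not cover; the intended workflow, as in real surveys, is to build
the tree from complete genomes and place partial records by motif
assignment.

## Motif assignment

A clade's expected variant set is the concatenation of motifs from the
root to that clade. A profile is scored for every named clade as
`matched − missing`, evaluated **only over motif sites inside the
profile's sequenced range** — this is what makes control-region-only
records assignable. The maximiser wins; ties go to the shallower clade
(claim no more resolution than the data support); a profile matching
nothing is `unassigned`, mirroring the real-world outcome of lineages that
fit no named branch. `motif_tree()` builds the clade-nesting skeleton
directly from a published motif table, so assignment does not require
re-deriving the tree from sequences.

## ρ dating and clocks

For a clade with `n` tips, `ρ = (1/n) Σ_e m_e n_e` (mean mutational
distance from the clade root to its tips) and
`σ = sqrt(Σ_e m_e n_e²)/n`, the standard error when per-edge counts are
independent Poisson draws. The edge subtending the clade (its defining
motif) is ancestral to the clade's coalescence and is never counted.

Conversion to years is `t = ρ/(μ·L)` with a clock defined by a per-site
rate μ and a countable-site total L. The shipped complete-mtDNA clock uses
μ = (1.665e-8 + 1.708e-8)/2 = 1.6865e-8 substitutions/site/year over
L = 16,569. A synonymous clock is a second filter/rate pair: `compute_rho`
can count synonymous changes only, and the clock object refuses
mismatched filter/clock pairings. The synonymous rate and its effective
site count are external calibrations and therefore configuration, not
constants baked into the package.

Published mutation-rate calibrations are nonlinear in time (purifying
selection inflates apparent rates at shallow depths). The package does not
re-derive any published correction formula; instead `clock_correction`
accepts any strictly increasing map with `f(0) = 0` — as a function or as
a two-column table interpolated piecewise-linearly and extended linearly
beyond its last row — and applies it identically to ρ ages (point estimate
and both CI bounds) and to skyline time grids. One correction object is
the single source of truth for both. σ is propagated to years through the
linear part of the clock (`σ_years = σ/(μ·L)`, delta method); the 95%
interval maps `ρ ± 1.96σ` through the full nonlinear clock and is floored
at zero.

Clade-age comparison is a normal z test on the propagated standard
errors. The underlying survey literature reports a "t-test" for such
contrasts without defining its inputs; the z comparison on Saillard errors
is the defensible formalisation, and it is labelled as such in outputs.

## Skyline post-processing

Skyline exports (tab-separated: time, mean, median, upper, lower — the
usual posterior-analysis column layout, recognised case-insensitively) are
validated on read: strictly increasing time grid, positive N~e~, HPD
bounds bracketing the median, with offending rows cited by number.
`correct_timescale` maps the grid pointwise through a clock correction and
touches nothing else; because corrections are strictly increasing the grid
order is preserved, and corrections compose (`g` after `f` equals
`g ∘ f`), which the tests exercise. Plotting is cosmetic (median line,
dashed HPD bounds, log N~e~ axis) and untested.

## Spatial statistics

Frequencies are percent carriers per population; carrier status includes
subclades, resolved by tree descent when a tree is supplied and by
haplogroup-name nesting otherwise. Populations sampled below a floor
(default n < 5) are flagged rather than dropped.

Kriging is *ordinary* kriging on the semivariogram: at each grid node the
weights solve the constrained system with Σw = 1 (checked to 1e-10 in the
tests), giving exact interpolation at observations when the nugget is
zero. Variogram models: spherical, exponential, linear; fitted by weighted
least squares on a binned empirical semivariogram (weights = pair counts,
12 bins, cutoff one third of the maximum distance by default). The
original survey maps were drawn with a commercial tool whose settings are
not public, so every variogram parameter here is explicit configuration
with logged values — surfaces are comparable to published maps
qualitatively, not numerically. Distances are great-circle (haversine, km)
on degree coordinates, appropriate at continental scale; a planar option
exists for synthetic tests where hand-checkable geometry matters.
Predictions outside [0, 100] arise from negative kriging weights
(screening) and are clipped with a message.

## The synthetic-data generator

The generator defines the study conditions under which the package's
claims are tested.

* **Reference**: 2,000 bp — a 400 bp control region, a 1,200 bp
  protein gene (400 codons, so synonymy is exercised), rRNA/tRNA filler
  and an `other` remainder. Small enough for exhaustive oracles, with the
  full partition structure of the real genome.
* **Mutation process**: per-edge counts Poisson(μ·L·years), positions
  uniform without within-edge repeats, derived alleles at a 20:1
  transition:transversion ratio (mtDNA-like). Repeat hits across edges are
  allowed and produce genuine homoplasy for the tree builder. The default
  per-site rate μ = 1.4e-7/site/year makes the per-genome rate μ·L =
  2.8e-4/year match the real complete-mtDNA clock, so mutation counts per
  lineage are realistic for Holocene-to-LGM timescales.
* **Genealogies**: star (the ρ calibration's reference shape) or Kingman
  coalescent (exponential epochs, rate `choose(k,2)`), both rescaled to an
  exact TMRCA — ultrametricity is asserted, and the Kingman epoch
  structure is tested against the closed-form epoch expectation.
* **Survey layout**: eight populations across the Near East, South Asia,
  Europe and Central Asia (25 samples each), three clades with TMRCAs of
  18, 10 and 6 kya and east–west frequency gradients (the older clade
  peaking in the Near East/Indus, the younger in Mediterranean Europe, the
  minor one South-Asia-specific) — the canonical shape of a two-phase
  dispersal history. Carrier counts per population are deterministic
  (`round(n·f)`), so truth frequencies are exact bookkeeping.
* **Motifs**: root motif of 11 variants, clade motifs of 5, positions
  drawn with control-region sites up-weighted 5× (the control region is
  hypervariable in real mtDNA) and each clade motif forced to contain at
  least one control-region site — real haplogroup motifs are, by survey
  design, classifiable from control-region data. 40% of samples carry
  control-region-only coverage, mirroring the usual mix of complete and
  partial records.
* **Determinism**: every generator takes a seed and restores the ambient
  RNG state; one master seed drives a whole study.

What the synthetic benchmarks therefore show: the estimators are unbiased
and correctly calibrated *under their own model* (Poisson clock, known
reference, no sequencing error, no heteroplasmy, no recombination — the
last being a safe assumption for mtDNA). What they do not show: robustness
to alignment artefacts, rate heterogeneity beyond the partition structure,
sample contamination, or biased geographic sampling. Those failure modes
must be judged on real data.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` use: 100 random parsimony
instances of up to 7 leaves and 12 sites against exhaustive enumeration;
20 random conflict-free matrices (6–14 taxa) for perfect-phylogeny
recovery plus an 8-branch basal-polytomy fixture; 200 star clades of 15
tips at a true age of 18,600 years for ρ calibration and interval
coverage; 10^5^ Poisson resamples for the σ check; 100 replicate pairs of
30-tip clades at 18 vs 10 kya for the age-contrast power; and a 200-sample
survey for assignment accuracy and kriging. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being checked while
keeping a full run in minutes on one core.

One benchmark deserves honesty: with 30-tip star clades at 18 vs 10 kya
under the complete clock, the expected z statistic of the age contrast is
about 4.4, so the per-replicate power of a p < 0.001 call is roughly 0.87,
not ≥ 0.95 — a detectable contrast, but not one detected in 95% of
replicates at these sample sizes. The package reports the realised power
rather than overstating it.

## Known limitations

* The tree builder is a greedy perfect-phylogeny surrogate for expert
  curation, not a full maximum-parsimony search; with dense homoplasy it
  can exceed the optimum, and no bootstrap support is computed.
* Insertions and heteroplasmies are carried as labels only; scoring never
  infers them from alignments.
* The synonymous clock's rate and site count, all hotspot weights, and any
  nonlinearity-correction curve are external calibrations the user must
  supply.
* Kriging assumes second-order stationarity of the frequency field;
  strong continental trends would call for universal kriging, which is
  out of scope.
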