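# mitophylo

An R toolkit for mitochondrial-DNA phylogeography of the kind used to trace
maternal lineages (haplogroups) across continents: it scores mitogenome
variants against a reference sequence, builds maximum-parsimony haplogroup
trees with clade-defining motifs, assigns complete and partial sequences to
haplogroups, dates clades with the ρ statistic under calibrated molecular
clocks, rescales Bayesian-skyline time axes through nonlinear clock
corrections, and interpolates haplogroup frequencies onto geographic grids
by ordinary kriging. A seeded coalescent simulator generates complete
synthetic surveys with known ground truth, so every stage is testable
without any external data.

It is aimed at population geneticists who work with human (or other
vertebrate) mitogenome collections — the combination of complete sequences,
control-region-only records, population coordinates and published motif
tables that a typical haplogroup survey produces.

## The statistics at the core

**Variant nomenclature.** Mutations are written PhyloTree-style against a
reference: `T152C` (transition, uppercase derived allele), `A16318t`
(transversion, lowercase), `573.1C` (insertion), `A249d` (deletion).

**Haplogroup tree.** For conflict-free binary characters the builder
returns the unique perfect phylogeny — edges carry mutation events,
polytomies are preserved. Conflicting (recurrent) characters are resolved
greedily by descending site weight, then carrier count, with the weaker
character recurring as a repeat event; hypermutable sites can be
down-weighted. Parsimony lengths are computed site-wise with Hartigan's
exact generalisation of the Fitch two-pass, so multifurcations are scored
correctly.

**ρ dating.** For a clade with `n` sampled tips,

    ρ = (1/n) Σ_e m_e n_e        σ = sqrt(Σ_e m_e n_e²) / n

summing over edges inside the clade (`m_e` mutations on edge `e`, `n_e`
tips below it); σ is the Saillard standard error under Poisson mutation.
Ages follow as `t = ρ / (μ·L)` for a clock with per-site rate μ over `L`
countable sites; the default complete-mtDNA clock uses the mean of two
published whole-genome rates, `(1.665e-8 + 1.708e-8)/2 = 1.6865e-8`
substitutions/site/year. Any strictly increasing calibration curve
(time-dependent rate, purifying-selection correction) can be loaded as a
two-column table and is applied identically to ρ ages and to skyline time
grids. Clade ages are compared with a normal z statistic on the propagated
standard errors.

**Spatial surfaces.** Population frequencies (percent carriers) are
interpolated by ordinary kriging — weights solve the semivariogram system
under the Σw = 1 unbiasedness constraint, with spherical / exponential /
linear variogram models fitted by weighted least squares and great-circle
(haversine) distances on degree coordinates. Gene diversity uses the
unbiased estimator `H = n/(n−1)·(1 − Σ p_i²)`.

## A worked example

Simulate a survey (8 populations across four regions, three clades with
coalescence ages 18, 10 and 6 kya), rebuild the tree from the complete
genomes, and date the oldest branch:

```r
library(mitophylo)
study <- simulate_study(seed = 42)
labs  <- study$truth$labels
complete <- labs$sample_id[!labs$partial & labs$clade != "background"]

tree   <- name_clades(build_mp_tree(unname(study$profiles[complete])), root_name = "U")
motifs <- extract_motifs(tree)
motifs[["U1"]]
#> [1] "T139C"  "C342T"  "G368A"  "T871C"  "A1164G"
identical(motifs[["U1"]], study$truth$motifs$Ua)   # motif recovered exactly
#> [1] TRUE

clock <- clock_model("custom", mu = study$config$mu, L_effective = study$ref$length)
compute_rho(tree, "U1")
#> <rho_estimate> U1: rho = 3.92 (sigma 1.101), n = 25, filter = all
rho_to_age(compute_rho(tree, "U1"), clock)
#> <age_estimate> U1: 14000 years (95% CI 6291-21709), custom clock
```

The branch auto-named `U1` carries exactly the five defining mutations of
the simulated 18-kya clade; its ρ-based age (14.0 kya, 95% CI 6.3–21.7)
brackets the truth — with 25 tips on a coalescent genealogy the interval is
wide, which is precisely why the package propagates σ everywhere.

Assignment and mapping run off the same objects:

```r
report <- assign_all(unname(study$profiles), study$truth$motifs,
                     motif_tree(study$truth$motifs, "U", L = study$ref$length))
table(report$clade)
#>         Ua         Ub         Uc unassigned
#>         38         23          7        132
tab  <- tabulate_frequencies(report, study$metadata, "U")
surf <- krige(tab, variogram_spec = "spherical")
```

(The 132 unassigned records are the simulated non-carrier background.)
`run_pipeline("all", config)` chains score → tree → assign → date → map
over files on disk and writes a manifest with hashes and the master seed.

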