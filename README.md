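# cpPhylogeo

Phylogeographic and historical-demographic analysis of chloroplast DNA
(cpDNA) haplotype data in R, built for studies of the kind done on Mexican
cloud-forest *Magnolia*: a few non-recombining plastid regions sequenced for
~100 individuals across structured populations, analysed from haplotype
networks all the way to coalescent model choice.

The package is aimed at population geneticists who today stitch this
workflow together across DnaSP, Arlequin, PERMUT, POPART and DIYABC, and
want one scriptable, seeded, testable pipeline instead.

## What it computes

* **Alignment handling** — aligned FASTA input (Biostrings), region
  concatenation with partition bookkeeping, complete-deletion filtering of
  gap/ambiguity columns, and site classification (polymorphic,
  parsimony-informative, singleton).
* **Haplotypes** — collapsing to a haplotype × population count table and a
  median-joining network (Bandelt–Forster–Röhl, ε = 0 by default) with
  GraphML and POPART-style NEXUS writers.
* **Diversity and structure** — haplotype diversity
  *Hd* = n/(n−1)(1 − Σpᵢ²) with Nei's sampling SD, nucleotide diversity π,
  Tamura–Nei (TN93) distances, AMOVA (Excoffier–Smouse–Quattro, one- and
  two-level designs) with stratum-appropriate permutation tests, pairwise
  F<sub>ST</sub>, the Pons & Petit G<sub>ST</sub>/N<sub>ST</sub>
  phylogeographic-structure test, and Mantel isolation-by-distance.
* **Historical demography** — Tajima's D, Fu's Fs (Ewens sampling formula
  with log-space Stirling numbers) and Ramos-Onsins & Rozas R2 with
  coalescent p-values conditioned on the observed n and S; mismatch
  distributions with sudden-expansion (Rogers–Harpending) fitting,
  F<sub>j</sub>(τ, θ₀, θ₁), tested by SSD and Harpending's raggedness via
  parametric bootstrap.
* **Coalescent ABC** — a structured Hudson coalescent (haploid cpDNA
  convention) with HKY finite-sites mutation simulates five competing
  three-lineage scenarios (simultaneous split / three divergence orders /
  secondary contact); scenario choice by rejection + weighted logistic
  regression on the 1% nearest simulations, type I/II error rates from
  pseudo-observed datasets, and Beaumont-style local-linear parameter
  estimation.
* **Synthetic data** — `generateStudyLike()` emits a full study-shaped
  dataset (96 samples, 3 lineages, 20 populations, 2,858 bp) from any
  scenario so every stage is testable offline, plus `table1Fixture()`, the
  published per-population haplotype count configuration.

## Worked example

```r
library(cpPhylogeo)

g   <- generateStudyLike(seed = 1)          # synthetic study-shaped dataset
flt <- filterCompleteColumns(g$alignment)   # complete-deletion column filter
ht  <- collapseHaplotypes(flt$alignment)
ht
#> HaplotypeTable: 28 haplotypes, 96 individuals, 20 populations
flt$siteClasses
#> SiteClasses: 2858 complete columns; 37 polymorphic, 23 parsimony-informative, 14 singleton

diversityByGroup(flt$alignment, "lineage")
#>     group  N N_H      pi    Hd  Hd_sd
#> 1   north 17  10 0.00147 0.934 0.0357
#> 2 central 74  19 0.00125 0.885 0.0206
#> 3   south  5   3 0.00126 0.800 0.1640

medianJoiningNetwork(ht)
#> HaploNetwork: 28 haplotypes + 3 median vectors, 30 edges (epsilon = 0)
```

The diversity table reads like the familiar per-lineage summary: N
individuals, N_H distinct haplotypes, per-site nucleotide diversity π (here
≈ 0.001, the low-π / high-Hd regime typical of plastid data) and haplotype
diversity with its sampling SD. The network holds the observed haplotypes
plus inferred median vectors; `writeGraphML()` exports it for plotting.

A full run — diversity, AMOVA, G<sub>ST</sub>/N<sub>ST</sub>, Mantel,
neutrality tests, mismatch fits and (optionally) the ABC stage — is one
call:

```r
cfg <- pipelineConfig(out_dir = "run1")
runPipeline(cfg)   # writes TSV/JSON/GraphML reports plus a manifest
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference checks from
scratch — the closed-form haplotype diversities of the published
per-population haplotype counts — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
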