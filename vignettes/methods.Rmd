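---
title: "Models and methods behind cpPhylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cpPhylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cpPhylogeo analyses aligned chloroplast DNA from structured plant
populations: it collapses sequences into haplotypes, quantifies diversity
and differentiation, tests for demographic change, and compares competing
demographic scenarios with approximate Bayesian computation (ABC). This
vignette explains the models, the conventions chosen where the methods
literature leaves freedom, and what the tests do and do not establish.

## Data model and site filtering

A `HaploAlignment` wraps a `Biostrings::DNAStringSet` of equal-width
sequences plus per-sample metadata (population code, one of three lineages,
optional coordinates). Because the four sequenced plastid spacers are
maternally co-inherited without recombination, they are concatenated and
treated as a single locus; `concatenateAlignments()` keeps the 1-based
column span of each region.

Gaps, `N`, `?` and IUPAC-ambiguous bases are handled by **complete
deletion**: `filterCompleteColumns()` removes any column that is not pure
A/C/G/T in *every* sequence. This makes haplotype identity and all
downstream site counts well-defined — two sequences share a haplotype iff
their filtered sequences are identical — at the cost of discarding columns
that pairwise-deletion methods would partially use. Per-pair deletion is
deliberately not offered anywhere downstream. Site classes follow the
standard definitions: a column is polymorphic with ≥ 2 observed bases,
parsimony-informative when ≥ 2 bases each occur in ≥ 2 sequences, singleton
otherwise; all indices are reported in the original column coordinates.

## Median-joining networks

`medianJoiningNetwork()` implements the Bandelt–Forster–Röhl heuristic:

1. build the minimum-spanning **network** (MSN) over the current node set —
   a pair (u, v) is linked iff its Hamming distance does not exceed the
   single-linkage connection height of u and v plus ε (for ε = 0 this keeps
   *all* tied minimum connections, which is why a Hamming square resolves to
   a 4-cycle rather than an arbitrary spanning tree);
2. for every triple in which one node is linked to the two others, propose
   the majority-consensus (median) vector; add the unseen candidates whose
   connection cost is within ε of the minimum;
3. drop median vectors of degree ≤ 2 and iterate until stable.

Determinism is obtained by fixing the tie rules: nodes are processed in
lexicographic label order, and a three-way base conflict in a median is
resolved in favour of the lexicographically smallest label of the triple.
Defaults are ε = 0 and equal character weights (the POPART defaults). A
median identical to an existing node is merged, never duplicated. Haplotype
labels are `H01…` in order of first occurrence in the alignment — the
numbering mirrors the usual publication style but makes no claim to match
any specific published numbering.

## Diversity and differentiation

* Haplotype diversity `Hd = n/(n−1)(1 − Σ pᵢ²)` with Nei's (1987) sampling
  variance; reports round Hd to 2 decimals and π to 5, the usual table
  format.
* Nucleotide diversity π is the mean pairwise p-distance per site, no
  multiple-hit correction (computed via per-column base counts, which is
  algebraically identical to averaging over all pairs).
* `tamuraNeiDistance()` implements TN93 with base frequencies taken from
  the whole matrix; whenever a logarithm argument is non-positive
  (saturation) the pair falls back to its p-distance with a warning. The
  test suite cross-checks the implementation against `ape::dist.dna()`.
* AMOVA follows Excoffier–Smouse–Quattro: sums of squared distances give
  variance components for one-level (populations) and two-level (lineage
  groups) designs. Negative components are reported as-is (Arlequin
  behaviour) and percentages are computed on the signed components.
  Permutation schemes are stratum-appropriate — samples among populations
  for F<sub>ST</sub>, whole populations among groups for F<sub>CT</sub>,
  samples among populations within groups for F<sub>SC</sub> — and every
  p-value uses the (b+1)/(B+1) convention with an explicit seed.
* `gstNst()` computes the Pons & Petit (1996) unbiased estimators, with
  N<sub>ST</sub> weighting haplotype pairs by Hamming distance (the choice
  of distance is configurable; whether the original PERMUT used corrected
  distances is not documented). The permutation test shuffles haplotype
  identities on the distance matrix and recomputes N<sub>ST</sub>,
  one-tailed. Note the unbiased estimators can be slightly negative for
  identical populations; that is expected small-sample behaviour.
* Mantel isolation-by-distance delegates to `vegan::mantel()` on
  population-pair genetic distances versus geographic distances. Geographic
  distances default to great-circle kilometres; a planar decimal-degree
  option exists because at this spatial scale the published choice of
  "Euclidean" is ambiguous.

## Neutrality tests and their p-values

Tajima's D uses the standard a₁…e₂ constants; it is an explicit error when
S = 0 (not silently 0). Fu's Fs is computed from the Ewens sampling
formula, `S′ = P(K ≥ k_obs | θ = k̄)`, with unsigned Stirling numbers of
the first kind accumulated in log space so n = 96 is no problem;
`Fs = ln(S′/(1−S′))`. R2 follows Ramos-Onsins & Rozas: `Uᵢ` counts the
singleton sites whose minor base sequence *i* carries; an exact 50/50 tie
(only possible at n = 2) is credited to the carrier of the
lexicographically smaller base, a documented arbitrary-but-fixed rule.

P-values come from neutral constant-size coalescent simulation conditioned
on the observed n and S (mutations placed on branches proportionally to
length, infinite sites) — the practice behind "1,000 permutations" in the
source tools. Tails: two-sided for D, lower for Fs and R2 (small values
indicate expansion).

## Mismatch distributions

The sudden-expansion expectation is the Rogers–Harpending transient
distribution

F_j(τ) = F̂_j(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i=0}^{j} τ^{j−i}/(j−i)! [F̂_i(θ₀) − F̂_i(θ₁)],

with equilibrium F̂_j(θ) = θ^j/(1+θ)^{j+1}; as τ → 0 it collapses to the
θ₀ equilibrium. Fitting minimises the plain SSD between the observed class
frequencies and the expectation renormalised over the observed support
0..d_max (generalised least squares is deliberately not replicated — the
reported statistic is SSD, so SSD is what is minimised), by bounded
L-BFGS-B from multiple starts on log-scale parameters with θ₁ capped at
10⁴ (numerically "infinite" growth). Harpending's raggedness uses the
boundary convention that classes −1 and d_max+1 have frequency zero, so a
uniform profile contributes only its two edge terms.

Goodness-of-fit p-values are parametric bootstrap: coalescent samples are
simulated *under the fitted expansion* in mutational units (sizes θ,
expansion at time τ), each replicate refitted, and p is the fraction of
replicates with SSD (or raggedness) at least as large as observed. Samples
below n = 8 are refused by default — a mismatch distribution from a handful
of sequences is uninformative, which is also why the original study skipped
its smallest lineage.

## The coalescent simulator and ABC

cpDNA is haploid and maternally inherited, so the simulator treats every
"effective size" prior value as a **haploid copy number**: a pair of
lineages in a population of size N coalesces at rate 1/N per generation and
E[TMRCA] = N for n = 2. This convention scales all times and is the single
most important thing to know when comparing priors across tools.

Five three-lineage scenarios are built from merge/resize/admixture events
applied backward in time (north, central, south; sample sizes 17/74/5):
simultaneous divergence at t₂; the three orders of pairwise divergence at
t₁ followed by full merge at t₂; and secondary contact, where the northern
lineage is an admixture (rate r) of the other two at t₁. Priors are uniform
— sizes 10–10⁵, times 100–10⁵ generations with rejection until t₂ ≥ t₁ —
with a fixed mutation rate of 1.59×10⁻⁹ /site/year × 10-year generations.
The admixture-rate prior U(0.1, 0.9) is an assumption (the source does not
state one). HKY mutation is overlaid with κ = 2 and configurable base
frequencies; mutation events arrive as a Poisson clock at rate μ per site
and the new base is drawn from the HKY jump chain. This "mutation-clock"
parameterisation is the common simulator shortcut; at plastid divergence
levels (π ~ 10⁻³) it is indistinguishable from the exact CTMC, and the
Watterson property test runs at large L so site collisions are negligible.

Summary statistics (15): per group S, mean pairwise differences k̄, and the
mean relative frequency of the rarest base across that group's segregating
sites; per group pair, pooled S and a Hudson-type
F<sub>ST</sub> = 1 − (mean within)/(mean between), clamped to [−1, 1] with
monomorphic pairs reported as 0. Whether the original pipeline used a
Weir–Cockerham or Hudson-type F<sub>ST</sub> is unstated; Hudson-type is
the default here.

Scenario choice standardises statistics by table-wide MAD, keeps the 1%
nearest simulations (Euclidean), and fits one-vs-rest logistic regressions
with Epanechnikov distance weights and covariates centred at the observed
point, so each scenario's probability is read off the intercept; the
probabilities are normalised to sum to one and CIs propagate the
intercept's sampling variance. The plain rejection frequencies are always
reported alongside, and the code falls back to them if the regression
degenerates. Error rates classify pseudo-observed datasets (prior-drawn
parameters) by the same rule. Parameter estimation is Beaumont-style
local-linear adjustment on log10 sizes and times (raw scale for r), with
weighted posterior summaries; times are also reported in years (× 10).

Reproducibility: every simulation seeds R's RNG from a counter derived from
the master seed, the scenario id and the simulation index, so reference
tables are identical row-by-row regardless of execution order or which
scenario subsets are built.

The desk-scale default (2×10⁴ simulations per scenario) is a deliberate
reduction of the study-scale 3×10⁶; it is enough for the qualitative
properties the tests check (scenario recovery; the near-indistinguishability
of the divergence-then-merge and secondary-contact scenarios at the
study's posterior means) but posterior probabilities carry wider Monte
Carlo error than a full-scale run.

## The synthetic-data generator: a stated world

`generateStudyLike()` wraps the simulator and dresses one dataset as the
field study: 96 samples in 20 populations (4 north / 15 central / 1 south,
the published sample-size layout), 2,858 bp, synthetic coordinates along
the mountain-range gradient. The default true history is scenario 2 with
Na = 2×10⁴, N₁ = N₂ = N₃ = 6×10⁴, t₂ = 2×10⁴ generations (~200 ka) and
t₁ = 3,500 generations (~35 ka). These values were fixed once, by
calibration against the study's observed scales: current sizes at the
prior-midpoint order of magnitude, an ancestral bottleneck that reproduces
the inferred pre-LGM expansion signal, and the published divergence-time
estimate for the recent split. Under this world, per-lineage Hd lands in
[0.6, 1] and π in [2×10⁻⁴, 3×10⁻³] — the study's observed ranges — in ≥
80% of seeded draws; the remainder is honest single-locus coalescent
variance, which no parameter choice removes.

What the generator does *not* emulate: within-lineage spatial structure
(samples are split into populations by contiguous blocks, so
F<sub>SC</sub> ≈ 0 — the study's own within-group structure was weak),
alignment gaps and missing data (complete-deletion is a no-op on synthetic
data; the filtering logic is exercised by hand-built fixtures instead),
mutation-rate heterogeneity across sites, and any niche/climate covariates.
A green end-to-end test therefore establishes that the statistical
machinery is correct on data with the study's shape and scale — not that
the real alignment would reproduce any particular published value.

`table1Fixture()` carries the exact published per-population haplotype
*counts* with placeholder star-topology sequences (every haplotype one step
from the first); sufficient for frequency-based statistics, and explicitly
not a claim about the real sequences.

## Numerical and design choices, in brief

* All permutation/simulation p-values: (b+1)/(B+1), explicit seeds
  everywhere; pipelines re-run byte-identically.
* Mismatch optimiser: multistart L-BFGS-B on log parameters, bounds
  τ ∈ [10⁻⁴, 4(d_max+1)], θ₀ ∈ [10⁻⁶, 10⁴], θ₁ ∈ [10⁻², 10⁴].
* The AMOVA design ambiguity in the source (its published degrees of
  freedom imply 18 populations / 95 sequences, not the 20/96 of the
  sampling table) is exposed as configuration — callers choose the
  inclusion set; nothing is hard-coded.
* The pipeline configuration round-trips through JSON (no YAML parser in
  the supported stack); subcommand-style orchestration is provided by
  `runPipeline()` with stage toggles rather than a shell executable, since
  the package is a library first.
* Known limitations: the published supplementary alignment cannot be
  redistributed or fetched offline, so the checks that need the real matrix
  (49 haplotypes, 47/18 sites, the published F-statistics) are encoded in
  the acceptance suite but cannot pass without that file being supplied
  locally; SSD/raggedness p-values are estimator-sensitive and should be
  read as order-of-magnitude agreement with published tables.
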