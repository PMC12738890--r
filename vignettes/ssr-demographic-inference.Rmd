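---
title: "Microsatellite population genetics and coalescent-ABC demographic inference with ssrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite population genetics and coalescent-ABC demographic inference with ssrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`ssrpop` implements the analysis chain used in conservation-genetic surveys
of diploid codominant microsatellite (SSR) data on structured populations of
long-lived plants: per-population diversity statistics, differentiation and
gene flow, AMOVA, ordination and clustering, the Evanno ΔK summary of
externally-run STRUCTURE analyses, and a coalescent-simulation-based
approximate Bayesian computation (ABC) workflow for comparing demographic
scenarios and estimating effective population sizes and divergence times.
The motivating setting is an 11-population, 15-locus survey of two closely
related lime (*Tilia*) species (242 individuals, two species clusters of 8
and 3 populations), and the package ships a synthetic-data generator with
exactly that shape so that every stage is testable without access to raw
genotypes.

## Data model

A dataset is a long-format tibble: one row per individual × locus with
columns `individual`, `population`, `locus`, `allele_1`, `allele_2`. Allele
states are absolute fragment sizes in nucleotides — what a capillary
electrophoresis run reports — not repeat counts; repeat-count arithmetic
happens only inside the simulator. Genotypes are unordered pairs stored
sorted; a missing genotype is `NA` in both allele columns (code `0` in the
GenAlEx dialect on disk, `-9` in STRUCTURE output). No missing-data filter is
applied by default: the upstream study reports none, so filtering is left to
the user.

## Diversity and differentiation

Per population and locus: `Na` (observed alleles), `Ne = 1/Σp²` (effective
alleles), Shannon's `I = −Σ p ln p`, observed heterozygosity `Ho`, expected
heterozygosity `He = 1 − Σp²`, and `FIS = (He − Ho)/He`. Three conventions
matter and are deliberate:

* `He` is the biased (plug-in) estimator, as in GenAlEx table output; the
  unbiased `2n/(2n−1)` variant is available via `unbiased = TRUE` but is not
  the default, because report tables in this field conventionally show the
  plug-in value.
* Population-level `FIS` is the mean of per-locus `(He − Ho)/He` with
  monomorphic loci excluded (`He = 0` leaves FIS undefined, reported `NA`).
  Table-style summaries report mean ± SE across loci, which implies per-locus
  averaging rather than a ratio of locus means.
* Pairwise `FST` defaults to the Nei-style `(HT − HS)/HT` on the unweighted
  pooled frequencies of the pair, accumulated as a ratio of locus sums; the
  Weir–Cockerham θ is available with `estimator = "wc"`. The exact estimator
  behind published GenAlEx tables is not recoverable from the reports, so
  both are implemented and the default documented.

Gene flow uses the island-model identity `Nm = (1/FST − 1)/4`; it is
undefined (NA, with a warning) at `FST ≤ 0`. Note that the species-level
`FST` and the AMOVA percentage of variation are different estimators of
differentiation and will not agree numerically; the pipeline reports both.

AMOVA operates on individual-level Smouse–Peakall squared genotypic
distances (half the squared Euclidean distance between allele-count vectors,
values 0–4 per locus, summed over loci with pairwise deletion of missing
loci). Sums of squares come from the distance matrix, variance components by
the method of moments with `n0 = (N − Σn_k²/N)/(k − 1)`, and the
among-population P-value from permuting individuals across populations (999
permutations by default, observed configuration included, so the smallest
attainable P is 1/1000 — consistent with "P < 0.001" reporting).

Nei's (1978) unbiased genetic distance feeds both PCoA (Gower-centred
`−d²/2`, eigendecomposition; negative eigenvalues are reported but excluded
from coordinates) and UPGMA (group-average linkage, heights at half the merge
distance). Distances of population pairs that share no alleles are undefined
(`−ln 0`); they are encoded as a large finite sentinel (1e9) with a warning
so clustering stays well-defined. UPGMA ties are broken by merging the pair
whose clusters have the lexicographically smallest leaf labels, and children
are printed label-ordered — determinism that golden-file tests rely on.

ΔK consumes a plain `(K, run, logL)` table of replicate STRUCTURE runs (the
admixture MCMC itself is an external tool and out of scope) and computes
`ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))` with the mean over replicates,
flagging zero-sd cells as undefined rather than returning infinities.

## The coalescent simulator

Each locus is simulated backward in time: within a group of diploid size `N`,
each lineage pair coalesces at rate `1/(2N)` per generation (continuous-time
exponential waiting times — exact in the `N ≫ k` regime the priors put us
in). Scenario events move lineages between groups: nested splits (scenario
1), an admixture origin of the third group with proportion `ra` (scenario
2; backward in time each lineage picks the first source with probability
`ra`), or a simultaneous merge of all groups (scenario 3). At the final time
the ancestral size `Nanc` takes over, which under the `Ni ≥ Nanc` prior
constraint encodes a founding bottleneck.

Mutations are laid on the genealogy as a Poisson process with per-locus rate
`μ_l`: generalized-stepwise (GSM) repeat changes with geometric magnitude
(`P(|step| = k) = (1 − P) P^(k−1)`; `P → 0` recovers the strict stepwise
model), on a bounded ladder of 40 contiguous repeat states centred on the
founding allele (steps that would leave the ladder are redrawn — the
standard bounded-ladder device that prevents drift to absurd sizes). A
second, much rarer Poisson process adds single-nucleotide indels (SNI):
±1-nt offsets that create off-ladder allele sizes. Alleles are reported as
total nucleotide sizes (offset + motif × repeats + a constant), so SNI
variants are distinct alleles, exactly as a fragment analyzer would see them.
The founding allele is repeat state 20 with a dinucleotide motif; only
relative sizes enter any statistic.

Hyperpriors mirror the published ranges: mean rate `μ̄ ~ U(1e−4, 1e−3)` with
per-locus rates Gamma(shape 2, mean `μ̄`) truncated to `[1e−5, 1e−2]`; mean
GSM coefficient `P̄ ~ U(0.1, 0.3)` with per-locus values truncated to
`[0.01, 0.9]` — the source range "1e−2 to 9" cannot be a geometric
probability above 1 and is read as 0.9; mean SNI rate log-uniform on
`[1e−8, 1e−4]` (it spans four orders of magnitude, where a linear-uniform
would put almost all mass at the top) with per-locus values truncated to
`[1e−9, 1e−3]`. Demographic priors are uniform with rejection for the
constraints: sizes on `[10, 20000]` with every `Ni ≥ Nanc`; times on
`[10, 10000]` generations with `t1 ≤ t2 ≤ t3 ≤ t4` for scenarios 1–2 (the
events are nested in the scenario diagrams) and `t1 ≤ t4` for scenario 3,
where `Nanc` takes over at `t1` itself and `t4` triggers nothing further by
default.

The simulator is validated against closed forms in the test suite: mean
pairwise coalescence time `2N`; equilibrium `He = 1 − (1 + 2θ)^(−1/2)` under
the strict stepwise model (θ = 4Nμ); `E[(δμ)²] = 2μt` for a two-population
split; and the scale invariance that doubling all sizes and times while
halving μ leaves the FST distribution unchanged (the often-quoted invariance
in N and t alone holds only if μ is rescaled, since θ is not dimensionless).

## ABC: scenario choice and parameter estimation

Summary statistics (the ABC feature vector) are, per group: mean alleles per
locus `A`, genic diversity `H`, allele-size variance `V` (repeat units), and
the Garza–Williamson ratio `M` = alleles / (repeat-unit range + 1); per group
pair: `FST`, the shared-allele distance `DAS = 1 − Σ min(p₁, p₂)` averaged
over loci, and `(δμ)²`. The exact statistic set used by the original DIYABC
analyses is not recorded in the reports; this set is the package's documented
choice, spanning within-group diversity, bottleneck signal (`M`, `V`) and
between-group divergence at both short (`FST`, `DAS`) and long (`(δμ)²`)
timescales. `DAS` is the frequency-based population form, which is zero for
identical frequency vectors (the genotype-pair form is not, and would violate
that anchor).

Rejection standardizes every statistic by its reference-table standard
deviation and keeps the `⌈tolerance · n⌉` rows closest to the observed
vector in Euclidean distance. Scenario choice pools the per-scenario
reference tables, keeps the closest `n_closest`, and fits a multinomial
logistic regression of the scenario label on the centred statistics with
Epanechnikov weights in the distance, evaluated at the observed point; 95%
intervals come from the delta method on the fitted coefficients. Two
numerical choices deserve notice:

* The regression carries a weak ridge penalty (0.1 on standardized
  covariates, exposed as `ridge`). Without it, complete separation of
  scenarios among a few hundred accepted simulations drives the Newton
  iteration to infinite coefficients and degenerate 0/1 posteriors; with it,
  posteriors agree with the rejection-proportion estimator while retaining
  the regression's variance reduction. nnet-style fits avoid the issue only
  by stopping early, which is a less transparent form of the same remedy.
* A scenario absent from the closest set gets probability 0 with a warning
  (the regression cannot estimate a class it never sees).

Parameter estimation uses the Beaumont local-linear adjustment: each
parameter (log-transformed — sizes and times are positive and
right-skewed) is regressed on the standardized statistics over the accepted
set with Epanechnikov weights, and each accepted draw is corrected to the
observed point, `θ_adj = θ − b'(s − s_obs)`. Summaries are weighted medians
and 2.5/97.5% quantiles. A rank-deficient design falls back to the
unadjusted rejection posterior with a warning.

Two genuine limitations of desk-scale ABC with SSRs are documented here
because the test suite works around them explicitly:

* **N–μ confounding.** Heterozygosity-type statistics identify `θ = 4Nμ`,
  not `N`. When the mutation rate is itself drawn from a decade-wide
  hyperprior, a fixed true `N` cannot be recovered reliably from 15 loci;
  the parameter-recovery validation therefore fixes a known mutation model,
  which is the standard design for method-validation experiments.
* **Saturation bias.** At `θ ≈ 10`, `He` sits on its plateau and the
  relation between `log N` and the statistics is strongly nonlinear across
  the accepted region, biasing the linear adjustment; at `θ ≈ 2` (μ = 1e−4,
  N = 5000) the adjustment is in its valid regime. Recovery experiments in
  the tests use the informative statistic subset (A, H, V, FST, (δμ)²),
  since `M` and `DAS` target bottleneck/admixture signal and only add noise
  to size/time estimation.

Model checking projects the observed statistic vector into a PCA of the
standardized simulated statistics and reports the fraction of simulations
closer to the origin — a percentile radius near 100% flags an observed
dataset outside the simulated cloud.

Calendar conversion multiplies generations by the generation time (default
100 years, a conservative figure for trees that first flower at 12–40 years
and live for centuries) and reports thousands of years before present
(`ka BP`).

## The synthetic-data generator

`make_study_fixture()` emulates the survey's shape: 11 populations at the
published sample sizes (N = 242), 15 dinucleotide loci, two species
clusters. Per locus, each species draws an independent Dirichlet base
frequency vector over 6–8 alleles (landing mean `Na` in the published 3.3–7.1
range), and each population draws its frequencies from a Dirichlet
concentrated around its species base (concentration 60, giving within-species
FST of a few percent against between-species FST several-fold higher — the
qualitative structure the analyses assume). Inbreeding is a single `f` per
population, uniform on [0, 0.2] (the published per-population FIS values span
−0.13 to 0.22; the generator's sampling model cannot produce heterozygote
excess, so the lower tail is clipped at 0), with genotypes drawn as
`P(hom ii) = p² + f p(1 − p)`, `P(het ij) = 2 p p' (1 − f)`, so `E[He]`
is independent of `f` and `E[Ho] = (1 − f) He` — both verified by
Monte-Carlo tests.

What the fixture does **not** emulate: the real allele-frequency spectra
(raw genotypes are not deposited), missing data, null alleles, isolation by
distance within species, and the mutational relatedness of alleles (fixture
frequencies are exchangeable across the ladder). A green test on the fixture
therefore establishes that the machinery is correct, not that any biological
conclusion about the original survey is reproduced.

## Numerical conventions

* All stochastic entry points take an explicit seed; nothing depends on the
  global RNG state (seeds are applied via `withr`). The pipeline derives
  per-stage seeds deterministically from the master seed so stages can be
  re-run in isolation.
* Report tables round to 3 decimals for statistics and integer percentages
  for AMOVA; computations are done and stored in full precision.
* Newick branch lengths are written with 6 decimals, no label quoting.
* PCoA treats eigenvalues below `1e−9 ×` the largest as zero.
* The permutation P-value includes the observed configuration in the null
  set, `(b + 1)/(m + 1)`.

## Known limitations

STRUCTURE's MCMC, multi-level AMOVA (regions within species), HWE/linkage
exact tests and null-allele correction are out of scope. The ABC machinery
aims at methodological fidelity, not at reproducing any published posterior
from data that is not available; reference-table sizes in examples and tests
(10⁴–2×10⁴) are far below production scale (10⁶ per scenario), and users
analysing real data should scale `n_draws` up and `tolerance` down
accordingly.
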