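---
title: "Variance partitioning and host discrimination in co-inoculation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance partitioning and host discrimination in co-inoculation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhizosge` analyses experiments in which a single legume host genotype is
grown with one or two rhizobium strains from a panel, every strain pair
is replicated with reciprocal fluorescent-marker assignments across
complete blocks, and three phenotypes are measured: the nodule count
credited to each strain, each strain's share of a pot's nodules, and the
host's shoot mass. This vignette explains the models, the synthetic-data
generator, the numerical choices, and what the test suite does and does
not establish.

```{r setup, message = FALSE}
library(rhizosge)
```

## The variance-partition models

For an observation on focal strain $i$ competing against strain $j$ in
pot $p$ of block $b$, the nodule-number model is

$$y_{ijpb} = \mu + m\,x_{\text{marker}} + d_i + s_j + g_{ij} + u_b +
w_p + e_{ijpb},$$

with independent Gaussian random effects: $d_i$ the direct genetic
effect (DGE) of the focal strain, $s_j$ the main social genetic effect
(SGE) of the competitor, $g_{ij}$ an ordered-pair genotype-by-genotype
interaction, $u_b$ a block effect, $w_p$ a pot effect shared by the two
observations of a pot, and $e$ residual. The marker enters as a fixed
effect. Every variance is estimated freely (no constraints), and the
pot term accounts for the non-independence of the two rows per pot.

For nodule proportion and shoot mass the focal/competitor designation is
arbitrary, so a strain's direct and social variances cannot be
distinguished; we constrain $\sigma^2_{DGE} = \sigma^2_{SGE}$ with a
within-pot correlation of $-1$ (proportion: the two shares sum to one)
or $+1$ (shoot mass: both symbionts act on the same plant). Rather than
fitting correlated bivariate effects, the package reparameterises: one
strain-effect vector $a$ enters each pot's single row through a signed
incidence, $+1$ for focal and $-1$ for competitor (proportion), or $+1$
for both (shoot mass). The two formulations give identical likelihoods
(`test-reml.R` verifies this against a brute-force multivariate-normal
computation), and the signed version is simpler and numerically stable.
Because the two orientations of a pot are linearly dependent for these
traits (proportions sum to 1; shoot mass is one number), only one row
per pot is used, with the lexicographically smaller strain as focal —
a deterministic, orientation-free choice. Shoot mass is analysed on the
natural-log scale; variance proportions are reported on the modelled
scale without back-transformation. Pots with no nodules have undefined
proportions and are excluded from the proportion model (they are
counted and reported).

Phenotypic variance is the sum of all components as they contribute to
a single observation; the shared strain variance of a constrained model
enters twice (once through each $\pm 1$ incidence), so DGE and main SGE
are each reported as $\sigma^2_a$ over that doubled total.

### REML engine

Variances are estimated by restricted maximum likelihood. Writing
$V = \sum_k \sigma^2_k Z_k Z_k^\top + \sigma^2_e I$, the criterion is

$$\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
\log|X^\top V^{-1} X| + y^\top P y\right].$$

The residual variance is profiled out and the likelihood is evaluated
through the $q \times q$ matrix $I + D Z^\top Z D$ ($D$ diagonal in
square-root variance ratios), so each evaluation costs a Cholesky in the
number of random-effect levels rather than observations. The pot term
would dominate $q$ (448 levels at the full design), so any disjoint 0/1
grouping factor is absorbed in closed form through its block-diagonal
contribution — an algebraic identity, verified to give the same
log-likelihood as the dense path and as `lme4` on the unconstrained
model. Optimisation is over log variance ratios (Nelder-Mead from up to
three fixed starts, then an L-BFGS-B polish) with a floor of
$e^{-18}$ on each ratio; a component driven to the floor is reported as
a boundary zero. Estimates are therefore non-negative by construction
and boundary estimates are legitimate outcomes, not failures.

### Likelihood-ratio tests

Each component is tested by refitting without it:
$\chi^2 = 2(\ell_{\text{full}} - \ell_{\text{reduced}})$, referred to
$\chi^2_1$ — every term here is one variance parameter, including the
constrained DGE + SGE pair, which is a single shared parameter removed
(with its correlation structure) by one test reported on both rows.
The $\chi^2_1$ reference is conservative when the true variance sits on
the boundary of the parameter space; no boundary mixture correction is
applied, and the acceptance suite confirms the resulting test of a
truly-zero G × G component rejects *below* the nominal 5% level.
Numerically negative statistics within $10^{-2}$ are clamped to zero;
larger negative values trigger a full-model re-optimisation from all
starting points before clamping.

## Partner choice, sanctions, and the neutral deviation

Partner-choice and sanctions tests are ordinary least-squares
regressions on strain genotypic means (unweighted per-strain averages
across pots, blocks and markers), with the slope tested by
$F(1, n_{\text{strains}}-2)$. The benefit axis is always the one-strain
shoot-mass genotypic mean. Within-nodule CFU shares in mixed nodules
are computed per nodule and then averaged per strain, so big nodules do
not dominate. Axenic growth rate is accepted as a user-supplied column
and run through the same regression; measuring it is out of scope.

Host benefit of discrimination uses the neutral expectation: with no
partner choice, host fitness with strains $R_1, R_2$ should equal the
mean of its one-strain fitness values, so the scaled deviation is
$(W_{R_1,R_2} - \bar W)/\bar W$ with $\bar W = (W_{R_1}+W_{R_2})/2$.
$W_{R_1}, W_{R_2}$ are one-strain genotypic means across all blocks
(the statistic is strain-indexed, not block-matched; a block-matched
variant would confound block noise into the denominator). The deviation
is regressed on the proportion of nodules initiated by the more
beneficial strain in a linear mixed model (random intercepts for that
strain, the competitor, and block), fitted by maximum likelihood via
`lme4`, with the slope tested by a likelihood-ratio $\chi^2_1$ against
the intercept-only mixed model — the report is a $\chi^2$ and the LRT is
the natural likelihood-based choice. "More beneficial" is resolved once
from the global benefit ranking; ties break lexicographically and are
flagged. A per-nodule fitness variant (shoot mass per nodule) is
provided. A log-transform sensitivity mode is *not* guessed at: the
deviation takes negative values and no defensible transform is implied,
so the package documents the issue instead of implementing one.

## The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate complete experiments
with the structure the models assume. Defaults describe the full study
design: 8 strains × 2 markers × 8 blocks, all 28 pairs twice per block
with reciprocal markers, 16 one-strain pots and 2 uninoculated controls
per block — 592 pots. Key parameters:

* `strain_quality` — latent per-strain axis (standardised units),
  driving host benefit, nodulation success and CFU proliferation at
  once; this deliberate confounding is the empirical situation the
  analysis is designed to detect, and `decouple_choice = TRUE` severs
  it for null simulations.
* `nodule_vc` — variance components of the latent focal-strain nodule
  count (`dge`, `sge`, `gxg`, `block`, `pot`, `resid`), defaulting to
  the ratio 32 : 14 : 7 : 3 : 7 : 37 on a phenotypic variance of 50
  (counts per strain per pot, mean total 40).
* `choice_strength` — log-odds of expected nodule share per unit
  quality difference. The default 1 makes the weakest strain take
  roughly a 0.1 share against the strongest — strong, near-exclusion
  partner choice.
* `shoot_quality_link` — log shoot mass gained per unit of
  occupancy-weighted symbiont quality, per symbiont. The default 0.3
  yields roughly a six-fold shoot-mass range across the strain panel in
  one-strain pots, matching the several-fold benefit spread a strain
  panel of this kind shows. Host benefit flows through realised nodule
  occupancy, so partner choice translates into host fitness.
* `cfu_link` — log CFU per unit quality (default 0.5), and the
  within-nodule share tilt in mixed nodules; CFU phenotyping covers the
  first `cfu_blocks = 2` blocks, one nodule per one-strain pot and up
  to two single-colour plus one mixed nodule per two-strain pot.
* `marker_effect` — additive marker effect, defaulting to 0 since no
  magnitude or direction is established for it; it exists so marker
  confounding can be simulated and the fixed effect exercised.

Counts are generated on a Gaussian latent scale, floored at zero and
discretised into single/mixed colour tallies (the analysis itself
models nodule number with Gaussian residuals, so the generator matches
the model's assumption rather than a count family);
`discretize = FALSE` keeps the latent Gaussian values so that the
generative truth coincides exactly with the fitted model — the mode the
parameter-recovery experiments use, with `choice_strength = 0` and
`marker_effect = 0` so the configured variance ratios are the whole
truth. G × G effects are ordered-pair for focal-level traits and
unordered-pair for pot-level shoot mass, matching which trait can see
orientation. All randomness flows from one seed through named
substreams, so a config is fully reproducible and stages can be re-run
independently.

What the generator does **not** emulate: overdispersed or zero-inflated
nodule counts, spatial structure within blocks, marker effects on
competitiveness (only an additive phenotype shift), nodule-age or
plant-size dependence of CFU, and measurement error in tallying.
Passing recovery tests therefore show the estimator is correct when its
assumptions hold — they do not certify robustness to count-model
misspecification in real data beyond the rounding the default mode
applies.

## Numerical and design choices

* **Recovery experiment sizes.** Variance-proportion recovery uses 50
  simulated experiments at the full 8 × 8 design and compares the
  median estimate per component to truth within 3 percentage points.
  With 8 strain levels a single experiment estimates strain variances
  on ~7 degrees of freedom (per-component sampling SDs of 2–12
  percentage points are intrinsic), so the median across replicates is
  the meaningful recovery measure, not per-dataset error. LRT
  calibration uses 500 simulations of a reduced 4 × 4 design, which
  keeps each null fit small while preserving the crossed
  focal/competitor structure; deviation-model calibration uses 300
  synthetic record sets at the full design size.
* **Marker fixed effect.** One marker column: the focal strain's marker
  for dyadic traits, the lexicographic orientation's marker for
  pot-level traits. With exactly two markers and reciprocal pairs this
  is one contrast; a two-column per-strain variant is not identified at
  the pot level.
* **Ties and degenerate inputs.** Benefit ties break lexicographically
  (flagged); zero-nodule pots are excluded from proportion and
  per-nodule traits with counts reported; a constant deviation vector
  short-circuits the mixed model to slope 0, $\chi^2 = 0$ (the model
  pair is degenerate there).
* **Interface.** All analysis functions take a tidy data frame (or the
  simulation object) first and return tibbles; `run_pipeline()` is the
  single-command orchestration (validate → variance partition →
  discrimination → deviation) with deterministic outputs, stage-named
  errors, and CSV/JSON/text reports. The function interface *is* the
  pipeline's entry point; no shell wrapper is shipped.

## Limitations

* Strain-level inference rests on 8 genotypes; variance proportions
  carry wide sampling intervals and the package reports them without
  shrinkage.
* $\chi^2_1$ boundary conservatism means true but small variance
  components will often fail to reach significance.
* The proportion model treats shares as Gaussian; near-boundary shares
  (close to 0 or 1) strain that assumption, exactly as strong partner
  choice produces them.
* Reproducing a specific published variance table requires that study's
  deposited data supplied through the schema-mapping configuration; the
  packaged experiments are synthetic.
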