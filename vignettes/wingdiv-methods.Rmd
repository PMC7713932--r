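---
title: "Models and methods in wingdiv"
author: "wingdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in wingdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wingdiv implements a complete comparative-phylogenetics workflow for a
species-level butterfly radiation: wing-colour trait construction from
specimen images, Brownian-motion models of colour evolution with rate
shifts and mean jumps, trait-dependent diversification testing (ES-sim),
time- and paleoenvironment-dependent birth–death diversification models,
and time-stratified DEC/DIVALIKE ancestral range estimation. This vignette
explains the models, the conventions, the numerical choices, and the
boundaries of what the synthetic-data tests can and cannot show.

## Conventions

All ages are in Ma before present, with the present at 0 and time
increasing into the past. Rate-model coefficients multiply this age, so a
speciation model `lambda0 * exp(coef * t)` with a negative coefficient
rises toward the present. Trees are rooted, binary and ultrametric;
ultrametricity is checked with a tolerance of `1e-6` times the crown age
and offending trees are rejected rather than silently stretched. Branches
are identified by the ape node id of their tipward end; `branch_of_clade()`
maps a set of tip labels to the stem branch of their clade.

## Wing colour traits

Colour is measured as the mode of the red, green and blue channels and of
the per-pixel channel sum ("total", 0–765) over a masked wing region, for
four regions (whole wing and three vein-delimited cells), i.e. 16 traits.
The mode is preferred over the mean because wing-colour distributions are
strongly skewed; ties break to the smallest value so the statistic is
deterministic. Three choices the measurement pipeline makes explicit:

* "total" is the mode of the per-pixel sum, not the sum of the three
  channel modes — it is then the mode of a genuinely measured quantity;
* a species' trait value is the arithmetic mean of its specimens' modes,
  rounded to two decimals (pooled-pixel modes across specimens would weight
  specimens by image size);
* "lightness" of a region is `mode_total / 3`. The lightness-independent
  index regresses each single-channel trait on its region's lightness
  across species by OLS and keeps the residuals, separating hue change
  from brightness change.

Camera calibration is assumed done upstream; the synthetic wing fixtures
are calibrated by construction (a dominant modal colour plus a controlled
fraction of uniform noise pixels, at most 45% so the mode stays
recoverable).

## Brownian trait evolution by reversible-jump MCMC

The trait model family is single-rate Brownian motion (BM), BM with
branch rate shifts (rBM1), BM with mean jumps (jump-BM), and both
(jump-rBM). A shift on a branch multiplies the Brownian rate of that
branch and its entire subtree; a jump adds a fixed displacement at the
rootward end of its branch, so all descendant tips inherit the pulse
before drifting on. The likelihood is the multivariate normal density of
the tip values, evaluated in O(n) by Felsenstein's pruning recursion; an
independent dense-covariance implementation backs it in the test suite.

Priors: the numbers of shifts and of jumps are truncated Poisson(log 2),
so a priori fewer than one of each is expected; shift multipliers are
log-normal(0, 1); jump sizes are normal with variance
`16 * sigma2 * median branch length` (prior SD of four median-branch
Brownian standard deviations — large enough not to penalise the strong
jumps of interest, small enough to be proper); `sigma2` carries the
scale-invariant 1/sigma2 prior and the root state a flat prior. Because
the jump-size prior scales with `sigma2`, updates of `sigma2` include the
jump prior term.

Proposal scales are expressed relative to a calibration constant
(`prop_width`, default 8). Reversible-jump birth/death moves propose from
the prior, so their acceptance ratio reduces to the likelihood ratio times
the Poisson count ratio. Chains default to 1.25 million generations
sampled every 1,000 with 25% burn-in; an effective-sample-size check on
the log-likelihood warns (never fails) below 200. Model selection uses
AICM (`2*var - 2*mean` of the posterior log-likelihood sample; the formula
is recorded in the output because several variants circulate) with the
parsimony rule: the best model wins only if it leads by more than 2 units,
otherwise the simplest model in the order BM, rBM1, jump-BM, jump-rBM is
retained. Jumps are reported on branches with posterior probability above
0.5.

A caveat the recovery tests make visible: when a jump sits on a short
stem, the posterior legitimately spreads mass between that branch and its
neighbours (the configurations are nearly likelihood-equivalent), so
recovery fixtures place jumps on long stems.

## ES-sim

The equal-splits statistic of a tip apportions each edge length along its
root-to-tip path, halved at every intervening split; `log(1/ES)` is the
tip-rate proxy. The test statistic is the Pearson correlation between the
trait and `log(1/ES)`; the null distribution is built by simulating
Brownian traits (rate fitted from the data by ML) on the same tree, and
the two-tailed p-value uses the add-one estimator, so its resolution is
`1/(nsim+1)` and it is never exactly zero. The correlation is invariant to
affine trait transformations, and the null depends only on the tree, two
properties the suite checks directly.

## Birth–death diversification models

The likelihood of the branching times is conditioned on the crown age and
the survival of both crown lineages. Writing `R(t)` for the integral of
`lambda - mu` from the present to age `t` and
`I(t) = int_0^t lambda(u) exp(R(u)) du`, the log-likelihood is

```
sum over internal nodes i (except the root) of
    [ log lambda(t_i) + R(t_i) - 2 log(1 + I(t_i)) ]
  - 2 log(1 + I(t_crown))
```

which for constant speciation and no extinction reduces exactly to the
pure-birth closed form `(n-2) log lambda - lambda * S` (`S` = total branch
length) — the identity the tests assert on every simulated tree. `R` and
`I` are computed by composite Simpson quadrature on a 2,049-point uniform
grid over the tree's age span, interpolated at the branching times with
cubic splines; both-constant models use closed forms. The accuracy target
(nested models agree to 1e-8) is asserted in the suite.

Functional forms for each of speciation and extinction: constant,
exponential in time, linear in time (floored at zero with a warning —
linear models are kept available but guarded), and exponential/linear in
an environmental covariate, where the covariate value at age `t` replaces
`t`. Extinction can be structurally absent ("zero"), which removes its
parameters from the count — parameter counts, not estimates-at-zero, drive
the AIC arithmetic. Fits use multi-start Nelder–Mead (BFGS when only one
parameter is free) on log-intercepts, seeded, with 10 starts by default.

Environmental covariates are `env_curve` objects: Andean paleoelevation
(km; a synthetic monotone uplift curve with late-Miocene and Pliocene
pulses ships for examples, and any measured series can be supplied), and
Panama connectivity built from per-epoch migration rates as
`1 - exp(-rate)` per Ma, assembled into a step curve over the epochs
(boundaries 50, 41.1, 23.7, 8.7, 5.2, 0 Ma by default). The "cumulative"
variant takes the running maximum toward the present; the per-Ma step
curve is the default reading.

The Pybus–Harvey gamma statistic and the Magallón–Sanderson estimator
complete the module. The crown Magallón–Sanderson rate is obtained by
solving `n (1 - alpha^2) = 2 exp(r t)` (with `alpha` the per-lineage
extinction probability) as a quadratic in `exp(r t)`, which reduces to
`ln(n/2)/t` at zero relative extinction; the stem case inverts
`n = (exp(r t) - eps)/(1 - eps)`. Both are checked against root-finding
oracles.

## DEC and DIVALIKE biogeography

Geographic ranges are subsets of eight Neotropical areas, restricted to
adjacency-connected subsets of at most six areas plus an absorbing empty
range that is never observed at tips, never reported at nodes, and never
part of the root prior (uniform over allowed non-empty ranges). Range
connectivity is evaluated on the static adjacency graph; time-slice
barriers act through dispersal multipliers so the state space — and hence
the meaning of the likelihood vectors — is constant across slices.

Anagenesis: dispersal into area `a` at rate
`d * sum over occupied b of m[b,a] * (dist[b,a]/mean dist)^(-x)` (the
distance exponent `x >= 0` is dimensionless because distances are
normalised by their mean; `x` is free only under distance hypotheses),
extirpation of each occupied area at rate `e`. Cladogenesis under DEC:
singleton parents are inherited identically; wider parents undergo subset
sympatry (full range + one member area) or vicariance with one singleton
daughter, all events equally weighted; DIVALIKE replaces these with all
ordered vicariant bipartitions into allowed ranges. Daughter assignment is
symmetrised over the two descendant branches at likelihood evaluation.

Likelihoods use pruning with dense matrix exponentials of the
slice-specific rate matrix, branches cut at slice boundaries (32, 23, 10,
7 Ma by default). The propagator diagonalises each slice's matrix once and
reuses it across branch segments, accepting the eigenbasis only when it
reconstructs the rate matrix to 1e-9 relative error; otherwise a dense
scaling-and-squaring exponential is used. State spaces here stay near 100
ranges, where the dense approach is exact and fast. An
exhaustive-enumeration oracle (independent code, `Matrix::expm`) pins the
pruning likelihood to 1e-8 on small trees in the suite, and marginal
ancestral ranges from the two-pass conditioning are pinned to a
brute-force joint posterior the same way.

The eight dispersal hypotheses combine three effects over the four time
slices: distance decay (free exponent), Panama connectivity (multipliers
0.1, 0.25, 0.5, 1.0 from oldest to youngest slice between the Central
American/Caribbean block and South America), and an Andes barrier (0.1 on
trans-Andean pairs in the two post-uplift slices). These multiplier values
and the example area adjacency/centroid distances are illustrative
defaults — published supplementary matrices should replace them via
`dec_config()` when replicating a specific study.

Two estimation caveats, both visible in the recovery experiments:

* the extirpation rate `e` is weakly identified from extant ranges. DEC
  cladogenesis always produces a singleton daughter, so tip ranges can
  contract without any anagenetic loss, and the profile likelihood in `e`
  is typically maximised at the zero boundary even when the generating
  process had `e > 0`. Dispersal `d` is recovered well (medians within a
  few percent at the tested scales); `e` should be interpreted
  qualitatively.
* the range-history simulator rejects replicates in which a lineage decays
  to the empty range. Data generated that way are survivorship-conditioned,
  and the matched estimator divides the likelihood by the probability that
  no sampled lineage died out (`condition_survival = TRUE`); the default
  remains the standard unconditioned DEC likelihood used for real data.

## Synthetic data: what it shows and what it does not

The generators reproduce the statistical structure the analyses assume:
pure-birth trees conditioned on tip count (the present is placed uniformly
between the n-th birth and the next simulated event — a simple scheme
whose crown-age expectation matches the Yule waiting-time sum to within a
half-waiting-time), reconstructed birth–death trees over a fixed duration
with time-varying rates honoured by thinning and rejection on fewer than
two survivors, Brownian traits with subtree rate shifts and stem jumps,
DEC histories that share the analysis module's rate matrix and
cladogenesis tables, and wing images with a dominant modal colour. Study
defaults mirror the system that motivated the package: 31 tips, crown age
near 28 Ma, speciation near 0.12/Ma, Brownian rates near the published
whole-wing value of ~53 squared colour units per Ma.

Passing recovery tests on these fixtures demonstrates internal
consistency — the estimators invert the package's own generators at
realistic sizes — not field validity: real wing images carry specular
highlights, scale wear and calibration drift that the fixtures idealise
away; real range data carry sampling gaps; and a real clade's trait
evolution need not be any member of the Brownian family. The
deposited-data replication entry point (`replicate_empirical()`) exists
precisely so the headline numbers can be recomputed from the study archive
once it is downloaded.

## Problem sizes in the shipped tests

The suite exercises the study scale directly where it is cheap (1.25
million-generation MCMC chains, 500-replicate ES-sim calibrations,
1,000-replicate gamma null) and scales down where an operation is
intrinsically expensive (20-replicate DEC recovery on 50-tip trees over an
8-area chain; exhaustive DEC oracles on trees of at most 4 tips and 3
areas, where enumeration is exact). Each scaled-down size was chosen so
the Monte-Carlo error of the checked statistic stays well inside the
asserted tolerance.
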