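---
title: "Phylodynamics of dated outline shapes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylodynamics of dated outline shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fbdshape` infers time-calibrated trees and piecewise-constant
diversification dynamics from collections of dated specimens described
by continuous shape characters. This vignette is the package's own
account of the science: the joint model, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limits of desk-scale inference.

## The joint model

Three submodels combine into one posterior.

**Tree model — the fossilized birth–death (FBD) skyline.** Lineages
branch at rate λ, terminate at rate μ, and are sampled through time at
rate ψ (all per ka, since ages are in ka). Sampling is a Poisson
process along lineages; a sample whose descendants are also sampled
appears *inside* the tree as a sampled ancestor (a degree-2 node in
this package's representation; the zero-length side branch is only a
file-format rendering). The extant-sampling probability ρ is zero
throughout: every specimen predates the sampling present. Rates are
piecewise constant across climate intervals bounded at 14.6, 12.9 and
11.7 ka BP (the Greenland event stratigraphy: GS-2, GI-1, GS-1,
Holocene), and the process is conditioned on its origin time and on
producing at least one sample. The density is assembled from the
standard two ingredients: `p0(t)`, the probability that a lineage alive
at age `t` leaves no sampled descendants, and the no-observed-event
branch propagator `q(t)`, both piecewise closed forms made continuous
across interval boundaries. Each bifurcation contributes λ, each
terminal sample ψ·p0, each sampled ancestor ψ, and each branch a
propagator ratio. A deSolve-based ODE integration of the same master
equations serves as an independent oracle in the tests.

**Character model — multivariate Brownian motion.** The continuous
characters are principal-component scores of elliptic Fourier
coefficients. They evolve as a correlated random walk with per-trait
variance rates σ² and a single shared among-character correlation r,
giving the trait covariance Σ with `Σ_ij = r·√(σ²_i σ²_j)`. The walk
starts at the process *origin* with the estimated root values; the
origin-to-root stem carries variance like any branch. This convention
matters for sampled-ancestor trees, whose root node can itself be a
sample: attaching the root-value parameter to the tree root would then
collide with an exact observation. The likelihood is computed by a
pruning pass after whitening the trait dimension through the Cholesky
factor of Σ; sampled ancestors enter as exact internal observations. A
dense `C ⊗ Σ` multivariate-normal evaluation is kept as a reference
implementation and cross-checked on random trees.

**Clock models.** The overall rate at which shape traverses trait
space varies across branches. Two relaxed clocks are provided: the
uncorrelated lognormal clock (ULNC) — each branch rate drawn
independently from a lognormal with estimated real-space mean M and
log-space spread S — and a two-category clock (nCat2) with two
estimated rate values and per-branch assignments. The rate is shared
across traits.

## Priors and their consequences

| block | prior | default |
|---|---|---|
| λ, μ, ψ (each interval) | Exp(rate 10) | mean 0.1/ka |
| origin time | U(0, ∞), improper | flat on support |
| root values | Normal(0, sd 2) | per trait |
| σ² | LogNormal(1, 0.3), log space | median e ≈ 2.7 |
| r | U(−1, 1), truncated to positive-definite Σ | r > −1/(k−1) |
| ULNC M | Exp(10) | mean 0.1 |
| ULNC S | Gamma(shape 0.54, scale 0.38) | mean ≈ 0.2 |
| nCat2 rates | Exp(5) | mean 0.2 |
| tip ages | Uniform on the calibrated one-sigma interval | per sample |

Two of these deserve comment. The `LN(1, 0.3)` variance prior is
parameterized in log space by default (the convention of the Bayesian
phylogenetic software family this pipeline mirrors); a real-space-mean
reading is available via `prior_spec(sigma2_log_space = FALSE)`. It is
*informative*: σ² is effectively confined to [1.5, 5], so when trait
axes with small true variance are added, the shared clock — not σ² —
absorbs the scale. That is precisely the mechanism behind the
taxa–trait benchmarking result below. Second, Exp(10) concentrates 95%
of its mass below 0.37/ka; any data whose generating rates exceed that
will be shrunk toward it unless the data volume is large. Both
consequences are visible in the results and discussed under
*Limitations*.

## Radiocarbon chronology

Dates are calibrated on the curve's native grid: the calendar-age
density is proportional to a normal evaluated at the curve mean with
variance `lab² + curve²`, normalized by the trapezoid rule (linear
interpolation between grid points, no spline). Per-locale dates are
summed (SPD) and renormalized; the median age (cumulative mass 0.5,
linearly interpolated) gives the point age and the 68.27%
highest-density region gives the one-sigma interval. Whether the
published convention behind such one-sigma regions is an HPD or a
central interval is genuinely ambiguous; both are implemented
(`sigma_range(type =)`), HPD is the default because it produces single
intervals for the unimodal-to-mildly-multimodal densities a smooth
curve yields. Ages are stored as ka, rounded to three decimals. Climate
bins are closed on the older side: an age equal to 14.6 belongs to
GS-2.

## Outline morphometrics

Outlines are centred, scaled to unit centroid size (root mean squared
distance to the centroid), rotated by a *supplied* per-specimen angle —
orientation is a manual curation input, never inferred — and re-indexed
so a designated homologous point comes first. Elliptic Fourier
coefficients are computed per harmonic; the number of harmonics is the
smallest whose cumulative power `(a²+b²+c²+d²)/2` reaches a threshold
(0.999 by default). PCA is centred but unscaled, on the flattened
coefficients; scores are the phylogenetic characters.

One numerical subtlety is documented rather than hidden: the classical
elliptic Fourier transform parameterizes the contour by arc length.
Reconstructing a contour from coefficients and re-transforming it
re-parameterizes any non-constant-speed curve, so the inverse–forward
round trip is exact only to the re-parameterization error (about 1e−3
for a mildly eccentric ellipse). `efa_transform(...,
parameterization = "uniform")` instead takes the discrete Fourier
coefficients of the vertices at equally spaced parameter values, which
is the exact inverse of `efa_inverse()` and is what the round-trip and
pure-ellipse tests use. The arc-length convention remains the default
for data analysis because it is the field standard and insensitive to
uneven point spacing along digitized contours.

With n specimens, centred PCA has rank at most n−1; the package
reports the true rank rather than padding axes, so "all axes" for an
87-specimen study means 86 informative axes plus the numerically null
remainder.

## The synthetic study

`make_study_scenario()` generates complete studies with the structure
the inference assumes. Its defaults are fixed study conditions, not
tuning knobs:

- **Window.** Sampling present at 11 ka BP, origin at 15 ka BP: the
  process runs in "model time" (ka before 11 ka BP), so the four-bin
  skyline is *exactly* the generating model and every sample age falls
  in [11, 15] ka BP with ρ = 0. Inference passes `present_bp = 11`.
- **Rates.** λ = (3.0, 1.2, 0.8, 0.5), μ = (0.1, 0.3, 0.4, 0.6),
  ψ = (1.5, 0.5, 0.5, 0.55) per ka from GS-2 to Holocene. The high
  early birth rate is what a single founder at 15 ka needs to seed a
  radiation that yields tens of sampled locales within four millennia —
  and mirrors the empirical finding that birth rates peak before the
  end of GS-2. ψ scales with `max(1, n_taxa/32)`: studies that collate
  more locales sample more densely.
- **Stratification.** Realizations are redrawn toward an even per-bin
  fill up to an attempt budget; beyond it, bins keep what they have and
  younger bins back-fill the total. A 16-taxon study achieves 4 per
  bin; larger studies show the same early-bin deficit the real record
  has (a single founder 0.4 ka before the first boundary cannot supply
  22 GS-2 locales at sane rates).
- **Traits.** Nine traits with variance rates decaying like a PC
  eigen-spectrum (3, 1.2, 0.6, …, 0.03), correlation 0.3, strict clock
  0.5 — so trait axes mimic ordered principal components.
- **Dates.** One locale per sample, 1 + Poisson(1.2) dates per locale,
  lab error 0.06 ka, against a synthetic calibration curve (smooth
  sinusoidal wiggles, amplitude 0.08 ka, per-point error ≈ 0.025 ka)
  spanning 10.5–16 ka. The curve is explicitly synthetic — it stands in
  for a real calibration curve's shape, not its values.

What the generator does *not* emulate: spatial structure and
between-region heterogeneity, taphonomic loss correlated with age,
curve plateaus as severe as real ones, measurement error on outlines,
and model misspecification of any kind (traits truly are Brownian, the
tree truly is FBD). Passing tests therefore demonstrate internal
correctness and calibration of the machinery, not robustness of the
method on real archaeological data.

## Inference machinery

The sampler is a plain Metropolis–Hastings kernel with fixed proposal
scales (no adaptation — reproducibility over speed). Moves: scale moves
on every positive scalar; slides on the correlation, root values and
origin; uniform tip-age slides within the calibrated interval; node-age
slides between each node's neighbours; narrow exchange; a
Wilson–Balding-style subtree regraft whose lifted bifurcation keeps its
identity (and branch rate); and a reversible-jump toggle between
terminal samples and sampled ancestors, with the born/killed branch
rate drawn from its conditional prior so the dimension factors cancel.
Two joint moves walk the ULNC hierarchy out of its funnel: one scales M
and all branch rates together, one scales S and the rates'
log-deviations (with Jacobian). Without them the hyperparameter
effective sample sizes collapse by an order of magnitude.

Starting state: tip ages at interval midpoints; a compact
age-sequential starting tree (repeatedly join the two youngest lineage
tops slightly above their ages); rates at prior means. Equal node ages
are avoided by construction — continuous proposals hit exact equality
with probability zero, and validation enforces strict parent–child age
ordering except at sampled-ancestor attachments.

Validation is layered, each layer independent of the code it checks:
closed-form `p0`/`log q` against numerical ODE integration; the
assembled density against a hand-coded constant-rate expression in the
classical (c1, c2) algebra; the pruning likelihood against dense
Kronecker-product normals on 100 random sampled-ancestor trees;
prior-only sampling (`tree_free = TRUE`) against every analytic prior;
and fixed-tree rate posteriors against 3-D grid integration.

Desk-scale problem sizes are used throughout the shipped experiments:
chains of 15k–40k generations on 16–32 taxa, two chains for the main
analysis, 20% burn-in, ESS computed by the AR-fit
spectral-density-at-zero estimator with a pass threshold of 200 on
prior, posterior and likelihood. These sizes are the package's chosen
trade-off for replicable examples; the empirical study this mirrors ran
two chains per script for 10⁸–10¹⁰ generations on a cluster, and the
interface accepts such budgets unchanged.

## Benchmarking experiments and what they show

**Under the prior** (`under_prior_contrast()`): with the trait
likelihood disabled, the sampling-rate posterior in a well-sampled bin
sits far from Exp(10) (Kolmogorov distance ≈ 0.7, median ratio ≈ 3–4):
the sampling times alone carry substantial rate signal, the same
contrast the empirical study drew between its full and under-the-prior
skylines.

**Taxa–trait grid** (`run_grid()`, `clock_trait_trend()`): adding PC
axes of decreasing variance monotonically drags the posterior median
clock rate down (0.18 → 0.04 across 2 → 9 traits on the 32-taxon
study). The mechanism is the informative σ² prior described above: low
variance axes cannot push their σ̂² below ≈ 1.5, so the shared clock
absorbs the shrinking scale. On the 16-taxon study the clock prior
dominates and the profile flattens — trait dilution is a
strong-signal phenomenon, which is why the shipped trend experiment
uses the larger study.

**Parameter recovery** (`recovery_experiment()`): across replicate
synthetic studies, 95% HPD intervals for the twelve skyline rates cover
the generating values in only ≈ 15–20% of parameter–replicate checks at
desk scale. This is a real and instructive failure, not a code defect:
the fixed-tree oracle and prior-sampling checks pass, and quadrupling
the chain length reproduces the same intervals with several times the
effective sample size. The generating rates that any single-founder,
four-millennium radiation requires (λ up to 3/ka, ψ ≈ 0.5–1.5/ka) lie
deep in the tail of the Exp(10) priors, and at 32 samples the
likelihood only partly overcomes that pull: posteriors for the
well-informed parameters sit between prior and truth (e.g. λ-GS-2 HPD
≈ [0.2, 1.0] against a truth of 3.0), and weakly-informed death rates
collapse toward the prior. The empirical study faced the same geometry
— its headline result was precisely that early birth rates "could not
be guessed from the prior" — but had 87 taxa and cluster-scale chains.
Users applying these priors to strongly radiating series should treat
absolute rate magnitudes with caution and read the skyline *contrasts*
between bins, which are far more robust.

## Known limitations

- Fossil-only FBD with ρ = 0 identifies (λ, μ, ψ) only jointly and
  weakly at small n; informative priors dominate absolute magnitudes.
- The MCC tree is selected from sampled trees; with diffuse posteriors
  over topologies (the regime here — clade supports are low, as in the
  empirical study), it is a summary device, not an estimate to
  interpret node by node.
- The one-parameter equicorrelation Σ cannot express block structure
  among traits; PCA decorrelates globally, not phylogenetically.
- Calibration assumes the lab and curve errors are independent
  normals; no reservoir corrections or stratigraphic sequence models.
- The sampler is ergodic but not tuned for large trees; beyond ~100
  taxa, mixing of topology moves becomes the binding constraint.
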