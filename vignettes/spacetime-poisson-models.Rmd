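---
title: "Space-time Poisson models for areal count panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time Poisson models for areal count panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Counts of rare events (deaths, disease cases) aggregated to administrative
districts and observed over a short run of years carry three kinds of
structure at once: spatial dependence between neighbouring districts,
a shared temporal trend with district-specific deviations, and the influence
of area-level covariates whose effects may be non-linear. `stpois` implements
the standard Bayesian disease-mapping treatment of such panels: hierarchical
Poisson regression with a BYM convolution of spatial random effects, a
differential time trend, and second-order random-walk (RW2) smoothers, plus
the exploratory machinery (global Moran's *I* with permutation inference,
Spearman screening) used before any model is fitted.

## Model hierarchy

For area $i$ and period $t$, counts are modelled as

$$y_{it} \sim \mathrm{Poisson}(E_{it}\, e^{\eta_{it}}),$$

where $E_{it} = P_{it} \cdot \sum y / \sum P$ are internally standardised
expected counts, so every exponentiated effect reads as a relative risk (RR)
against the panel-wide average rate. The linear predictor is

$$\eta_{it} = \alpha + \textstyle\sum_k \beta_k x_{itk}
  + \sum_k f_k(x_{itk}) + u_i + v_i + \mathrm{trend}_{it}.$$

* $u_i$ — spatially structured residual, intrinsic CAR (ICAR) prior on the
  queen-contiguity graph: precision structure $Q = D - A$, each effect
  conditionally centred on its neighbours' mean. Sum-to-zero per connected
  component; islands are point-constrained at zero.
* $v_i$ — unstructured iid residual. Together $u + v$ is the BYM
  convolution; `exp(u_i + v_i)` is reported as the residual RR of area $i$.
* trend, parametric families (`null_parametric`, `model1a`, `model1b`):
  $(\gamma + \delta_i)\tilde t$ with $\tilde t$ the period centred at the
  panel midpoint. $\gamma$ is the grand log-linear slope; the exchangeable,
  sum-to-zero $\delta_i$ are differential trends — $e^{\delta_i} > 1$ marks
  areas whose risk rises faster than the common trend.
* trend, dynamic families (`null_dynamic`, `model2`): $\phi_t + \psi_t$,
  an RW2 smooth plus an iid period effect, replacing the linearity
  assumption.
* $f_k$ — RW2 effects over binned covariate values for covariates declared
  `nonlinear` (family `model1b`); all other covariates enter linearly.

Precisions $\tau_u, \tau_v, \tau_\delta, \tau_\phi, \tau_\psi, \tau_{f_k}$
carry Gamma(1, 5e-5) priors by default. Fixed effects
($\alpha, \beta, \gamma$) get diffuse N(0, precision 0.001) priors.

### Scaled structures

Every GMRF structure matrix is rescaled before fitting so that the geometric
mean of the marginal variances of its constrained generalized inverse equals
one. Without this, a given $\tau$ implies entirely different effect sizes on
different graphs or bin counts, and a single default hyperprior would be
ad hoc. The generalized inverse is taken over the positive eigenspace (the
null space — per-component constants for ICAR, constant and linear for RW2 —
is constrained out); island entries, which are point-constrained with zero
marginal variance, are excluded from the geometric mean. Scaling is
idempotent and recorded in `scale_factor`.

## Estimation

The hierarchy is estimated by Markov chain Monte Carlo rather than an
approximate integration scheme: at the panel sizes this package targets
(hundreds of areas, a handful of periods) an exact, dependency-free sampler
is fast, and every conditional can be verified against closed forms or
quadrature in the test suite. The sampler combines:

* adaptive single-site Gaussian random-walk Metropolis updates for
  $\alpha, \beta_k, \gamma$ and each element of $\delta, u, v, \phi, \psi$,
  tuned toward 0.44 acceptance during burn-in and frozen afterwards;
* a joint one-block update for each RW2 covariate field: a log random-walk
  proposal for $\tau_f$ followed by a proposal of the whole field from the
  Gaussian (Taylor) approximation of its Poisson full conditional at the
  proposed precision, accepted or rejected jointly. Single-site updates mix
  the (field, precision) pair pathologically slowly when the field has many
  bins — the chain lingers in an under-smoothed regime with inflated
  effective dimension — and the block move is the standard remedy;
* conjugate Gibbs draws for every precision:
  $\tau \mid x \sim \mathrm{Gamma}(a + (m-d)/2,\; b + x^\top Q x / 2)$ with
  $d$ the structure's rank deficiency.

After each sweep the sum-to-zero constraints are re-imposed by compensated
projection: the mean of $u$ per component moves into $v$, the mean of
$\delta$ into $\gamma$, and the means of $\phi$, $\psi$ and each $f_k$ into
$\alpha$. Each projection leaves $\eta$ — and hence the posterior —
exactly invariant while keeping every stored draw on its constraint
manifold. Covariates are mean-centred internally for sampling (decorrelating
$\beta$ from $\alpha$); the stored intercept draws are mapped back to the
raw scale, which is exact because $\eta$ is linear in the state.

Initialisation is deterministic: all latent components at zero, all
precisions at one. A chain is declared divergent (hard error) if any
$|\eta| > 50$. The whole chain is a pure function of the seed; split-chain
potential scale reduction factors for the fixed effects are reported with
every fit.

### Reporting conventions

RR point estimates are `exp` of the posterior mean coefficient; intervals
are `exp` of the posterior 2.5%/97.5% quantiles (mean versus quantiles can
disagree in ordering for skewed posteriors; interval endpoints are always
ordered). Residual RRs summarise `exp(u_i + v_i)` draw-wise. DIC uses the
latent-field focus conventional in disease mapping: `Dbar` is the posterior
mean deviance and the plug-in deviance is evaluated at the posterior mean of
$\eta$ (which equals $\eta$ at the posterior mean state, by linearity).
Lower DIC is better; `pD = Dbar - Dhat` is the effective number of
parameters.

## Exploratory statistics

Univariate Moran's $I = (n/S_0)\, z^\top W z / z^\top z$ on row-standardised
queen weights, with $z$ mean-centred rates; expectation $-1/(n-1)$ under
exchangeability. The bivariate statistic normalises the cross product by the
two norms (the GeoDa convention), reducing exactly to the univariate form
when both arguments coincide; it is used with the same variable at $t$ and
$t+1$ to measure the persistence of spatial pattern. Significance uses
pseudo p-values $(r+1)/(M+1)$ from $M$ random relabellings (default 9,999,
floor $10^{-4}$), directional on the side of the observed deviation from
$-1/(n-1)$. In the bivariate test only the second vector is permuted — the
time-$t$ map is held fixed, so the null destroys space-time alignment while
preserving the marginal map. Islands contribute nothing to the numerator but
stay in $n$. Spearman correlations use tie-corrected average ranks
(Pearson on mid-ranks).

## Covariate binning

RW2 covariate effects live on `bins` (default 100) equally spaced bins
spanning the observed covariate range; each observation maps to the nearest
bin midpoint, and out-of-range values (possible only with a user-supplied
range) clamp to the boundary bin with a warning. The default is fine enough
that discretisation error is negligible against posterior spread; the
scaled-structure convention keeps the prior comparable across bin counts.
Bins without observations are smoothed across by the prior, and curve
summaries report the per-bin observation count so sparsely supported regions
can be read with care.

## The synthetic study generator

The restricted nature of cause-of-death microdata means realistic method
evaluation must run on synthetic panels. The generator emulates a national
district panel: a 20 x 20 unit-square lattice (400 areas, matching the order
of ~400 districts) over 5 yearly periods; log-normal populations (median
200,000, log-sd 0.5, giving a mean around 24 events per area-year at the
baseline rate of 12 per 100,000 person-years); and the study's covariate
set — income (EUR 1,000), unemployment (%), population density (people/km²,
entered log-transformed) time-varying, plus depression prevalence (%) and
three provider-supply rates (per 100,000) temporally constant. Each
covariate is a global mean plus a scaled-ICAR spatial component plus iid
noise, clipped to plausibility bounds; time-varying covariates evolve as a
stationary AR(1) (persistence 0.9–0.95) with spatially structured
innovations. Default true effects are of the magnitude typical for
ecological suicide regressions: income RR 0.994 per EUR 1,000, unemployment
RR 1.015 per point, log-density RR 0.959, GP supply RR 1.003, grand trend RR
1.008 per year, with residual-field standard deviations 0.1 (spatial), 0.05
(unstructured) and 0.005 (differential slopes). A built-in non-linear
variant gives unemployment a rise-then-plateau true effect (slope 0.04 per
point up to 11%, flat above), the shape reported for unemployment in
ecological suicide studies; a quadratic variant exercises curve recovery.

What the generator does *not* emulate: real administrative geography
(irregular polygons, heavily skewed adjacency degrees), covariate
measurement error, boundary changes, reporting artefacts, or
overdispersion beyond what the latent fields induce. Passing recovery tests
therefore demonstrates the estimator's correctness under the model's own
assumptions at realistic signal-to-noise — not robustness to
misspecification on real data.

## Problem sizes and tolerances in the test suite

Oracle checks run at desk scale: Moran statistics against an $O(n^2)$
brute-force double sum ($n \le 200$, tolerance 1e-12); the intercept-only
posterior against adaptive quadrature (20,000 draws, three Monte Carlo
standard errors); conjugate updates against Gamma moments (10,000 draws);
scaling against an eigendecomposition oracle (1e-6). Simulation studies use
the generator's default study scale: ten replicates of the 400-area panel
with 15,000 iterations (5,000 burn-in) for coefficient recovery, and the
same scale with 6,000 iterations for DIC model-ranking checks — sizes chosen
so the full suite runs in a few minutes while leaving Monte Carlo margins
wide of the assertions.

## Known limitations

* The ICAR/RW2 structures are dense matrices and scaling uses a full
  eigendecomposition; practical up to a few thousand areas, not for
  national-grid rasters.
* No proper-CAR (Leroux/BYM2) mixing parameter, no space-time interaction
  types beyond the differential-trend and dynamic-trend families, no
  WAIC/LOO.
* $\delta_i$ is exchangeable; a spatially structured differential trend is
  a plausible alternative the package does not implement.
* Whether to use person-year offsets instead of internally standardised
  expected counts is a modelling choice; the package standardises
  internally (or accepts a user-supplied offset matrix) so that RRs are
  relative to the panel average.
* The permutation test's sidedness convention (directional on the observed
  side) and the bivariate permutation scheme (second vector permuted) are
  declared conventions; other software may differ in the third decimal of
  pseudo p-values.
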