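---
title: "Methods: from OTU composition to net community production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU composition to net community production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonNCP)
```

planktonNCP chains four analysis stages that together ask a single
question: which members of a eukaryotic plankton community predict the
carbon export potential of the surface ocean? This vignette explains the
models behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. NCP from the O2/Ar mass balance

Net community production (NCP) is gross primary production minus community
respiration; under steady state it approximates the carbon exported from
the mixed layer. The O2/Ar method isolates the biological part of oxygen
supersaturation: argon has nearly the same solubility behaviour as oxygen,
so the percent deviation

$$\Delta(\mathrm{O_2/Ar}) =
  \left[\frac{(\mathrm{O_2/Ar})_{sample}}{(\mathrm{O_2/Ar})_{sat}} - 1\right]
  \times 100\%$$

removes physically driven O2 changes ( `deltaO2Ar()` ). The air–sea flux
balance then gives

$$\mathrm{NCP} = k\,\rho\,[\mathrm{O_2}]_{sat}\,\Delta(\mathrm{O_2/Ar}),$$

assuming steady state and no vertical mixing across the mixed-layer base
(`computeNcp()`). The implementation exposes both solubility conventions:
`o2SaturationConcentration()` evaluates a per-mass Garcia–Gordon-type fit
(Benson–Krause µmol kg⁻¹ coefficients) and multiplies by the mixed-layer
density, which is the explicit ρ factor above; `perMass = TRUE` returns the
raw per-mass value for callers who carry ρ themselves. The per-mass+ρ
convention is the active default.

Parameters and defaults:

* **Gas transfer.** The piston velocity uses the quadratic wind-speed law
  $k = a\,u_{10}^2\,(Sc/660)^{-1/2}$ with
  $a = 0.251\ \mathrm{cm\,hr^{-1}(m\,s^{-1})^{-2}}$, the widely used
  reanalysis-wind calibration; the coefficient is an argument because
  calibrations differ at the few-percent level. The Schmidt number is the
  standard O2-in-seawater quartic in temperature (value 568 at 20 °C,
  normalized by the 660 reference).
* **Ventilation weighting.** A sample integrates gas exchange over the O2
  residence time, so `weightedPistonVelocity()` weights each of the 60
  preceding daily piston velocities by the fraction of the mixed layer not
  yet ventilated by more recent days:
  $\omega_i = \prod_{j>i} (1 - f_j)$, $f_j = \min(k_j \Delta t / \mathrm{MLD}, 1)$,
  with $\Delta t$ = 1 day and weights normalized to one. For constant wind
  this reduces exactly to the unweighted value.
* **Mixed layer depth.** `mixedLayerDepth()` takes the shallowest depth at
  which σθ exceeds the surface value by 0.03 kg m⁻³, linearly interpolated
  between bracketing CTD levels. A profile that never crosses the threshold
  is an explicit "MLD undefined" error rather than a silent extrapolation.
* **Photosynthetic quotient.** O2-based NCP is converted to carbon with
  PQ = O2/C = 1.4 by default; `pq = 1` is the documented sensitivity case
  for regions where the effective quotient is lower.
* **Normalization.** NCP/POC (mmol C m⁻² day⁻¹ over mmol C m⁻³, i.e.
  m day⁻¹) is the biomass-normalized export-potential index used to split
  stations for the network stage.

The steady-state assumption is documented, not tested: checking it against
satellite chlorophyll time series is outside this package's scope.

## 2. Spike-and-slab variable selection (SSVS)

The sparse regression model is
$y_i \mid \beta, \sigma^2 \sim N(x_i\beta + \alpha, \sigma^2)$ with the
spike-and-slab prior
$\beta_j \sim \pi\,\delta_0(\beta_j) + (1-\pi)\,N(0, \psi_j^2)$,
$\pi \sim \mathrm{Beta}(1,1)$, $\psi_j^{-2} \sim \mathrm{Ga}(a_j, b_j)$,
$\sigma^{-2} \sim \mathrm{Ga}(a, b)$ and $\alpha \sim N(\mu_0,
\sigma_0^2)$. Predictors are mean-centered and variance-scaled first. The
Gibbs sampler (C++ inner loop, R's RNG, bit-reproducible under a seed)
updates $\beta_1 \ldots \beta_p$ sequentially, then $\pi$, the slab
precisions, the noise precision and the intercept. Each $\beta_j$ step
marginalizes the coefficient analytically, so the inclusion decision uses
the exact slab-vs-spike marginal likelihood ratio combined with the prior
odds, and a slab draw follows only when the predictor is included — the
standard Dirac-spike conjugate update. When $\beta_j$ sits in the spike,
its slab precision is refreshed from the prior, keeping the slab proposal
honestly dispersed.

Defaults: 10 000 iterations with the first 5 000 discarded; the prior
constants, which the model leaves unspecified, are set weakly informative:
$a = b = a_j = b_j = 0.01$, $\mu_0 = 0$, $\sigma_0^2 = 10^4$.

The posterior inclusion probability is the fraction of kept draws with
$\beta_j \neq 0$. Predictors are ranked by $p(\beta_j)$ and the selected
set is the prefix before the *sharp drop*, formalized here (the verbal rule
has no canonical formula) as the largest consecutive gap among the first
`maxK` (default 5) ranked positions; ties in $p(\beta_j)$ break
lexicographically, and an all-equal vector returns an empty selection with
an explicit flag instead of an arbitrary cut. Selection operates on NCP in
carbon units, but because predictors are standardized and the response
enters only through least-squares sufficient statistics, the ranking is
invariant to the O2-vs-carbon scale choice.

The cross-checks are classical: `forwardStepwiseAicc()` greedily minimizes
AICc (Gaussian form, $n\log(\mathrm{RSS}/n) + 2k$ with $k$ counting the
intercept and the variance parameter, plus $2k(k+1)/(n-k-1)$),
`simpleR2Scan()` reports univariate r² and slope p-values, and
`variancePartition()` decomposes the adjusted R² of 2 or 3 disjoint
predictor sets by fitting all subset-union models and solving the
inclusion–exclusion system — the Venn fractions may legitimately be
negative and are reported as-is. `fitMlr()` reports both plain and
adjusted R² so either convention of "variance explained" can be quoted.

## 3. SparCC co-occurrence networks

Relative-abundance data are compositional: closure to a constant sum
induces spurious negative correlation. SparCC works on log-ratio variances
$t_{ij} = \mathrm{var}\,\log(x_i/x_j)$, which are invariant to the
constant-sum constraint, and solves the sparse linear approximation
$t_i = (p-2)\,\omega_i + \sum_j \omega_j$ for basis variances $\omega$,
from which correlations follow. Because the approximation assumes most
pairs are uncorrelated, the most strongly correlated pair (above 0.1) is
iteratively removed from the system, up to 10 rounds; the estimate is the
element-wise median of 20 Dirichlet-resampled replicates. These internal
constants follow the original algorithm's published defaults and sit in
`sparccConfig()`. Two numerical guards keep the linear system honest:
basis variances are floored at a tiny positive value, and an exclusion
that would leave a component in too few equations (or make the system
singular) stops the exclusion loop rather than corrupting the estimate.

P-values come from a permutation null — every OTU shuffled independently
across samples, SparCC re-estimated — with the two-sided add-one estimator
$p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + B)$, so no p-value is ever
exactly zero.

Network stage conventions, in pipeline order: the rare-taxa filter keeps
OTUs with ≥ 3 reads in ≥ 20% of samples (the sentence defining this rule
is grammatically ambiguous; the inverse reading is available via
`inverse = TRUE`), samples are standardized to the median sequencing
depth, stations are split at the median NCP/POC (for odd n the median
station joins both halves; both behaviours of the inclusive ≥/≤ split are
thereby represented), and edges require |r| > 0.75 together with
p < 0.05. The p-value direction is switchable because the strict reading
of the source convention ("p > 0.05") would keep only non-significant
edges while simultaneously describing them as significant; the package
treats that as a typo and defaults to p < 0.05.

Topology metrics follow the field's definitions: density $2E/N(N-1)$,
average connected neighbors $2E/N$, degree centralization
$\sum(k_{max} - k_i)/((N-1)(N-2))$ (1 for a star, 0 for a regular graph),
mean local clustering with degree-< 2 nodes contributing zero (the
alternative, excluding them, is a documented switch away), and
characteristic path length and diameter over reachable pairs only, since
thresholded networks routinely contain isolated clusters. Isolated nodes
are dropped before metrics, matching the convention that they are not part
of the displayed network; `includeIsolates = TRUE` folds them back in.

## 4. Synthetic data with planted ground truth

The study design this package targets — 21 stations, hundreds of OTUs,
a handful of true predictors — cannot be validated on real data at desk
scale, so the generator plants known structure and every downstream stage
is scored on recovery. The default scenario uses 21 stations and 464 OTUs;
library sizes are log-normal around 105 253 reads with cv 0.3 (real
library-size distributions are overdispersed, and a log-normal is the
simplest positive heavy-tailed choice); the dominance spectrum is a power
law $w_j \propto j^{-1.3343}$, the exponent solving "top-20 OTUs carry 78%
of reads at 464 OTUs". The per-station basis is
$w_j e^{z_j}$ with $z \sim MVN(0, \Sigma_{\log})$, closed to a composition
and realized as multinomial counts — exactly the regime SparCC's log-ratio
machinery assumes, with $\Sigma_{\log}$ the planted truth for correlation
recovery.

The NCP link plants $y = \alpha + \sum_j \beta_j z_j + \varepsilon$ on
standardized relative abundances, with defaults $\beta = (6, -5, 4)$ on
dominance ranks 2, 5 and 9, residual sd 1 (so $|\beta|/\sigma \ge 3$: a
strong but not degenerate signal, and three true predictors mirroring the
motivating analysis), and $\alpha = 20$ mmol C m⁻² day⁻¹, which keeps
synthetic NCP in a realistic positive range. POC is
$c_0 + c_1 \cdot \mathrm{biomass} \cdot \mathrm{lognormal}$, guaranteeing
a positive NCP/POC denominator. Station physics: MLD uniform on 11–22 m,
60-day AR(1) daily winds (mean 6.5 m s⁻¹, lag-1 coefficient 0.6,
innovation sd 2 — summer polar-shelf values that put the O2 residence time
in the days-to-weeks band), polar-surface T and S ranges, a linearized
σθ, and a CTD profile built so its density-threshold MLD reproduces the
drawn MLD exactly. The measured O2/Ar ratio is back-computed from the
planted NCP through the same flux equations the analysis applies, so the
flux stage can be tested as an exact round trip.

One master seed feeds independent per-stage substreams (a deterministic
hash of the stage name), so any stage can be regenerated in isolation.

For the network contrast, `coupledBasisCorrelation()` builds a
core–periphery factor block (core loadings 0.95–0.995, periphery
0.82–0.92) whose thresholded network is a dense hairball with hubs, and
`ringBasisCorrelation()` builds a circular chain (adjacent correlation
0.86, geometric decay) whose network is a sparse ring. The core loadings
are deliberately strong enough that every core pair stays above the 0.75
edge threshold after SparCC's attenuation, for any seed; the periphery
supplies the degree heterogeneity that separates the two topologies on
centralization.

What the generator does **not** emulate: sequencing error, chimeras,
taxonomy misassignment, zero-inflation beyond multinomial sampling, EIMS
instrument noise, or spatial autocorrelation between stations. Passing
recovery tests therefore demonstrates correctness of the algorithms under
their own model assumptions — not robustness to the messiness of real
amplicon data.

## Problem sizes used in validation

The shipped test-and-acceptance runs use 20 seeded replicates of the
default 21 × 464 scenario for selection recovery, null control and the
stepwise agreement check; 100 random small designs for the least-squares
oracle; 100-sample, 20–30-OTU compositions for SparCC recovery, null and
the coupled-vs-loose contrast (80–100 permutations); and 50 random graphs
of at most 12 nodes for the exact graph-metric oracle. These sizes make
every Monte-Carlo margin wide relative to its threshold while keeping a
full validation run around two minutes on a single core.

## Known limitations

* The flux stage neglects vertical mixing, entrainment and time-dependent
  dynamics; NCP inherits the steady-state caveat of the O2/Ar method.
* The sharp-drop rule is a formalization of a verbal criterion; pathological
  inclusion-probability profiles (uniform, or gaps beyond `maxK`) return
  conservative answers by design.
* SparCC's basis-variance approximation assumes sparse true correlations;
  with pervasive strong correlation the exclusion heuristic saturates and
  estimates attenuate.
* The single-chain sampler reports no convergence diagnostics beyond the
  stored draws; at the default 10 000 iterations on n ≈ 21, p ≈ 20
  problems, mixing is rapid, but users scaling p up should inspect the
  draws.
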