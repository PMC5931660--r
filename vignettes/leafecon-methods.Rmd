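---
title: "Models and methods behind leafecon"
author: "leafecon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

`leafecon` implements a leaf-economics comparison of co-occurring woody
species that differ in nativity (native vs invasive) and leaf habit
(deciduous vs evergreen). The motivating design is a temperate forest
panel of about 19 species — most natives evergreen, a few natives
deciduous, and a small set of invasive species that are all deciduous —
with 4–14 individuals per species. Three strands of analysis are tied
together:

1. **Photosynthetic light response.** Each leaf's net CO2 assimilation
   is measured at a descending 12-step irradiance sequence
   (800, 1000, 1300, 1000, 800, 500, 300, 200, 100, 50, 20, 0
   umol photons m-2 s-1; the repeated 1000 and 800 steps are genuine
   replicate observations and are kept). The curve is summarised by the
   four-parameter non-rectangular hyperbola.
2. **Leaf economics.** Chemistry (C, N, ash) and structure (SLA, LDMC,
   thickness, area) are converted into construction costs and
   resource-use efficiencies.
3. **Group inference.** Univariate hierarchical Bayesian contrasts by
   nativity and habit, and standardized major axis (SMA) tests on
   log-log trait scaling relationships.

## The light-response model

Net assimilation at irradiance $q$ is
$$A_{net}(q) = \frac{\phi q + A_{max} -
  \sqrt{(\phi q + A_{max})^2 - 4\theta\phi q A_{max}}}{2\theta} - R_d ,$$
the lower root of $\theta A^2 - (\phi q + A_{max})A + \phi q A_{max} = 0$
minus dark respiration. Parameters, units and bounds:

| parameter | meaning | units | bounds | default prior (top level) |
|---|---|---|---|---|
| $A_{max}$ | light-saturated gross rate | umol CO2 m-2 s-1 | $(0, 100)$ | N(10, 10^2) truncated |
| $\phi$ | apparent quantum yield | mol CO2 mol-1 photons | $(0, 0.125]$ | N(0.06, 0.03^2) truncated |
| $\theta$ | convexity | — | $(0, 1]$ | Uniform(0, 1) |
| $R_d$ | daytime dark respiration | umol CO2 m-2 s-1 | $[0, 10)$ | N(1, 2^2) truncated |

Numerically we evaluate the root in the rationalised form
$2\phi q A_{max}\,/\,(b + \sqrt{b^2 - 4\theta\phi q A_{max}})$ with
$b = \phi q + A_{max}$: it is algebraically identical, avoids
cancellation for small $\theta$, and is continuous through $\theta = 0$
where the model degenerates to the rectangular hyperbola
$\phi q A_{max}/(\phi q + A_{max})$. The discriminant is provably
non-negative for $\theta \le 1$. The light compensation point has the
closed form $q^* = R_d(A_{max} - \theta R_d) / (\phi(A_{max} - R_d))$,
defined when $R_d < A_{max}$; the package checks it against numeric
root-finding in its tests.

### Per-curve least squares

`fit_curve_mle()` fits one curve by Levenberg–Marquardt nonlinear least
squares (`minpack.lm`) inside the physiological box, with starting
values read off the curve (respiration from the dark step, the initial
slope for $\phi$, the plateau for $A_{max}$) and a small multi-start
grid as fallback. It refuses — returning a diagnostic failure object,
never an exception — when a curve has fewer than five distinct
irradiances, lacks low (≤ 50) or saturating (≥ 800) coverage, or is
flat. These per-curve fits double as initial values for the MCMC.

### The hierarchical Bayesian model

`fit_hierarchical()` (JAGS via `rjags`) models all curves jointly.
Species-level random effects act on $\log A_{max}$, $\log\phi$,
$\mathrm{logit}\,\theta$ and $\log R_d$, so every draw respects the
truncation bounds at every level; top-level means (optionally one per
group, e.g. per leaf habit) carry the truncated-normal priors above.
Individual-level random effects are included for the capacity
parameters $A_{max}$ and $R_d$ only. This asymmetry is a deliberate
design choice: a 12-point curve contains almost no information about a
single leaf's $\phi$ or $\theta$, and their within-species variance
components sit against zero, where a Gibbs sampler mixes extremely
slowly (the classic variance-component funnel); between-leaf variation
in those two parameters is instead absorbed by the residual. With this
structure the default desk-scale budget of 3 chains x 5,000 retained
iterations after 2,500 burn-in converges cleanly (all Gelman–Rubin
statistics ≤ 1.1 and typically ≤ 1.05); the full 3 x 100,000 protocol
remains one `hb_config(iter = 1e5, burnin = 5e4)` away.

Prior scales for the random-effect SDs are parameter-specific:
half-normal(0.5) for the log-scale capacity SDs (species means of
$A_{max}$ plausibly span several-fold ranges), half-normal(0.15) for
the species-level $\log\phi$ and $\mathrm{logit}\,\theta$ SDs — quantum
yield and convexity are strongly conserved across C3 leaves, and a
broader prior both misrepresents physiology and slows mixing. The
observation SD has a half-normal(2) prior.

Chains are initialised from the per-curve least-squares fits (pooled
geometrically to species level, jittered per chain), and every chain
records an explicit RNG seed derived from the configuration seed, so a
fit is exactly reproducible.

Convergence is declared when every monitored parameter's Gelman–Rubin
statistic is at or below 1.1 (threshold configurable); otherwise the
fit object is flagged non-converged and the pipeline propagates the
flag rather than failing.

## Leaf economics

Construction cost per gram of leaf is
$$CC_{mass} = (-1.041 + 5.077\,C_{mass})(1 - 0.67\,Ash) + 5.325\,N_{mass},$$
with all concentrations as mass fractions. Evaluating at fractional
inputs reproduces realistic costs near 1.5 g glucose g-1; inputs that
arrive in mg g-1 (values above 1) are rescaled by 1/1000 with a
warning, since the formula is meaningless at that scale. The nitrogen
term assumes nitrate is the dominant N source (its reduction to organic
N is the costly step) and that leaf nitrate accumulation is negligible.
Maintenance and transport costs are out of scope by construction of the
formula.

Area and mass bases are linked through SLA:
$A_{max,mass}$ [nmol g-1 s-1] $= A_{max,area}$ [umol m-2 s-1]
$\times$ SLA [cm2 g-1] $\times$ 0.1, and for mass fractions
$X_{area}$ [g m-2] $= X_{mass} / \mathrm{SLA} \times 10^4$. The
conversions are exact inverses. Efficiencies are PNUE
($A_{max,area}/N_{area}$), PEUE ($A_{max,area}/CC_{area}\times 1000$),
WUE ($A_{max,area}/E$ at the saturating light step) and the
dimensionless $A_{max}/R_d$. All ratios are computed **per individual
and then averaged**; the tests demonstrate that the alternative (ratio
of group means) gives different numbers, so the choice is part of the
contract.

## Group inference

For each trait, `fit_group_model()` fits
$$y_{is} = \beta_0 + \beta_{nat}\,I(\text{invasive})
 + \beta_{habit}\,I(\text{evergreen}) + u_s + \varepsilon_{is},$$
with a Gaussian species intercept $u_s$ and one observation per
individual (individual effects are therefore absorbed by the
residual). Priors are scaled to the data — betas N(0, $(10\,s_y)^2$),
variance components half-normal($2 s_y$) — so the same specification
serves $\phi$ (≈ 0.06) and $A_{max,mass}$ (≈ 300). A contrast is
"significant" exactly when its central 95% credible interval excludes
zero; an interval touching zero is not significant. Traits spanning
orders of magnitude (mass-basis rates, SLA, leaf area, efficiencies)
are log-transformed first via an explicit transform registry; LCP,
$\phi$, LDMC and thickness stay on the identity scale. Because every
invasive species is deciduous, the two indicators are partially
confounded; the fit records this in a `confounding_note` rather than
silently dropping a term. No multiple-testing adjustment is applied
across traits — contrasts are reported per trait, which is a documented
limitation.

`summarize_groups()` reports group means ± SE where the SE is taken
over **species means** within the group (an individual-level variant is
available); a single-species group reports `NA`, not zero.

## SMA trait scaling

The SMA slope on the analysis scale is
$\hat b = \mathrm{sign}(r)\, s_y / s_x$ with intercept
$\bar y - \hat b \bar x$; both axes are log10-transformed for trait
scaling. Because SMA returns $|\hat b| \to 1$ for uncorrelated
equal-variance data, all group comparisons are gated behind a
correlation prefilter: $R^2 > 0.1$ and correlation-test $p < 0.1$,
both strict. Testing is hierarchical:

1. **Common slope** — likelihood-ratio statistic
   $-\sum_i n_i \log(1 - r_i^2(\hat b))$, where $r_i(b)$ is the
   within-group correlation between residual scores $y - bx$ and axis
   scores $y + bx$, and $\hat b$ maximises the profile criterion
   (golden-section search on $\log|b|$, tolerance 1e-10); reference
   distribution $\chi^2_{g-1}$.
2. Only if the common slope is **not** rejected at $\alpha = 0.05$:
   an **elevation** test (Wald, on group means of $y - \hat b x$) and a
   **shift-along-axis** test (Wald, on group means of $y + \hat b x$),
   both with the common-slope uncertainty propagated through the
   numerically profiled information. When the slope test rejects, both
   are reported as not applicable (`NA`).

The tests are validated three ways in the suite: the slope against a
direct-formula oracle (1e-12), the size/power of the group tests by
simulation (≈ 5% type-I at the null; ≥ 95% power for a slope halving or
a 1-unit elevation shift at n = 100/group), and decision agreement with
a label-permutation oracle on small samples. Graded significance codes
(+, *, **, ***) mirror the conventional 0.1/0.05/0.01/0.001 thresholds.

## The synthetic study generator

`panel_config()` defaults encode the emulated design: 13 native
evergreen, 3 native deciduous and 3 invasive (deciduous) species;
4–14 individuals per species; the 12-step irradiance sequence; additive
Gaussian measurement noise with SD 0.3 umol m-2 s-1 on assimilation (a
typical gas-exchange residual scale). Group structure enters as
multiplicative shifts: deciduous species carry 1.75x the evergreen
$A_{max}$ baseline of 7.6 umol m-2 s-1 (so evergreen ≈ 7.6, deciduous
≈ 13.3, matching the magnitude of the reference group means), SLA and
N_mass are elevated in deciduous leaves, and leaf area is 3.4x larger
in invaders over a 0.67x habit shift, reproducing an
invasive-vs-native area fold near 2.4. Species- and individual-level
scatter is log-normal (logit-normal for $\theta$) with SDs 0.15/0.10
(capacity), 0.03/0.02 ($\phi$) and 0.3/0.2 (logit $\theta$) — no
empirical variance components are available for the emulated design,
so these are fixed choices at magnitudes a field ecophysiologist would
consider ordinary, not fitted values. Transpiration is generated as predicted assimilation
divided by a species-constant water-use efficiency (default
6 umol CO2 mmol-1 H2O), floored at a small positive flux, so WUE at
saturating light is recoverable by construction. N_mass is coordinated
with SLA at **both** levels, as the leaf economics spectrum demands: a
species' mean N_mass follows the habit-specific log-log slope (default
0.9 evergreen, 0.45 deciduous) applied to its SLA deviation from the
habit baseline, and each individual's N_mass follows the same slope
applied to its SLA deviation from the species mean, plus residual
scatter. Both between- and within-species variation therefore carry the
habit-dependent scaling shift that the SMA stage is meant to detect.

What the generator does **not** emulate: seasonal or diurnal
physiology, stomatal dynamics, instrument drift, missing steps or
curve-quality failures, phylogenetic signal, and any non-Gaussian error
structure. Passing tests therefore certify the estimators against the
stated generative model, not against every pathology of field data.

## Numerical and reproducibility choices

- Every stochastic stage takes an explicit integer seed; the same
  configuration reproduces byte-identical synthetic tables and
  draw-identical MCMC output (per-chain RNG streams are derived from
  the seed).
- Default problem sizes are desk-scale by design: the hierarchical fit
  runs 3 x 5,000 retained draws (~3–4 minutes on one core for the
  19-species panel, ~2,350 observations), group-model simulations use
  2 chains x 1,000 draws per replicate, and SMA power checks use
  n = 100 per group. All sizes scale up through configuration.
- Degenerate inputs have defined behaviour rather than crashes: flat
  curves yield failure objects; a constant trait yields a
  degenerate-fit flag; a missing factor level yields an
  inestimable-contrast flag; zero denominators yield `NA` efficiencies;
  a CI touching zero is "not significant"; SMA comparisons report
  nothing when fewer than two groups pass the prefilter.
- The pipeline (`run_full_analysis()`) refuses to silently drop
  species (group sizes are checked against the input), and every
  number in the contrast report carries the group means it was computed
  from.

## Known limitations

- The group model treats nativity and habit as jointly estimable even
  though they are partially confounded by design; the credible
  intervals honestly widen, and the confounding is surfaced, but no
  causal separation is possible with all invasives deciduous.
- Individual-level $\phi$/$\theta$ variation is not separately
  estimated (see above); studies specifically targeting within-species
  quantum-yield variation need longer chains and richer curves than
  this desk configuration.
- SMA inference uses asymptotic $\chi^2$/Wald references; at very small
  group sizes the permutation oracle in the test-suite is the more
  reliable guide.
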