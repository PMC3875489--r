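---
title: "A turgor-driven stomatal conductance model with a cavitation tradeoff, and how it is fitted"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A turgor-driven stomatal conductance model with a cavitation tradeoff, and how it is fitted}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turgor)
```

## The model

`turgor` models leaf stomatal conductance of shrubs and subshrubs as the
steady state of a small soil-plant-atmosphere system with three coupled
ingredients.

**Turgor-proportional conductance.** Stomatal conductance is proportional to
the turgor pressure of the guard cells,

$$g_s = K_\psi \,(\pi + \psi_x)_+,$$

where $\psi_x$ (MPa, $\le 0$) is the xylem water potential at the leaf,
$\pi$ (MPa) the osmotic pressure of the leaf and guard cells, and $K_\psi$
(mol H$_2$O m$^{-2}$ s$^{-1}$ MPa$^{-1}$) an apparent compliance of the
guard-cell structure (the product of a mechanical compliance and stomatal
density). Negative turgor means closed stomata, hence the positive part.

**Photosynthesis-driven osmotic adjustment.** The osmotic pressure rises
above its baseline $\pi_0$ as photosynthesis supplies osmotica, saturating
in net assimilation $A_n$ and scaled by the intercellular CO$_2$ ratio:

$$\pi = \pi_0\left(1 + \xi\,\frac{(A_n)_+}{K_i + (A_n)_+}\,
\frac{C_0}{C_i}\right).$$

$K_i$ (µmol CO$_2$ m$^{-2}$ s$^{-1}$) is a half-saturation constant, $\xi$ a
dimensionless gain, $C_0$ a reference CO$_2$ mole fraction (370 µmol
mol$^{-1}$ by default, typical of the measurement period; when $C_i$ is not
recorded it defaults to $C_0$, making the CO$_2$ factor neutral). Negative
assimilation (pre-dawn respiration) contributes no adjustment: the
Michaelis term is floored at zero, because the adjustment was formulated
for daytime assimilation.

**Cavitation-limited water supply with an efficiency-safety tradeoff.** The
soil-to-leaf hydraulic conductance declines hyperbolically with xylem
tension,

$$K(\psi_x) = \frac{g_p}{1 + C_\lambda\, g_p\, |\psi_x|},$$

where $g_p$ is the maximum (uncavitated) conductance. The loss rate
$\lambda = C_\lambda g_p$ is proportional to $g_p$ itself: wider xylem
vessels conduct more water but embolize at smaller tensions, so a plant
cannot be both maximally efficient and maximally safe. $C_\lambda$ (m$^2$ s
mol$^{-1}$) is treated as a single constant shared by all species. The
tension at which half the conductance is lost is $-1/(C_\lambda g_p)$.

**Closure.** Transpiration is $E = g_s D$, with $D$ = VPD/$P$ the
dimensionless (pressure-scaled) vapor pressure deficit. The steady state
balances demand against supply,

$$g_s D = K(\psi_x)\,(\psi - \psi_x),$$

with $\psi$ the soil water potential. Substituting $g_s$ makes this a
quadratic in $\psi_x$; `solve_leaf()` evaluates the closed-form root and
also exposes a bracketing bisection on $[-\pi, \psi]$ as an independent
check (the two agree to $10^{-8}$ MPa on dense grids; the tests assert
it). When $\psi \le -\pi$ no turgor is possible: the stomata are closed
and the xylem equilibrates with the soil. A useful consequence is that the
closure soil water potential is simply $-\pi(A_n)$, independent of $D$.

```{r}
behavior_benchmarks(pft_params())
```

These are the forward benchmarks at the reference assimilation
$A_n = 6.5$ µmol m$^{-2}$ s$^{-1}$: conductance at the favorable corner
($\psi = -0.033$ MPa, about field capacity, and $D = 0.0035$, about 91%
relative humidity at 30&deg;C and sea level), conductance under wet soil but
high demand ($D = 0.05$), and the closure potential. The subshrub group
(SUBS, *Artemisia*) opens widest under favorable moisture but closes at the
wettest soil, the deciduous groups tolerate drier soil - the
tolerance-versus-opportunism contrast the group parameters encode.

## Parameters and units

All conductances are molar internally: $g_p$ is stored in mol m$^{-2}$
s$^{-1}$ MPa$^{-1}$ even though group tables conventionally print mmol
(`pft_params()` and `obs_params()` convert on construction). A single
internal unit system avoids the mmol/mol confusion that mixed tables
invite. `units_io` converts instrument exports - mmol conductances,
molar or velocity resistances (via the ideal-gas molar density of air),
hPa/mbar pressures - into this convention, drops records violating
physical sanity bounds, and averages replicates per leaf-hour so repeated
measurements on one leaf do not masquerade as independent data. Averaging
is mandatory before fitting.

## The synthetic-data generator

Field campaigns measure diurnal courses: several leaves, several hours per
day, several days per observation (a species at a site), with soil water
potential unknown but approximately constant within a day.
`generate_dataset()` emulates exactly this structure: half-sine diurnal
drivers peaking at noon (default peaks $D_{max} = 0.04$ - about 4 kPa VPD
at sea level, a realistic semiarid midday - and $A_{max} = 12$ µmol
m$^{-2}$ s$^{-1}$, with intercellular CO$_2$ drawn down by a quarter at
peak assimilation), one latent soil water potential per day drawn
uniformly from $[-3, -0.1]$ MPa, true parameters defaulting to the
published group estimates, and i.i.d. Gaussian observation noise on $g_s$
(SD 0.1 mol m$^{-2}$ s$^{-1}$ by default in the design; recovery studies
here use 0.05) truncated at zero by inverse-CDF sampling. The generator
returns the generating truth alongside the records, so recovery is
testable end to end.

What it does not emulate: weather-driven soil moisture dynamics,
radiation-photosynthesis coupling beyond the sine proxy, instrument drift,
or heteroscedastic noise. Passing recovery tests therefore show that the
inference machinery works on data satisfying the model's own assumptions -
not that field data satisfy them.

## Hierarchical fitting

`fit_level()` fits the six parameters per unit under bounded-uniform
priors with an i.i.d. Gaussian likelihood (single residual SD per level)
by Metropolis-within-Gibbs: every scalar parameter in turn gets a Gaussian
random-walk proposal reflected at its prior bounds (reflection is
symmetric, so the acceptance ratio is the likelihood ratio). Three nesting
levels mirror the analysis design:

* **OBS** - one parameter set per observation, plus one latent soil water
  potential per observation-day and the single shared $C_\lambda$;
* **PFT** - one set per functional group;
* **GLB** - one pooled set.

The staging is two-pass (`fit_hierarchy()`): the OBS fit runs first, and
its posterior-mean day potentials and $C_\lambda$ are fixed inputs to the
PFT and GLB fits. Free-parameter counts follow the convention 5 per unit,
plus the day potentials and $C_\lambda$ at the OBS level only, with the
residual SD not counted; the study layout of 43 observations over 80 days
gives $43 \times 5 + 80 + 1 = 296$.

Prior bounds: $K_\psi \in [0.01, 1.5]$ (the published prior), $g_p \in
[0.0005, 0.08]$ mol m$^{-2}$ s$^{-1}$ MPa$^{-1}$, $K_i \in [20, 400]$,
$\pi_0 \in [0.5, 2]$ MPa, $\xi \in [0, 250]$, $C_\lambda \in [0.1, 10]$,
day potentials in $[-8, -0.01]$ MPa (shrubs tolerate severe drought), and
$\sigma \in [0.001, 1]$. Where the original bounds are not recoverable
these envelope all published estimates with margin. $\sigma$ gets a
bounded-uniform prior too (a precision-gamma prior would be the WinBUGS
idiom; the choice is a config default, not a claim about the original
analysis).

### Numerical choices

* Proposal scales start at a tenth of each prior range and adapt every 25
  burn-in iterations toward an acceptance rate in $[0.2, 0.5]$ (capped at
  five prior ranges), then freeze; the first half of each chain is
  discarded.
* Chains start by default from a deterministic warm start: alternating
  rounds of bounded least squares over each unit's parameters (`nlminb`)
  and 1-D optimization of each day's potential, jittered per chain.
  Started from prior draws instead (`init = "prior"`), chains need about
  an order of magnitude more iterations to traverse the posterior ridge
  described below; warm starts are the standard remedy, and the
  prior-draw option remains for diagnostics such as the flat-likelihood
  uniformity test.
* Convergence is summarized by split-half R-hat per parameter; the
  bisection fallback of the solver runs to $10^{-12}$ MPa.
* The quadratic root is selected inside $[-\pi, \psi]$; if both roots fall
  inside (never observed on tested grids) the larger-turgor root is taken
  with a warning. As $C_\lambda \to 0$ the quadratic degenerates and the
  solver switches to the exact linear-supply solution.

### Identifiability: what a fit can and cannot tell you

With the day potentials latent, the likelihood has an exact compensation
direction in the supply-limited regime. When $K_\psi \pi$ is large
relative to what $g_p$ can deliver, midday conductance is set almost
entirely by supply, and raising $K_\psi$ while lowering $\pi_0$ (with
$\xi$, $K_i$ and the day potentials adjusting) leaves predictions nearly
unchanged: for a deciduous-shrub-like parameter set the profile deviance
is flat to less than 0.1 over $K_\psi \in [0.16, 0.9]$. The posterior then
spreads along this ridge, and its mean is not a reliable point estimate of
$K_\psi$ or $\pi_0$ for such units - though predictions, the residual SD,
and demand-limited units (subshrub-like, large $K_\psi$) are recovered
well. With the day potentials known, bounded maximum likelihood recovers
all three structural parameters to a few percent, so the limitation is
the latent-potential design, not the data volume. The same geometry makes
the plug-in deviance at the posterior means a poor summary on ridged
fits, which is why DIC's effective-parameter count can turn negative
there - a pathology the published observation-level DIC also displays.

## Model comparison

Nested levels are compared by the difference in deviance against a
$\chi^2$ with degrees of freedom equal to the difference in parameter
counts. `compare_levels()` uses the posterior mean deviance (what
WinBUGS-style summaries print as "Deviance"); `glance()` also reports the
plug-in deviance and DIC. The $\chi^2$ reference distribution is
likelihood-ratio theory, so the repeated-simulation calibration of the
test's type-I rate uses bounded maximum-likelihood deviances
(`fit_deviance_ml()`, with the finer model started from the coarser
model's optimum so the statistic is non-negative by construction); 200
scaled-down null replicates put the rejection rate inside the binomial
band around 5%. The Welch (unequal-variance) form is used for the
group-mean comparison of fitted day potentials, as only "t test" is
conventionally specified.

## Behavioral analysis

`response_surface()` evaluates $g_s$ over a (soil potential x demand)
lattice; `ensemble_curves()` sweeps all observation-level parameter sets
and returns pointwise mean +/- SD; `vulnerability_curve()` averages
$K(\psi_x)$ across sets and finds the tension at which the mean curve
halves by bisection (invariant to axis resolution, cross-checked against
a dense scan). Under the mean-of-curves convention the observation-level
ensembles put the group half-loss tensions at about -14.5 (DCDS), -13.8
(LEGM) and -12.1 MPa (SUBS) - deciduous xylem slightly safer than
subshrub xylem, the ordering the efficiency-safety tradeoff implies. The
averaging convention behind published group half-loss figures is not
stated, so these values are reported, not asserted.

Favorable-corner conventions ($\psi = -0.033$ MPa, $D = 0.0035$,
$A_n = 6.5$) are package constants; grids export as plain tables and
plotting (`autoplot()`, `plot_ensemble_curves()`) is a thin layer on top,
since the analysis surface is numeric.

## Problem sizes used in the test suite

The packaged checks run fits at reduced scale chosen to exercise every
code path with useful statistical power: recovery at 3 observations x 3
days x 36 records/day with 2 chains of 2,000 iterations; the nested
comparison pattern at 6 observations with per-observation parameter
jitter (lognormal, 20% CV, emulating observation-level spread); interval
coverage over 20 replicate simulations; calibration over 200 null
replicates via maximum likelihood. The forward behavioral benchmarks are
exact desk-scale computations and run in well under a second.

## Known limitations

Steady-state only (no stomatal dynamics, boundary-layer conductance, leaf
energy balance, or hydraulic capacitance); a single homoscedastic Gaussian
residual per level; $C_\lambda$ is weakly informed by gas-exchange data in
realistic ranges (tensions of ~1 MPa lose only a few percent of
conductance, so its posterior stays close to the prior); and the
latent-potential ridge above. These are properties of the model and
design, and the package reports them rather than hiding them.
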