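---
title: "Modelling the nocturnal decline of plant dark respiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the nocturnal decline of plant dark respiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctresp)
```

## The model

Dark respiration at the prevailing temperature, `R_T` (µmol CO2 m⁻² s⁻¹,
efflux positive throughout this package), is conventionally written as a
basal rate at a reference temperature scaled by a Q10 response,

$$R_T = R_{T_o}\,Q_{10}^{(T - T_o)/10},$$

with `Q10` fixed (default 2) or temperature-dependent,
$Q_{10}(T) = 3.09 - 0.0435\,T$. The package's central object is the
*temperature-independent* nocturnal decline of the basal rate itself,

$$R_{T_o}/R_{T_o,\mathrm{initial}} = \max(0,\; 1 - a\,h^b),$$

with `h` hours since the onset of darkness and default coefficients
`a = 0.08`, `b = 0.54`. The clamp at zero is a guard for pathological
configurations only; with the default coefficients the curve stays positive
far beyond any real night. Merging the two gives the nocturnal formulation
anchored at sunset,

$$R_{T,t} = R_{T,\mathrm{sunset}}\;Q_{10}^{0.1\,(T_t - T_\mathrm{sunset})}\,
(1 - a\,h^b),$$

implemented in `new_formulation()`. Key assumptions: the decline is
multiplicative and independent of the temperature response; it resets at
each sunrise (no carry-over between nights, no thermal acclimation across
days); and it applies to the whole maintenance term, because the
land-surface scheme scales leaf respiration to root and stem respiration
linearly (`maintenance_resp()`), so a factor on leaf respiration passes
through unchanged.

Where the temperature-dependent Q10 appears inside the merged formulation,
it is evaluated at the *instantaneous* temperature `T_t`. The exponent
notation does not force this choice — the sunset temperature or the midpoint
would be defensible — but the instantaneous reading is the literal one, is
continuous in time, and reduces correctly as `T_t → T_sunset`.

## Temperature control and apparent versus inherent Q10

Over a night, the observed decrease in `R_T` splits into `alpha`, the part
explained by cooling acting through the inherent Q10, and `beta`, the
further temperature-independent decrease; `TC = alpha/(alpha + beta)`
(`tc_decompose()`). The decomposition uses endpoint pairs (start and end of
night), matching how such measurements are made in practice. Two boundary
conventions matter:

* a *warming* night is reported as `TC = NA` with a warning rather than a
  negative number — the construct assumes nocturnal cooling;
* a night with no decrease at all (`alpha = beta = 0`) is also `NA`: the
  fraction is genuinely undefined there.

`apparent_q10_curve()` and `tc_curve()` give the closed-form dependence of
the apparent Q10 and of TC on the linear cooling rate `c` for a night of
length `L`: the apparent Q10 is
$Q_{10,inh}\,(1 - aL^b)^{-10/(cL)}$, which diverges as `c → 0` and relaxes
to the inherent value for fast cooling, while TC rises from 0 to 1. The
inherent Q10 is conceptually tied to brief (≤ 30 min) temperature
manipulations; the package treats that window as metadata validation on
measurement pairs, not as physics.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `a`, `b` | — | 0.08, 0.54 | universal decline coefficients |
| `q10` (fixed) | — | 2 | conventional land-surface value |
| TDQ10 intercept/slope | —, °C⁻¹ | 3.09, 0.0435 | linear temperature dependence of Q10 |
| `t_upp`, `t_low` | °C | 36, 0 | logistic high/low temperature limits of leaf respiration; smoothing 0.3 is fixed, not user-configurable |
| `(n_r + n_s)/n_l` | — | 1 | root+stem respiration equal to leaf respiration for an unstressed broadleaf canopy; only the ratio matters |
| `beta_sw` | — | 1 | unstressed soil water |
| `growth_fraction` | — | 0.25 | growth respiration as a fraction of `GPP − R_m` |
| `r_ref` (site) | µmol m⁻² s⁻¹ | 1 | canopy leaf respiration at 25 °C; sets the absolute scale of a site run |
| timestep | min | 15 | sub-daily stepping of the site simulator |
| NPP threshold | g C m⁻² yr⁻¹ | 50 | mask percentage effects where the baseline NPP is tiny |
| exclusion window | min | 30 | drop post-dusk samples contaminated by light-enhanced dark respiration (LEDR) |

Growth respiration is clamped at zero: at night GPP is zero and the
unclamped `0.25 (GPP − R_m)` would be negative, which has no biological
reading as growth.

## What the synthetic generators emulate

The generators produce data with exactly the statistical structure the
pipeline assumes: per-species power-law decline with replicate- and
measurement-level noise; constant-temperature "lab" nights and cooling
"field" nights (the field condition in the decline dataset still has the
*measurement* temperature held constant, as in leaf-cuvette protocols); an
optional LEDR transient confined to the first 30 min (an additive
exponential burst with a 10-min decay — a stand-in whose only load-bearing
property is its confinement, so that the exclusion window provably removes
it); high-noise whole-tree nights with lognormal night-to-night variation in
the initial signal, for exercising the top-decile filter (retaining
`ceiling(0.10 n)` nights — with 62 nights, 7); and sinusoidal diurnal
forcing whose GPP is a half-sine between the sunrise and sunset of the
standard declination/hour-angle equations, exactly zero at night.

Noise is multiplicative Gaussian on respiration. Respiration magnitudes
differ ~50-fold between leaf and whole-tree scales, so relative noise is the
natural invariant; nothing instrument-specific (IRGA drift, leak
signatures) is imitated.

The default dataset — 31 species, 4–20 replicates per species, hours 0–10
sampled every 6 min, noise sd 0.03, all species on the universal
coefficients — is the package's study condition for parameter recovery.
Passing tests on these data demonstrate that the *pipeline* is unbiased and
correctly weighted when the data really are power-law declines with this
noise structure. They do not demonstrate that real nights are power laws,
that real noise is multiplicative Gaussian, or anything about species whose
decline parameters differ from the universal pair; between-species
heterogeneity is available (`a_sd`, `b_sd`) but is not part of the default
conditions.

## The fitting pipeline and its numerical choices

`normalize_trace()` drops samples inside the exclusion window and anchors
the remainder at the first retained sample (ratio exactly 1).
`bin_hourly()` averages ratios in hourly bins `[k, k+1)`; `aggregate_species()`
averages replicate bin means with `SEM = sd/√n` (SEM 0 for a single
replicate). `fit_power_law()` minimises $\sum_i w_i\,(y_i - \hat y_i)^2$
with $w_i = 1/\mathrm{SEM}_i$ by Levenberg–Marquardt, the intercept fixed at
1 by the functional form.

**Bin abscissa.** The bin mean of a concave power law is not the curve at
the bin centre, so evaluating the model at `k + 0.5` biases the fitted scale
low whenever bins hold many sub-hourly samples (most visibly in bin 0, where
the curve has a cusp). The default therefore compares each bin mean with the
model's own within-bin average, $1 - a\,\overline{h_i^b}$ over the hours the
bin actually contains; this makes the estimator exactly unbiased for data
generated by the power law, for any sampling layout, and is why the
noiseless round-trip test recovers the generating coefficients to 1e-6.
The conventional centre-of-bin evaluation remains available
(`abscissa = "centre"`) and is used automatically when an aggregate carries
no sampled-hour information.

**Weights.** `1/SEM` (not inverse variance) is the documented convention of
this analysis; weighted and unweighted fits coincide when all SEMs are
equal. A zero SEM would give an infinite weight, so single-replicate bins
receive the largest finite weight present; if every SEM is zero the fit is
unweighted. `r²` is computed on the weighted residuals as
`1 − SS_res/SS_tot`. Parameter intervals are Wald/t on the residual degrees
of freedom, and the curve band is first-order delta method from the
parameter covariance; the `b`-gradient term $-a h^b \log h$ is set to 0 at
`h = 0`, its limit. Because replicate ratios share their noisy normalization
basis, species bin means are weakly correlated across bins; the covariance
ignores this, so intervals are mildly anti-conservative — a documented
limitation.

**Log-linearization.** Group slope statistics regress
$\log(1 - \mathrm{ratio} + \epsilon)$ on $\log h$, $\epsilon = 10^{-6}$,
dropping non-positive transformed responses with a warning. On an exact
power law this slope is the exponent `b`. Other transforms (e.g. log ratio
on time) yield different slope magnitudes, so cross-study slope values are
comparable only under a stated convention — this one is stated prominently
for that reason.

**Group comparisons.** Welch's t (via `stats::t.test`) compares group mean
slopes; all-pairs within-group comparisons use
`t = (s_i − s_j)/√(se_i² + se_j²)` with `df = n_i + n_j − 4` and a
Bonferroni threshold `α/m` over the `m` pairs actually tested.

## Evaluating formulations

Four formulations are compared: standard (fixed Q10 = 2),
standard-modified (TDQ10), and the two merged with the decline.
`simulate_trace()` drives each with the observed temperatures and elapsed
hours, anchored at the first retained sample (prediction 1 there). The
one-to-one regression excludes that anchor pair by default, since it equals
unity by construction and inflates apparent fit quality on average.
Standardized residuals follow
$S_i = r_i / \sqrt{\sum r_j^2 / df}$ on the anchored residuals, with
`df = N − 1` by default: no parameters are fitted in the comparison, and the
anchoring consumes one degree of freedom. Taylor statistics use population
standard deviations so that the Taylor identity
$cRMS^2 = \sigma_p^2 + \sigma_o^2 - 2\sigma_p\sigma_o r$ holds exactly.

## The site simulator

`run_site()` steps one site through sub-daily forcing: leaf respiration
follows the temperature-limited response at the instantaneous air
temperature at every step (leaf temperature is taken equal to air
temperature — no energy balance at this scale), and GPP is prescribed from
forcing rather than computed, which isolates the respiration effect exactly.
Through the night the decline factor multiplies the *full*
temperature-limited leaf respiration, with `h` accrued from the timestep at
or immediately preceding sunset and reset at sunrise. Multiplying the full
limited response (rather than re-anchoring the Q10 term at the captured
sunset state) is the reading under which disabling the decline reproduces
the standard run step for step; for a scalar product the order is immaterial
anyway. Maintenance, growth (clamped), `R_p = R_m + R_g` and
`NPP = GPP − R_p` follow at every step, so carbon closure
(`NPP + R_p = GPP`) holds to rounding at each timestep by construction, and
paired runs trade respiration for NPP one-to-one in absolute terms.

Nightly integrals are trapezoidal on the model timestep.
`nightly_leaf_integral()` closes each night at sunrise, completing the final
partial step with the sunrise-step value (carrying the decline at the full
night length), because the stepped series itself resets at sunrise. At
constant night temperature the relative reduction of the nightly leaf
integral has the closed form $(a/(b+1))\,L^b$ — 19.88 % for a 12 h night —
and the 15-min trapezoid reproduces it to better than 0.1 %. Under cooling,
the cusp of $h^{0.54}$ at dusk limits the 15-min trapezoid to roughly 0.2 %
of a fine-grid integral; users wanting tighter agreement should pass a finer
`timestep` to `cumulative_overestimation()`.

Sun geometry uses the declination/hour-angle approximation with polar
clamping; it is accurate to a few minutes, which is well inside a 15-min
timestep.

## Problem sizes used in the tests

The test suite and acceptance script run entirely on synthetic data built at
call time: the recovery study uses 200 seeded repetitions of a 6-species
dataset for the median-bias property and a single 31-species dataset
(≈ 370 traces, 310 species-bins) for confidence-interval coverage; the
Welch calibration uses 10 000 simulated null tests; site runs cover 2–3
simulated days at a 15-min timestep. These sizes were chosen so that every
statistical property is measured with comfortable Monte-Carlo margin while
the whole suite stays interactive.

## Known limitations

* The decline coefficients are treated as universal; no thermal acclimation,
  no day-time inhibition of respiration, no carry-over between nights.
* Confidence intervals from the weighted fit ignore the within-replicate
  correlation induced by normalizing to a noisy initial sample (mildly
  anti-conservative, as above).
* The site simulator has no leaf energy balance, no photosynthesis model,
  no soil moisture dynamics (`beta_sw` is a fixed scalar) and no vegetation
  structure; it is a mechanism demonstrator for the respiration effect, not
  a land-surface model.
* Global or gridded results are out of scope; the simulator is
  deliberately single-site.
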