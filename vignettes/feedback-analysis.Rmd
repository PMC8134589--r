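---
title: "Estimating climate–carbon cycle feedbacks across timescales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating climate–carbon cycle feedbacks across timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfeedback)
```

## The feedback framework

Land and ocean carbon reservoirs respond to both rising atmospheric CO2 and
a changing climate. Over a time interval, the change in combined land +
ocean storage is modelled as a bilinear response

$$\Delta C_B = \beta\,\Delta C_A + \gamma\,\Delta T_A +
  f(\beta,\gamma)\,\Delta C_A \Delta T_A,$$

where $\beta$ (GtC ppm$^{-1}$, or GtC GtC$^{-1}$ after dividing by
$m = 2.12$ GtC ppm$^{-1}$) is the carbon-concentration feedback, $\gamma$
(GtC K$^{-1}$, negative when warming releases carbon) is the
carbon–climate feedback, and $f$ (GtC ppm$^{-1}$ K$^{-1}$) couples the two
drivers. Carbon conservation ties the stores to cumulative anthropogenic
emissions, $\Delta C_E = \Delta C_A + \Delta C_B$, so

$$\Delta C_E = (1+\beta)\,\Delta C_A + \gamma^{*}\,\Delta T_A,
  \qquad \gamma^{*} = \gamma + f\,\Delta C_A ,$$

with everything expressed in GtC. Dividing by $\Delta T_A$ relates the four
standard sensitivities: $\mathrm{TCRE}^{-1} = (1+\beta)\,\alpha^{-1} +
\gamma^{*}$, where $\alpha = \Delta T_A/\Delta C_A$ and
$\mathrm{TCRE} = \Delta T_A/\Delta C_E$.

## The spectral estimator

Annual records of $C_E$, $C_A$ and $T_A$ are decomposed into Fourier
harmonics (`amplitude_spectrum()`): means removed, no taper and no
detrending, one-sided amplitudes $2/N$ times the modulus of the FFT
coefficient. The trend is deliberately left in the series — it is carried by
the low-frequency harmonics, which is precisely what lets a single
regression span inter-annual to multi-decadal timescales. When the three
series share phases harmonic by harmonic, the conservation identity holds
per amplitude: $a_k = (1+\beta) b_k + \gamma^{*} c_k$. Dividing by the
temperature amplitude $c_k$ gives per-timescale ratios
$\zeta_k = a_k/c_k$ ($=\mathrm{TCRE}^{-1}$) and $\eta_k = b_k/c_k$
($=\alpha^{-1}$), computed by `zeta_eta()`, and an ordinary least-squares
regression of $\zeta_k$ on $\eta_k$ across timescales
(`fit_beta_gamma_star()`) whose slope estimates $1+\beta$ and whose
intercept estimates $\gamma^{*}$.

Choices that matter, with defaults:

* **Fit band** — harmonics with timescales in $[2, 90]$ years, the
  industrial-record choice; configurable per call.
* **Intercept reading of $\gamma^{*}$** — the per-harmonic identity makes
  $\gamma^{*}$ the regression intercept; `gamma_star_by_timescale()` gives
  the per-harmonic version $\zeta_k - (1+\beta)\eta_k$, whose band mean
  coincides with the intercept on exact systems.
* **Regression weighting** — unweighted OLS. Per-harmonic uncertainties are
  not propagated into weights; with amplitude ratios spanning an order of
  magnitude this is a known approximation, flagged here rather than hidden.
* **Denominator floor** — harmonics whose temperature amplitude is below
  $10^{-9}$ of the maximum are excluded (the ratio is undefined), as is the
  phase-degenerate Nyquist harmonic of even-length records.
* **Units** — all regression inputs are converted to GtC first; $\beta$ is
  reported in both GtC GtC$^{-1}$ and GtC ppm$^{-1}$ ($\times 2.12$).
  Functions that take a bare $\beta$ require an explicit unit tag
  (`"GtC_per_GtC"` or `"GtC_per_ppm"`) because the factor 2.12 is the
  single most common bookkeeping error in this area.

For a quasi-equilibrium epoch with negligible emissions ($\zeta_k \approx
0$), the identity collapses to $\gamma_k = -m (1+\beta)\,\eta_k$
(`preindustrial_gamma()`), with $\eta_k$ in ppm K$^{-1}$ taken from CO2 and
temperature reconstructions. A "100-year timescale" value is reported as the
band mean over harmonics with periods in $[90, 110]$ years
(`band_statistics()`): a discrete harmonic grid has no harmonic at exactly
100 years, so a symmetric band around it is the natural reading.

## Airborne fraction, gain and amplification

The airborne fraction $AF = \Delta C_A/\Delta C_E$ is computed per harmonic
as $b_k/a_k$ (`airborne_fraction_spectrum()`). The feedback gain factor and
amplification follow two algebraically equivalent routes,

$$g = \frac{-\gamma^{*}\alpha}{1+\beta} = 1 - \frac{1}{AF(1+\beta)},
  \qquad G = \frac{1}{1-g} = AF(1+\beta),$$

implemented separately (`gain_from_alpha()`, `gain_from_af_beta()`,
`amplification()`) and tested to agree to $10^{-10}$ on inputs satisfying
$AF = 1/(1+\beta+\alpha\gamma^{*})$. Budget rescaling by a ratio of
amplifications, with relative-quadrature error propagation, is in
`allowable_emissions_scale()`; the ensemble rules (propagated
$\tfrac{1}{n}\sqrt{\sum\sigma_i^2}$ vs plain sample spread) are
`ensemble_mean_sigma()` and `ensemble_sd()`.

## The box model

`simulate_box()` closes the loop with three parameters: per year,

$$C_A = C_0 + \frac{\Delta C_E - \gamma^{*}(T_A - T_0)}{(1+\beta)\,m},
  \qquad T_A = T_0 + \frac{s}{\ln 2}\ln\frac{C_A}{C_0} + \varepsilon,$$

with $s$ the warming per CO2 doubling (the conventional assessed range is
1.5–4.5 K) and $\varepsilon$ an optional internal-variability series. The
two equations are simultaneous; since no closed form exists, each year is
solved by damped fixed-point iteration (damping 0.5, tolerance $10^{-10}$
ppm, 1000-sweep cap, initialised from the previous year). The logarithmic
coupling is weak at realistic parameters, so convergence takes a handful of
sweeps; the per-year carbon-conservation residual
$|\Delta C_E - (1+\beta) m \Delta C_A - \gamma^{*} \Delta T_A|$ is the
solver's acceptance check and stays below $10^{-8}$ GtC. The numerator is
evaluated in GtC with $\beta$ in GtC GtC$^{-1}$ and the quotient converted
to ppm — the only dimensionally consistent reading of the carbon balance.

`self_consistency_recovery()` closes the round trip: simulate with known
$(\beta, \gamma^{*})$, refit with the spectral estimator. The forcing trend
is not harmonic, so recovery is not exact; with exponential emissions over
168 years and $\varepsilon = 0$ the refit lands within a few percent of the
input $\beta$ (the contract tested is 10%, with 30% on $\gamma^{*}$, whose
intercept is far more leakage-sensitive).

## FEA estimators for experiment triplets

For model experiments run in fully coupled (COU), biogeochemically coupled
(BGC: only the carbon cycle sees rising CO2) and radiatively coupled (RAD:
only the radiation sees it) configurations, the feedback parameters are
recovered from deltas at a fixed horizon relative to a reference year:
$\beta^{\mathrm{BGC}} \approx \Delta C_B^{\mathrm{BGC}}/\Delta
C_A^{\mathrm{BGC}}$, $\gamma^{\mathrm{RAD}} = \Delta
C_B^{\mathrm{RAD}}/\Delta T_A^{\mathrm{RAD}}$, the COU–BGC difference
estimating $\gamma^{*}$, the COU–RAD difference estimating $\beta + f\Delta
T_A$, and

$$f = \frac{\Delta C_B^{\mathrm{COU}} - (\Delta C_B^{\mathrm{BGC}} +
  \Delta C_B^{\mathrm{RAD}})}{\Delta C_A^{\mathrm{COU}}\,
  (\Delta T_A^{\mathrm{COU}} - \Delta T_A^{\mathrm{BGC}})}.$$

Exact forms that retain the small BGC warming are available alongside the
approximate ones. One internal-consistency choice deserves a note: the
cross-pair exact form for $\beta^{\mathrm{COU-RAD}}$ is implemented as
$(\Delta C_B^{\mathrm{COU}}\Delta T^{\mathrm{RAD}} - \Delta
C_B^{\mathrm{RAD}}\Delta T^{\mathrm{COU}})/(\Delta C_A^{\mathrm{COU}}\Delta
T^{\mathrm{RAD}})$, the sign that agrees with its approximate form on any
bilinear system; the opposite ordering, sometimes seen in print, returns
$-\beta$. The reference year and horizon are explicit configuration, with
defaults at the first and last record years. `fea_by_timescale()` resolves
the estimators by window length with sliding windows, reporting mean ± sd.

## What the synthetic generators emulate — and what they do not

The generators are first-class, tested code; their defaults are the study
conditions, not tuning knobs.

* `gen_harmonic_system()` — multi-harmonic CO2/temperature systems tied to
  emissions through the conservation identity with prescribed
  $(\beta, \gamma^{*})$. Phase-locked mode makes the amplitude identity
  exact per harmonic (the correctness fixture); free-phase mode keeps the
  identity only for complex coefficients, deliberately exposing the
  estimator's phase assumption.
* `gen_exponential_emissions()` — the industrial emission path
  $0.27\,e^{0.018 t}$ (doubling time $\approx 38.5$ yr); an exponentially
  forced linear system has constant response ratios, which is why $\beta$
  and $AF$ come out near-constant across timescales.
* `gen_ar1_noise()` — stationary AR(1) internal variability,
  parameterised by its marginal sd; a stand-in, since the true spectral
  shape of internal variability is not characterised here.
* `gen_icecore_like()` — firn-diffusion-style low-pass smoothing of an
  annual record via the spline smoother.
* `gen_experiment_triplet()` — COU/BGC/RAD runs with prescribed
  $(\beta, \gamma, f)$, a logarithmic temperature response, and BGC warming
  exactly zero by default (optionally noised), so every FEA estimator has
  an algebraic ground truth.

What passing tests on these fixtures demonstrate is *internal* correctness:
the estimators invert their own generating model exactly, the two gain
routes agree, the box model conserves carbon. What they cannot demonstrate
is robustness to everything real records add — phase mismatch between CO2
and temperature variability, non-CO2 forcing, observational error,
ice-core age-model distortion — beyond the specific perturbations
(free phases, AR(1) noise, firn smoothing) the generators provide.

## Other numerical choices

* **"N-year spline"** (`spline_smooth()`): a cubic smoothing spline whose
  stiffness is calibrated numerically so the amplitude response on a pure
  tone of period N is 0.5 — the dendroclimatology convention. Amplitude is
  measured over the central half of the record to keep natural-boundary
  effects out of the calibration; if even the stiffest admissible spline
  cannot reach 0.5 (very long cutoffs on short records) the stiff endpoint
  is used.
* **Resampling** (`resample_to_years()`): observations to the nearest
  calendar year, same-year collisions averaged with a warning, gaps filled
  by linear interpolation — the minimal gap rule, stated rather than
  assumed.
* **Cumulative emissions**: a running sum of annual fluxes; the rectangle
  rule is exact for annual totals.
* **Degenerate inputs**: constant series yield all-zero spectra; fits
  require at least 3 in-band harmonics and nonzero $\eta$ variance;
  single-harmonic bands report sd 0 with n = 1; denominators below the
  floors above raise typed errors rather than returning infinities.

## Problem sizes

The test suite and examples use records of 100–300 years, 5–6 harmonics
for exact-recovery fixtures, a 168-year exponential-forcing box-model run,
and 140-year 1%-per-year CO2 triplets — the native scales of the records
and experiments this methodology targets, and comfortably exact for the
properties being checked (identities hold to $10^{-8}$–$10^{-12}$).

## Limitations

Non-CO2 greenhouse-gas forcing is ignored by construction. $\gamma^{*}$
from the industrial-period fit conflates $\gamma$ and $f\Delta C_A$; the
two are separable only in the triplet design. The spectral estimator
assumes the per-harmonic identity transfers from complex coefficients to
amplitudes, which strictly requires aligned phases; the free-phase
generator exists precisely to probe that gap. Uncertainty propagation
covers the documented ensemble and quadrature rules, not a full error
model of real observational inputs.
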