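---
title: "Host-plant energetics: models, processing chain and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-plant energetics: models, processing chain and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostcost)
```

`hostcost` turns raw stop-flow syringe respirometry traces into CO₂
production rates, derives growth-rate and growth-cost statistics for
larvae reared on different host plants, and fits the allometric and
mixed-model analyses those statistics feed. This vignette is the package's
account of the underlying science: the models, their assumptions, the
tunable parameters and the choices made where the design was genuinely
open.

## The measurement model

In stop-flow (closed-system) respirometry an animal is sealed in a syringe
of volume $V_s$ (default 20 mL) for an incubation time $T$ (default 60 min
at 22 °C). An aliquot $V_i$ of the incubated air (7 mL for 3rd instars,
10 mL for 4th instars and pupae) is then injected into a CO₂-scrubbed
carrier stream flowing at rate $F$ (mL min⁻¹) through an infrared analyzer
reading in ppm. The processing chain is:

1. **Baseline.** A linear model is fitted to the pre-injection reference
   segment (analyzer on scrubbed carrier air) and evaluated over the whole
   trace. A linear rather than constant baseline absorbs slow analyzer
   drift; a constant-mean option exists for drift-free runs. The reference
   window defaults to everything up to 5 s before the injection marker and
   must contain at least 5 samples.
2. **Fraction × flow.** Baseline-corrected ppm are divided by $10^6$
   (air fraction) and multiplied by $F$, giving an instantaneous mL min⁻¹
   of CO₂ passing the analyzer.
3. **Integration.** That quantity is integrated over the injection bolus by
   the trapezoidal rule with time in minutes, giving the CO₂ volume (mL)
   in the aliquot. On smooth boluses sampled at 1 Hz the trapezoid error
   is far below the 0.1 % documentation tolerance (the tests compare it
   against closed-form Gaussian and rectangular areas and high-resolution
   quadrature).
4. **Corrections.** The paired empty-syringe control volume is subtracted
   *first*; the difference is scaled by $V_s / V_i$ (the un-injected air
   carries CO₂ at the same fraction) and divided by $T$:

   $$\dot{V}\mathrm{CO}_2 = (V_{sample} - V_{control}) \frac{V_s}{V_i} \frac{1}{T}
   \quad [\mathrm{mL\,min^{-1}}]$$

Design choices worth stating: the animal's own body volume is *not*
subtracted from $V_s$ (the correction is defined on the total syringe
volume); no temperature or pressure standardization is applied (all
measurements at one temperature); negative corrected volumes are retained
with a `negative_volume` QC flag rather than truncated at zero, because
truncation would bias low rates upward; sessions with no detectable bolus
are flagged `no_bolus` and integrated over the whole post-injection
segment rather than dropped.

**Window auto-detection.** The integration window defaults to the
contiguous run of samples whose baseline excess exceeds $k = 3$ times the
reference-window noise SD (the run containing the largest excess). Three
SDs is conservative enough not to chase noise spikes yet keeps ≥ 99.5 % of
a Gaussian bolus area at realistic signal-to-noise; it can be overridden
per session with an explicit window. With a noiseless trace the threshold
floor is $10^{-9}$ ppm, so effectively the whole bolus is integrated —
this is what makes the exact round-trip test (recovery of the latent rate
to within $10^{-6}$ mL min⁻¹) meaningful.

## Derived statistics

* **Growth rate** $= \log(\text{mass}_g \times 1000) / \text{dev time}_d$,
  i.e. logged mass in milligrams per day of development. The milligram
  conversion keeps the log positive for realistic larvae. The log base is
  a free convention that rescales the metric by a constant; the package
  defaults to the natural log with `base10` selectable.
* **Growth cost** $= (\text{dev time}_d / \text{mass}_g) \times 24 \times
  60 \times \dot{V}\mathrm{CO}_2$, in mL CO₂ per g. Note a unit subtlety:
  this formula extrapolates the per-minute rate over the *whole*
  development period per gram of attained mass — total mL g⁻¹, not an
  hourly quantity, although the statistic is sometimes glossed per hour.
  The formula is implemented exactly as defined; the textual gloss is
  noted here rather than "fixed", since host comparisons are unaffected by
  the constant.
* Both metrics use the 4th-instar mass and the development time from
  hatching to the 4th instar, the stage at which performance is scored.

## Inference layer

* **Mass scaling.** $\ln \dot{V}\mathrm{CO}_2 \sim \ln \text{mass} +
  \text{host}$ fitted by maximum likelihood; the common slope is the
  scaling exponent $b$, and $\exp(\text{intercept}_h)$ is the host
  coefficient $a_h$ under the package's explicit unit convention: rate in
  mL h⁻¹ at mass 1 g. (Back-transformed coefficients need a stated unit
  convention to be interpretable; this one makes $a$ the predicted hourly
  rate of a 1 g larva.) Host-specific slopes are tested by a
  likelihood-ratio test against the interaction model, with
  df = n_hosts − 1.
* **Mixed models.** Gaussian linear mixed models (lme4) with a family
  random intercept — or individual nested in family for the repeated
  metabolic-rate measurements — fitted by REML; fixed-effect LRTs refit by
  ML automatically, since REML likelihoods are not comparable across fixed
  structures. Singular fits (variance component at zero) are reported, not
  hidden; in that boundary case the fixed effects coincide with ordinary
  least squares, which the tests assert.
* **Wald χ² tests** are Type II (respecting marginality), matching the
  convention of `car::Anova`. For `lm` fits the chi-square statistic is
  F × df with a χ² reference.
* **Tukey contrasts** use estimated marginal means averaged over other
  factors at covariate means, with studentized-range adjustment. The
  reference distribution is asymptotic (z/χ², infinite denominator df)
  rather than Kenward–Roger: with hundreds of observations the difference
  is negligible, and it keeps the mixed-model and fixed-model paths
  consistent. With two levels the adjustment is exactly the unadjusted
  test, which the tests assert against a Monte-Carlo studentized-range
  null for k = 3.
* A sex covariate can be added to any model formula; it is excluded from
  the default models, whose design follows a protocol in which sex was
  known only for a subset and was not retained in final models.

## The synthetic-data generator

The generator exists so that the full pipeline — trace numerics included —
can be exercised and parameter recovery tested without any external data.
It emulates a split-brood rearing experiment: 15 families distributed over
three hosts (*Urtica dioica*, *Salix caprea*, *Ribes uva-crispa*), with
measurement counts per stage and host fixed at the emulated design's
replication (49/52/56 third instars, 88/97/109 fourth instars, 18/21/29
pupae). The same individuals are measured at both larval instars (and a
subset at pupation), making the nested family/individual random effect
identifiable.

The latent rate model is

$$\dot{V}\mathrm{CO}_2 = a_{host} \cdot \text{mass}_g^{\,b} \cdot
\exp(u_{family} + v_{individual} + \varepsilon),$$

with defaults $b = 0.84$, $a = 0.43/0.39/0.44$ mL h⁻¹ at 1 g for
Urtica/Salix/Ribes, and Normal log-scale effects
$u \sim N(0, 0.05^2)$, $v \sim N(0, 0.05^2)$,
$\varepsilon \sim N(0, 0.10^2)$. The variance components are free choices:
they give a realistic ~11 % total CV around the allometric mean and a
family ICC small enough to be credible for wild-caught broods.

**Free choices, and why.** Absolute masses and development times are not
constrained by the emulated protocol, so the defaults are internally
consistent choices rather than calibrated values: lognormal medians
ordered Urtica > Salix > Ribes for mass (0.32/0.28/0.26 g at the 4th
instar) and Urtica < Salix < Ribes for development time (14/15.5/18 d to
the 4th instar), respecting the performance hierarchy the design
emulates — fastest growth on nettle, slowest on gooseberry. Jointly with
the rate coefficients these defaults imply a growth-cost pattern in which
Urtica and Salix are similar and Ribes is ~35 % more expensive, the
qualitative pattern of interest; the Urtica–Salix similarity was a
deliberate parameter choice, fixed before any test was run.

**Traces.** Each measurement gets a synthetic analyzer run: baseline
(default 2 ppm, drift 0.002 ppm s⁻¹, white noise SD 2 ppm, 1 Hz sampling),
injection marker at 150 s, and a Gaussian bolus (SD 8 s, centred 5 SDs
after the marker) whose fraction×flow area equals
$\dot{V}\mathrm{CO}_2 \cdot T \cdot V_i / V_s$ — i.e. the generator and the
processor are exact inverses up to integration error. The Gaussian shape
is a free choice; area-based processing is shape-agnostic by construction,
and the tests verify this with rectangular pulses. Animals are batched
(default 8 per batch) and each batch gets one empty-syringe control
session, generated with a true rate of zero.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: analyzer nonlinearity and calibration error,
baseline steps or non-linear drift, incomplete mixing of syringe air,
animal activity during incubation, body-volume displacement, tailing
(non-Gaussian) boluses, and any correlation between mass and development
time beyond their shared host and family structure. Parameter recovery on
synthetic data demonstrates that the estimators are consistent and the
numerics exact under the stated model, not that the model captures every
artifact of a real analyzer.

## Determinism and problem sizes

Every stochastic routine takes an explicit seed; one pipeline seed fans
out to per-stage and per-session child seeds through a fixed integer
derivation, so stages are independently rerunnable and a full
`run_all()` is byte-reproducible. The test suite runs its heavier
simulations at sizes chosen to make the statistical assertions sharp but
cheap: the full-design recovery test uses the complete 519-measurement
study (451 larval measurements) once; the null-calibration check runs 200
replicate studies of the 4th-instar design on latent rates (trace
processing is shown exactly unbiased by the round-trip tests, so
re-synthesizing traces in every replicate would only re-test the same
numerics); the Ribes-inflation power check uses 50 replicates; the
variance-recovery and p-uniformity checks use 100 and 500 small fits.

## Known limitations

* The Gaussian mixed models are fitted on the raw rate scale for the
  metabolic-rate response (the field's convention); since the generative
  model is multiplicative, mild heteroscedasticity and induced
  host × stage interaction are expected at large sample sizes. The
  mass-scaling model, fitted on the log scale, is exactly specified.
* Wald χ² and asymptotic contrasts are large-sample tools; with very few
  families or measurements, profile or parametric-bootstrap intervals
  would be preferable and are not implemented.
* Flow-through respirometry, O₂, respiratory quotients and
  specific-dynamic-action curves are out of scope.
* The generator's absolute masses, times and rates are plausible, not
  calibrated to a real cohort; only the design structure, the allometric
  parameters and the ordering relations are pinned.
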