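# hostcost

Host-plant energetics of herbivorous insect larvae, from raw stop-flow
(syringe) respirometry traces to mixed-model inference.

Polyphagous caterpillars grow at very different speeds on different host
plants. One candidate explanation is energetic: digesting and detoxifying a
chemically challenging plant consumes energy that is then unavailable for
growth ("metabolic load"). Testing that idea requires connecting three
layers of data that normally live in separate tools:

1. **Respirometry traces.** An animal is sealed for a fixed time in a known
   air volume; an aliquot of the incubated air is injected through a CO₂
   analyzer. The CO₂ it produced is the baseline-excess analyzer signal,
   converted to an air fraction, multiplied by the carrier flow and
   integrated over the injection bolus, corrected for the un-injected
   air (total syringe volume / injected volume) and a paired empty-syringe
   control, and divided by the incubation time:
   the production rate V̇CO₂ in mL min⁻¹.
2. **Derived performance statistics.**
   growth rate = log(mass × 1000) / development time (log-mg per day), and
   growth cost = (development time / mass) × 24 × 60 × V̇CO₂ — the measured
   rate extrapolated over development, per gram of attained mass
   (mL CO₂ g⁻¹). A lower growth cost means cheaper growth.
3. **Inference.** The allometry V̇CO₂ = a_host · mass^b fitted as a
   common-slope log-log regression (with a likelihood-ratio test for
   host-specific slopes), and Gaussian linear mixed models with
   family random intercepts for host effects on growth rate, metabolic
   rate and growth cost, scored by Type II Wald χ² tests and
   Tukey-adjusted pairwise contrasts.

`hostcost` implements all three layers as a tidyverse-style pipeline, plus
a seeded synthetic-data generator that produces split-brood cohorts
(15 families across *Urtica*, *Salix* and *Ribes*, with the replicate
counts of the emulated design) and raw analyzer traces with known latent
parameters, so every stage — including the numerics of trace integration —
is testable end to end without any external data.

## Worked example

```r
library(hostcost)

cfg    <- sim_config()                  # the default synthetic study design
study  <- sim_study(cfg, seed = 1)      # cohort + 585 raw analyzer traces
vco2   <- process_study(study)          # traces -> V̇CO₂ (mL min⁻¹)
metrics <- attach_metrics(study$cohort, vco2)

larvae <- dplyr::filter(metrics, stage != "pupa")
fit <- fit_mass_scaling(larvae)
fit
#> <allometry_fit> rate = a * mass^b, 451 observations
#>   b = 0.8399
#>   a[Urtica] = 0.4261 mL CO2 h^-1 at 1 g
#>   a[Salix] = 0.3945 mL CO2 h^-1 at 1 g
#>   a[Ribes] = 0.4440 mL CO2 h^-1 at 1 g
#>   mass x host interaction LRT: chi2 = 0.262, df = 2, p = 0.877
```

The generator simulated rates with b = 0.84 and a = 0.43/0.39/0.44; after
full trace synthesis and processing the fit recovers them to two decimals,
and the interaction test correctly finds no evidence for host-specific
exponents (the data were generated with a common slope).

```r
fourth <- dplyr::filter(metrics, stage == "instar4")
gc_fit <- fit_lmm(fourth, growth_cost ~ host + (1 | family_id))
wald_chi2_tests(gc_fit)
#>   term  chisq    df  p_value
#> 1 host   269.     2 3.75e-59
pairwise_contrasts_tukey(gc_fit, "host")
#>   contrast       estimate    se    df statistic p_value p_unadjusted
#> 1 Urtica - Salix    -5.17  4.47   Inf     -1.16   0.479     2.47e- 1
#> 2 Urtica - Ribes   -62.6   4.35   Inf    -14.4    0         4.49e-47
#> 3 Salix - Ribes    -57.5   4.23   Inf    -13.6    0         5.81e-42
```

Under the default parameterization larvae on *Urtica* and *Salix* pay a
similar cost per gram of growth while *Ribes* feeders pay ~60 mL CO₂ g⁻¹
more — the qualitative pattern the defaults were chosen to emulate.

One call runs everything and writes a browsable output directory
(`cohort.csv`, `traces/`, `vco2.csv`, `metrics.csv`, `fits.json`,
`manifest.json` with file hashes):

```r
manifest <- run_all(cfg, seed = 1, out_dir = "run")
make_report(manifest, file = "run/report.txt")
```

A thin CLI over the same functions lives in `inst/cli/hostcost.R`
(`simulate`, `process`, `metrics`, `fit`, `run-all`, `report`).

## Scope

The package models stop-flow (closed) syringe respirometry only; flow-through
respirometry, O₂/respiratory-quotient analysis and energy conversion to
joules are out of scope. See the methods vignette
(`vignettes/host-plant-energetics.Rmd`) for the model assumptions, the
generator's design and its limitations.
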