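---
title: "Methods: the N loss risk index, its surrogate transport model, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the N loss risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nriskindex)
```

## The risk model

Nitrogen loss risk is scored per *block* (a group of fields under common
management) and per calendar month as the product of N availability
(*source*, kg N ha⁻¹ month⁻¹) and the likelihood of movement (*transport*,
a dimensionless fraction in [0, 1]) along each of two flow paths:

$$\mathrm{Leaching\ index} = leach \times (urine + dung + effluent + fert
  + bg\,residues + cultivation)$$
$$\mathrm{Runoff\ index} = runoff \times (erosion + dung + fert
  + ag\,residues)$$

Urine is treated as washed into the soil immediately and therefore
unavailable to runoff; belowground residues and cultivation mineralization
likewise contribute to leaching only, and erosion-borne soil N and
aboveground residues to runoff only. Both indices are exactly linear in
every source term, which the test suite asserts as an invariant.

The runoff equation also circulates in a variant that prefixes its dung,
fertilizer and aboveground-residue terms with the *leaching* fraction. We
treat that as a transcription slip — the source-by-pathway structure of
the tool implies the runoff fraction throughout — but
`runoff_index(..., literal_eq2 = TRUE)` reproduces the variant (the
erosion term keeps the runoff fraction in both modes) so the two readings
can be compared.

Scores are unitless. They rank blocks, months and managements; they are
not estimates of kg N ha⁻¹ lost, and no rescaling is applied that would
invite that reading.

## Surrogate transport model

Operationally, national transport-risk layers for this kind of index are
produced by a process-based farm-systems simulator run over tens of
thousands of locations. This package instead ships a deliberately simple
daily water-balance surrogate so that every downstream stage is computable
and testable anywhere. The protocol it implements is unchanged:

* a conservative tracer of 450 kg N ha⁻¹ applied on the 15th of the month,
  for every simulated year in which the full horizon fits the record;
* leaching fraction = tracer mass drained past 1000 mm depth within
  730 days, divided by 450; averaged (arithmetically) across years;
* runoff fraction = runoff summed over the 30 days after application,
  divided by the 200 mm benchmark and capped at 1; averaged across years.

The cap at 1 is a deliberate choice: the 200 mm normalizer is a high
percentile of simulated runoff, so uncapped values above 1 are possible in
principle, but a bounded [0, 1] scale keeps the index interpretable.

### Daily structure

Each soil layer carries storages at saturation, field capacity and wilting
point (thickness × volumetric contents) and a drainage coefficient
`k_drain` (day⁻¹). Per day:

1. **Runoff partition.** `runoff = rain × min(1, curve × slope_mult) ×
   wetness`, with `wetness` the antecedent relative saturation of the top
   layer. The curve parameter is a soil property in (0, 1]; the slope
   multipliers default to 1.0 / 1.2 / 1.5 / 2.0 for flat / rolling / easy /
   steep. Slope classes are part of the protocol, but no functional form
   for how slope enters the transport calculation is prescribed; a
   configurable multiplier on the runoff partition is the simplest
   mechanism that preserves the slope contrast.
2. **Infiltration and cascade.** The remaining rain enters the top layer;
   each layer drains `k_drain × (storage − field capacity)` to the layer
   below; the bottom layer's outflow is deep drainage. Saturation excess
   *backs up* the profile and leaves as additional surface runoff — water
   never bypasses a layer that cannot transmit it, so an impermeable layer
   (`k_drain = 0`) gives exactly zero leaching.
3. **Evapotranspiration.** Potential evapotranspiration is satisfied
   top-down from water held above wilting point.
4. **Irrigation** (irrigated blocks, October–April): at the end of any day
   on which plant-available storage falls below 50 % of capacity, the
   profile is refilled to field capacity.

Daily water conservation — rain + irrigation = runoff + deep drainage +
ET + storage change — holds to machine precision and is asserted at
10⁻⁶ mm on every simulation in the tests.

### Tracer transport

The tracer moves by complete mixing: the fraction of a layer's tracer
leaving each day equals the fraction of its (post-inflow) storage leaving
downward. Complete mixing conserves mass exactly and guarantees leached ≤
applied, but reaches full breakthrough only asymptotically: even a
profile flushed many times over retains a vanishing residue, so the
"complete flushing" limit is tested as > 0.99 rather than exactly 1.
Piston displacement would give exact breakthrough but needs a front-
tracking scheme with no benefit for a relative index. Tracer is not
removed by ET (the solute stays behind), and the accounting plane is the
bottom of the first layer whose depth reaches 1000 mm.

All application months are propagated in a single pass (one tracer column
per application) over one water-balance simulation, which keeps a
12-month × multi-year risk table at a fraction of a second per location.

## Source accounting

All sources resolve to kg N ha⁻¹ month⁻¹ at block scale.

* **Excreta**: per-head monthly urine-N and dung-N rates by stock class,
  age and region, times head counts, divided by block area. Dairy-shed
  effluent follows the milking-cow count at a configurable per-head yield.
  The rate table shipped in `inst/extdata/` is illustrative and synthetic;
  operational use should substitute an authoritative inventory through the
  same CSV schema.
* **Fertilizer**: mass applied × product N fraction, bucketed by month.
* **Crop residues**: released only when the residue C:N ratio is below 25
  (otherwise the N is treated as microbially immobilized and poses no
  risk), over the three months *after* harvest, split equally — the
  three-month window is stated in the protocol, the within-window split is
  ours. Belowground release is multiplied by 1.4 for shallow-rooting and
  0.7 for deep-rooting crops; we added an intermediate class at 1.0.
* **Cultivation of pasture**: a two-pool first-order stand-in (the
  original method's equations are not public): short (< 3 yr) pastures
  release a 150 kg N ha⁻¹ pool and long-term pastures 300 kg N ha⁻¹ over a
  6-month horizon, with fallow months extending the horizon. The release
  rate is set so 99.5 % of the pool is released within the horizon, so the
  configured pool is conserved to well within 1 %. All constants are
  arguments.
* **Erosion**: estimated sediment yield = cover factor × land-use
  multiplier (t ha⁻¹), calibrated by the linear correction
  `max(0, 0.92 × estimated − 15.7)`; the floor is needed because the
  printed line goes negative below ≈ 17 t ha⁻¹. Eroded soil carries the
  soil's total N fraction; seasonal N is split equally over the season's
  three months. The multiplier table shipped is an illustrative placeholder
  spanning the calibrated 70–800 range.

## Mitigation

Two mechanisms, mirroring how actions actually work:

* **Source deltas** scale a source category by `1 + δ` (δ ≥ −1, floored at
  zero) for the months and land uses they apply to; risk is then
  recomputed, so multiple deltas compose multiplicatively.
* **Modifiers** (wetlands, denitrification beds, …) multiply a pathway
  score by `1 − e`. They are filtered by land use and pathway, their base
  effectiveness is adjusted by climate/slope/soil class factor tables
  (default 1; the adjusted value must stay in [0, 1]), and they apply in
  series from most to least effective — ties broken by name so the audit
  trail is deterministic. The final score is `baseline × Π(1 − eᵢ)` and is
  therefore order-invariant; the prescribed ordering shapes only the audit
  trail, whose absolute reductions diminish step by step. Modifiers are
  assumed independent (no synergy or antagonism) and optimally placed; the
  modifier library ships empty — effectiveness values are user-supplied
  configuration, not hard-coded.

## Validation machinery

Observed N losses across land uses are right-skewed and clustered, so the
tool's validation is rank-based: risks and observations are converted to
ranks (1 = greatest; ties get average ranks) and observation rank is
regressed on risk rank by OLS, with pointwise t-based 95 % confidence and
prediction bands and a count of points outside the prediction band. The
interval construction is the standard linear-model one; nothing in the
protocol prescribed a specific construction, and the t-based band is the
conventional choice.

`sensitivity_analysis()` rescales one source at a time (default 50 % and
150 %) and reports the ratio of perturbed to baseline totals per pathway;
by linearity a source that is absent gives a ratio of exactly 1, and the
sole source scaled by 1.5 gives exactly 1.5.

`scale_factor()` diagnoses land uses the index systematically under-scores
(shallow-rooted vegetable rotations are the motivating case): it compares
raw-scale OLS slopes of loss on risk between a focal cohort and a
reference. The loss-on-risk orientation keeps observation noise in the
dependent variable, so a cohort whose index runs k times too low yields an
estimate near k without noise-induced attenuation; ranks cannot carry this
information because they are invariant to rescaling, which is why the rank
fit also stores the raw slope. Uncertainty is a seeded percentile bootstrap
(default 1000 resamples) over focal pairs with the reference slope held
fixed.

## Synthetic data: what it does and does not emulate

The generator exists so that every stage runs without external data. Daily
weather is a two-state (wet/dry) Markov chain with gamma wet-day depths,
winter-peaked wet-day probability and summer-peaked sinusoidal PET
(southern hemisphere), calibrated so the expected annual total matches the
configured rainfall. Three soil archetypes span the agronomic contrast that
drives the index: stony-shallow (low storage, fast drainage — leaches),
deep-fine (high storage, slow drainage — retains), intermediate. Farm
calendars cover all source categories across land uses, and observation
sets are generated as `loss = (a + b × risk) × lognormal noise`, with
vegetable blocks responding to `risk × attenuation` (default 6) to
exercise the scale-factor recovery. Multiplicative lognormal noise mirrors
the right-skew of real loss observations.

What the generator does **not** emulate: real geography and soils, spatial
correlation of weather, lag times between risk and measured loss,
freeze–thaw, preferential flow, within-block heterogeneity, and the
measurement structure of a real observation database (mixed methods,
uneven land-use coverage, sub-annual records). Passing tests therefore
demonstrate that the machinery computes its contracts correctly under
known structure — not that the index is accurate for any real farm.

## Numerical choices and degenerate inputs

* Water balance asserted to 10⁻⁶ mm day⁻¹; computed in double precision
  with explicit per-day closure reported.
* A point counts as outside the prediction band only when beyond it by
  more than `1e-8 ×` the rank range: an exact monotone fit has ~10⁻¹⁴
  residuals and a zero-width band, and without the guard every point would
  sit "outside" by floating-point noise.
* Zero variance in either rank vector → degenerate fit, `r² = 0`, flagged;
  fewer than 3 pairs → error.
* Sensitivity ratios with a zero baseline are `NA` with an `undefined`
  flag rather than silently 0 or 1.
* Modifier effectiveness ties break lexicographically by name; adjusted
  effectiveness outside [0, 1] is an error, not clamped.
* Slope classification is closed on the left class (7.0° is flat, 7.1°
  rolling).
* Month arithmetic wraps the calendar (a November harvest releases residue
  in December–February).

## Problem sizes in the shipped tests

The suite exercises the transport surrogate on 200 randomized
soil × climate fixtures of 3 years' daily weather (applications in year 1
so the 2-year horizon fits), 1000 random source vectors for the linearity
invariant, 500 replicate fits for the prediction-band miss rate, and
96-observation synthetic sets (matching the scale of a filtered national
observation database) for rank-recovery — sizes chosen to make the full
suite run in well under a minute of compute per module while leaving the
statistical assertions sharp.

## Known limitations

* The surrogate water balance has no crop growth, N cycling,
  macropore/preferential flow, snow or frozen-soil physics; its transport
  fractions are plausible contrasts, not calibrated predictions.
* Runoff generation is a one-parameter partition; intense-storm dynamics
  within a day are not represented.
* The cultivation-mineralization stand-in and all shipped rate tables are
  illustrative defaults.
* Rank validation establishes ordering skill only; the index must not be
  fed into mass-balance models as a loss estimate.
* GeoJSON output uses synthetic grid placement when blocks carry no
  geometry; no raster output is produced.
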