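---
title: "Projecting CO2 emissions from mangrove loss: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting CO2 emissions from mangrove loss: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveflux)
```

## The accounting problem

Most global estimates of emissions from mangrove conversion book the whole
carbon stock as emitted in the year of loss, count only the first metre of
soil, and ignore the sequestration the lost area would have performed had
it remained intact. All three simplifications bias decade-scale
projections. `mangroveflux` models the realistic alternative: deforestation
proceeds at a constant proportional rate, each deforested cohort releases
its labile carbon over years to decades, the stock at risk depends on which
land use replaced the forest, and the counterfactual sequestration stream
is accounted separately. The spatial accounting unit is the marine province
(the top level of the coastal bioregionalisation), which aligns with the
climatic and geomorphic gradients that drive both carbon density and loss.

## Model structure and assumptions

Three coupled components, all with closed forms:

**Area.** `dA/dt = -A d` gives `A(t) = A1 exp(-d t)`. The deforestation
rate `d` is constant (business as usual): historical rates persist to the
horizon. This is the assumption most responsible for projection error in
regions where loss is slowing.

**Cohort emissions.** The cohort deforested in year `y` (flux
`A1 d e^{-dy}` ha/yr) carries an effective labile stock per hectare

\[ c = c_{\max} \sum_{i=1}^{5} f_i\, p_i, \]

where `c_max` is the total ecosystem carbon stock (TECS: soil organic
carbon to the chosen depth plus aboveground carbon), `p_i` the historical
share of loss from driver `i`, and `f_i` that driver's emission factor.
Future loss by driver is assumed proportional to the historical mix. The
cohort then emits exponentially at rate `r`, so

\[ E(T) = \int_0^T A_1 d\, e^{-dy}\, c\, (1 - e^{-r(T-y)})\, dy
       = A_1 c \left[ 1 - e^{-dT} - \frac{d\,(e^{-dT} - e^{-rT})}{r - d} \right]. \]

Two structural facts follow and are enforced by tests: `0 <= E(T) <= A1 c`
with `E -> A1 c` as `T -> infinity` (conservation: everything eventually
deforested emits its labile stock, no more), and `E` is linear in `A1` and
in `c`, which is what makes the per-driver decomposition through the
addends `c_i = c_max f_i p_i` exact rather than approximate.

**Foregone sequestration.** Intact area sequesters soil carbon at
`s` Mg C ha^-1 yr^-1; the counterfactual (no-loss) minus actual difference
is `S(T) = s A1 T - s A1 (1 - e^{-dT})/d`, zero when `d = 0`. Sequestration
is accrued on gross lost area; partial compensation of erosion losses by
accretion elsewhere is not netted out.

Out of model scope: CH4 and N2O, tidal/lateral export partitioning,
area gains from landward or poleward migration, and temporal change in the
driver mix.

## Parameters, units, defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `horizon_years` | projection horizon T (yr) | 90 | 2010 baseline extent projected to 2100 |
| `emission_release_rate` | r (yr^-1), per driver | `log(2)/10` | emissions are decadal, not annual: a 10-yr half-life encodes that; no published per-driver values exist, so one global default, overridable per driver |
| `co2_per_c` | CO2:C mass ratio | 44/12 | stoichiometry |
| `soc_depth` | SOC integration depth | `"2m"` | 2-m stocks validated better against field measurements; 1 m kept for the sensitivity grid |
| `seq_rate_mgc_ha_yr` | s | 1.5 | global mean soil sequestration rate for mangroves |
| `erosion_ef_multiplier` | scaling of the erosion emission factor | 1.0 | 0.5 encodes the low-erosion scenario (erosion emissions partly offset by accretion) |
| `include_climatic_driver` | count losses from extreme climatic events | `TRUE` | the exclusion scenario zeroes that share *without* renormalising the others: the loss is removed, not reassigned |

Emission factors are fractions in [0, 1] with a confidence level 1–3
(global average < similar region < similar region and geomorphic setting).
Confidence is carried as metadata only; no uncertainty propagation is done
over it.

## Numerical choices

- The closed form, not the time grid, is authoritative: trajectories
  (`project_trajectory()`, default 91 annual points) evaluate the closed
  forms at each grid time, so the final point equals the horizon value
  exactly.
- `r = d` is a removable singularity; the code switches to the analytic
  limit `1 - e^{-dT} - dT e^{-dT}` when `|r - d| < 1e-9 max(r, d)`. Tests
  stress the ridge at relative offsets from 0 to 1e-4 against adaptive
  quadrature at 1e-8 relative tolerance.
- Small-`d` terms use `expm1` to avoid cancellation; `d = 0` short-circuits
  to zero emissions and zero foregone sequestration.
- Derivatives of the projected total: parameters in which the model is
  linear (`A1`, `c_max`, `f_i`, `s`) get exact analytic derivatives
  (`L_component / theta`); `d` and `r` use a central finite difference with
  a *relative* step of 1e-4, because parameter scales span four orders of
  magnitude. The finite differences are verified against a hand-derived
  symbolic derivative of the closed form to 1e-6 relative.
- The derivative of the total with respect to `r` peaks on the
  deforestation timescale `1/d` and then decays to zero — the release rate
  only matters in the short term. The test asserts exactly that shape, not
  global monotonicity.
- Ranking ties are broken by province identifier; driver shares are
  reported to integer percent and emissions to 0.1 Tg, and rounding happens
  only at the reporting layer.
- Share-simplex tolerance is 1e-9; a province with `d = 0` may carry an
  all-zero share vector and stays listed in rankings with a zero total.

## The synthetic province generator

`generate_provinces()` emulates the province-level statistical structure of
the global input datasets so the full pipeline is testable without any
download:

- **Areas**: log-normal (sdlog 2.1), rescaled so the largest province is
  1.8 Mha; at n = 37 the ten largest provinces hold roughly 88% of the
  area, matching the observed concentration.
- **Deforestation rates**: truncated normal on [0, 0.0055] yr^-1 with the
  *truncated* mean calibrated to 0.0009 (0.09 %/yr) by solving for the
  location parameter; a province has no loss with probability 2/37.
- **Stocks**: truncated normals inside the observed ranges with truncated
  means calibrated to 646.7 (SOC 2 m) and 101.2 (ABC) Mg C ha^-1; SOC to
  1 m is a uniform 0.42–0.60 fraction of the 2-m stock, keeping the
  2 m >= 1 m invariant by construction and the 1-m mean near 331 Mg C ha^-1.
- **Driver shares**: Dirichlet with expectation proportional to the global
  per-driver loss totals (219,392 / 92,787 / 39,595 / 41,525 / 10,529 ha)
  and total concentration 1.2 — deliberately overdispersed so that
  single-driver-dominant provinces, which the real data contain, occur.
- **Emission factors**: per-driver uniform ranges (commodities 0.55–0.85,
  erosion 0.35–0.80, clearing 0.25–0.60, climatic 0.10–0.45, settlement
  0.65–0.95), chosen as plausible spans around typical land-use conversion
  factors; confidence levels sampled 1–3.

The seed fully determines the output and the caller's RNG state is
restored. What the generator does *not* emulate: spatial autocorrelation
between neighbouring provinces, correlation between area and carbon
density, and the long right tail of field TECS (above the modelled-stock
range). Passing tests on synthetic worlds therefore demonstrate the
*mechanics* of the pipeline — validation, closed forms, attribution,
ranking, sensitivity — not the realism of any particular global total.

The six-province fixture (`fixture_table1()`) is the converse: its
per-driver effective-carbon addends are reverse-engineered through the
closed form so that the decomposition reproduces the published per-driver
cumulative emissions exactly at the default configuration. Published
areas and rates are used where they exist; the Andaman and North Brazil
Shelf rates are synthetic stand-ins (0.1 and 0.2 %/yr) and are labelled as
such in the fixture documentation.

## Design choices where the design was open

- **Regression direction** for the stock validation: field stocks are the
  response, modelled stocks the predictor — the fit answers how well the
  model predicts the truth.
- **Single global `r` vs per-driver rates**: both are supported; the
  default is one global value because no per-driver estimates are
  available to justify differentiation.
- **Foregone sequestration on gross lost area**: erosion-accretion netting
  is a spatial process the province-level model cannot resolve; the
  erosion emission-factor multiplier is the coarse knob for it.
- **Scenario grid as column variants**: alternative area/rate datasets
  enter as extra columns of the province table that scenarios reference by
  name, which keeps every scenario resolvable (and failures nameable)
  without a registry of datasets.
- **Problem sizes in tests**: property tests use 25–40 randomized
  parameter draws, synthetic recovery uses n = 1000 provinces, and
  projection oracles use n = 37 — the sizes at which the checked
  statistics stabilise.

## Known limitations

Constant `d` and a frozen driver mix are the dominant structural
approximations; both bias projections upward where loss is slowing. The
model is province-aggregate: within-province covariance of carbon density
and loss rate is invisible, so a province whose loss concentrates in its
carbon-richest stands will be underestimated. Emission-factor confidence
is metadata, not a prior — no credible intervals are produced. And the
headline global totals depend on the full 37-province input table;
the packaged fixture covers only the six hotspot provinces, so
package-internal global sums are fixture- or synthetic-scale, with the
published global total usable as an external denominator for
concentration shares.
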