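---
title: "Methods: the island carbon-cycle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the island carbon-cycle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandcarbon)
```

## The model and its assumptions

`islandcarbon` simulates the annual carbon cycle of a small inhabited
island — modelled on Gouqi Island in the East China Sea — as a
stock-and-flow system: seven carbon stocks (tC) advanced by an explicit
fixed-step update `S(t) = S(t − dt) + (inflows − outflows)·dt`, with 24
named process fluxes (tC yr⁻¹) computed from the current stocks, a set of
rate and emission coefficients, and externally prescribed forcings
(annual mean temperature and radiation, visitor and resident counts,
land and inshore areas). The year is the natural unit: both the tourist
season and the ecosystems cycle annually, and all coefficients are
annual means. There is no sub-annual seasonality, no spatial structure,
and no CO₂-equivalent weighting — methane is tracked as carbon mass
only.

Human-activity emissions are bilinear in activity volume and a per-unit
coefficient. Visitor volume enters through the stay-day distribution
`sd₁..sd₅` (fractions staying 1–5 days, summing to 1): a visitor staying
*k* days contributes *k* activity-days and *k − 1* lodging nights.
Ecosystem processes are stock-proportional, with photosynthesis scaled
by the saturating light factor `rade/(rade + 6)·690` and the temperature
factor `1.05^(20−temp)`, and respiration-like processes (respiration,
litter decomposition, soil uptake, wetland CH₄ release) by the linear
factor `(20 − temp)`. The mussel-shell sink is area-driven:
`area · growth_r · shell_c_r / 0.27`, the carbonate-formation pathway
Ca²⁺ + 2HCO₃⁻ → CaCO₃ + CO₂ + H₂O. The divisor 0.27 is kept as the
named constant `shell_carbon_divisor` without further interpretation
(it is plausibly the carbon mass fraction of shell material, but the
model treats it as a fixed structural constant).

## Units and conversion conventions

The canonical internal unit is tC for stocks and tC yr⁻¹ for fluxes.
Source coefficients are reported in mixed units (g CO₂, g CH₄, g C per
activity unit), so each coefficient declares its unit and is converted
exactly once, at the flux boundary: CO₂ mass × 12/44, CH₄ mass × 12/16,
and ×10⁻⁶ g→t for the gram-denominated activity coefficients.
Stock-proportional ecosystem expressions inherit the tC scale of the
stock they multiply, so only the gas ratio applies there — the only
reading under which the stock equations are dimensionally coherent.

Two deliberate unit decisions:

* **Areas.** The shell-growth rate `growth_r` is per m², so the culture
  area enters in m² (km² × 10⁶). The ecosystem rate equations, by
  contrast, are transcribed exactly as written in the source model, with
  the habitat area entering as its km² numeric value: the per-m² units
  attached to those rates are dimensionally incompatible with
  stock-proportional equations, and transcription fidelity wins.
* **`growth_r` magnitude.** The source prints 1 500 000 at unit
  g C m⁻² yr⁻¹, which is physically impossible (three orders of
  magnitude above productive aquaculture). The fixture stores 1500
  g C m⁻² yr⁻¹, the only reading that puts the shell sink at the
  reported ~4 × 10⁴ tC yr⁻¹ order of magnitude.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `nv` | visitors yr⁻¹ | 1 000 000 | drives all tourism fluxes |
| `sd` | – | 0.1/0.2/0.5/0.1/0.1 | stay-day distribution |
| `ce_ferry` | g CO₂ km⁻¹ | 106 | ferry emission, with `dis_ferry` = 140 km |
| `ce_ssb` | g CO₂ km⁻¹ | 40 | shuttle bus, with `pd_ssd` = 14 km day⁻¹, `ssd_r` = 0.7 |
| `ce_desalination` | g CO₂ t⁻¹ | 2784 | with `per_wc` = 1.2 t person⁻¹ day⁻¹ |
| `growth_r` | g C m⁻² yr⁻¹ | 1500 | shell sink, with `shell_c_r` = 0.95 |
| `temp` | °C | 8 | both temperature responses |
| `rade` | MJ m⁻² yr⁻¹ | 1.2 | light limitation of photosynthesis |
| `ch4_use_r` | – | 1 | landfill CH₄ released (none captured) |

The visitor count deserves a note: the source parameterisation sets
1 000 000 visitors while its own situation table reports 210 400
tourists. The fixture keeps 1 000 000 as the default because it is the
value that reproduces the reported small-shuttle-bus budget row (310
tC yr⁻¹) exactly; any other count is one `island_forcings()` call away.

## The fixtures: what they emulate, and what they do not

`config_as_printed()` is the source parameterisation verbatim (with the
two unit decisions above). Its initial stocks are all zero — also as
published — which makes every stock-proportional ecosystem flux
identically zero. That degeneracy is preserved and tested, not patched:
it is how the published equations behave.

`config_calibrated()` is the package's reconstruction of the island's
reported 2014 budget. Several published coefficients are inconsistent
with the published results (the water-activity coefficient produces
~10× its reported row; desalination computes to ≈5968 vs the reported
6870; the ferry row implies a far larger per-km coefficient than
printed). Rather than guess intent, calibration applies the minimal,
fully documented override set: eleven per-flux multipliers, each
computed at build time as reported-row / as-printed-value, plus positive
initial stocks for forest, wetland and soil solved in closed form from
the net per-unit-stock rates. The small-shuttle-bus and shopping rows
need no override, and the tourist-car flux is left unscaled (scaling
resident cars alone closes the shared private-car row) — a leave-one-out
test verifies that dropping any single override breaks at least one
row. The calibrated run uses a single annual step (`dt = 1` yr): the
reported budget is a one-year account at the island's 2014 operating
point, so fluxes are evaluated at those stocks rather than allowed to
compound sub-annually at the model's very fast ecosystem turnover rates.
The initial-stock values are therefore a documented convention — the
stocks at which the net rates reproduce the reported rows — not a claim
about the island's actual standing carbon.

`config_random(seed)` draws every rate, coefficient and forcing
uniformly within ±50 % of the published value (fractions clipped to
\[0, 1\], stay fractions renormalised) with positive stocks at the
calibrated order of magnitude, reproducibly from the seed and without
touching the global RNG. It emulates parametric spread around the 2014
operating point, not structural uncertainty: passing property tests on
these draws demonstrates arithmetic fidelity and invariants
(non-negativity, linearity, conservation), **not** that the model is
well calibrated for any real island other than through
`config_calibrated()`'s regression.

## Numerical choices

* **Explicit Euler, fixed step.** The source model is a difference
  equation system; fidelity to its semantics outranks solver elegance.
  Default `dt = 1/12` yr over a 1-yr horizon for exploratory runs; the
  calibrated fixture uses `dt = 1`. The step-refinement test works in a
  deliberately damped growth regime because the published ecosystem
  rates (net per-stock rates of 3–20 yr⁻¹) put a monthly step far
  outside the asymptotic first-order range.
* **Temperature above the 20 °C reference.** The linear `(20 − temp)`
  factor would go negative; it is clamped to 0 with a warning by
  default, and `temp_mode = "strict"` raises instead. The published
  model is only exercised at 8 °C.
* **Negative stocks.** The source never specifies overdraft behaviour;
  the integrator floors at zero with a warning naming the stock, or
  errors under `on_overdraft = "error"`.
* **Rounding.** Reported precision is emulated with half-up rounding:
  budget rows to the nearest 10 tC yr⁻¹, shares to 0.1 %. Base R's
  round-half-even would not reproduce the reported tables.
* **Conservation.** By construction, the change in total stock over any
  run equals the time-integral of external inflows (all
  emission-tagged fluxes) minus external removals (wetland litter
  exported to the sea), verified to 1e-9 relative tolerance.

## Budget accounting decisions

The budget classifies soil uptake (`adsorption`) as an **emission** row
named `soil_respiration`, because that is how the island's reported
table presents it, even though the flux mechanistically removes CO₂;
the classification is a mapping argument
(`default_mapping(soil_respiration_as = "sink")`) so either reading is
one switch away. Forest and wetland rows are net
(photosynthesis − respiration − decomposition/litter/CH₄), with the
netting membership visible in the mapping table. `decomposition` is an
internal forest→soil transfer, exactly as the source equations route
it, and does not touch the atmospheric pool. The landfill CH₄ chain
(waste → pool → release) carries the solid-waste row at the generation
flux; the release flux is internal routing.

The reported emission rows sum to 33 950 tC yr⁻¹ while the reported
headline total is 36 780; the ≈2830 tC gap is unexplained in the source
and the package surfaces it: the model's own totals are the default,
and `budget_shares(headline_mode = TRUE)` substitutes the reported
totals as denominators, which is the only way the published percentages
(81.2 % shell sink, 18.7 % desalination, the 40.4 % combined
electrification reduction) are reproducible. Two published shares
(50.3 % "of the carbon exchange", 17.1 % soil respiration) are not
reproducible from any combination of the published values and are not
targeted. Likewise scenario savings are reported both model-computed
(difference of budget runs) and in published-headline form
(`reported_scenario_savings()`), because the published ferry saving
(12 960 tC yr⁻¹) does not equal the ferry budget row (11 070). The
published claim that 3× macroalgae farming improves the credit by 70 %
is not reproducible from any printed arithmetic (the added sink,
75 375 tC yr⁻¹, is far larger) and is not targeted either.

## Problem sizes

The test suite exercises: 100 seeded random parameterisations for the
flux–oracle equivalence, 25 more in unit tests; 1-yr runs at monthly
steps (12 flux evaluations) for conservation and determinism; and
single-step annual runs for all budget regressions. Everything completes
in well under a minute on one core.

## Known limitations

* Single representative year: no demographic or tourism growth
  dynamics, no inter-annual carry-over beyond the stocks themselves.
* Inbound/outbound tourist transportation beyond the ferry is excluded
  (as in the source analysis), so tourism footprints are lower bounds.
* The imported-food and residential-electricity arrows of the
  conceptual model carry no published coefficient; they exist as
  zero-default pass-through emission terms (`food_import`,
  `residential_electricity`) so the flux topology is complete without
  invented numbers.
* The calibrated fixture reproduces the reported budget by construction;
  it is a regression anchor, not independent validation.
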