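---
title: "Carbon accounting and bioenergetics of CO2-to-VFA-to-PHB gas fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon accounting and bioenergetics of CO2-to-VFA-to-PHB gas fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasferm)
library(dplyr)
```

gasferm quantifies a two-phase mixed-culture bioprocess: anaerobic
homoacetogenic enrichment that fixes CO2/bicarbonate into volatile fatty
acids (VFA), and an aerobic stage that converts those acids (or CO2
directly) into polyhydroxybutyrate (PHB). This vignette explains the models
behind each module, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Elemental stoichiometry

All carbon accounting reduces to element mass fractions of molecular
formulas. `parse_formula()` accepts fractional subscripts because measured
biomass elemental compositions are non-integer: the aerobic PHB-stage
biomass is modelled as C4.09 H7.13 O1.89 N0.76, the anaerobic VFA-stage
biomass as C60H87N12O23P, and the PHB monomer as C4H6O2. Parentheses,
hydrates and isotopes are rejected outright — no species in this process
needs them, and refusing them is safer than guessing.

Atomic masses are IUPAC conventional weights to at least three decimals
(C 12.011, H 1.008, O 15.999, N 14.007, Na 22.990, P 30.974), overridable
from a YAML file. With these weights carbon is 14.30% of sodium bicarbonate,
40.00% of acetic acid and 54.53% of butyric acid; reported values that were
rounded (54%) are compared at 1% relative tolerance in the tests, exact to
the printed digit otherwise. Charged species (the acetate anion C2H3O2⁻)
have their mass computed from element counts alone — the electron mass is
ignored and the charge is kept only for reaction balance diagnostics.

## Gas dosing

CO2 dosing uses the ideal-gas density `d = P·Mw/(R·T)` with
R = 0.082057 L·atm·mol⁻¹·K⁻¹: 3.60 g/L at 2 atm and 298 K (reported as 3.58,
a rounding difference absorbed by the 1% tolerance). Two sparged-volume
conventions are provided because the source arithmetic (40 ml/min over 2 min
→ 20 ml) divides flow by duration where `volume = flow × duration` would
give 80 ml. `mode = "as_printed"` (the default) reproduces the reported
numbers and emits a once-per-session note about the dimensional
inconsistency; `mode = "physical"` is the consistent alternative. Dissolved
CO2 input is sparged volume × density × a flat dissolution fraction
(default 0.75). No Henry's-law speciation or kLa kinetics is attempted —
the flat fraction is the model.

## Thermodynamic feasibility

`reaction_delta_g()` computes `ΔG° = Σ coef·ΔGf°` over signed stoichiometric
coefficients, from a standard-state formation-energy table (acetate −370.3,
CO2 −394, H2 0, 3-HB −361.84, H2O −237.13 kJ/mol; the table value −394 is
used verbatim rather than the more common −394.4). Values are standard-state
at 298 K; no pH-7 transformation, concentration corrections or
ionic-strength terms are applied, matching the standard-condition
computation being reproduced. "3-HB" is treated as an opaque species with
its tabulated energy; for atom counting it is assigned the anion composition
C4H7O3⁻.

Two acetogenesis bookkeepings ship side by side. The as-printed form
(acetate − [CO2 + 4 H2]) yields +23.7 kJ/mol but is carbon- and
hydrogen-imbalanced; `check_element_balance()` reports C +1, H −5 and
charge −1, and `thermo_report()` carries those diagnostics next to the
energy so the imbalance is never propagated silently. The balanced overall
reaction is written `2 CO2 + 4 H2 → CH3COO⁻ + H⁺ + 2 H2O`: the proton is
included explicitly (ΔGf°(H⁺) = 0 under the standard convention, so the
energy, −56.56 kJ/mol, is unaffected) because omitting it would leave one
hydrogen and one charge unaccounted and the balance diagnostic would then
flag the package's own "balanced" reaction. The acetate-to-PHB condensation
(2 acetate → 3-HB + H2O, +141.63 kJ/mol) is likewise reported with its
residual hydrogen/charge imbalance — the reported reaction does no proton
bookkeeping, and the diagnostics say so rather than pretending otherwise.

## The carbon ledger

`carbon_balance()` sums elemental carbon over input and output streams. Each
stream is either a compound concentration with a formula or a direct gC/L
value — exactly one, enforced at construction. The unassigned remainder
`total_in − total_out_known` is the residual "metabolites" term: the
process's miscellaneous-input and metabolite-output catch-alls are modelled
as this single signed residual because neither is defined operationally.
When the residual is the balancing term, closure is 1 by construction and
conservation holds to machine precision; when an explicit metabolites stream
is supplied, closure becomes measured output over input. A negative residual
(outputs exceeding inputs) is reported with an over-closure flag, never
clipped.

The VFA pool is split acetic:butyric at a default 1.5:1 ratio, interpreted
as a **mass** ratio (the measurement basis is not stated; the choice is
configurable and recorded in the output tibble). Yield metrics are plain
ratios with guard rails: `fermentable_yield()` requires positive VSS, and
`percent_phb()` rejects PHB exceeding dry cell weight. For the
bicarbonate-fed reactor the DCW of 4.21 g/L is used (two values appear in
the source tables; 0.236/4.21 reproduces the printed 5.6% content, so that
one is canonical).

## From-scratch ANOVA

`one_way_anova()` and `two_way_anova()` implement the classical
sums-of-squares decompositions directly (between/within; main effects,
interaction and residual for the balanced two-factor layout), with F
statistics and upper-tail F p-values via `stats::pf()`. They are
cross-checked against `stats::aov()` in the test suite but never delegate to
it. Degenerate layouts are reported rather than errored: zero residual
variance with non-zero effect variance yields `F = Inf` with a flag, and
constant data yield `F = 0`. Unbalanced two-way layouts are refused — the
orthogonal decomposition does not apply — with a pointer to a one-way
analysis of cell means.

The campaign's exact published F statistics are deliberately not test
targets: the underlying replicates are unpublished, so only the design
structure (factor levels, degrees of freedom) and simulation-based
properties are asserted — type-I error calibrated to 0.05 over 2000 seeded
null replicates, and near-certain detection of effects the size of the
published group differences.

## The synthetic campaign generator

`generate_enrichment()` emulates the five-generation enrichment schedule —
glucose:bicarbonate 6:0, 4:2, 2:4, 0:6 g/L, then a gas-fed generation with
6 g/L bicarbonate — for cultures AC, CF, RF and their blend, three 72-h
cycles per generation, sampled every 12 h. Cycle end-points are drawn around
the campaign's reported group means: per-generation bicarbonate reduction
(e.g. 45.68/50.92/53.8% for AC/CF/RF in G1, 49.6/53.5/55.4% in G3), gas-phase
CO2 consumption for enriched cultures (54.8/63.2/82.1%), end-point VFA
titers (2.017/3.243/2.307/3.467 g/L for AC/CF/RF/Blend), and cycle-end pH
per generation starting from pH 7.0.

Where the campaign reports nothing, a default is chosen once and flagged
`assumed` in the dataset metadata: replicate standard deviations (5%
relative), blend-culture means (parent-culture average; the blend was only
formed after the third generation), the gas-fed generation's bicarbonate and
pH means (carried over from G3), and end-point DCW/PHB (4.45 and 0.182 g/L,
i.e. 4.1% content). Out-of-range draws (negative concentrations, percentages
outside [0, 100], pH outside [0, 14]) are rejected and resampled rather than
clipped, preserving the distribution shape near the bounds; the rejection
count is logged in the ground truth.

Within-cycle shapes are a modelling invention — the campaign reports only
end-points. Bicarbonate decays exponentially toward its drawn end-point
(`linear` is selectable), pH interpolates linearly, OD600 and VFA follow a
scaled logistic, and PHB accumulates late (squared logistic), reflecting
storage-polymer induction after growth. Because noise enters only through
the end-points and the interpolants are monotone, the physical invariants —
bicarbonate non-increasing, OD600 non-decreasing within a cycle — hold by
construction. This is exactly what the generator does **not** test about
real data: measurement noise within a trajectory, non-monotone excursions,
lag phases and culture crashes are all absent, so passing recovery tests
demonstrates the analysis pipeline's correctness, not robustness to messy
instrumentation.

Randomness is Mersenne-Twister, seeded per call with the global RNG state
restored afterwards; the RNG name and seed are recorded in the CSV/JSON
sidecar written by `write_enrichment_csv()`. `generate_ledger_scenario()`
builds exactly conservative ledger fixtures (outputs partition input carbon
minus a planted metabolite residual), and `generate_anova_dataset()`
produces seeded normal draws per cell with ground truth attached.

## Problem sizes and numerical choices

The simulation-based checks use deliberately modest sizes — 2000 null
replicates for type-I calibration, 500 for power, three cycles per
generation as in the campaign — chosen as the smallest sizes at which the
Monte-Carlo standard error is well inside the asserted bands (for 2000 null
replicates, se ≈ 0.005 against an acceptance band of ±0.015). Equilibrium
classification of ΔG° uses a 1e-9 kJ/mol band around zero. Element-balance
sums below 1e-12 atoms are snapped to zero to absorb floating-point dust
from fractional biomass formulas. The ledger carries gC/L internally; mg/L
is accepted at the YAML boundary via `*_mgc_per_l` / `*_mg_per_l` keys.

## Known limitations

The thermodynamics is standard-state only — no ΔG°′ at pH 7, no reaction
quotients, no ATP coupling — so it answers "is the overall chemistry
feasible as tabulated", not "what is the in-situ driving force". The gas
model has no equilibrium speciation. COD is an input, never computed from
formulas. The ANOVA module offers no post-hoc tests or mixed models. And the
generator's ground-truth realism is bounded by the campaign's reporting:
every unreported dispersion parameter is an assumption, clearly labelled as
such in the output.
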