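---
title: "Methods: projecting Trichodesmium N2 fixation under acidification and P limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting Trichodesmium N2 fixation under acidification and P limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichoproj)
```

## The problem

*Trichodesmium* is a filamentous diazotrophic cyanobacterium that supplies a
substantial fraction of the new nitrogen entering oligotrophic surface
oceans. Two pressures act on it in a high-CO₂ future: seawater pH falls
(rising [H⁺] depresses its N₂ fixation), and phosphorus, which already
limits its growth over large oceanic regions, is expected to become scarcer.
Chemostat experiments with P-limited cultures show these stresses interact:
under acidification, cells accumulate polyphosphate (raising their P quota),
and both C biomass per unit P and the C-biomass-specific N₂ fixation rate
fall. This package implements the resulting offline projection: grid-cell
scalings of a *Trichodesmium* N₂ fixation climatology by linear functions of
[H⁺], with a stronger combined penalty where P is the limiting nutrient,
plus the laboratory arithmetic that produces the scaling constants.

## The projection model

Let NF be total N₂ fixation in a grid cell (g N m⁻² yr⁻¹) and R_Tr the
fraction contributed by *Trichodesmium*; NF·R_Tr is the reference
climatology. With anchors [H⁺]₀ = 10^−8.01 and [H⁺]₁ = 10^−7.81 mol L⁻¹
(the pH interval spanned by the calibration cultures, total scale) define
x = ([H⁺]ₛ − [H⁺]₀)/([H⁺]₁ − [H⁺]₀). Then per cell

* P-replete: projected = NF·R_Tr·(1 + oa·x), oa = −0.184;
* P-limited: projected = NF·R_Tr·(1 + oap_C·x)(1 + oap_N·x),
  oap_C = −0.392, oap_N = −0.101.

The model's assumptions are explicit and strong: the response is linear in
[H⁺] (not pH), calibrated on one strain over one 0.2-pH-unit interval, and
applied offline — the scaled fixation does not feed back on nutrients,
biomass or circulation. x is interpolated inside the interval and
extrapolated outside it on both sides.

### Numerical choices

* **Clamping.** Extrapolation at extreme [H⁺] can drive a linear bracket
  negative; a fixation rate cannot be negative, so each bracket (and the
  single P-replete factor) is clamped below at 0 before use. On the alkaline
  side factors above 1 are allowed (a cell less acidic than the lower anchor
  is projected to fix slightly more); the projection object carries an
  `any_factor_above_one` flag so such runs are visible.
* **Anchor identity.** At [H⁺]ₛ = [H⁺]₀ every scenario reproduces the
  reference exactly; this is asserted in the test suite for states, masks
  and scenarios.
* **Application order.** Mask → factor → multiply, per cell, with no spatial
  smoothing; the global integral is the plain area-weighted ocean sum
  divided by 10¹² g Tg⁻¹.

## Phosphorus limitation

Because *Trichodesmium* uses both phosphate and dissolved organic phosphorus
(DOP), the limiting factor is the dual-substrate Michaelis–Menten form with
a shared denominator:

$$V^{PO_4} = \frac{PO_4/K^{PO_4}}{1 + PO_4/K^{PO_4} + DOP/K^{DOP}},\qquad
  V^{DOP} = \frac{DOP/K^{DOP}}{1 + PO_4/K^{PO_4} + DOP/K^{DOP}},$$

with V^P their sum, bounded in [0, 1) and saturating at 1. The only
observationally anchored constraint is the preference ratio: K^PO₄ is about
5 times smaller than K^DOP. The default values, `k_po4 = 0.01` and
`k_dop = 0.05` mmol m⁻³, are package choices on the oligotrophic scale of
surface phosphate and are fully overridable; every result that matters at
desk scale (the 5:1 term ratio at equal concentrations, bounds,
monotonicity, scale invariance) is independent of the absolute values.

"P-limited" is not operationally defined by the limiting-factor equations
alone, so two rules are provided. The default (`argmin`) calls a cell
P-limited iff V^P is strictly below every auxiliary (Fe, N) limitation
factor there; ties resolve to *not* P-limited, which is the conservative
choice because the P-limited branch applies the stronger penalty. The
alternative (`threshold`) compares V^P against a fixed cutoff. The rule and
the resulting P-limited ocean fraction are recorded in every run summary.

## Culture calibration

`calibrate_effects()` derives the P-limited constants from a paired
ambient/acidified replicate table: oap_C is the fractional change of the
treatment-mean POC:POP ratio and oap_N that of the treatment-mean
n2_fix_per_cell/POC. Contrasts are computed on treatment means because
that is how culture stoichiometry ratios are conventionally reported; a
per-pair variant (mean of pairwise fractional changes) is exposed as an
option and documented as such. oa cannot be derived from a P-limited table —
it comes from a P-replete experiment — so it is accepted as an external
constant with default −0.184.

Supporting arithmetic follows standard practice: percent changes are
100·(acidified − ambient)/ambient (scale-invariant, sign-preserving); paired
t tests delegate to `stats::t.test(paired = TRUE)` after guarding n ≥ 2 and
non-degenerate variance, with the one-tailed option testing a decline; cell
density divides total filament length per mL by the mean cell length of the
sampled filaments; the DNA P quota counts **2 phosphorus atoms per base
pair** (one per nucleotide per strand — the factor is forced by the
chemistry) over a 7,750,108 bp genome at 100 copies per cell; RNA P uses the
320.5 g mol⁻¹ mean residue mass; acetylene-reduction rates convert at 4:1
ethylene:N₂.

`simulate_culture_table()` is the parameter-recovery instrument: it plants
exact multiplicative treatment effects (defaults: POC ×0.78, PON ×0.82,
POP ×1.28, cell-specific N₂ fixation ×0.70, C fixation ×0.83, i.e. the
reported −22 %, −18 %, +28 %, −30 %, −17 % responses) on n = 3 pairs —
the chemostat design — with optional log-normal replicate noise. With zero
noise the calibration must recover the planted contrasts exactly
(0.78/1.28 − 1 ≈ −39.1 % and 0.70/0.78 − 1 ≈ −10.3 %); with noise it must
concentrate on them as replication grows. Derived parameters are validated
against the model's domain (each fraction in (−1, 0]); a noisy table whose
derived oap_N crosses zero is rejected rather than silently accepted.

## The synthetic ocean generator

The generator emulates, statistically, the gridded fields an Earth-system
biogeochemistry model would supply; it is the package's study-condition
definition, not a tuning surface. Defaults, chosen once:

| quantity | default | basis |
|---|---|---|
| grid | 2° × 2.5°, all-ocean mask | minimal-assumption frame; mask injectable |
| global NF integral | 155 (1981–2000), 130 (2081–2100) Tg N yr⁻¹ | simulated historic total and its projected 25 Tg decline |
| mean R_Tr | 60/155, 47.4/130 | global *Trichodesmium* integrals per era |
| era pH mean | 8.05 / 7.80 | brackets the calibration interval [8.01, 7.81] |
| pH spread | 0.03 | modest spatial variability |
| PO₄ | log-normal, median 0.03 mmol m⁻³, gyre depression | tens-of-nanomolar oligotrophic surface phosphate |
| DOP | 1.5 × PO₄ × log-normal noise | DOP pools commonly exceed phosphate in gyres |
| NF envelope | Gaussian in latitude, 25° half-width | tropical/subtropical habitat |
| aux limits | uniform, Fe [0.1, 0.9], N [0.3, 1.0] | uninformative non-P limitation |

All draws come from one seeded stream per (seed, era) in a fixed order, so a
(config, seed) pair determines every value bit-for-bit. The NF field is
rescaled after noise so its global integral matches the target exactly;
R_Tr is clipped to [0, 1] and iteratively rescaled to its target mean
(tolerance 1 %).

What the generator does **not** emulate: real coastlines and bathymetry,
spatial autocorrelation beyond the smooth latitude envelopes, covariance
between pH and nutrient fields, seasonality, and inter-era field
correlation. Tests passing on these fields therefore demonstrate the
correctness of the calibration→limitation→projection→integration machinery
and its invariants, not the realism of any particular global number; the
headline integrals obtained on synthetic fields characterize the generator.

States serialize to a self-describing text format: a `#`-comment header
(era, grid edges, units) over a one-row-per-cell CSV body, written with
`%.17g` so doubles survive the round trip bit-exactly. Run summaries go to
JSON at ≥ 15 significant digits plus a plain-text table.

## nifH upscaling

Group rates follow abundance / (nifH copies per cell) × cell-specific rate,
with daily totals assuming 12 h of active fixation; contribution fractions
normalize per cell and flag zero-total cells as NA. Per-group conversion
factors and cell rates are configuration, shipped as a clearly labelled
placeholder CSV (`inst/extdata/placeholder_group_params.csv`) — single
average values per group, no distributional sampling. Abundance mapping is a
pluggable `predict` contract; the bundled default is a deterministic
parametric surface (log₁₀ abundance linear in a temperature proxy) so the
pipeline runs without learned weights. Training a statistical abundance
model is deliberately out of scope; the contract preserves the pipeline
shape for anyone who supplies one. How volumetric (per-litre) rates should
be depth-integrated into areal fields is left to the caller: R_Tr can be
supplied directly as a field, or computed from rates that are already areal.

## Pipeline and reproducibility

`run_pipeline()` executes generate → calibrate → limit → project → report
under one YAML-serializable config and one seed; the resolved config is
embedded in the summary, and re-running it reproduces the summary's numbers.
Stage failures abort with the stage name and the original error class;
distinct CLI exit codes map to the error classes. An empty scenario list
yields only the reference integral; a config with all effects zero yields
exactly zero deltas; an all-false mask makes the combined scenario collapse
to acidification-only — all asserted in the suite.

Problem sizes are chosen for tight feedback: unit and property tests run on
coarse 15°–45° grids (tens to hundreds of cells) and the default pipeline
example on the
2° × 2.5° grid (12,960 cells, well under a second); invariant sweeps cover
20 seeds. The whole suite runs in a few seconds on one CPU.

## Known limitations

* The linear-[H⁺] responses are calibrated over 0.2 pH units on one strain;
  extrapolation beyond the interval, though supported (with clamping), is a
  first-order illustration, not a prediction.
* The offline design ignores feedbacks of reduced fixation on nutrient
  fields and community composition, and treats R_Tr as an era-specific input
  with no interpolation between eras.
* Reproducing published global integrals requires the Earth-system-model
  fields and abundance maps those numbers were computed from; with synthetic
  fields only the computation's structure is verifiable, which is exactly
  what the test suite targets.
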