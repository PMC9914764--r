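---
title: "Response-surface modelling of oyster mushroom shelf-life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface modelling of oyster mushroom shelf-life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfrsm)
library(dplyr)
```

## The problem

Fresh *Pleurotus ostreatus* (oyster mushroom) spoils within days of harvest:
the fruiting body has no protective cuticle, respires and transpires
heavily, and its high water content feeds rapid microbial growth. Two
handles are available post-harvest — packaging (none, vented polyethylene
bags "PBP", or polypropylene vacuum bags "VBP") and storage temperature
(ambient versus 4 °C) — and one pre-harvest handle: the growing substrate,
where wheat straw can be partially replaced by agro-industrial residues
(olive pruning residues, OLPR; spent coffee grounds, SCG; or both). This
package models measured shelf-life (days until visible spoilage) over
packaging and residue incorporation rate, diagnoses the fit, finds the
settings that maximise shelf-life, and tracks the microbiological and
physicochemical quality of stored batches.

## The design and the model

Each response is observed on a replicated 3×3 layout: packaging
$X_1 \in \{\mathrm{VBP}, \mathrm{none}, \mathrm{PBP}\}$ coded $-1,0,+1$,
crossed with three residue rates $X_2$ (0/0.3/0.7 for single residues,
0/0.17/0.33 for the combined mixture), with the (no packaging, rate 0)
point run five times — 13 runs, 9 distinct points, 4 pure-error degrees of
freedom. The layout is sometimes described as a central composite design,
but it has no axial points and its replicated point is a corner of the
grid, not the centre; `shelf_life_design()` builds it exactly as run.

Shelf-life is fitted by ordinary least squares (QR factorisation; the
normal-equations solve is retained only as a test oracle) with the
six-term second-order polynomial

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_{12} X_1 X_2 +
      \beta_{11} X_1^2 + \beta_{22} X_2^2 .$$

Packaging is carried as an *ordered* factor on a numeric code, spending one
degree of freedom on its linear and one on its quadratic contrast; it is
never expanded into nominal contrasts, and it is never interpolated: a
"half-vacuum bag" has no physical meaning.

### Coding schemes

Two codings of the rate are supported. **Level coding** (the default) sends
the ordered levels to $-1, 0, +1$, exactly as the design tables print them.
**Range coding** is the affine map $(x - \bar x)/(\Delta x/2)$ onto
$[-1, 1]$; because 0.3 is not the midrange of $[0, 0.7]$, the middle level
then sits at $-1/7$ rather than 0. The two codings span the same model
space except through the single interaction column, so fitted values,
residual and model sums of squares, $R^2$, PRESS and optima agree to well
under the print resolution on these layouts (at most 0.045 days in fitted
values across all six tables, exactly zero when the interaction column is
dropped); per-term sums of squares for the linear and interaction rows are
coding-dependent, and every report states its coding.

### Prediction at unseen rates

The coded polynomial is defined at the three rate levels. For a continuous
rate the fit is re-expressed, per packaging level, as the unique quadratic
in *actual* rate units through its three level predictions
(`actual_rate_poly()`); predictions outside the fitted rate range are
flagged as extrapolations but still evaluated.

## Adequacy diagnostics

`anova_shelf()` reports partial (type III) per-term F tests — the increase
in residual SS when one column is dropped — with sequential SS behind a
flag; the overall model F; and the residual split into **pure error**
(within the replicated point, model-free) and **lack of fit** (between
distinct design points). PRESS is computed by the leverage shortcut
$\sum_i (e_i/(1-h_{ii}))^2$, which the test suite verifies against explicit
leave-one-out refitting; predicted $R^2 = 1 - \mathrm{PRESS}/SS_{tot}$.
Adequate precision is the fitted-value range over
$\sqrt{p\,MS_{res}/n}$. Degenerate cases are explicit: an interpolating fit
(residual SS at rounding level, below $10^{-10} SS_{tot}$) reports
infinite F flagged with p = 0; a design without replicates has no
lack-of-fit test; a run with leverage 1 makes PRESS undefined.

## Optimisation

`optimize_shelf_life()` enumerates the admissible packaging levels and, for
each, maximises the actual-units quadratic analytically — the interior
vertex when the curvature has the right sign and the vertex is in bounds,
otherwise the better endpoint — then verifies the result against a dense
grid (step 0.001 in rate). A Derringer one-sided desirability ramp scores
the optimum against the prediction range over the box. Ties between
packaging levels would be broken toward the level with the larger
desirability integral over the rate interval; on all shipped data the
optima are strict.

## Microbial contamination and quality

Total microbial counts (log10 CFU/g) are graded into four bands: low
(< 5.0), medium (5.0–6.5), high (6.5–8.05) and very high (> 8.05). The
published band definitions leave gaps (5.0–5.1 and 8.0–8.1) at the
one-decimal resolution of plate-count data; we close the low/medium edge at
5.0 — a count of exactly 5.0 is medium — and the high/very-high edge at the
8.05 midpoint. This closure is the only one under which the published
day-by-day band fractions (83.3 % of packed samples low on day 3 ambient;
77.8 % and 88.9 % on day 4 for PBP and VBP) are reproduced exactly, which
the test suite asserts exactly. The source text announces "five contamination
levels" but defines four; four are implemented. Consumability windows use
the 8.1 log CFU/g threshold above which batches are ranked unfavourable,
and a window never reopens after the threshold is first exceeded.

Quality metrics follow the published formulas: weight loss
$100\,(W_0-W_t)/W_0$ (acceptable up to an inclusive 5 %), firmness on the
instrumented 1–9 score (acceptable at 3.0 and above), and the veil metric
$100\,(V_t-V_f)/V_t$. As printed, that formula computes the fraction of
veils *not* open even though the narrative treats rising "veil opening" as
deterioration; `veil_opening()` implements the formula verbatim, records
the convention on its output, and offers the complement
(`convention = "opened"`), which is the direction in which the
monotonicity of the acceptability rules is meaningful.

## The synthetic generator

`simulate_design()` draws responses from a known quadratic surface plus
i.i.d. Gaussian noise on any layout; the default noise SD of 0.2 days sits
between the replicate standard deviations observed in the two shipped
temperature regimes (0.16 and 0.38 days). `simulate_tmc()` grows log
counts linearly with noise applied *before* a cumulative-maximum
projection, so trajectories are non-decreasing with occasional plateaus
like the observed series, then rounds to one decimal. `simulate_quality()`
decays weight geometrically, firmness linearly floored at the score 1, and
opens veils monotonically. All generators thread an explicit seed through a
locally scoped RNG; the global stream is untouched. What the generator does
*not* emulate: between-substrate heterogeneity of noise, measurement
rounding of the design responses, and any mechanistic microbial growth
model (Baranyi/Gompertz-type kinetics are out of scope) — so passing
parameter-recovery and calibration tests demonstrates correctness of the
estimators under the stated model, not robustness to real-data violations
of it.

Calibration checks run at these sizes: noiseless recovery over 100 random
coefficient draws (coefficients recovered to $10^{-8}$); 500 Monte-Carlo
tables at noise SD 0.4 for unbiasedness of the OLS coefficients; 1000
null-model replicates for the lack-of-fit test, whose rejection rate at the
nominal 5 % level lands between 3 % and 7 %.

## Reproducing the published tables — and where they cannot be reproduced

`reproduce_study()` refits all six responses (three residue schemes × two
temperatures) from the transcribed run tables and lines the
coding-invariant statistics up against the published values. Four of the
six fits agree closely at model level (for the ambient OLPR response:
$R^2$ 0.9833 vs 0.9832, model F 82.30 vs 82.15, lack-of-fit F 15.23 vs
15.26, adequate precision 20.32 vs 20.29). A cluster of published values,
however, cannot be regenerated from the published run tables by *any*
least-squares quadratic, under either coding, with packaging numeric or
categorical, fitted to runs or to cell means:

* the ambient OLPR PRESS (9.26 printed vs 10.99 recomputed) and with it
  the predicted $R^2$ (0.8753 vs 0.8521);
* the 4 °C combined-residue model F (1065.54 printed vs 403.15
  recomputed): the published predicted column for that response implies a
  residual SS of 1.31, yet the least-squares minimum over every basis
  containing that surface is 0.62 — the published surface is not a
  least-squares fit of the published data;
* the published optima. The recomputed ambient-OLPR maximum is 8.86 days
  at rate 0.37 under PBP (9.18 days at 0.289 printed); 9.18 coincides with
  the vertex of the quadratic through the *measured* VBP cells, so the
  printed optimum is not internally consistent with its printed packaging
  either (the source itself prints both 9.12 and 9.14 for another
  response). The recomputed 4 °C combined-residue maximum is 25.52 days at
  the rate boundary 0.33 under VBP (26.26 at 0.22 printed).

These recomputed values are reported as they are; the comparison table and
the test suite show the discrepancies rather than tuning the model
basis per quantity until each printed number is matched. The published
per-term SS rows (e.g. a packaging SS of 25.30 where the coded contrast is
near zero) evidently come from the source software's internal categorical
basis and are emitted but not certified. One further misprint is handled in
the data: the ambient TMC table prints "103" for one reading (M3A, no
packaging, day 6); the shipped fixture records 10.3, the value consistent
with the surrounding trajectory, and the fixture checksums are pinned so
any further edit fails the suite deliberately.

```{r compare}
reproduce_study() |>
  filter(quantity %in% c("r2", "f_model", "f_lof")) |>
  arrange(quantity, temperature, scheme)
```

## A worked run

```{r worked}
design <- study_shelf_life("OLPR", "ambient")
fit <- fit_shelf_life(design)
glance(fit)
anova_shelf(fit)
optimize_shelf_life(fit)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(fit)
```

## Known limitations

* Shelf-life responses are triplicate means transcribed at one decimal;
  run-level replicate spread beyond the five replicated runs is not
  available, so pure error rests on a single design point.
* The quadratic surface is descriptive within the factor box; rate
  extrapolation is flagged, and packaging is never treated as continuous.
* TMC classification at band edges depends on the gap-closure convention
  described above; readings falling exactly on 5.0 or 8.05 are classified
  per that convention, not per the (gapped) published wording.
* The firmness score's mapping to newtons is not published and is not
  modelled; the 1–9 score is taken as given.
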