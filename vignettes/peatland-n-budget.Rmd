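---
title: "Methods: the annual peatland N budget and its uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the annual peatland N budget and its uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatbudget)
```

## The budget as an estimator

`peatbudget` treats annual soil organic matter (SOM) turnover in a
flooded-rice peatland as a quantity estimable from an annual nitrogen
mass balance. The reasoning: SOM oxidation releases mineral N and C in
the stoichiometric ratio of the soil; a rice crop grown without N
fertilizer integrates plant-available N over the season; so crop N
uptake, purged of every non-SOM source, indexes SOM-N mineralization,
which the soil C:N ratio converts to C loss.

The growing-season ledger partitions fertilizer-omission (0N) plot
uptake among four measured or assumed sources:

* **Crop residue** (`ndr`) — isotope pool dilution. Residue enriched in
  ¹⁵N is incorporated before planting; at harvest the tiller enrichment
  between the unlabelled background and the input residue gives the
  mixing fraction `fNdr`, scaled by uptake and by the labelled share of
  the residue mixture. The mixing equation assumes two well-mixed N
  pools and no isotope fractionation — reasonable at enrichments (≈ 9
  atom %) far above natural abundance (≈ 0.366 atom %).
* **Surface irrigation water** (`ndsw`) — the unweighted seasonal mean
  inlet concentration of NH₄-N + NO₃-N times the crop-coefficient-
  adjusted evapotranspiration volume (1 m over 1 ha = 10⁷ L, exact).
  The assumption is that the water the crop transpires carries its
  dissolved N into the root zone; whether the seasonal average should
  be time-weighted is not determinable from endpoint data, so the
  unweighted mean is used and the sampling dates enter symmetrically.
* **Shallow groundwater** (`ndgw`) — the uptake difference between
  mesocosms with perforated and sealed bases. Surface water flows over
  both treatments identically, so the contrast isolates upwelling N.
* **Deposition and fixation** — fixed literature values (defaults 6 and
  25 kg N ha⁻¹ yr⁻¹), carried as exact constants with zero SE. The
  fixation default sits mid-range of reports for paddy cyanobacteria
  and is deliberately generous: over-counting a non-SOM source makes
  the peat estimate conservative.

The residual is surface-peat N; the groundwater term, itself attributed
to subsurface SOM mineralization, is added back to give total
peat-derived uptake. Dividing by the N uptake efficiency (NUE) converts
plant capture to gross mineralization — all loss pathways
(denitrification, volatilization, leaching) are folded into NUE rather
than modelled. The fallow season adds late-spring soil NO₃-N (assumed
denitrified at flooding) minus overwinter residue-N mineralization.
The annual N total times the soil C:N ratio gives gross C mineralized;
subtracting the residue C returned at tillage gives net C loss. The net
loss subtracts the residue credit — the only reading consistent with a
"net" quantity and with treating the residue input as a gain to the
soil. Subsidence follows by converting net C loss to a depth of
oxidised organic soil through the SOM carbon fraction, bulk density and
the fraction of subsidence attributable to oxidation.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `nue` | fraction | 0.50 | common fertilizer-N uptake efficiency in rice; the single most influential assumption, hence the built-in sensitivity scan |
| `n_deposition` | kg N ha⁻¹ yr⁻¹ | 6 | regional wet + dry deposition estimate |
| `n_fixation` | kg N ha⁻¹ yr⁻¹ | 25 | mid-range for free-living cyanobacteria in paddies |
| `som_pct_c` | g C g⁻¹ SOM | 0.58 | conventional SOM carbon fraction |
| `f_min` | fraction | 0.67 | share of subsidence due to SOM oxidation (vs compaction) on a neighbouring Delta island since 1995 |
| `cumulative_et_m`, `crop_coefficient` | m, — | 0.634, 1.06 | flooded-period ET and rice crop coefficient |
| `cn_ratio`, `bulk_density` | kg C kg⁻¹ N, g cm⁻³ | site-specific | measured soil profile, no defaults |

NUE enters as `1/nue` on the peat total, so net C loss is convex
decreasing in NUE: each efficiency increment buys a smaller reduction
in estimated loss. `nue_sensitivity()` and `plot()` expose this; the
default grid spans 0.30–0.90 in steps of 0.05.

## Error propagation, twice

Every measured input is a `quantity` (value, SE, units). Sums and
differences combine SEs by root sum of squares under an independence
assumption (no covariances are estimable from the measurement design);
multiplication by exact factors (1/NUE, C:N, unit conversions) scales
the SE by the same factor. Two conventions are offered for the
peat-total line:

* `se_mode = "paper"` (default): the peat total is surface peat +
  groundwater, and its SE combines the surface-peat SE — which already
  contains the groundwater SE — with the groundwater SE again. This
  reproduces the published SE column and is retained for fidelity.
* `se_mode = "consistent"`: the groundwater term cancels algebraically
  in the peat total (it is subtracted in the residual and added back),
  so the SE is propagated from the genuinely independent components
  only. This is the smaller, internally consistent value, and it is the
  one the Monte-Carlo twin converges to, because the draw chain cancels
  the term exactly as the algebra does.

Values are identical in both modes; only the reported SE differs.
`monte_carlo_budget()` draws each measured input independently from
Normal(value, SE), re-runs the deterministic chain per draw (vectorised,
so 10⁵ draws cost well under a second) and summarises each line. On the
linear chain with fixed NUE and C:N the Monte-Carlo sd must match the
consistent analytic SE up to sampling error — the suite checks agreement
within 3% at 10⁵ draws. Attaching `cn_se` makes the chain nonlinear;
there the Monte-Carlo summaries are the authoritative uncertainty.
Draws are not truncated at zero by default — truncation would shrink
the sd and break the analytic comparison — but `truncate_negative =
TRUE` is available as a sensitivity option, with truncated draws
counted.

## Degenerate inputs and numerical conventions

* Estimates that can plausibly go negative through measurement error —
  the mixing fraction outside [0, 1], a negative groundwater contrast,
  recoveries summing past 100%, negative fallow mineralization — are
  returned raw with a warning, never clamped. Clamping would bias every
  downstream mean and SE.
* An input-residue enrichment equal to background is an error (the
  tracer carries no information), as are non-positive NUE, C:N, bulk
  density, `f_min` and empty replicate sets.
* All arithmetic runs at full double precision; rounding happens only
  at display time (one decimal for N lines, whole numbers for C lines,
  two decimals for subsidence) and in the human-readable CSV report.
  The JSON report stores 12 significant digits, and re-running the same
  configuration is byte-identical.
* Exactly balanced ledgers (uptake equal to the sum of sources) may
  leave a float residue of order 10⁻¹⁴; the negative-value warnings
  ignore anything above −10⁻⁹ kg N ha⁻¹.

## The synthetic-data generator

`site_scenario()` plus `generate_site_data()` simulate the complete
measurement campaign the pipeline expects: Normal replicate-level noise
for plots, mesocosms and fallow samples; tiller enrichments obtained by
*forward* isotope mixing at the scenario's true fraction plus
instrument noise; inlet concentrations Normal truncated at zero (the
one deliberate departure from the untruncated propagation model —
negative concentrations are unphysical; at the default noise level the
induced bias on the budget is a few hundredths of an SE). The default
scenario mirrors the Site-1 design — four plot and mesocosm replicates,
five water dates, five residue samples — with sds calibrated so the
simulated SEs at those replicate counts match the reported magnitudes
(plot sd 20 → SE 10 at n = 4, mesocosm sd 12.7 → contrast SE ≈ 9, and
so on). Ground truth is computed by `closed_form_truth()` from the true
parameters and stored with the data, never re-derived from noisy files;
regeneration under the same seed is identical.

`scenario_analytic_se()` gives the delta-method SE each estimator
carries under the known noise model. It is the reference scale for the
parameter-recovery suite (200 seeded campaigns: bias below half an SE,
known-variance 95% intervals covering at their nominal rate within
binomial error). A deliberate distinction: intervals built from
*per-dataset* SEs estimated at n = 4 undercover by several points —
the familiar z-versus-t small-sample effect — and that is a property of
the study design, not of the estimator. Users reporting four-replicate
budgets should read the ±1.96 SE intervals accordingly.

What the generator does **not** emulate: within-season temporal
dynamics (only endpoint quantities are drawn), spatial correlation
among plots, covariance between measurements, non-Normal measurement
error, and any mechanistic soil N cycling. Passing recovery tests
therefore demonstrates correctness of the estimator under its own
assumptions, not robustness to field realities outside them.

## Known limitations

* The published annual-totals SE column cannot be reconstructed from
  the published per-line SEs by the stated propagation rule; the
  package reports its own internally consistent SEs for those lines
  and labels the convention via `se_mode`.
* The harvest tiller enrichments behind the published residue line are
  not available, so that line is reproduced as a measured summary
  input and validated by synthetic round trips instead.
* The fallow fall/spring residue-N levels are published only as their
  difference; the packaged fixture anchors the spring value at the
  residue-mixture N content and carries the difference's SE on the
  fall line, which leaves every derived quantity and SE unchanged.
* C:N is a point value in the analytic path; soil NO₃-N lost before
  flooding by pathways other than denitrification, multi-year residue
  carry-over and NUE varying with N supply are all outside the model.

## Problem sizes

The test suite runs the full published-fixture reproduction (exact,
sub-second), Monte-Carlo validation at 10⁵ draws, and 200-seed
parameter-recovery campaigns — about ten seconds end to end on one
core, sizes chosen so the statistical assertions have comfortable
power while the suite stays interactive.
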