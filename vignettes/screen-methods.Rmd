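---
title: "Methods: paired-line synthetic-lethality screening and its companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-line synthetic-lethality screening and its companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`mycSynLeth`, the choices made where the underlying experimental protocol
leaves the analysis open, and what the synthetic-data generators do and do
not emulate.

## The screen model

An arrayed kinome library (by default 719 genes, 3 distinct siRNA duplexes
per gene) is screened in two paired clones of the same cell line: one
overexpressing c-Myc, one carrying the empty vector. Each well holds one
(cell line, siRNA) combination; viability is read out as MTS absorbance
48 h after transfection. Every 96-well plate carries its own controls:
non-targeting negative-control wells, and lethal positive/death controls
used only for quality reporting, never for normalization.

### Surviving fractions

The normalization reference is the per-plate **median of the non-targeting
negative-control wells**. Viability protocols differ in whether they
normalize to non-targeting controls or to the plate's sample median; we use
the non-targeting controls because they are the biologically neutral
reference the screen design provides, and the median (not the mean) so that
a single failed control well cannot distort the plate. Dividing by a
same-plate reference makes the surviving fraction invariant under any
multiplicative plate effect — incubation differences, reagent batch, reader
gain — which is why `plate_effect` cancels exactly in the generator-based
tests. A plate without negative controls is an error, not a silent fallback.

### Median-centered z-scores

Within each stratum, sample-well surviving fractions are standardized as

    z = (SF − median(SF_sample)) / scale

* **Center**: the median, so that a heavy lethal tail (the screen's signal)
  does not shift the reference point. After standardization the sample-well
  median of every stratum is 0 to within 1e-9, a property the test suite
  asserts.
* **Scale** (default `"mad"`): the normal-consistent MAD,
  `1.4826 · median(|SF − median|)`, again robust to the lethal tail. The
  sample standard deviation (`scale = "sd"`) is provided for comparison; on
  screens with many true positives it over-estimates the noise scale and
  deflates all z-scores.
* **Stratification** (default `"per_plate"`): estimating center and scale
  per plate guards against residual per-plate distribution differences; the
  cost is a noisier scale estimate (about 80 sample wells per plate). The
  `"per_cell_line"` option pools a whole line and suits small, single-plate
  datasets; the two lines are always standardized separately, since the
  overexpressing clone's globally different growth must not be absorbed
  into the control clone's scale.
* **Degenerate strata**: a zero MAD falls back to the sd with a warning; if
  that is also zero (constant readings) all z in the stratum are set to 0
  with a warning rather than NaN.

Controls are *scored* (they receive z values, useful for QC separation
plots) but are always excluded from center and scale estimation.

### Hit calling: concordance plus selectivity

A gene is called synthetic-lethal when

1. at least `minConcordant = 2` of its siRNAs have `z < threshold = −2`
   (strict inequality) in the overexpressing line, and
2. its **selectivity** `mean z(overexpressing) − mean z(control)` is at most
   `selectivityMargin = −1`.

The concordance rule is the standard defense against off-target artifacts:
a single rogue duplex, however lethal, cannot call a gene. The selectivity
margin encodes the *synthetic* part of synthetic lethality — a gene equally
lethal in both clones is a general essential gene, not a target for the
lesion-specific therapy the screen is after. The margin of one robust
z-unit is a design choice: 0 would admit genes whose differential effect is
within noise, while −2 would demand the full hit-threshold effect as pure
differential. Both the margin and each gene's selectivity value are kept in
the output so the criterion is auditable, and genes with any unmeasured
siRNA are reported and never called (concordance cannot be evaluated for
them).

### Expected false discoveries of a z < −2 rule

Standardized scores of null genes are approximately N(0, 1) by
construction, so each siRNA has P(z < −2) ≈ 0.023 from noise alone; with
the default off-target rate the per-well tail probability is ≈ 0.04. Over
719 genes the probability that 2 of 3 duplexes cross by chance,
`3·p²·(1−p)`, predicts a handful of chance-concordant genes per screen,
only partially removed by the selectivity filter. This is inherent to the
rule, not to its implementation: any screen calling hits at z < −2 with
2-of-3 concordance across ~2000 scores should expect a small tail of
false candidates alongside strong true hits, which is why screens of this
design validate candidates with independent duplexes downstream. The test
suite measures exactly this: recall of the planted set is 1.0 and the null
false-call rate stays well under 1% of genes, while per-screen precision
with only five planted genes is limited by those few chance-concordant
calls.

## The synthetic screen generator

`simulateScreen()` is a pure function of its configuration and seed:

* layout: sample wells filled plate by plate (80 per plate, row-major), the
  same layout replicated in both lines with per-line plate identifiers;
  8 negative, 4 positive and 4 death-control wells per plate;
* planted synthetic-lethal genes: mean surviving fraction 0.4 in the
  overexpressing line, 1.0 in the control line — a strong, clearly
  detectable effect (about −8 robust z-units at the default noise);
* off-target model: each sample well independently receives, with
  probability 0.02, an extra multiplicative viability factor drawn
  uniformly from [0.5, 1] — *well-level*, not gene-level, mimicking the
  single-rogue-duplex artifacts the concordance rule exists to reject
  (partial, variable severity; many draws do not even cross the threshold);
* noise: readings are `plate_effect × true_SF × (1 + N(0, 0.05))`, floored
  at 0, with `plate_effect` log-normal (log-sd 0.05).

What it does **not** emulate: edge effects and spatial gradients within
plates (no B-score correction is implemented, matching the analysis chain
it models), transfection-efficiency variation between wells, siRNA-specific
knockdown efficiency, or correlated off-target effects shared between
duplexes. Passing tests therefore demonstrate the statistical chain's
correctness and its behavior under plate effects, well noise and rogue-well
artifacts — not robustness to spatial artifacts real plates can show.

## Dose-response: residual activity and 4PL fitting

Radiometric kinase counts are mapped to percent residual activity between
the assay's low control (full inhibition) and high control (no inhibitor):
`100·(cpm − low)/(high − low)`. Values outside [0, 100] are preserved by
default — clipping before least-squares fitting biases the plateaus — with
an opt-in `clip` flag for reporting.

The potency model is the four-parameter logistic with variable slope,

    y = bottom + (top − bottom) / (1 + 10^((log10 IC50 − log10 c) · hill)),

fitted by Levenberg-Marquardt least squares under box constraints
(defaults: bottom ∈ [−10, 50], top ∈ [50, 120], hill ∈ (0, 5] — a
decreasing percent-scale inhibition curve; equal bounds pin a parameter).
Because the RSS surface is multimodal in (log IC50, hill), the optimizer is
restarted from a fixed deterministic grid — log IC50 at every observed
log-dose, hill at 0.5, 1 and 2 — and the lowest-RSS solution wins, ties
broken toward the hill slope closest to 1. This makes the fit a
deterministic function of the data and constraints. On noiseless
model-generated data the parameters are recovered to better than 1e-6
relative error, and on a small series the solution matches an exhaustive
grid search over (log IC50, hill) to within the grid resolution — both
asserted in the tests.

Uncertainty is a case-resampling percentile bootstrap (1000 resamples by
default, caller-supplied seed, resamples with fewer than four distinct
concentrations discarded). At n ≈ 9 dose points a case bootstrap is
approximate; the suite checks ≥ 85% empirical coverage at nominal 95%
rather than exact calibration, at a reduced replicate count (40 series ×
199 resamples) chosen to keep the property test fast while still detecting
gross miscalibration.

`compareTitrations()` refuses to interpolate: per-dose differences and the
rescue index (mean difference over doses ≤ 5 µM, the tested concentration
range of the inhibitor) are only defined on a shared dose grid.

## ΔΔCt relative quantification

Technical replicates are averaged per (sample, gene); ΔCt subtracts the
*arithmetic mean Ct* of the housekeeping genes (18S and β-actin in the
modeled assay) — equivalent to the geometric mean of housekeeping
expression levels, the conventional multi-reference combination; ΔΔCt
subtracts the reference sample; fold change is `efficiency^(−ΔΔCt)` with
the textbook perfect-doubling efficiency 2, configurable for
efficiency-corrected designs. The reference sample's fold is set to exactly
1 (not `2^−0` with round-off). A uniform Ct shift of a sample — pipetting
or input amount — cancels in the housekeeping normalization, a property the
tests assert. No outlier rejection is performed on replicates.

## CAM tumor volumes

Tumor burden is estimated from two perpendicular external diameters via the
spherical formula `V = (4/3)·π·r³`. The default radius rule is the
geometric mean, `r = ½·√(d1·d2)`, the standard two-diameter estimate for
spheroidal xenografts and symmetric in the diameters; `"single-diameter"`
(`r = (d1+d2)/4`, half the mean caliper diameter) covers the alternative
single-diameter reading of the spherical formula. A tumor regresses iff
`ΔV = V_post − V_pre < 0`, strictly — an unchanged tumor is not regression.
Group summaries are per embryo; between-group inference (ANOVA etc.) is
left to standard tools on the exported per-embryo table.

The CAM generator draws a latent per-embryo size log-normally around 3 mm,
scatters the two pre-diameters multiplicatively around it, and applies a
per-group growth factor (defaults 1.3 vehicle vs 0.8 treated) with
multiplicative noise — enough structure to test sign recovery and
classification, with no pretense of modelling vascularization or treatment
kinetics.

## Problem sizes used in the test suite

The suite runs the full-size default screen (719 × 3 × 2 lines ≈ 5200
wells) for the end-to-end checks — 20 seeds for the recovery properties and
20 for the null-rate property — and smaller libraries (20–300 genes) where
the check is structural rather than statistical. Dose-response recovery
uses 200 simulated series at the modeled 53 nM potency (9 half-log doses,
3-point noise); bootstrap-coverage checks use 40 series × 199 resamples.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run routinely.

## Known limitations

* No spatial/edge-effect correction; plates are assumed exchangeable after
  median normalization.
* The hit rule is deterministic concordance, not an error-controlled test:
  no per-gene p-values or FDR are produced, and (as derived above) a few
  chance-concordant genes per screen are expected at z < −2.
* The 4PL bootstrap is a case bootstrap at small n; its interval is
  approximate and reported as such.
* ΔΔCt assumes equal amplification efficiency across genes unless the
  caller supplies a different `efficiency`.
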