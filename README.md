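# mycSynLeth

Synthetic-lethality analysis for paired-line kinome RNAi screens, with the
downstream validation assays that typically follow such a screen.

## The problem

Arrayed siRNA viability screens look for genes whose knockdown kills cells
carrying a particular lesion — here, c-Myc overexpression in medulloblastoma —
while sparing an isogenic control clone. The raw data are absorbance readings
(MTS viability assay) from 96-well plates: thousands of sample wells, each
transfected with one siRNA duplex against one kinase, alongside per-plate
non-targeting negative controls and lethal positive/death controls. Turning
those readings into a defensible hit list requires plate-wise normalization,
robust standardization, and a concordance filter against the single-siRNA
off-target artifacts that dominate false positives in RNAi screens.

`mycSynLeth` implements that chain end to end, for two cell lines screened in
parallel with the same library:

1. **Surviving fraction** — `SF = reading / median(negative-control readings
   on the same plate)`, cancelling multiplicative plate effects.
2. **Median-centered z-score** — `z = (SF − median(SF)) / (1.4826 · MAD)`,
   center and scale estimated per stratum (per plate by default) from sample
   wells only; the sample sd is available as an alternative scale.
3. **Gene aggregation** — the siRNA-level z-scores of each gene, paired
   across the overexpressing and control lines.
4. **Hit calling** — a gene is synthetic-lethal when at least
   `minConcordant = 2` of its siRNAs score `z < −2` (strict) in the
   overexpressing line **and** its selectivity, `mean z(over) − mean z(ctrl)`,
   is at most `−1`.

Companion modules cover the assays used to validate such hits: percent
residual kinase activity from radiometric counts,
`100·(cpm − low) / (high − low)`, with four-parameter logistic
(variable-slope) IC50 fitting
`y = bottom + (top − bottom) / (1 + 10^((log10 IC50 − log10 c)·hill))`
and a seeded percentile-bootstrap CI; ΔΔCt relative quantification against
housekeeping genes, `fold = E^(−ΔΔCt)`; and CAM xenograft tumor volumes from
perpendicular caliper diameters, `V = (4/3)·π·r³` with `r = ½·√(d1·d2)`.

Because screens of this kind rarely deposit raw well-level data, the package
ships seeded generators (`simulateScreen()`, `simulateDoseResponse()`,
`simulateQpcr()`, `simulateCam()`) that reproduce the statistical structure
of every stage with known ground truth, so recovery can be measured.

## Worked example

```r
library(mycSynLeth)

sim <- simulateScreen(screenSimConfig(), seed = 1)   # 719 genes x 3 siRNAs, 2 lines
sim$dataset
#> ScreenDataset: 5178 wells, 54 plates, 2 cell line(s), 719 library genes
#>   roles: death_control=216, neg_control=432, pos_control=216, sample=4314

res <- screenPipeline(sim$dataset, "M2.1", "V11")
subset(res$hits, hit)[, c("gene", "n_sirnas_below", "min_z_line_a", "selectivity")]
#>       gene n_sirnas_below min_z_line_a selectivity
#> 1  KIN0509              3       -14.23      -13.21
#> 2  KIN0679              3       -13.49      -13.44
#> 3  KIN0299              3       -12.81      -12.73
#> 4  KIN0471              3       -12.00      -11.58
#> 5  KIN0129              3       -11.73      -11.57
#> 20 KIN0435              2        -5.77       -3.22
#> 22 KIN0152              2        -5.33       -1.52

sort(names(which(truthLabels(sim$truth))))
#> "KIN0129" "KIN0299" "KIN0471" "KIN0509" "KIN0679"
```

All five planted synthetic-lethal genes (surviving fraction 0.4 in the
overexpressing clone, 1.0 in the control) are recovered with deeply negative
z-scores in all three duplexes; two further genes cross the concordance
threshold through the combination of well noise and off-target draws — the
expected false-discovery behavior of a z < −2 rule over 2157 siRNA scores
(see the vignette's discussion of the screen's error rates).

```r
d   <- 10^seq(-9, -5, by = 0.5)                        # molar dose grid
ser <- simulateDoseResponse(ic50 = 53e-9, doses = d, noiseSd = 3,
                            nSeries = 1, seed = 7)
fit4PL(ser$concentration, ser$response, nBoot = 1000, seed = 7)
#> FourPLFit: IC50 = 6.493e-08 M (bottom 3.07, top 100, hill 1.06), rss 58.47, n = 9
#>   bootstrap CI: [3.642e-08, 1.485e-07] M

residualActivity(550, 100, 1000)   # cpm vs low/high assay controls
#> 50
```

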