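# fluxdeconv

Bioenergetic profiling of small whole organisms — developing zebrafish
embryos in particular — from microplate extracellular-flux respirometry.

Plate-based flux analyzers record *level traces*: oxygen tension (mmHg) and
pH inside a transient few-microlitre microchamber formed over each well,
through repeated mix/wait/measure cycles.  `fluxdeconv` turns those traces
into physiology:

1. **Rate estimation** — per-cycle oxygen consumption rates (OCR, pmol
   O2/min) from a diffusion-aware two-compartment chamber model (plate-wall
   diffusion + atmospheric leak + organismal consumption), and extracellular
   acidification rates (ECAR, mpH/min) from the measure-phase pH slope.
2. **Calibration** — ECAR → proton production rate (PPR, nmol H+/min) by
   dividing through a titration-measured chamber buffer capacity, and
   cross-calibration of plate OCRs against closed-chamber Clark-electrode
   rates.
3. **Partitioning** — inhibitor-based deconvolution of basal respiration.
   With basal rate `R_b`, post-oligomycin `R_o`, post-azide `R_a` and
   post-FCCP `R_f`:

   | component | definition |
   |---|---|
   | mitochondrial respiration | `R_b − R_a` |
   | ATP-turnover-linked | `R_b − R_o` |
   | proton leak | `R_o − R_a` |
   | non-mitochondrial | `R_a` |
   | maximal uncoupled capacity | `R_f − R_a` |

   so mitochondrial = ATP-linked + leak, and the nonmito/ATP/leak fractions
   of basal respiration sum to 1 exactly.
4. **Statistics** — one-way ANOVA with Student–Newman–Keuls post hoc
   comparisons (studentized range, step-down with the non-testing rule),
   one-sample t tests against zero, and titration working-dose selection.
5. **Synthetic assay** — a ground-truthed generator of full plate runs
   (exact matrix-exponential integration of the chamber model, lognormal
   well/clutch variation, Gaussian sensor noise), Clark traces, buffer and
   inhibitor titrations, so the entire pipeline is testable end to end
   without an instrument.

See the vignette (`vignettes/flux-deconvolution.Rmd`) for the model, the
defaults and their rationale, and known limitations.

## Worked example

Simulate a mid-pharyngula (30 hpf) islet plate with the default injection
protocol (oligomycin 9.4 µM at cycle 7, FCCP 2.5 µM at cycle 13, azide
6.25 mM at cycle 19), estimate rates and partition:

```r
library(fluxdeconv)

sim   <- simulate_plate(30, seed = 1)
rates <- estimate_ocr(sim$run)                 # compartment method
rates[rates$well == "A2", c("cycle", "ocr_pmol_min", "ecar_mpH_min", "r2", "min_O2")][1:3, ]
#>    cycle ocr_pmol_min ecar_mpH_min        r2   min_O2
#> 25     1     154.7701     17.26561 0.9988355 132.8048
#> 26     2     153.6755     17.28255 0.9990650 132.6341
#> 27     3     153.6141     16.80464 0.9994490 132.1116
```

Well A2 holds two 30 hpf embryos, so ~154 pmol/min is ~77 pmol/min/embryo;
minimum O2 stays far above the 100 mmHg hypoxia floor and the measure
phases are essentially linear (R² ≈ 0.999).  Extract basal (mean of cycles
5–6) and treatment rates (two consecutive cycles at each post-injection
extreme), then partition:

```r
sw <- sim$run$layout$well[sim$run$layout$role == "sample"]
ph <- extract_phase_rates(rates[rates$well %in% sw, ], sim$run$schedule)
p  <- partition(ph$ocr_basal, ph$ocr_oligomycin, ph$ocr_azide, ph$ocr_fccp)
round(100 * colMeans(p[c("f_nonmito", "f_atp", "f_leak")]), 1)
#> f_nonmito     f_atp    f_leak
#>      29.1      52.6      18.4
```

At this stage roughly 18% of basal respiration is proton leak, ~29% is
non-mitochondrial, and the rest is coupled to ATP turnover.  The full
pipeline (simulation → rates → calibration → partitioning → cross-stage
statistics) runs from a single seeded config:

```r
report <- run_pipeline(run_config(stages = c(3, 24, 48), seed = 1))
report
#> <flux_report>
#>   stages: 3, 24, 48 | 60 wells | calibration factor 1
#>  hpf  n        OCR_pe        PPR_pe leak_pct nonmito_pct
#>    3 20  14.2 +/- 0.3 0.19 +/- 0.00      1.3        51.5
#>   24 20  70.1 +/- 1.9 0.78 +/- 0.02     26.6        29.4
#>   48 20 124.2 +/- 2.2 1.35 +/- 0.02      9.5        28.9
#>   basal OCR trend: 2.44 pmol/min/embryo per hpf (R2 = 0.998)
```

Per-embryo basal OCR and PPR rise linearly with developmental age; the
leak fraction is indistinguishable from zero at 3 hpf
(`report$leak_vs_zero[["3"]]`), peaks around the segmentation stages and
falls again by hatching; `report$comparisons$f_leak` carries the
ANOVA/SNK letters.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "fluxdeconv", load_package = "installed")'
```

All fixtures are generated in code; the suite includes an independent
`deSolve` integration oracle for the chamber model, a permutation oracle
for the group comparisons, and seeded end-to-end recovery checks.

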