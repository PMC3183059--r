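---
title: "Deconvoluting whole-organism respiration from extracellular flux traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting whole-organism respiration from extracellular flux traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdeconv)
```

## The measurement problem

A 24-well extracellular flux analyzer measures the respiration of live
zebrafish embryos by periodically lowering a sensor onto each well, forming a
transient microchamber of a few microlitres.  While the chamber is closed,
oxygen tension (mmHg) and pH fall as the embryos respire and extrude acid;
when the sensor lifts and the well is stirred, the chamber re-equilibrates
with the 700 uL bulk.  One measurement cycle is 2 min mix, 1 min wait and
1.5 min measurement.  A run takes six basal cycles and then injects up to
four pharmacological agents, with 18 further cycles.

The quantity of interest is the oxygen consumption rate (OCR, pmol
O2/min) and the proton production rate (PPR, nmol H+/min).  Neither is
observed directly: the raw data are *level traces* — time series of chamber
O2 and pH — and the conversion to rates must account for oxygen diffusing
back into the depleted chamber through the plate walls and from the
atmosphere.  With specific inhibitors, the basal OCR can then be
deconvoluted into its physiological components:

* **oligomycin** (ATP-synthase inhibitor) removes the respiration coupled to
  ATP turnover;
* **FCCP** (protonophore uncoupler) drives respiration to its
  substrate-unlimited maximum;
* **sodium azide** (cytochrome c oxidase inhibitor) removes all
  mitochondrial respiration, leaving the non-mitochondrial floor.

Writing $R_b$, $R_o$, $R_a$, $R_f$ for the basal, post-oligomycin,
post-azide and post-FCCP rates:

$$
R_\mathrm{mito} = R_b - R_a,\quad
R_\mathrm{ATP} = R_b - R_o,\quad
R_\mathrm{leak} = R_o - R_a,\quad
R_\mathrm{nonmito} = R_a,\quad
R_\mathrm{maxunc} = R_f - R_a .
$$

These are algebraic identities, so $R_\mathrm{mito} = R_\mathrm{ATP} +
R_\mathrm{leak}$ and the non-mitochondrial, ATP-linked and leak fractions of
basal respiration sum to one exactly — the package's tests assert both to
machine precision.  Negative components (possible when leak is near zero and
noise dominates) are **retained and flagged**, never clipped: "leak not
different from zero" must remain a testable statistical statement.

## The chamber model and rate estimation

The microchamber is modelled as a linear two-compartment system.  With
$O_{ch}$ the chamber tension, $O_w$ a slow wall/plastic compartment,
$O_{atm}$ ambient tension, $V$ the chamber volume (uL) and $k_{O_2}$ the O2
solubility (pmol/uL/mmHg):

$$
\frac{dO_{ch}}{dt} = -\frac{OCR}{V\,k_{O_2}}
  + k_w (O_w - O_{ch}) + k_a (O_{atm} - O_{ch}), \qquad
\frac{dO_w}{dt} = k_{w}' (O_{ch} - O_w),
$$

during a measurement; with the sensor up, the consumption term is dropped
and a fast mixing term $k_{mix}(O_{atm}-O_{ch})$ re-equilibrates the
chamber.  The coefficients are piecewise constant, so propagation over any
interval is **exact** via the matrix exponential of the augmented 3x3
system (`Matrix::expm`); there is no integration step error anywhere in the
generator or the estimator, which a `deSolve` fine-step integration
cross-checks in the test suite.

`estimate_ocr()` offers two methods:

* `"slope"` — OCR is the negated OLS slope of the measure-phase O2 samples
  times $V k_{O_2}$.  This ignores the diffusion terms and therefore
  under-reads whenever the chamber is depleted below ambient (about 4–5% at
  default physics); it is kept as the transparent baseline.
* `"compartment"` (default) — fits the model above per cycle.  Because the
  system is linear, the chamber trajectory is affine in OCR,
  $O_{ch}(t) = b(t) + OCR\,s(t)$, with $b$ the zero-consumption path from
  the cycle's initial state and $s$ the unit-consumption response.  The
  least-squares OCR is therefore available in closed form — the fit is the
  exact optimum, not an iterative approximation.  The wall-compartment
  state is carried forward across cycles by propagating the fitted model
  through each phase.

On noiseless traces the compartment estimate reproduces the generating
truth to numerical precision in every cycle and phase; estimated well OCR
is proportional to embryo count (1–3 embryos per well) to within $10^{-6}$
of the integer ratio.  These checks are why the generator and estimator
deliberately share the model: recovery becomes a meaningful end-to-end
test.  Mismatch robustness is probed separately by perturbing $k_w$/$k_a$.

ECAR is the negated OLS pH slope over each measure phase (mpH/min) in both
methods, matching the generator's linear acidification construction
exactly in the noiseless limit.

## Calibration

**Buffer capacity.** Five additions of a known quantity of protons (0.1 N
HCl) into the running media give the raw titration slope (mpH per nmol in
the titrated volume).  `buffer_capacity()` folds the volume ratio into the
chamber value, $BC_{chamber} = \text{raw} \times V_{titrated}/V_{chamber}$,
so that the conversion is literally a division: $PPR = ECAR / BC_{chamber}$.
The default well/chamber volumes are 700 uL and 7 uL; the chamber volume is
a configuration field, not an instrument constant.

**Clark-electrode cross-calibration.** Matched runs on a closed 1.5 mL
Clark cell anchor the absolute scale: the calibration factor is the ratio
of Clark to plate mean rates and multiplies every plate OCR.  Applied to
the published means (0.091 vs 0.308 nmol O2/min/embryo) the factor is
0.2955 and maps the plate mean back onto the Clark mean exactly.  The
factor is applied after rate estimation and before partitioning; since
fractions are invariant under any positive scaling (asserted exactly in
the tests), the ordering is observable only in absolute rates.

## The synthetic assay and its defaults

`simulate_plate()` generates ground-truthed runs under the study
conditions: a 24-well islet plate with temperature-control wells A1, B3,
C4, D6; embryos per well of 3/2/2/2/2/1 at 3/7/12/24/30/48 hpf; oligomycin
9.4 uM at cycle 7, FCCP (1.875 uM up to 12 hpf, 2.5 uM later) at cycle 13,
azide (6.25 mM, 1.25 mM at 48 hpf) at cycle 19.

The default ground-truth table (`default_stage_table()`) encodes the
developmental physiology the method measures:

* basal OCR per embryo linear in age, through 91 pmol/min at 30 hpf (the
  Clark-anchored value) and about 15 pmol/min at 3 hpf;
* leak fractions 0, 0, 0.27, 0.27, 0.18 and 0.094 across the six stages;
* non-mitochondrial fraction highest at 3 hpf (0.55), flat at 0.30 from
  12 hpf on, making the ATP-linked fraction lowest at 3 hpf;
* FCCP fold-increase of mitochondrial respiration peaking at 7 hpf
  (1.9x) and declining to 1.2x by 48 hpf;
* basal PPR linear in age through 1 nmol H+/min/embryo at 30 hpf.

Exact per-stage OCR values and FCCP magnitudes are published only
graphically, so these defaults are declared package choices with the
correct qualitative structure, not claimed reproductions.  Physics
defaults (7 uL chamber, $k_{O_2} = 1.4$ pmol/uL/mmHg for fresh water at
28.5 C, $O_{atm} = 155$ mmHg, $k_w = k_w' = 0.06$, $k_a = 0.02$,
$k_{mix} = 3$ per min, chamber BC 10 mpH/nmol, pH 7.4) are likewise
configuration, chosen once as physically plausible values; the source
protocol states only that diffusion and leak exist.

Noise has three parts: a lognormal per-well rate multiplier (CV 10%), a
lognormal per-plate clutch multiplier (CV 10%), and additive Gaussian
sensor noise (SD 0.2 mmHg on O2, 0.0005 on pH).  The biological
multipliers scale all of a well's rates jointly — sibling embryos are
uniformly bigger or smaller — so partition *fractions* are nearly
noise-free per well, while absolute rates carry realistic spread.  The
generator does not emulate: drift in the temperature-control wells,
instrument spike artefacts, chorion oxygen gradients, FCCP dose-response
within a well, or systematic model mismatch (real plastic is not a single
well-mixed compartment).  Passing recovery tests therefore demonstrate
correctness of the estimation and partitioning machinery under the stated
noise structure, not robustness to every failure mode of real plates.
Under FCCP the generator applies a configurable PPR multiplier
(default 1.5); no published default exists.

## Rate extraction rules

Basal OCR/ECAR is the mean of cycles 5 and 6; if either is QC-invalid the
latest two consecutive valid basal cycles are used, with a warning.
Treatment rates take two consecutive cycles at the post-injection extreme:
the extreme cycle is paired with whichever adjacent cycle gives the more
extreme two-cycle mean, with the earlier pair on exact ties (the published
rule fixes "two consecutive cycles at the extreme" but not the pairing;
this operationalization is deterministic).  Injection windows are bounded
by the next injection.  Hypoxia QC fails any cycle whose measure-phase O2
dips below 100 mmHg; a pipeline stage aborts if more than half its sample
wells fail.  Degenerate measure phases (under 3 samples) are flagged
invalid, never silently dropped or propagated as NaN.

## Statistics

Cross-stage comparisons use one-way ANOVA (via `stats::aov`) followed by
the Student–Newman–Keuls step-down procedure on the studentized range
(quantiles from `stats::qtukey`, never re-tabulated).  For a pair spanning
$r$ ranks of the ordered means, $q = |\bar y_i - \bar y_j| /
\sqrt{MSE/n_h}$ is compared with $q_{\alpha,r,df}$; the harmonic mean
$n_h$ of the pair's sizes handles unequal $n$ (the source protocol used
balanced groups and does not specify a variant).  A span declared
non-significant blocks all pairs inside it (the non-testing rule), which
keeps homogeneous subsets contiguous; the letter annotations follow.  At
$k = 2$ the SNK decision coincides with the pooled two-sample t test
through the $q = t\sqrt2$ identity, asserted in the tests, and the
family-wise error under a six-group null is checked by simulation.  Leak
fractions at 3 and 7 hpf are compared against zero with one-sample
t tests.  Zero within-group variance with unequal means is reported as
all-significant with a `degenerate` flag rather than an error.

Titration dose selection mirrors the experimental rule — the concentration
producing the maximum respiration change without killing the embryos:
among non-lethal doses, the smallest whose response is within 5%
(configurable) of the non-lethal maximum.  The tolerance is a package
choice; the original selection was by inspection of the curves.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and identical seeds give
bit-identical outputs; `run_pipeline()` derives per-stage seeds from the
config seed, and a YAML config round-trips losslessly.  The shipped test
and acceptance workloads use single plates per stage (20 sample wells, 24
cycles, about 13k samples per plate), 200-replicate calibration recovery
loops and a 2000-replicate null simulation for the SNK error rate — sizes
chosen so the whole suite runs in a couple of minutes on one core while
keeping Monte-Carlo error well below the tolerances asserted.

## Known limitations

* The instrument vendor's exact rate algorithm is proprietary; the
  compartment estimator is a declared surrogate sharing its cited
  structure (plate diffusion + atmospheric leak + consumption), not a
  re-derivation, and no V7-plate parameterization is attempted.
* Oligomycin hyperpolarizes the inner membrane and therefore slightly
  over-estimates leak; no correction is applied, matching the source
  method, and the caveat transfers to all leak estimates.
* Clutches are treated as replicates; there is no mixed-effects modelling
  of the clutch hierarchy.
* The COX IV mitochondrial-content index shipped as a default is
  synthetic (correct qualitative shape only); real densitometry should be
  supplied for content-normalized rates.
* Buffer capacity may be titrated in the full well or the chamber; both
  volumes are arguments, and the default assumes a full-well titration.
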