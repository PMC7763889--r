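# kegfr

Kinetic eGFR and early kidney-graft function assessment in R.

## The problem

After kidney transplantation, the graft's glomerular filtration rate
(GFR) changes within hours while serum creatinine takes days to
re-equilibrate, so steady-state estimating equations (CKD-EPI) badly lag
the true filtration rate exactly when clinicians most need it — in the
first postoperative days, when patients at risk of **slow graft function
(SGF)** should be identified. This package is for transplant
nephrologists, intensivists and biostatisticians who want to compute and
evaluate the **kinetic estimated GFR (KeGFR)** on post-transplant
creatinine trajectories:

$$\mathrm{KeGFR} \;=\; \Bigl(1 - \frac{24\,(C_b - C_a)}{\Delta t \cdot \mathrm{Max\Delta PCr}}\Bigr)\;\frac{\mathrm{SSPCr}\cdot\mathrm{CrCl}}{0.5\,(C_b + C_a)}$$

with creatinine $C_a, C_b$ (µmol/L) measured $\Delta t \le 36$ h apart,
$\mathrm{Max\Delta PCr} = 133$ µmol/L/day the maximal plausible
creatinine rise at zero GFR, and SSPCr/CrCl the anchor creatinine and
its CKD-EPI eGFR.

The package provides:

* the formula layer: `ckd_epi()`, `kegfr()`, `creatinine_reduction_rate()`;
* rule-based graft-function labels: SGF by the CRR rule
  (CRR crossing 20% with POD3 creatinine > 132 µmol/L), the POD5
  (Humar) variant, and DGF (dialysis within 7 days);
* the trajectory pipeline: measurement pairing, postoperative-day
  assignment, per-day estimate series, exclusion bookkeeping, group
  trajectory slopes, follow-up eGFR (`run_pipeline()` and friends);
* estimator evaluation: ROC/AUC with patient-level bootstrap intervals,
  paired DeLong comparison, ROC01 optimal cutpoints, Bland–Altman
  agreement, follow-up regression, baseline tables
  (`evaluate_cohort()` and friends);
* a mass-balance synthetic cohort simulator with immediate / slow /
  delayed graft-function phenotypes (`cohort_config()`,
  `generate_cohort()`, `recovery_suite()`), so the whole pipeline is
  testable against known ground truth.

## Worked example

Simulate a 326-patient cohort, run the pipeline, and compare the two
estimators at postoperative day 1:

```r
library(kegfr)

cohort <- generate_cohort(cohort_config(n_patients = 326, seed = 1))
pipe <- run_pipeline(cohort$measurements, cohort$patients)
pipe
#> <kegfr_pipeline>
#>   screened: 326
#>   excluded (no POD1 KeGFR): 18
#>   excluded (SGF status indeterminate): 6
#>   analyzed: 302
#>   SGF among analyzed: 77 (25.5%)

evaluate_cohort(pipe, pod = 1, n_boot = 2000, seed = 2)
#> <kegfr_discrimination> POD 1, n = 302 (77 SGF)
#>   KeGFR   AUC 0.980 (CI 0.963-0.995)
#>   CKD-EPI AUC 0.949 (CI 0.924-0.971)
#>   DeLong: z = 2.60, p = 0.00926
#>   ROC01 cutoffs: KeGFR 18.4, CKD-EPI 11.4 mL/min/1.73m2
```

Reading: of 326 screened patients, 24 are excluded (no POD1 kinetic
estimate, or indeterminate SGF status); a quarter of the analyzed
patients are SGF. At POD1 the kinetic estimate discriminates SGF from
non-SGF better than the steady-state equation (higher AUC, paired
DeLong p < 0.01), and its optimal ROC01 cutoff sits near
18 mL/min/1.73 m²: a POD1 KeGFR below that flags a patient likely to
have slow graft function. Because the cohort is simulated, the true GFR
is known, and `recovery_suite()` additionally reports that KeGFR tracks
the true POD1 GFR with a smaller mean absolute error than CKD-EPI.

A thin command-line wrapper for the simulate / estimate / evaluate steps
is installed at `inst/cli/kegfr-cli.R`.

## Documentation

The methods vignette (`vignettes/kinetic-egfr-methods.Rmd`) describes
the estimators and their assumptions, the labelling rules and their
ambiguities, the simulator's mass-balance model and calibration, the
numerical choices, and what the synthetic validation does and does not
establish about real data.
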