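---
title: "Kinetic eGFR after kidney transplantation: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic eGFR after kidney transplantation: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kegfr)
```

## The estimation problem

In the first days after kidney transplantation the glomerular filtration
rate (GFR) of the graft changes by tens of mL/min within hours, while
serum creatinine — the quantity actually measured — needs days to
re-equilibrate. Steady-state estimating equations such as CKD-EPI assume
creatinine is at its equilibrium for the current GFR; applied to a
rapidly falling creatinine they lag far behind the true filtration rate.
Kinetic eGFR (KeGFR) corrects for this by using *two* creatinine
measurements and a mass-balance argument.

This matters clinically because the early graft-function phenotype —
immediate (IGF), slow (SGF) or dialysis-requiring delayed (DGF) graft
function — carries prognostic information, and an estimator that reads
the trajectory correctly on postoperative day (POD) 1 can identify
slow-graft-function patients days before the rule-based label can be
applied.

## The two estimators

**CKD-EPI (2009 creatinine equation).** `ckd_epi()` implements the single
min/max form

$$\mathrm{eGFR} = 141 \cdot \min(S/\kappa,1)^{\alpha}
  \cdot \max(S/\kappa,1)^{-1.209} \cdot 0.993^{\mathrm{age}}
  \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{black}]$$

with creatinine $S$ in mg/dL, $\kappa = 0.7/0.9$ and
$\alpha = -0.329/-0.411$ for women/men. Creatinine is handled in
µmol/L package-wide; the 88.42 µmol/L-per-mg/dL conversion happens only
inside this function. The ancestry coefficient is configurable and **off
by default** (`black = FALSE`); when enabled it is recorded by the caller,
not guessed. The equation is for adults; age below 18 is rejected.

**Kinetic eGFR.** For creatinine $C_a$, $C_b$ measured $\Delta t$ hours
apart,

$$\mathrm{KeGFR} = \left(1 - \frac{24\,(C_b - C_a)}
  {\Delta t \cdot \mathrm{Max\Delta PCr}}\right)
  \cdot \frac{\mathrm{SSPCr} \cdot \mathrm{CrCl}}{0.5\,(C_b + C_a)}$$

where $\mathrm{Max\Delta PCr}$ is the maximal plausible daily creatinine
rise at zero GFR (133 µmol/L/day by default), and SSPCr/CrCl are an
anchor creatinine and its associated CKD-EPI eGFR. The factor 24 converts
the observed rise to a per-day rate: $\Delta t$ is in hours and
$\mathrm{Max\Delta PCr}$ per day. At creatinine steady state
($C_a = C_b = \mathrm{SSPCr}$) the expression collapses exactly to CrCl;
creatinine rising at the maximal rate drives it to zero. Raw negative
values are physiologically meaningless and are clamped to zero with a
`clamped` flag (configurable to raw for diagnostics).

Two conventions deserve emphasis:

* **Pair eligibility.** The kinetic estimate is only computed for pairs at
  most 36 h apart; wider pairs are refused, not silently computed. The
  boundary is inclusive (`delta_hours <= 36`): with daily laboratory
  sampling the distinction between "less than" and "at most" 36 h is
  immaterial, and an inclusive bound keeps exactly-daily pairs eligible.
* **The anchor.** By convention the anchor is the *first creatinine
  recorded after transplantation* with its CKD-EPI value, even though that
  sample is itself not at steady state. This keeps the estimator
  self-contained in the post-operative record. Because the product
  $\mathrm{SSPCr} \cdot \mathrm{CrCl}$ varies only weakly with the anchor
  creatinine (as $S^{-0.209}$), the choice is more robust than it looks,
  but it does bias the kinetic estimate downward when the anchor is very
  high. `pipeline_config(anchor = "baseline")` switches to the last
  pre-transplant value where available; the post-transplant anchor stays
  the default.

## Graft-function labels

The primary SGF rule is: creatinine reduction rate (CRR) between POD1 and
POD3 crossing 20% **and** POD3 creatinine above 132 µmol/L, with
$\mathrm{CRR} = 100\,(C_{POD1} - C_{POD3})/C_{POD1}$.

The direction of the CRR comparison is genuinely ambiguous in the SGF
literature. The rule as printed in recent cohort work reads "CRR **>**
20%": under one-compartment kinetics this selects patients still making
substantial *relative* progress between POD1 and POD3 — i.e. still far
from equilibrium — while fast grafts have already equilibrated by POD1
and show a small POD1→POD3 CRR. Older descriptions of SGF emphasise a
*low* creatinine reduction rate instead. Both readings are implemented
(`crr_comparator = "gt"` / `"lt"`); the printed `"gt"` form is the
default, and the package does not guess which reading a given study
actually ran. A missing creatinine always yields an explicit
`indeterminate` status, never a silent non-SGF.

The alternative historical (Humar) definition — POD5 creatinine strictly
above 264 µmol/L — and the DGF rule (any dialysis within seven days of
transplantation) are provided alongside. SGF is labelled independently of
dialysis by default, since dialysed patients can and do meet the SGF
rule; `exclude_dgf = TRUE` gives the strict variant.

**POD assignment.** Daily values are rarely timestamped exactly 24k hours
after surgery. POD k is defined as the measurement closest to
$k \times 24$ h within ±12 h, earliest on ties. The window half-width is
configurable; ±12 h tiles the acute phase without gaps or overlap.

## Pipeline rules

* KeGFR at POD k uses the pair *ending* at the POD k measurement, with
  the immediately preceding measurement as the first element — the most
  local choice, taken because daily sampling leaves no shorter candidate.
* Pairs spanning a dialysis session are excluded from kinetic estimation
  by default: dialysis removes creatinine non-renally, so the mass
  balance underlying the formula does not hold across a session.
* The exclusion flow mirrors clinical cohort practice: patients without a
  POD1 kinetic estimate are excluded first, then patients whose SGF
  status cannot be established. The run manifest preserves the
  bookkeeping identity screened = analyzed + both exclusion counts.
* Follow-up eGFR uses windows (in days) of [60, 120), [150, 210) and
  [330, 400) for the 3/6/12-month visits, nearest-to-centre within a
  window, with absence simply propagating (complete-case analyses
  downstream; no imputation anywhere in the package).

## Evaluation choices

* **Orientation is declared, never auto-flipped.** Lower eGFR indicates
  slow graft function; the same orientation is applied to both
  estimators, and an AUC below 0.5 would be reported as such. Predictions
  use score ≤ cutoff ⇒ positive.
* **AUC** is the midrank Mann–Whitney statistic (ties count one half),
  which equals exhaustive positive/negative pair counting; the test suite
  asserts this equivalence directly.
* **Confidence intervals** are percentile bootstrap over patients, 2000
  replicates by default, with a mandatory seed.
* **Paired AUC comparison** uses the DeLong structural-components
  covariance with a two-sided normal reference. It is checked in the
  suite against both an independent implementation (pROC) and a
  per-patient swap permutation oracle. The within-patient pairing of the
  two scores is required, not assumed.
* **ROC01 cutoff**: the threshold minimising
  $\sqrt{(1-Se)^2 + (1-Sp)^2}$, ties broken towards higher sensitivity
  and then the lower threshold, with PPV from the confusion table at the
  selected cutoff.
* **Baseline tables**: continuous variables as median (Q1, Q3) with
  Wilcoxon rank-sum, categorical as count (%) with Fisher's exact test,
  Holm-adjusted across all rows of the table (the adjustment family is
  the whole table, a deliberately conservative reading).

## The cohort simulator

Because real transplant-cohort records are not freely available, the
package ships a generator whose defaults are the study conditions the
rest of the package is validated under.

**Kinetics.** Latent creatinine follows the one-compartment mass balance
$V\,dc/dt = G - k\,g(t)\,c$ with $k = 1.44$ L/day per mL/min (1 mL/min =
1.44 L/day, with body-surface indexing absorbed by working throughout in
mL/min/1.73 m²). Two calibration decisions tie the simulator to the
estimators it exercises:

* $G$ is chosen per patient so that the long-term steady state is
  *consistent with CKD-EPI*: given the true one-year GFR $g_1$ and
  demographics, the steady-state creatinine $c_1$ solves
  $\mathrm{CKDEPI}(c_1) = g_1$ and $G = 1.44\,g_1 c_1$. This replaces an
  anthropometric generation-rate formula: it guarantees that at
  equilibrium the steady-state estimator is unbiased, so any acute-phase
  advantage of the kinetic estimator is attributable to kinetics, not to
  a mismatch between the simulator's creatinine scale and the equation.
* $V = G / 120$, i.e. the latent rise at zero GFR is exactly
  120 µmol/L/day — inside the 133 µmol/L/day bound the kinetic formula
  assumes. $V$ is therefore an *effective* volume (typically 50–90 L,
  larger than anatomical), a deliberate trade: the simulator stays in the
  regime where the formula's maximal-rise assumption holds, at the cost
  of somewhat slower equilibration than real patients show.

**Phenotypes.** IGF: exponential GFR rise with a 0.25-day time constant
to a plateau that clears creatinine to a normal-range target
(65–90 µmol/L) — immediate function is *defined* by prompt creatinine
normalisation, and the plateau may exceed the one-year GFR (early
hyperfiltration before maintenance immunosuppression settles). SGF:
linear GFR rise from 8–15 mL/min at 6–10 mL/min per day. DGF: GFR below
4 mL/min for the acute phase with dialysis sessions at days 1.7/3.7/5.7,
each applying an instantaneous 40% creatinine reduction (crude, but
sufficient to exercise the dialysis-pair exclusion logic). Phenotype
frequencies are conditional on donor type (SGF concentrated in deceased
donation) with marginals near 0.75/0.23/0.02, and the SGF/DGF phenotypes
carry −10/−15 mL/min/1.73 m² one-year deficits.

**Heterogeneity.** Creatinine at transplantation is lognormal
(median 650, log-SD 0.35, range 200–1500 µmol/L) independent of the
graft phenotype, and daily labs are jittered ±6 h. These two spreads are
what degrade the steady-state estimator at POD1 in practice — the POD1
creatinine reflects the starting point and the sampling time as much as
the graft — while the kinetic estimator normalises both away (the anchor
product varies only as $S^{-0.209}$, and the slope term divides by the
actual $\Delta t$).

**Noise and missingness.** Multiplicative lognormal measurement noise
with 5% SD (a typical Jaffé assay CV), 2% missingness per acute
measurement and 10% per follow-up visit. Measured values are rounded to
0.1 µmol/L as a laboratory would report them.

**Follow-up shortcut.** The acute phase (days 0–5) is integrated with a
fixed-step solver; follow-up samples are drawn from the analytic steady
state $c_1$ instead of integrating to day 400. With a creatinine time
constant under one day, the quasi-steady value is exact to well below
the measurement noise by month 3.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: rejection episodes and other
non-monotone GFR trajectories, calcineurin-inhibitor pharmacology, assay
recalibration drift, muscle-mass changes during recovery (creatinine
generation is constant per patient), informative missingness, and
residual native-kidney function. Discrimination on the synthetic cohort
(AUCs around 0.95–0.98) is accordingly cleaner than any real cohort
would show; the package treats the AUC *ordering* and error *ordering*
between estimators as the transportable findings, not the absolute
values.

## Numerical choices

* Integration: classical fourth-order Runge–Kutta on a fixed grid with
  step at most 0.01 day (the whole cohort is integrated as one vector
  ODE via deSolve, with dialysis as multiplicative events). The suite
  checks the analytic steady state to <1% by day 20 and self-convergence
  to <0.1% under step halving.
* All sampling times are aligned to the solver grid; matching uses
  rounded keys to avoid floating-point misses.
* The degenerate single-POD group in trajectory fits is reported with an
  `NA` slope, not dropped; rank-deficient regression fits keep aliased
  terms as `NA` rows with a warning.
* Determinism: a seed is mandatory for the generator and the bootstrap;
  the same seed reproduces generated tables byte-for-byte, and the
  pipeline itself is deterministic (fixed ordering, no RNG).

## Validation design and problem sizes

The acceptance layer of the test suite re-derives every statistic by an
independent route: hand-evaluated kinetic-formula arithmetic on a
randomized grid (relative tolerance 1e-9); the CKD-EPI piecewise
published form on a 500-point grid (0.1 mL/min/1.73 m²); exhaustive
pair-counting, threshold-scan and hypergeometric enumeration oracles; a
10⁴-swap permutation oracle for the DeLong p; and ground-truth recovery
on simulated cohorts. The simulation sizes — 20 seeds of 2000 patients
for the discrimination ordering, 50 replicates of 300 patients for the
effect-recovery coverage, 200 replicates for bootstrap coverage — were
chosen to make the Monte-Carlo error of each checked proportion small
relative to its acceptance margin while keeping the default suite fast
on a laptop.

One subtlety of the end-to-end effect recovery: the regression
conditions on the *rule-based label*, not the generating phenotype, so
label/phenotype disagreement (2–3% at default noise) attenuates the
recovered SGF coefficient slightly (typically to −9 ± 2 for an injected
−10). The 95% interval covers the injected value in well over 90% of
replicates at n = 300, which is the property the suite asserts; an exact
point recovery would require regressing on the phenotype, which real
data never provides.

## Known limitations

* The anchor convention inherits the non-steady-state first creatinine;
  the package implements it as the field uses it and documents the bias
  rather than silently "improving" it.
* The CRR comparator ambiguity is exposed, not resolved.
* The 2009 CKD-EPI equation (with optional ancestry coefficient) is the
  only steady-state equation provided; MDRD, the 2021 race-free refit,
  and cystatin-C equations are out of scope.
* Bootstrap intervals are percentile intervals; no BCa correction.
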