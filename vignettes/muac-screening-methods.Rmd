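---
title: "Methods: MUAC screening accuracy for adolescent thinness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MUAC screening accuracy for adolescent thinness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muacscreen)
```

## The problem

Thinness in adolescents is defined against a growth reference: a girl is
thin when her BMI-for-age z-score (BAZ) falls below −2, severely thin
below −3. Computing BAZ requires height, weight, her exact age and a
reference table — a burden in field settings. Mid-upper arm circumference
(MUAC) needs one tape measure and no arithmetic. `muacscreen` quantifies
how well a MUAC threshold reproduces the BAZ classification: the package
covers the scoring of the reference standard, the estimation of the
optimal MUAC cutoff with its diagnostic accuracy profile, the reliability
of the underlying measurements, and the design of such a study.

## Growth-reference scoring

The LMS method models a measurement's age-specific distribution by a
Box–Cox power `L`, median `M` and coefficient of variation `S`, giving

\[ z = \frac{(X/M)^L - 1}{L\,S}, \qquad z = \frac{\log(X/M)}{S} \ \text{when } L = 0 . \]

`lms_z()` implements this with the exact continuity limit at `L = 0`;
`inverse_lms()` is its closed-form inverse (round-trip verified to 1e-9
in the tests). Lookups are by *completed* month with no interpolation,
matching how WHO reference software indexes its monthly tables; ages are
floored to completed months (`exact_age_months()`), and a birthday
day-of-month that does not exist in the target month (the 31st in
February) counts as not yet reached.

Beyond ±3 SD the raw z-score is highly sensitive to the tails of the
fitted reference distribution, so `restricted_z()` follows the WHO
convention of rescaling linearly in the measurement: above +3,
`z* = 3 + (x − SD3)/(SD3 − SD2)`, symmetrically below −3. The adjustment
never moves a value across the ±3 boundary, so categories are unchanged;
a flag records where it applied and `baz(..., restricted = FALSE)`
disables it.

Categories follow the WHO 2007 inequalities: z < −3 severe thinness,
−3 ≤ z < −2 thinness, −2 ≤ z ≤ +1 normal, +1 < z ≤ +2 overweight,
z > +2 obesity. The overweight/obesity boundaries are sometimes printed
inconsistently in the applied literature; this package pins them to the
WHO convention and the tests assert every boundary value exactly.

## Diagnostic accuracy

MUAC screens in the *positive-if-low* direction: a value at or below the
cutoff is test-positive (the inclusive boundary matches how report
tables print "≤ c" cutoffs). `roc_curve()` sweeps every distinct
observed value plus the two degenerate sentinels and computes the
trapezoidal AUC over (1 − specificity, sensitivity). This trapezoid is
algebraically identical to the tie-corrected Mann–Whitney statistic
(ties counted one half) — the tests verify the identity exhaustively on
random small instances rather than trusting the algebra.

The optimal cutoff maximises Youden's J = SN + SP − 1. Ties are broken
first by higher sensitivity (a screening tool should prefer not to miss
cases), then by the smaller cutoff. At the chosen cutoff the package
reports the full 2×2 metric set with interval methods chosen as
standard epidemiological practice, since applied papers rarely name
them:

* sensitivity, specificity, predictive values, accuracy —
  Clopper–Pearson exact binomial intervals (`clopper_pearson()`;
  coverage ≥ nominal by construction, verified by simulation);
* likelihood ratios — the log-method interval
  exp(log LR ± z·se) with the usual delta-method standard errors
  (`lr_ci()`); zero cells flag the interval rather than erroring;
* AUC — the DeLong placement-value variance estimator (`auc_ci()`),
  truncated to [0, 1], cross-checked against an independent
  implementation in the test suite.

AUC interpretation bands are fail (< 0.6), poor, fair, good and
excellent (≥ 0.9), half-open with the top band closed.

## Measurement reliability

Duplicate measurements are averaged for analysis (`average_replicates()`;
a single missing replicate falls back to the present value, both missing
is an error). Their agreement is summarised two ways:

* technical error of measurement, TEM = √(Σd²/2n), an absolute
  imprecision in measurement units that estimates the per-replicate
  error SD (parameter recovery within ±10% at n = 5000 is a test), and
  its relative form as a percentage of the grand mean of all
  measurements in scope;
* a two-sided paired t-test of first versus second measurement
  (`paired_ttest()`), with zero-variance differences reported as a
  degenerate flag rather than an error so that perfectly repeated
  measurements can still be tabulated.

Correlations use the sample Pearson r with the Fisher-z interval and
Cohen's interpretation bands (|r| < 0.1 negligible, to 0.3 weak, to 0.5
medium, 0.5–1 strong; boundaries half-open, upper band closed — so
r = 0.5 reads "strong").

## Study design

`diag_sample_size()` implements the standard diagnostic-accuracy
formulas: N1 = ⌈z² SN(1−SN)/(L²P)⌉ for sensitivity and
N2 = ⌈z² SP(1−SP)/(L²(1−P))⌉ for specificity, the larger inflated by a
design effect for multistage sampling and by non-response. Ceiling is
applied at each stage. Non-response inflation is multiplicative
×(1 + rate) by default; the divisive convention ÷(1 − rate) is a flag,
since both circulate in practice. With anticipated SN 94%, SP 79%,
prevalence 21.3%, precision 5%, design effect 2 and 10% non-response
these formulas give N1 = 407, N2 = 324 and a final size of 896; field
studies sometimes quote slightly different final figures from the same
inputs (rounding conventions and feasibility adjustments vary), and the
package makes no attempt to reproduce any particular published total
beyond its own stated arithmetic.

## The synthetic cohort generator

No individual-level adolescent dataset ships with the package, so
validation rests on a generator whose defaults describe the kind of
school-based cohort the methods target: n = 884 girls, ages uniform over
120–179 completed months, BAZ ~ N(−0.84, 1.30) giving a thinness
prevalence of Φ((−2 + 0.84)/1.30) ≈ 18.6%, mean MUAC 20.7 cm with total
SD 2.5 cm, MUAC rising 0.9 cm per year of age, and a target population
correlation of 0.80 between MUAC and BAZ.

The MUAC model is linear,

\[ \mathrm{MUAC} = \beta_0 + \beta_1\,\mathrm{age}_c + b\,(z - \mu_z) + e, \]

with z independent of age. `solve_muac_coefficients()` sets
b = ρ·σ_total/σ_z and σ_e² = σ_total² − b²σ_z² − β1²σ_age², which makes
corr(MUAC, z) = ρ and Var(MUAC) = σ_total² hold *exactly* in the
population — the calibration is closed-form, not fitted — and raises a
configuration error naming the violated constraint when the target is
infeasible (e.g. ρ = 0.99 with the default variance budget). Keeping
BAZ independent of age is what makes this closed form possible; real
cohorts show mild age trends in BAZ, which the generator deliberately
omits.

Height is linear in age (150 cm at age 12, 3.3 cm/yr, residual SD 6 cm
— a realistic within-age spread; reported single-age height SDs in
field tables are sometimes printed in metres). BMI is the inverse LMS
transform of the latent z on the bundled reference, and weight follows
as BMI·(height/100)², so scoring a noise-free generated record recovers
the latent z exactly (a test). Each instrument is then measured twice as
truth plus iid Normal error (MUAC 0.15 cm, height 0.3 cm, weight
0.1 kg), sized so the relative TEM lands well inside anthropometric
acceptability.

One master seed drives fixed substreams per sampled quantity (ages,
latent z, residuals, each replicate), so changing one error parameter
never perturbs the other draws, and the same seed is byte-identical.

The bundled LMS fixture (`synthetic_lms()`,
`inst/extdata/synthetic_lms.csv`) uses smooth plausible curves —
L = −1.4, S = 0.11, M = 16 + 0.04·(month − 120) — and is explicitly
*not* the WHO 2007 reference; analyses of real data should pass the
real WHO table to `read_lms()`. Consequently the generator validates the
machinery (correlation and AUC recovery, TEM recovery, round-trips,
denominators), not population-specific cutoff values: a cutoff estimated
on synthetic data is not a field recommendation.

`binormal_case_control()` provides controlled-truth ROC inputs: cases
N(μ − δ, σ) against controls N(μ, σ) with δ = σ√2·Φ⁻¹(AUC*), so the
population AUC in the positive-if-low direction equals the target
exactly; the tests and the acceptance script recover 0.86 to within
±0.02 over 20 replicates of n = 884.

## The analysis pipeline

`run_analysis()` chains validation → replicate averaging → BAZ scoring →
four condition definitions (thinness including severe, severe thinness,
thinness only, overweight including obesity) × six strata (ages 10–14
and pooled), and emits descriptive, reliability, correlation, category
and diagnostic tables plus per-stratum ROC coordinates
(`write_report_bundle()`; full precision in a JSON sidecar, CSV cells
rounded half-up only at serialisation). Two definitional choices are
explicit because the field literature leaves them open:

* For the "thinness only" condition the control group excludes severely
  thin girls by default (they are neither case nor control); a switch
  (`builtin_conditions(thinness_only_excludes_severe = FALSE)`) counts
  them among the cases instead, collapsing the condition into "thinness
  including severe".
* A stratum lacking a case or a control is flagged not estimable and
  the run continues; all-tied strata yield AUC 0.5 with a flagged
  degenerate interval.

The pipeline is fully deterministic: all randomness lives in the
generator, so re-running `analyze` on the same inputs is byte-identical
(asserted in the tests).

## Numerical choices and problem sizes

Report percentages round half away from zero (`round_half_up()`), the
convention of epidemiological report tables, at 1 decimal for
percentages and cutoffs and 2 for ratios, J and AUC. Thresholds are the
observed distinct values — no 0.1 cm re-gridding — with rounding applied
only at presentation. The validation suite sizes its simulations for
tight-but-fast checks: 20 replicate cohorts of n = 884 for parameter
recovery, n = 5000 for TEM recovery, 2000 replicates for
Clopper–Pearson coverage, 200 for DeLong coverage, and exhaustive
oracles at n ≤ 30 for the AUC and Youden identities.

## Limitations

* The generator omits puberty/maturation biology, school clustering,
  socio-economic covariates and BAZ–age trends; passing tests show the
  estimators are correct, not that any particular cutoff generalises.
* Only BMI-for-age is scored (no height-for-age or weight-for-age), and
  the analysis is female-only by default, though reference tables are
  pluggable by sex.
* Youden's J is the only cutoff criterion (no closest-to-(0,1) or
  cost-weighted selection), and there is no partial AUC.
* ICC and Bland–Altman reliability analyses are out of scope; TEM and
  the paired t-test are what is provided.
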