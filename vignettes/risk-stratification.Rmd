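---
title: "Risk stratification for suspected common bile duct stones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification for suspected common bile duct stones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbdrisk)
```

## The clinical problem

ERCP (endoscopic retrograde cholangiopancreatography) is both the
diagnostic gold standard and the treatment for stones in the common bile
duct (CBD), but it is invasive: pancreatitis, bleeding and perforation
are all recognised complications, and a substantial fraction of ERCPs
performed for suspected stones find none. Professional societies have
therefore published rule-based criteria that stratify patients into
high (HR), intermediate (IR) and low risk (LR) using nothing but
bedside information: liver function tests, transabdominal ultrasound
and the clinical diagnosis of ascending cholangitis. `cbdrisk`
implements three such criteria — SAGES, ASGE 2019 and ESGE — and the
machinery to evaluate any of them against an ERCP outcome on
patient-level tabular data.

## The three criteria

All three rules consume the same boolean factors, derived by
`derive_factors()` from raw fields with **strict** threshold
comparisons (a 6.0 mm duct is not dilated; a bilirubin of exactly
1.7 mg/dL is not elevated):

| factor | definition (defaults) |
|---|---|
| `imaging_stone` | echogenic focus with acoustic shadow in the CBD on ultrasound |
| `dilated_cbd` | CBD diameter > 6 mm |
| `cholangitis` | ascending cholangitis (Charcot's triad, adjudicated upstream) |
| `tb_over_sages` | total bilirubin > 1.7 mg/dL |
| `tb_over_asge` | total bilirubin > 4 mg/dL |
| `lft_abnormal` | any of bilirubin/ALT/AST/ALP above reference range |
| `age_over_asge` | age > 55 years |

Cholangitis is deliberately a recorded boolean rather than something
re-derived from fever/pain fields: it is a clinical diagnosis made
upstream of the rules. Likewise `lft_abnormal` may be supplied directly
(covering transaminase or alkaline-phosphatase derangement, for which
no reference ranges are configured here); a bilirubin above the 1.7
cut-off forces it `TRUE` regardless.

The rules themselves:

* **SAGES** counts four factors — imaging stone, dilated duct,
  cholangitis, bilirubin > 1.7 — and assigns HR for ≥ 2, IR for exactly
  1, LR for 0. The strata are exclusive by construction.
* **ASGE 2019** assigns HR for imaging stone, cholangitis, or
  (bilirubin > 4 *and* dilated duct); its IR factors are abnormal LFTs,
  age > 55, or dilated duct.
* **ESGE** assigns HR for cholangitis or imaging stone; IR for abnormal
  LFTs or dilated duct.

The ESGE HR disjunction is a subset of the ASGE one, so ESGE-HR implies
ASGE-HR — a property the test suite asserts on simulated cohorts.

## Two assignment policies

For ASGE and ESGE the published IR factors are near-universal in a
symptomatic cohort (almost everyone has a deranged LFT or a dilated
duct), so IR *membership* overlaps heavily with HR membership and the
three labels do not partition the cohort. `cbdrisk` therefore carries
both readings side by side in every assignment:

* `exclusive_stratum` — the HR > IR > LR hierarchy; always a partition.
* `meets_hr`, `meets_ir`, `meets_strict_lr` — independent indicator
  memberships; `meets_strict_lr` is true only when no listed factor is
  present.

This is a genuine design decision, not a convenience. Published stratum
counts for criteria of this family are only mutually consistent when
the HR count is read exclusively, the IR count as indicator membership,
and the LR count — for ASGE — as the *complement of HR* rather than the
strict "no factor present" definition. The evaluation report records
which policy each row uses in its `policy` column (`exclusive`,
`indicator`, `complement_of_hr`, `strict`), so no number is ever
ambiguous about its denominator. The definitional tension between
"LR = none of these factors" and "LR = everyone not high risk" is a
property of the source criteria as used in practice; we expose both
rather than resolving it.

## Evaluation design

`evaluate_cohort()` scores, for each criterion:

* the **HR stratum as a predictor of stone presence** (exclusive HR for
  SAGES, `meets_hr` for ASGE/ESGE),
* the **IR stratum as a predictor of stone presence** (exclusive for
  SAGES, indicator for ASGE/ESGE), and
* the **LR stratum as a predictor of stone absence** — the outcome is
  inverted, so "true positive" means low-risk and stone-free
  (exclusive LR for SAGES, complement-of-HR for ASGE, strict LR for
  ESGE).

Each row carries the full 2×2 table and sensitivity, specificity, PPV,
NPV and accuracy. A metric whose denominator is zero (e.g. PPV of an
empty stratum) is returned as `NA` and named in an `undefined` field —
never silently coerced to 0.

**AUC of a binary indicator.** A yes/no predictor has one operating
point; its ROC curve is the three-point polyline
\((0,0)\rightarrow(1-\mathrm{spec},\ \mathrm{sens})\rightarrow(1,1)\)
and the trapezoidal area reduces algebraically to
\((\mathrm{sens}+\mathrm{spec})/2\). This is what `binary_auc()`
computes, and it is the quantity usually reported when a risk stratum
is treated as a test. No rank-based AUC over a continuous score exists
in this design; the test suite nevertheless cross-checks the value
against a general-purpose ROC package on expanded 0/1 scores.

**Confidence intervals.** `auc_ci()` uses the Hanley–McNeil normal
approximation with \(Q_1 = A/(2-A)\), \(Q_2 = 2A^2/(1+A)\) and
\[
SE^2 = \frac{A(1-A) + (n_+-1)(Q_1 - A^2) + (n_--1)(Q_2 - A^2)}{n_+ n_-},
\]
clipped to \([0,1]\). Different statistics packages use different AUC
variance estimators, and intervals published alongside binary-indicator
AUCs rarely state which; Hanley–McNeil is the textbook default and is
hand-verified in the tests, but interval bounds should not be expected
to reproduce any particular third-party output to the last digit.

**Association tests.** `chi_square_p()` is the Pearson chi-square for
the 2×2 table *without* continuity correction, on 1 df. The
no-correction choice matters for small cells (a table like
`{2,0,28,60}` is significant at 0.043 without correction and not with
it) and matches how such tables are conventionally reported in the
diagnostic-accuracy literature. Tables with a zero margin return an
undefined-flagged result. The implementation is the closed-form
statistic; tests compare it against a brute-force expected-count
summation and against `stats::chisq.test(correct = FALSE)` to 1e-10.

**Sample size.** `sample_size_accuracy()` is the standard
normal-approximation formula \(n = \lceil z^2 p(1-p)/d^2 \rceil\) for
estimating a proportion \(p\) to absolute margin \(d\). Note that for
an expected accuracy of 70% this gives 323 at a 5% margin and 81 at a
10% margin; studies quoting a calculated size near 80 "at 5%" have, in
effect, used a 10% margin. We implement the standard formula and leave
the arithmetic to the caller.

## The reference cohort

`reconstruct_cohort()` deterministically builds a 90-patient synthetic
cohort (60 ERCP-confirmed stones) whose joint factor structure
satisfies the 23 count constraints listed by `cohort_constraints()`:
marginal factor prevalences (66 imaging stones, 77 dilated ducts, 11
cholangitis), the exclusive SAGES strata 69/19/2 with 56/4/0 stones,
ASGE and ESGE high-risk counts 68 and 67 each carrying 58 stones, the
87-patient IR indicator memberships, and the 2 factor-free low-risk
patients. These constraints logically entail every confusion-table
cell the evaluation produces, so *any* cohort passing
`verify_cohort()` yields the same accuracy tables; the shipped cohort
is one convenient witness, built by hand from twelve archetype groups
rather than by search, and frozen both in code and as
`inst/extdata/reference_cohort_synthetic.csv`.

Fields the constraints do not pin are representative fill: one
bilirubin value per threshold class (e.g. 2.6 mg/dL for "elevated but
under 4"), duct diameters cycling through a few plausible values per
group, a deterministic age formula capped below 56 for the three
patients whose IR-indicator membership would otherwise change, and a
fixed male/female interleave. They make the table realistic to look at;
no criterion or metric depends on them beyond the threshold class.

```{r}
all(verify_cohort(reconstruct_cohort())$pass)
evaluate_cohort(reconstruct_cohort())
```

## The synthetic-cohort generator

`simulate_cohort()` is a seeded generative model for property tests and
power exploration, *not* a model of biliary disease. Stone status is
Bernoulli(prevalence); imaging is a conditional detection coin
(default 0.95 sensitivity / 0.30 false-call rate, chosen to match the
reference cohort's marginals of 57/60 and 9/30); cholangitis occurs
only in stone carriers (default rate 11/60); duct diameter is normal
(11 ± 2.7 mm with stone, 7 ± 3 mm without, floored at 2 mm — a duct
diameter cannot vanish); total bilirubin is log-normal (right-skewed,
strictly positive, the natural choice for a bilirubin); an extra
Bernoulli(0.30) derangement models transaminase/ALP abnormality
independent of bilirubin; age is truncated normal around 45 ± 15 years.

What the generator does **not** emulate: correlation between duct
diameter and bilirubin beyond their common dependence on stone status,
stone size or number, the selection process that put patients on an
ERCP list in the first place, and any site or operator effect on
ultrasound. Consequently, passing parameter-recovery tests shows the
pipeline computes what the generative model implies — e.g. ESGE HR
sensitivity converging to
\(1-(1-p_{\mathrm{chol}})(1-p_{\mathrm{img|stone}})\) at n = 100,000 —
not that any criterion performs identically on real patients.

## Numerical and interface choices

* Strict inequalities everywhere; boundary values fall on the
  non-factor side. This follows the "more than" wording of the
  operational definitions.
* The HR > IR > LR hierarchy is the only tie-break; it is total, so
  stratification is deterministic.
* Display rounding (percentages to 1 decimal, AUC to 3) is confined to
  the text renderer; CSV/JSON exports and all internal values are full
  precision.
* CSV booleans are 0/1; empty cells are missing data and any missing
  required field is an error naming the field and patient. Unknown CSV
  columns ride along untouched.
* The report's provenance block records thresholds, package version and
  an order-sensitive content digest of the input, so a report can be
  matched to its cohort.
* Problem sizes in the shipped tests: cohorts of 90–500 for
  property checks, 1,000 random 2×2 tables for the chi-square oracle,
  and a single 100,000-patient cohort for parameter recovery; the whole
  suite and the end-to-end pipeline are fast enough to run on every
  commit.

## Known limitations

* The criteria are implemented exactly as worded in their operational
  form here; sub-variants (e.g. alternative ASGE bilirubin/cholangitis
  nuances across guideline revisions) are out of scope.
* Hanley–McNeil intervals are reported, not validated against any
  external implementation, for the reason given above.
* LR strata have very different meanings across criteria (strict vs
  complement-of-HR); cross-criterion comparison of "LR accuracy" should
  always quote the `policy` column.
* The reference cohort is a reconstruction: individual-level fields not
  pinned by the count constraints are representative, and analyses that
  depend on them (age effects, sex differences) would be meaningless on
  it.
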