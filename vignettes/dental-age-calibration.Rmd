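---
title: "Dental age estimation and population-specific calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental age estimation and population-specific calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalage)
```

## The problem

Radiographic dental age estimation assigns each of the seven left permanent
mandibular teeth (FDI 31–37) one of eight developmental stages, A (first
cusp calcification) to H (apical closure), read from a panoramic
radiograph; a pre-calcification state, coded `0`, precedes A. Each (sex,
tooth, stage) combination carries a "self-weighted" score; the scores sum
to the **dental maturity score** (DMS), normalised so that full maturity —
all seven teeth at H — equals 100. A sex-specific conversion table maps the
DMS to an **estimated dental age** (EDA). The difference EDA − CA between
the estimate and the child's **chronological age** (CA, date of radiograph
minus date of birth) measures how well reference standards built on one
population transfer to another; a systematic positive difference means the
standard overestimates age in the population under study.

This package implements that pipeline end to end — staging with
contralateral substitution, maturity scoring, score-to-age conversion,
age-group-stratified accuracy assessment, calibration of a
population-specific prediction equation, rater reliability, and survey
sample-size planning — together with a seeded synthetic-cohort generator so
every stage is testable without access to radiographs.

## Cohort handling

CA is the exact day count between dates divided by 365.25, reported to two
decimals. The rounding rule for the final digit is not standardised in the
clinical literature; `compute_chronological_age()` rounds **half-up** by
default (the convention of clinical age tables) and offers half-even and
full precision as options.

Ages are stratified into eight yearly groups, `3 to <4` … `10 to <11`,
closed at the lower bound and open at the upper (an "exclusive-type" class
interval): a child of exactly 4.00 years belongs to `4 to <5`. Records
whose *estimated* age falls below 2.5 years — the lower end of the
estimation range — are excluded after estimation, with an exclusion log, in
the order the study design prescribes: eligibility screening first, then
radiograph interpretation, then the below-range exclusion.

## Staging and scoring

When a left tooth is missing or unreadable, the stage of its contralateral
counterpart (41–47) is substituted; substitution never leaves the mandible.
A record in which some tooth is missing on both sides is unscorable and is
logged out, mirroring the exclusion of poor-quality radiographs.

Score tables are **data, not code** (`sex`, `tooth`, `stage`, `score` CSV);
loading validates completeness, within-tooth monotonicity, a zero score for
the pre-calcification state, and the full-maturity sum of 100 per sex, and
fails naming the offending cell. Because the canonical published score and
conversion tables are not reproduced here, the packaged files
(`score_table_synthetic.csv`, `conversion_table_synthetic.csv`) are
clearly-labelled **synthetic stand-ins** with the same structure and
realistic weights; users with access to a published edition can drop in
their own CSV without touching code.

## Conversion and the prediction model

Score-to-age conversion interpolates linearly between the table's knots
(the published percentile curves are smooth, but no functional form is
given, so the piecewise-linear rule is the least-assumption choice; it is
exact at knots and monotone). Scores outside the table raise an error by
default; a clamping policy is available for pipeline use.

The population-specific prediction equation is the logistic growth curve

$$\mathrm{CA} = \frac{1}{a + b\,c^{\mathrm{DMS}}}, \qquad a, b > 0,\; 0 < c < 1,$$

a bounded, strictly increasing function of the maturity score with upper
age asymptote $1/a$. The published coefficients — males
$(a, b, c) = (0.083, 0.351, 0.969)$, females $(0.083, 0.350, 0.970)$ — are
stored at their printed three-decimal precision, with no hidden digits
(`default_prediction_models()`). The algebraic inverse
$\mathrm{DMS} = \ln((1/\mathrm{CA} - a)/b)/\ln c$ is defined for any age in
$(0, 1/a)$; ages below the zero-score prediction $1/(a+b)$ invert to
negative scores, which are flagged on the forward pass rather than
forbidden on the inverse.

## Calibration

The term "logistic regression" in this literature means logistic **curve
estimation** (the growth curve above), not binary-outcome regression; only
the former is implemented. Two fitting modes are provided because the
original procedure is not fully specified:

* **Fixed asymptote**: with $u = 1/a$ known, the model linearises to
  $\ln(1/\mathrm{CA} - 1/u) = \ln b + \mathrm{DMS}\ln c$ and ordinary least
  squares gives $b$ and $c$. Both published $a$ values being 0.083
  ($\approx 1/12$) hints that the original fit may have fixed a 12-year
  asymptote, but this is unconfirmed, so it is an option, not the default.
* **Free asymptote** (default): full nonlinear least squares over
  $(a, b, c)$ by Levenberg–Marquardt, initialised from the linearised fit
  with a provisional asymptote of $1.05 \times \max(\mathrm{CA})$ and
  box-constrained to the model's invariants. On noiseless data the two
  modes agree to $10^{-6}$.

Fit quality is reported as $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ on the age
scale and Spearman's rank correlation (mid-ranks for ties; t-approximation
p-value, exact permutation available up to $n = 8$, where full enumeration
is still cheap). Both individual-child pairs and group means can be fitted;
the package's drivers use individual pairs.

## Accuracy assessment

Each age–sex stratum is summarised by means and sample SDs ($n-1$) of CA
and EDA, their mean difference, and an independent-samples t-test.
`compare_from_summary()` computes the test from summary statistics alone,
which is what reproducing a printed table requires; `compare_group()` is
the raw-data wrapper, and both agree to $10^{-12}$. Student's
pooled-variance form is the default, with Welch's unequal-variance form
behind a flag. It is worth noting that the published per-group p-values are
reproduced markedly better by the Welch variant (unsurprising when the EDA
SD is several times the CA SD), so the package's fixture tests check the
printed p-values against that variant. P-values are labelled by the
four-level convention (non-significant at $p \ge 0.05$ through very highly
significant at $p < 0.001$), boundary-inclusive at 0.05. Strata with a
single child are reported descriptively with the test omitted. No
multiple-testing correction is applied across strata, matching the source
analysis. Whole-sample bias is summarised by OLS of EDA − CA on CA plus
the overall mean and SD of the differences.

## Reliability

A `round(0.20 * n)` subsample (half-up; 32 of 160) is re-scored and
compared by: percent exact-stage agreement with counts of one-stage-ahead
and one-stage-behind discrepancies; unweighted Cohen's kappa with the
large-sample normal test against zero agreement (Fleiss' null standard
error); and the Pearson correlation of test and retest maturity scores.
Kappa is computed on stage labels pooled across all seven teeth — the
published report does not say per-tooth or pooled, so pooled is the default
and a per-tooth breakdown is always emitted. The degenerate case of two
constant identical ratings (chance agreement 1) reports kappa 1 with an
explicit degeneracy flag.

## Sample size

`required_sample_size()` implements the finite-population proportion
formula $n = \mathrm{DEFF}\,N p(1-p) / [\tfrac{d^2}{Z^2}(N-1) + p(1-p)]$
with a conservative ceiling; $Z$ is supplied directly (1.96 default), as in
the survey calculators this mirrors. With $N = 420$ and maximum-variance
$p = 0.5$ it gives 201.

## The synthetic-cohort generator

The generator emulates the *statistical* structure the analysis assumes —
nothing biological. Per (sex, group) cell it draws CA uniformly within the
yearly interval (inset 0.01 years so date-derived rounding cannot move a
child across a group boundary), forms a latent dental age
CA + bias + Gaussian noise, inverts the conversion table to a latent
maturity score, quantises that score into per-tooth stages, and lays dates
on a first-of-month grid so the day-count CA reproduces the drawn value to
two decimals. Defaults are the study conditions and were fixed once:

* group sizes: the published distribution (74 males, 86 females);
* per-group biases: the published mean differences (years);
* age-noise SD 0.30 years — the level at which published-coefficient
  recovery is specified, and comparable to the published per-group EDA SDs;
* `missing_left_rate` 0.05 (occasional missing left tooth with the
  contralateral readable), `missing_both_rate` 0 (the study excluded
  unscorable radiographs before analysis);
* `rater_flip_rate` 0.10 per tooth for retest simulation, chosen to
  reproduce the reported ~90% test–retest stage agreement.

**Stage quantisation.** Each tooth receives the stage whose score is
nearest the tooth's proportional share $(\mathrm{DMS}/100) \times
\mathrm{score}(\mathrm{tooth}, H)$, ties to the earlier stage. The
alternative floor rule ("largest stage not exceeding the share") is
systematically biased: for any valid 7-tooth/8-stage table its average
deficit is at least $100/16 = 6.25$ score points (about 0.5 years through
the conversion curve), which would corrupt every downstream bias estimate.
The nearest rule is unbiased to first order; its error is bounded by half
the sum of the per-tooth maximum single-stage increments
(`quantisation_bound()`), verified exhaustively in the tests over a dense
score grid.

The generator inverts the **conversion table** (the same route the
pipeline uses for estimation) rather than the prediction equation, because
the published equations saturate near 10.2 years at DMS 100 and could not
represent the oldest children's estimated ages; the conversion table spans
the full range. What the generator does *not* emulate: within-group age
clustering (some published strata have zero CA variance, implying rounded
integer ages), per-tooth stage-sequence correlations beyond what a single
latent score induces, and any real missingness mechanism. Passing
recovery tests on synthetic cohorts therefore shows the *pipeline* is
correct and unbiased under the stated noise model, not that the synthetic
radiology is realistic.

## Determinism and problem sizes

Every stochastic operation takes a seed; the study driver splits one root
seed (cohort: seed, retest selection: seed + 1, rater noise: seed + 2), and
identical seeds give byte-identical serialised reports. The test suite and
the analysis drivers use the study's own scale throughout — 160-record
cohorts, 74/86 calibration pairs, 20-seed recovery averages, a dense
half-point score grid for the quantisation bound — which keeps the whole
suite in the seconds-to-a-minute range.

## Known limitations

* The packaged score and conversion tables are synthetic stand-ins;
  absolute EDA values from them are structurally sensible but not
  clinically meaningful. Swap in a published edition for real use.
* Third molars, four-tooth variants and weighted kappa are out of scope.
* The calibration inherits the printed three-decimal coefficients'
  precision; no attempt is made to recover hidden digits.
* Two published male strata carry internally inconsistent printed
  summaries (mean difference vs printed means); the fixture tests document
  rather than resolve this.
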