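---
title: "Methods: validating a food frequency questionnaire against repeated 24-hour recalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a food frequency questionnaire against repeated 24-hour recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqvalidate)
```

## The measurement problem

A food frequency questionnaire asks how often each of a fixed list of foods
was eaten over a reference period, on an ordinal scale. It is cheap to
administer at scale but coarse: responses are discretised, retrospective,
and biased in ways that differ by food. The reference method used here —
repeated 24-hour dietary recalls — is closer to actual consumption on the
recorded days but sees only a handful of days, so it carries large
within-person (day-to-day) variance for anything not eaten daily. Relative
validation asks: do the two instruments *rank* people consistently? The
package operationalises that question as a battery of statistics computed on
a common currency, **intakes per day per questionnaire category**, derived
from each instrument.

## From raw records to daily frequencies

**FFQ.** Each of the nine ordinal levels maps to a representative daily
frequency. The instrument fixes the endpoints (never = 0; "4 times a day or
more" = 4/day); the default mapping uses arithmetic midpoints of each stated
range, e.g. "2–3 times a week" = 2.5/7 ≈ 0.357/day, "1–3 times a month" =
2/30.44. Any monotone mapping with the same endpoints can be supplied;
`validate_frequency_mapping()` enforces those constraints. Unanswered items
are imputed as "never" — skipped frequency questions overwhelmingly mean
non-consumption in this instrument family — and each imputation is recorded
in an `imputed` provenance attribute so sensitivity analyses can drop them
instead.

**Recalls.** Every recall food is mapped (many-to-one) onto a questionnaire
category; occasion counts are summed per category over all completed days
and divided by the number of completed days. A day with nothing reported
still counts as a completed day: a fasting day is information. Only the
partition-invariant totals matter, which the tests exploit.

**Quality.** Records classify into three exclude levels, checked portion
indications first: level 2 if any of the three portion-photo answers is
missing, else level 1 if at least 10% of items are unanswered, else level 0.
The threshold and rule order are the Northern-European diet-database
convention this instrument family uses; only level-0 records enter the
analysis by default.

## Portions, nutrients, and misreporting screening

Per-category portions come from three sources keyed by the item's portion
class: photo-plate grams for starch/protein/vegetable classes (four strictly
increasing levels each), fixed natural units (an egg, a piece of fruit), and
sex × 10-year-age-band median tables for everything else. All packaged gram
tables are synthetic defaults and are plain replaceable data.

Nutrient intake is the linear weighting Σ frequency × portion(g) ×
content(per g) over categories, for energy and 14 nutrients. The packaged
composition table is synthetic but internally consistent: energy is computed
from the macronutrients (4/9/4/7 kcal per g of protein/fat/carbohydrate/
alcohol), so the consistency invariant is exact.

Resting energy expenditure uses weight-based sex × age-band linear
equations (Henry/Oxford family, MJ/day converted to kcal), stored as a
coefficient table so any equation set can be swapped in; age bands are
lower-inclusive, so ages 30 and 60 fall in the bands beginning there. The
screening statistic PAL = reported energy intake / REE flags severe
under-reporting strictly below 0.7 and implausible over-reporting at or
above 3.0. The asymmetry (strict vs weak inequality) is deliberate and
matches how such filters are reported; both thresholds are configurable.
Flagged participants are reported alongside, not silently dropped: the
default policy computes nutrient statistics both with and without them.

Energy adjustment offers both standard methods: the **residual method**
(nutrient regressed on energy by OLS; residual plus the prediction at the
cohort-mean energy, keeping natural units — the add-back constant does not
affect correlations) and the **density method** (units per 1,000 kcal).
Residual-adjusted values are exactly uncorrelated with energy by
construction, which the tests assert at 1e-10.

## Food groups and diet indices

The 108 categories aggregate by exact summation into 30 food groups. Diet
indices are rank-based sums over components: rMED (nine components, cohort
tertiles scored 0–2, meat and dairy reversed, alcohol scored 2 inside a
moderate window and 0 outside), HNFI (six components, 0/1 at the cohort
median), and PDI (eighteen components, cohort quintiles 1–5, animal groups
reversed). Ties at a cut point go to the *higher* rank class — the
"at-or-above the median" convention. Cut points are computed within the
scoring cohort per recording method, mirroring per-method ranking; a shared
cohort can be supplied instead. The shipped component lists are package
defaults expressed on the packaged 30 groups; they are data, not code, and
a `diet_index_spec()` can encode any index in this family. Constant
components degenerate deterministically: everyone receives the lowest-rank
points and a warning is logged.

## The statistics battery

* **Correlations.** Spearman (average ranks on ties) for food groups, whose
  distributions are right-skewed and zero-inflated; Pearson for indices and
  nutrients, with Spearman also reported. Zero-variance inputs yield an NA
  coefficient rather than an error.
* **Tertile cross-classification.** Participants are cut into ranked thirds
  per method at positions ⌈n/3⌉ and ⌈2n/3⌉ of the stable (value,
  participant-id) ordering, so heavy ties — common for episodic foods —
  classify deterministically. Reported: the 3×3 table, % same (overall and
  per extreme tertile), % adjacent, % gross misclassification (opposite
  extremes); the three percentages sum to 100.
* **Bland–Altman.** Differences (test − reference) against pair means. Two
  interval summaries are reported explicitly because they answer different
  questions: the t-based 95% CI of the *mean* difference (systematic bias)
  and the conventional mean ± 1.96·sd limits of agreement
  (individual-level spread), with counts of points above/below the limits
  and a carried-through flag for screening-excluded participants.
* **ICC(A,k).** Reproducibility of the repeat FFQ uses the two-way,
  absolute-agreement, average-measures intraclass correlation computed from
  ANOVA mean squares, (MSR − MSE)/(MSR + (MSC − MSE)/n), with the
  single-measure coefficient reported alongside. The 95% CI applies the
  F-based single-measure interval (McGraw–Wong) and maps it to average
  measures by the Spearman–Brown relation. Quality bands split at
  0.5/0.75/0.9, "excellent" strictly above 0.9.
* **PCA with cross-validated Q².** Food-group matrices are
  auto-transformed chemometrics-style: log10(x + 1) — the unit offset
  admits the exact zeros of episodic foods and is configurable — then
  column centring and unit-variance scaling so each group carries equal
  weight. R² is cumulative explained variance from the exact
  eigendecomposition. Q² = 1 − PRESS/SS uses seven interleaved
  ("venetian-blinds") deletion groups over the preprocessed matrix cells in
  row-major order; each held-out group is predicted from a NIPALS fit that
  tolerates the missing cells. Cell-wise deletion is the default, matching
  the every-seventh-*observation* convention of chemometrics software;
  row-wise deletion is available as an option. Preprocessing is computed
  once on the full matrix rather than inside each CV fold — a simplification
  that slightly flatters Q², shared by common implementations and stated
  here so nobody mistakes Q² for a fully honest prediction estimate.

Quantiles everywhere (descriptives, rank cuts) use linear interpolation of
order statistics (R type 7), recorded in the report, since conventions
differ across software. No multiple-testing adjustment is applied; p-values
are reported raw.

## What the synthetic generator emulates

Each participant has a latent habitual frequency per category,
λ = median · GSD^z, truncated at the instrument ceiling of 4/day,
with a Bernoulli never-consumer mask for episodic foods. The z-scores mix an
independent part with two latent dietary-pattern factors (a prudent axis and
a sweet/convenience axis, loadings fixed per group, unit marginal variance),
because real food groups are correlated across people; the default pattern
share (0.35) puts two-component pattern models in the explanatory range
(R² roughly 25–35%) seen for real food-group data. The FFQ observes
λ through a per-category multiplicative bias and log-normal noise, then
discretises to the nearest representative level (ties to the lower level,
values above the scale truncated to the top). Recall days draw Poisson
occasion counts per category and day — the within-person variance the
reference method averages over — with log-normal amount noise around the
true portion. The repeat FFQ redraws its error independently given the
truth (an optional drift term exists but defaults to 0), so reproducibility
has a closed-form target. Demographics mirror a middle-aged Nordic
screening cohort: ages 35–64, ~61% women, BMI ~N(26, 4.3²), and a recall
completion distribution with a large six-day majority and a small
non-completing tail.

The generator deliberately does **not** model seasonality, weekday/weekend
intake differences, differential misreporting by BMI or sex, portion-size
reporting error in the FFQ photos, or correlated FFQ–recall errors.
Passing tests therefore show that the *statistical machinery* is correct
under a known error structure — not that any real instrument is valid, and
not that real recall errors are independent of FFQ errors (they are
probably not, which is exactly why real validation coefficients should be
read as optimistic).

**Exact diagnostic mode.** When every error term is off (all sds 0, biases
1), the latent truth is drawn *on* the nine-level representative grid and
recall occasions are emitted so aggregation reproduces the truth exactly.
Without this, discretisation alone would break the zero-noise round trip;
the mode exists so end-to-end identity (all correlations and ICCs exactly
1) is a meaningful pipeline check. It is a diagnostic configuration, not a
realistic cohort.

## Analytic targets and the recovery design

Because the FFQ observation is a known discretisation of a log-normally
perturbed truth, its conditional mean m(λ) and variance v(λ) have closed
forms (normal-CDF differences over the level midpoints on the log scale).
With recall errors independent of FFQ errors given λ:

* the expected FFQ-vs-recall Pearson correlation is
  cov(m(λ), λ) / sqrt{(var(m) + mean(v)) · (var(λ) + mean(λ)/k)} — the
  classical attenuation law r = r_truth,FFQ · sqrt(σ²_b/(σ²_b + σ²_w/k))
  with σ²_b = var(λ) and σ²_w = mean(λ) (Poisson within-person variance);
* the repeat-FFQ ICC has single-measure value ρ = var(m)/(var(m) +
  mean(v)) and average-measures value 2ρ/(1 + ρ).

`analytic_attenuation()` and `analytic_repeat_icc()` evaluate these with
numerical integration only — no simulation — so they are independent
oracles for the whole generator→engine→statistics path.

The recovery experiment (`recovery_design()`) checks observed against
analytic values to ±0.05 over 20 seeded replicates at n = 500 with six
recall days. Its configuration is a *power* choice: the sampling noise of a
Pearson correlation is of order (1 − r²)/√n, so the probed category must
correlate strongly enough that estimator noise stays well inside the band.
The design uses a common continuously varying category (median 1
intake/day, GSD 2.4, no never-consumers), FFQ log-noise 0.25, and full
six-day completion. Under the heavy-tailed default cohort (GSD 2.5 with
top-coding at 4/day) the estimators themselves wobble by more than the
band — a property of Pearson correlation under skew, not of the pipeline —
which is why the recovery design is fixed separately from the cohort
defaults.

## Problem sizes and numerical choices

The shipped checks run at sizes chosen to keep Monte-Carlo error
comfortably below the asserted tolerances: oracle-equivalence fixtures of
≤10 rows at 1e-10 on exact-arithmetic inputs; a zero-error cohort of 100; a
20 × n = 500 recovery grid; a default validation study of 320 consented
participants; ICC noise floors at n = 2000. Degenerate inputs are handled
deterministically rather than rejected wherever a defensible convention
exists: zero-variance correlation inputs return NA, constant index
components score lowest-rank with a warning, zero-variance PCA columns are
dropped with a warning, zero energy yields NA density-adjusted values, and
a perfect ICC reports a degenerate CI at the point value.

## Known limitations

The component lists of the shipped indices, the 108-item schema, all gram
and composition tables, and the REE coefficients are synthetic defaults —
structurally faithful, numerically invented; analyses of real data must
supply the real tables. The PCA Q² is cell-wise and preprocessing is not
re-estimated per fold (see above). The energy screening uses REE rather
than total energy expenditure, so the "PAL" here is the screening ratio
EI/REE, not a physical activity level. And the generator's independence of
FFQ and recall errors given the truth is an assumption real instruments
likely violate; the analytic targets are targets for this error model, not
for nature.
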