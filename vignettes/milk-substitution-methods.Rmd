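---
title: "Design-based beverage trends and milk substitution modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based beverage trends and milk substitution modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milksub)
```

## The problem

Fluid milk is the leading dietary source of several nutrients that United
States children underconsume — calcium, vitamin D and potassium among the
"nutrients of public health concern" — and its consumption declines
steadily through childhood while sugar-sweetened beverages (SSBs) rise.
milksub implements a complete, testable analysis of this phenomenon on
NHANES/WWEIA-style 24-hour recall microdata:

1. classification of recalled items into overlapping beverage groups from
   their 4-digit WWEIA category codes;
2. design-based estimation — survey-weighted means, covariate-adjusted
   (least-squares) means, and age-trend regression, all with
   Taylor-linearized variances that respect the stratified, clustered
   sample;
3. population-ratio nutrient contributions of caloric beverages;
4. two same-person substitution models: adding one cup of milk (NFS,
   USDA food code 11100000) to every diet, and isocaloric replacement of
   nonmilk caloric beverages consumed at lunch and dinner with milk.

Because the survey microdata are large external downloads, the package
ships a synthetic generator that emulates their structure with known
ground truth, so every estimator is validated end-to-end offline.

## Design-based estimators

A `survey_design` couples nonnegative analysis weights $w_i$ (day-1
dietary weights, divided by the number of pooled cycles) with strata $h$
and PSUs $j$ nested in strata. The first sampling stage is treated as
with-replacement — the NHANES-standard approximation — so no
finite-population correction is applied.

The weighted mean is $\hat\mu = \sum w_i y_i / \sum w_i$ with linearized
scores $z_i = w_i (y_i - \hat\mu) / \sum w_i$. Scores are totalled within
PSUs, $z_{hj} = \sum_{i \in (h,j)} z_i$, and

$$\widehat{\mathrm{Var}}(\hat\mu)
  = \sum_h \frac{n_h}{n_h - 1} \sum_j (z_{hj} - \bar z_h)^2 ,$$

where $n_h$ is the number of PSUs in stratum $h$. A stratum carrying
positive weight but a single PSU is an error naming the stratum — never a
silent collapse. Subpopulations (age groups) are handled by zeroing
weights outside the domain while retaining every stratum and PSU, the
standard domain-estimation device that keeps the variance honest.

Trend regression fits weighted least squares of an outcome on continuous
age plus categorical covariates (sex, ethnicity, poverty–income ratio
level), with the sandwich variance
$(X'WX)^{-1} M (X'WX)^{-1}$, $M$ being the same stratified between-PSU
covariance applied to the weighted score vectors $w_i x_i e_i$. The age
coefficient is the change per year of age across 6–18 y. Tests use
$t$ with PSUs-minus-strata degrees of freedom, two-sided, the
survey-regression convention. Collinear indicator columns (including
indicators of empty covariate cells) are dropped with a note.

Least-squares means by age group are predicted marginal means: the model
is outcome on age-group indicators plus covariates, and each group's mean
averages predictions over the pooled weighted covariate distribution
(observed-margins convention; the footnotes of the published tables do
not state a margin convention, and observed margins is what SAS-style
LSMEANS with observed margins over a pooled sample produces).

The contribution of a beverage group to a nutrient uses the population
ratio method, $100 \sum w_i s_i / \sum w_i t_i$, with a linearized ratio
SE. Contributions of any partition of the total sum to 100 by
construction.

## Substitution scenarios

**Add a cup.** One cup equivalent of milk NFS is added to every
subject's daily totals. Because the identical vector is added to
everyone, ordinary inference is meaningless (the "samples" are not
independent); results are judged by the 10% meaningful-change rule: a
shift of at least 10% of the baseline mean counts.

**Isocaloric replacement.** For each subject, items that are (i) in the
replacement scope, (ii) consumed at lunch or dinner, and (iii) caloric
(energy strictly above 0 kcal — the only non-arbitrary cut) have their
nutrients removed and replaced by an energy-matched amount of milk using
its per-kilocalorie density vector. Energy is conserved exactly: the
per-kcal energy component is pinned to 1 and the adjusted energy column
is copied from baseline, so the identity holds to the last bit rather
than to rounding. The default scope `all_caloric` is the
caloric-beverages-excluding-milk group, so plain milk, flavored milk and
milk substitutes are never replaced; `ssb_only` and
`milk_substitutes_only` expose the narrower readings, which remain
ambiguous in the source analyses. Scenario 2 is tested with
design-weighted paired t tests (the weighted mean of within-subject
differences over its linearized SE), marked significant at p < 0.01; an
unweighted variant is available for sensitivity.

## Key parameters and their defaults

- **Milk profile.** The per-cup nutrient vector of milk NFS is not
  published alongside the modeling tables, but the add-a-cup table pins
  it down: adjusted-minus-baseline differences are constant across age
  groups, so `default_milk_profile()` recovers each nutrient as the mean
  of the three printed differences (122 kcal, 290.3 mg calcium, 2.99 µg
  vitamin D per cup; added sugars exactly 0) and validates every
  component against all three printed pairs at their printed precision.
- **Cup weight.** `grams_per_cup = 244` g, the standard cup of fluid
  milk; used only for reporting per-gram densities and cup equivalents,
  never for energy arithmetic.
- **Added sugars** stay in teaspoon equivalents end-to-end, as the
  tables print them; `tsp_to_grams()` exposes the conventional 4.2 g/tsp
  for cross-checks only.
- **Occasion map.** Lunch = codes {2, 10}, dinner = {3, 4, 14}
  (English and Spanish NHANES-style labels), fully configurable as YAML;
  unknown codes are non-meal with a once-per-code note.
- **Category map.** The ten beverage groups are data, not code; the
  caloric-excluding-milk group is implemented as all beverage-range
  subgroups (70–79) except diet beverages (71) and waters (77, 78). The
  source description of this group ("main group 8") is internally
  inconsistent with its own 2-digit subgroup codes, so the subgroup
  reading is shipped and the map is editable without touching code.
- **Rounding.** Printed percent changes use half-away-from-zero rounding
  (87.5 → 88), integer above 10% and one decimal below, with a small
  epsilon so values that are exactly half at full precision round up
  despite floating-point representation.

## What the generator emulates — and what it does not

`generator_spec()` produces a balanced stratified design (15 strata × 2
PSUs by default), lognormal weights, uniform integer ages 6–18, and
demographic categories at published prevalences (51% male, 57%
non-Hispanic White, ...). Each of eight beverage categories follows a
two-part model: Bernoulli daily consumption at a constant probability,
and a gamma-distributed amount (right-skewed, strictly nonnegative, like
real intake data) whose conditional mean makes the *per-capita* mean
grams exactly linear in age. The intercepts and slopes are calibrated
once to the published child beverage table — e.g. flavored milk declines
at 6.21 g/d per year of age, soft drinks rise at 25.3 — so the
generator's closed-form truth ledger (`export_truth()`) carries exactly
the quantities the estimators should recover. Per-gram nutrient
densities are set to realistic values for each category, which places
caloric beverages at about 18% of daily energy (11% excluding milk),
matching the published contribution estimates. A single composite
rest-of-diet item with age-trended energy (1506 kcal at age 6, +27.9
kcal/y) gives total-intake tables realistic denominators. Beverage
occasions are allocated 35% breakfast / 13% lunch / 12% dinner / 40%
snack; the quarter of nonmilk beverage volume at meals yields a mean
replacement of roughly 0.4–0.5 cup equivalents, the observed scale of
the meal-replacement scenario. About 0.4% of subjects (females 12+) are
flagged pregnant/lactating and 20.3% as unreliable recalls, the
approximate exclusion rates of the real cohort.

Deliberate simplifications: consumption probability is constant in age
(real uptake of coffee or sports drinks rises with age; the per-capita
trend is carried entirely by the amount model); probability and amount
are independent given age (no zero-inflation correlation); weights are
independent of intake (no oversampling or nonresponse structure); one
recall day per subject; no within-PSU intracluster correlation beyond
what the design induces. Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to every feature of
real survey data.

## Numerical and degenerate-input choices

Zero weights are legal (the subject contributes nothing); a zero-weight
lone-PSU stratum is inert rather than an error. Grams-zero items must
carry zero nutrients. Negative nutrients are rejected at read time, as
are fatty-acid components above 105% of total fat and added sugars
exceeding total sugars in gram terms. With no replaceable items the
replacement model is the identity. A paired t with zero SE and nonzero
mean is flagged and reported at the smallest representable p rather than
zero. Single-level factors are dropped from model frames before fitting;
a single age group collapses the LS mean to the overall weighted mean.

## Validation sizes

The shipped tests exercise: exact reproduction of the printed
percent-change and add-a-cup arithmetic; energy conservation to 1e-9
kcal on 1,000 synthetic subjects; agreement of the linearized SE with a
delete-one-PSU jackknife within 15% on 50 random small designs (2–4
strata, 2–3 PSUs); and recovery of the flavored-milk slope with 95% CI
coverage inside [90%, 99%] over 200 replicates of 5,000 subjects. These
sizes keep the full suite under half a minute while leaving Monte Carlo
error well below the tolerances tested.

## Limitations

Single-day intakes only — no usual-intake (measurement-error) modeling;
no multiple-testing adjustment (none is applied in the analyses this
package reproduces); substitution models estimate the maximum potential
effect assuming full compliance, not behavior. Classification is purely
code-driven; no food-description text matching, and no nutrient database
is bundled — item tables must arrive with their nutrient panel attached.
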