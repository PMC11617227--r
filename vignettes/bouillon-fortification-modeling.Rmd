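---
title: "Modeling bouillon fortification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bouillon fortification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the two assessment
branches, the absorption sub-models, the fortification simulator and the
level-selection rules, together with the numerical choices and the places
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Two routes to the same question

The question is always the same: what share of a target population
(children 6–59 months, women of reproductive age 15–49 y, adult men) has
inadequate intake of vitamin A, folate, vitamin B12, iron or zinc, and how
does that share move when bouillon is fortified at a candidate level,
given the staple-food fortification already in place?

**Household branch.** Household surveys report food acquired over a recall
period, not individual intake. The package converts household totals to
apparent per-person consumption with the adult-male-equivalent method: each
member's AME weight is their FAO energy requirement (moderate physical
activity) divided by the 2900 kcal/d of the reference 18–30-y male, and
food is assumed distributed in proportion to these weights. Because the
total quantity a household reports is the least reliable part of such data,
adequacy is judged on the *density* scale: the household diet's nutrient
content per 1000 kcal,

    density_n = (sum_f grams_f x nutrient_nf) / (sum_f grams_f x energy_f) x 1000,

compared against the selected member's critical density
`EAR / energy requirement x 1000` (inadequacy) and tolerable upper density
`UL / energy requirement x 1000` (excess). One member per household per
target group is selected uniformly at random; households without an
eligible member are excluded for that group. The interpretation is
conditional: the household diet would meet the member's needs *if* energy
needs are met and food follows energy shares.

**Recall branch.** Replicate 24-hr recalls support direct estimation of
usual-intake distributions (next section). Inadequacy is the weighted share
of usual intakes below the age/sex-specific EAR; excess is usual intake
above the UL, restricted to preformed retinol for vitamin A and to folic
acid for folate, the forms on which those ULs are defined. Vitamin B12 has
no UL, and the package refuses to fabricate one: `tolerable_upper_density()`
signals a typed error (`bouillonfort_no_ul`) and the selection rules treat
the constraint as vacuous.

Iron is special in both branches. Requirements among menstruating women are
strongly right-skewed, so a cut-point misestimates prevalence; the package
uses the full-probability approach instead: each person's (or household's)
risk is `P(absorbed requirement > absorbed intake)` under a log-normal
absorbed-requirement distribution, and prevalence is the weighted mean
risk. The per-group log-normal parameters ship in
`iron_requirements.csv` as documented approximations to the FAO/WHO
probability tables and are fully replaceable — the exact tabulations are
not in the public literature in machine-readable form, so provenance is
carried per row rather than asserted.

## Reference data

All reference values are versioned CSVs under `inst/extdata/`, loaded by
`default_references()` and replaceable per file. EAR and UL values are IOM,
except zinc, which uses EFSA physiological requirements for children and
corrected IZiNCG physiological requirements for adults (both on the
*absorbed* scale, which is why zinc adequacy runs through the absorption
model). Energy requirements are FAO 2004 moderate-activity values; women of
reproductive age are treated as nonpregnant/nonlactating in the household
branch because maternity status is not observed there. Child strata are
6–11, 12–47 and 48–59 months, chosen to align with the IOM reference bands
(7–12 mo, 1–3 y, 4–8 y) while partitioning 6–59 months; where IOM defines
no EAR under 12 months the packaged value is AI-derived and labelled so in
its `source` field. Ages are months internally; input files carrying years
convert via `years_to_months()` (year *y* maps to the half-open band
`[12y, 12y+12)`).

Fortification standards (`fortification_standards.csv`) carry the target
level, the observed compliance fraction and the printed program value.
`effective_content()` multiplies target by compliance at full precision;
rounding (half away from zero, at the printed number of decimals) happens
only at presentation. Compliance may exceed 1 (Ghana oil, 106%). The
effective content is applied to 100% of the vehicle: the model does not
distinguish partially fortified from unfortified product.

## The usual-intake estimator

The recall branch deliberately replaces the NCI MIXTRAN/DISTRIB machinery
(covariate-adjusted, two-part, survey-replicated) with a documented
transform–decompose–shrink estimator. This is the package's single largest
simplification and the main caveat for real-data use.

Given person-day intakes, `fit_usual()`:

1. log-transforms (adding half the smallest positive value when zeros are
   present, removed after back-transformation);
2. pools the within-person variance `w` over persons with replicate days
   (no replicates anywhere is an error — the components are not separable);
3. estimates the between-person variance by method of moments,
   `b = max(var(person means) − w x mean(1/k), 0)`;
4. shrinks each person's mean toward the weighted grand mean with the
   classical adjustment factor `sqrt(b / (b + w/k))`;
5. back-transforms with the log-normal mean correction `exp(. + w/2)`.

The square-root form of the shrinkage factor is a deliberate choice: it
rescales the person means so the *distribution* of estimated usual intakes
has variance `b`, matching the latent usual-intake distribution. The
unrooted reliability ratio would minimise per-person prediction error but
under-disperse the distribution, biasing tail prevalences — and prevalence
at a cut-point is exactly what the package reports. With `w = 0` the
estimator returns each person's mean unchanged; with `b = 0` everyone
collapses to the grand mean.

Fortificants and breast milk enter on opposite sides of this estimator, on
purpose. A fortificant consumed with bouillon varies day to day like any
other food, so it is added per person-day *before* fitting
(`add_then_shrink_fortificant()`). Breast-milk nutrients are not captured
by the recall food list and are modelled as a constant age-band volume
times milk composition, so they are added to the fitted usual intakes
*afterwards* (`shrink_then_add_breastmilk()`); a breastfed child outside
the configured volume bands is an error, not a silent zero. Child results
are computed per breastfeeding stratum and post-stratified to 6–59 months
with configurable shares (`poststratify_6_59()`), since surveys often
enroll from 12 months.

## Absorption models

Functional forms are implemented in code; every coefficient ships in
`absorption_params.csv` and is injectable, so parameter sets can be swapped
without touching the code.

- **Nonheme iron** uses a log-linear prediction equation in ferritin,
  phytate and dietary covariates. Only ferritin and phytate vary here; the
  remaining covariates (vitamin C, meat/fish/poultry, tea, calcium) are
  fixed at reference values recorded in the parameter file. Heme iron is
  taken as 10% of non-bouillon iron, absorbed at 25%. In the household
  branch no ferritin exists, so iron absorption is a flat 10% of the total
  non-bouillon diet — and the heme split is *not* applied there (the flat
  fraction already describes the total diet); that resolution is recorded
  here because the convention is genuinely ambiguous, and it is
  configurable via the parameter file.
- **Zinc** uses the saturable trivariate dose-response model: absorbed zinc
  is the positive root of
  `TAZ^2 − TAZ(Amax + Z + Kr(1 + P/Kp)) + Amax·Z = 0`
  (all in mmol/d), monotone increasing in zinc, decreasing in phytate,
  bounded by `Amax`. The adult constants are the published trivariate
  values (`Amax = 0.091`, `Kr = 0.033`, `Kp = 0.68` mmol/d); the child set
  keeps the binding constants and down-scales `Amax` to 0.048 mmol/d, an
  explicitly labelled approximation in lieu of the child-specific
  publication's full parameterisation.
- **Vitamin B12** absorption is modelled as saturable active transport plus
  passive diffusion, `absorbed(d) = Amax·d/(d + K) + p·d`, calibrated so
  ~50% of a 1 µg/d dose is absorbed (`Amax = 1.5` µg, `K = 2` µg,
  `p = 0.009`). This is a parameterisation choice for the dose-dependent
  curve reported in the B12 absorption literature: fractional absorption is
  strictly decreasing in dose and the absorbed amount strictly concave,
  which is what the downstream contracts rely on. Because the packaged B12
  EAR is on the total-intake scale (it already assumes 50% absorption),
  the absorbed-scale comparison uses `EAR x 0.5`; the factor ships in the
  parameter file.

Fortificant zinc and B12 are added to dietary intake *before* the
absorption model is applied. Bouillon iron is tracked separately and
absorbed at its own fraction — 2% by default (ferric pyrophosphate), with
4% and 10% as the standard sensitivity assumptions — because fortificant
iron chemistry, not diet composition, governs it.

## Fortification scenarios and level selection

`fortification_scenario()` fixes the staple mode (`status_quo`, `target`,
`none`), the bouillon levels, the bouillon-iron absorption and the fortified
coverage. In the household branch the bouillon fortificant adds
`bouillon grams x level / energy x 1000` to the baseline density; in the
recall branch it adds `bouillon grams x level` per person-day. Added folic
acid counts 1.7x toward dietary folate equivalents and 1x toward the
folic-acid UL column; added vitamin A counts as preformed retinol on the UL
side. Nutrient retention is 1.0 by construction — levels are defined at the
time of consumption. Voluntary in-market bouillon fortification and
supplement/micronutrient-powder programs are excluded from baselines.

Coverage below 1 is a documented extension: fortified bouillon is assigned
to a Bernoulli subset of households/persons under the scenario seed, so a
coverage-c scenario is, in expectation over assignments, the c-weighted
mixture of the full and null scenarios (a property the tests check by
simulation).

`select_levels()` applies the WHO-style rule to a level grid: a level is
acceptable iff every group's above-UL prevalence (point estimate or lower
95% confidence bound) is strictly below the chosen threshold; the best
level is the acceptable one with the greatest total inadequacy reduction.
Two open choices are resolved as follows and are configurable: ties in
inadequacy reduction break toward the *lower* level (conservative on excess
risk), and the UL constraint is evaluated under the status-quo staple
scenario only — the target-compliance sensitivity rerun can be fed through
the same function by whoever wants the stricter reading. The default grids
are seven strictly increasing levels spanning 20–250 µg/g (vitamin A),
20–120 µg/g (folic acid), 0.2–2 µg/g (B12) and 0.6–5 mg/g (iron, zinc);
interior points beyond the commonly reported levels (40/80/120/160/200,
40/80, 1.2, 1.8/3, 1.2/3) are package choices and overridable everywhere.

## What the synthetic generator does and does not emulate

`generate_hces()` draws household rosters from a categorical composition
distribution, gives every food a log-normal per-AME quantity (median and
log-SD per food), inflates a small fraction (3%, x8) to emulate episodic
acquisition — purchases recorded in bulk that were not consumed in the
window — and scales by household AME. Bouillon is zero-inflated: 90% of
households consume, with a log-normal median of 2.2 g per AME per day,
calibrated so apparent adult medians land in the 1.6–2.2 g/d range reported
by national surveys in settings where bouillon is a daily condiment, and
children near 0.8 g/d. `generate_recalls()` draws log-normal person-level
usual intakes (between-person CV 0.4), multiplies by mean-one log-normal
day noise (within-person CV 0.4), and records every generating parameter in
a `truth` element so recovery tests compare against analytic values
(`pnorm((log(EAR) − mu)/sigma_b)`).

The generator is faithful to the *statistical structure* the methods
assume, not to any country's diet: the 12-item food list is synthetic, with
plausible West-African-style densities (maize-dominated energy, high
phytate, leafy-vegetable provitamin A, fish as the main B12 source).
It does not emulate multi-stage sampling designs (a single weight column
stands in for the design), seasonality, food away from home,
between-nutrient correlation beyond what shared foods induce in the
household branch, or reporting error beyond the episodic-acquisition
outliers. Passing tests therefore demonstrate that the *methods* recover
known truth under their own assumptions — not that any particular
real-world prevalence is correct.

## Numerical choices

- **Truncation.** Apparent per-AME consumption above the survey-weighted
  95th percentile (per food) is replaced by that percentile. The percentile
  is a weighted analogue of `quantile(type = 7)` (plotting positions at the
  left-cumulative weight share, linear interpolation), exact type 7 under
  equal weights; with fewer than 20 nonmissing values no truncation occurs
  and the skip is recorded on the result.
- **Confidence intervals.** Household/person percentile bootstrap, 500
  replicates by default, seeded; this replaces design-based balanced
  repeated replication, which needs stratum/PSU variables the package does
  not model. Post-stratified child CIs combine stratum bootstrap replicates
  replicate-wise.
- **Degenerate inputs.** Zero-energy households are excluded and logged on
  the result; missing food-composition rows are an error, never a silent
  zero; zero total survey weight is an error; risk at zero absorbed intake
  is 1.
- **Problem sizes.** The shipped checks run the monotonicity suite on
  5000 synthetic households and 1000 + 1000 recall persons x 2 days across
  every 7-level grid; parameter recovery uses 2000 persons x 2 days (within
  3 percentage points of analytic truth) and 200 simulated surveys of 800
  households against a 50 000-household Monte-Carlo truth (bootstrap CI
  coverage at least 90%). These sizes give Monte-Carlo error comfortably
  inside the asserted tolerances while keeping the default suite quick.

## Known limitations

The usual-intake estimator ignores covariates, episodic foods and
correlated probability/amount processes; the AME method assumes
energy-proportional intrahousehold allocation, which is least reliable for
young breastfeeding children; density-based adequacy is conditional on
energy needs being met; absorbed-iron requirement distributions and the
child zinc `Amax` are documented approximations; the UL side inherits every
limitation of ULs as reference values (tail estimation, weak child data).
All of these are properties of the methods themselves, and the package's
role is to make each assumption explicit, seeded and replaceable.
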