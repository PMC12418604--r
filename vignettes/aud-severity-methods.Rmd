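---
title: "Dimensional AUD severity from claims data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensional AUD severity from claims data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

ICD-10 codes a binary notion of alcohol use disorder (AUD), while the
clinical reality — and the DSM-5 — treats AUD as dimensional.  `audsev`
implements a dimensional severity phenotype that can be computed from
routinely collected statutory-health-insurance (SHI) billing records:
five ordered, deliberately *overlapping* severity levels defined purely
by which alcohol-specific ICD-10 codes a person accumulates:

| Level | Clinical meaning | Codes |
|---|---|---|
| 0 | any alcohol-specific diagnosis | union of 1–5 |
| 1 | acute intoxication | F10.0, T51.0, T51.9 |
| 2 | harmful use | F10.1 |
| 3 | dependence | F10.2 |
| 4 | withdrawal (± delirium) | F10.3, F10.4 |
| 5 | chronic end-organ damage | K70.0–.4, K70.9, K85.2, K85.20, K86.0, F10.5–F10.9, E24.4, G31.2, G62.1, G72.1, I42.6, K29.2 |

Fetal-damage (O35.4) and alcohol-in-blood (R78.0) codes are excluded.
Levels are *sets*, not a partition: a person with both F10.2 and F10.3 in
a period belongs to levels 3 and 4.  Removing lower levels from people
who also reach higher levels would make the lower-level groups look
artificially healthy, so overlap is a feature of the phenotype.

The package validates the phenotype the way the underlying study design
does: severity should show a dose-response relationship with somatic
comorbidity, measured by the Elixhauser Comorbidity Score (ECS, the count
of 0–31 distinct comorbidity categories flagged in the same calendar
year).

Because real SHI billing data cannot be shared, everything here runs on a
synthetic claims generator with *planted ground truth*; a green test
establishes that the pipeline recovers what was planted, not that any
real-world claim is true.

## Pipeline and record selection

Raw billing records carry a setting and a qualifier.  Only
outpatient-`confirmed` and inpatient-`admission`/`primary`/`secondary`
records qualify; exclusionary/suspecting/symptomless outpatient and
surgery/follow-up inpatient records are dropped (and counted).  Unknown
qualifier strings are dropped with a warning rather than failing, since
claims dialects vary.  Outpatient diagnoses are only dated to a quarter;
they are assigned the quarter's median day, taking the **earlier** of the
two middle days for even-length quarters (90 days in Q1 of a non-leap
year gives day 45, i.e. Feb 14).  Inpatient diagnoses take the admission
day.

The study population comprises persons aged 18–99 with at least one
qualifying alcohol-specific diagnosis and at least one insured day in the
year considered.  Two analysis subsamples serve different questions:

* **Subsample 1** (description): per person, the *first* year each
  severity level was recorded, at most 5 rows plus a level-0 row; the
  level-0 row uses the first year with any AUD diagnosis, and covariates
  and ECS travel with the selected year.
* **Subsample 2** (dose-response): per person-year, only the *maximum*
  severity level, at most one row per year.

Annual employment status is the status with the most in-year days, ties
broken by the hierarchy employed > unemployed > retired > other; persons
without spells fall into "other", the residual class.  Age uses the
calendar-year convention (year − birth year); the source material states
only the 18–99 bounds, so this is a documented choice.

## The regression model

The dose-response validation is a population-averaged Poisson regression
of the ECS on the maximum annual severity level (reference: level 1),
adjusted for year, sex, age group (18-24, …, 75+) and employment,
estimated by generalized estimating equations with an exchangeable
working correlation across a person's repeated annual observations and
robust (sandwich) standard errors.  Coefficients are exponentiated to
rate ratios.

No GEE implementation ships with this environment's R stack, so
`gee_poisson()` implements the estimator directly: Fisher scoring on the
GEE score equations, with Liang–Zeger moment estimators

$$\hat\phi = \frac{\sum_{ij} r_{ij}^2}{N - p}, \qquad
  \hat\rho = \frac{1}{\hat\phi}\,
  \frac{\sum_i \sum_{j<k} r_{ij} r_{ik}}{(\sum_i n_i(n_i-1)/2) - p},$$

where $r_{ij}$ are Pearson residuals.  These conventions (including the
$-p$ corrections) match the reference GEE implementation in Python
statsmodels, against which the engine is verified to seven decimals on a
frozen fixture.  With independence working correlation — or a single
observation per person — the estimates coincide with an ordinary Poisson
GLM to numerical precision, which the tests assert at 1e-6.  An
unstructured working correlation (free per year-pair) is available as a
sensitivity option.

Prevalence estimates are classified cases divided by insured persons,
with Wilson score 95% intervals (the error-bar method is a documented,
swappable choice; Wilson behaves correctly at 0 and 1).

## The synthetic world

`sim_config()` states the generating world once; its defaults are
calibrated to the published analysis the pipeline emulates:

* any-AUD annual prevalence 2.7% (2017–2019) and 2.9% (2020–2021);
  level-specific prevalences 0.4 / 1.3 / 1.5 / 0.2 / 0.7% for levels 1–5;
* ECS rate ratios 1.24 / 1.32 / 1.47 / 1.65 for maximum severity levels
  2–5 versus level 1, baseline (level-1) mean ECS 3.5;
* within-person exchangeable correlation of ECS 0.708;
* demographics matching the described case mix (30.6% female, mean age
  ≈ 54, employment shares 41.8 / 25.1 / 17.7 / 15.4%);
* qualifier noise below the observed dialect shares (<10% outpatient,
  <4% inpatient), occasional excluded codes, 70% outpatient records.

**Activity and severity sets.** `n_persons` at-risk persons sit inside an
insured pool of `insured_pool_size`; each is independently "active" in a
year with probability p0(year)·pool/n, so the expected annual case count
equals planted prevalence × denominator exactly.  An active person-year
draws its severity-level *set* from a joint distribution over the 31
non-empty subsets, solved by fixed point so that the conditional level
marginals equal the planted prevalences after (a) a clinical containment
boost — a withdrawal year also carries dependence codes with probability
0.9, reflecting that withdrawal is largely nested in dependence — and
(b) conditioning on non-emptiness.  Overlap percentages beyond this are
emergent, not calibrated.  Level-5 persons get a sticky diagnostic
signature (liver-only 40%, F10.5–9-only 21%, polyneuropathy-only 9.6%,
combinations otherwise), with every signature group guaranteed to appear
in the first level-5 year so study-window composition matches the
planted distribution.

**Comorbidity.** ECS is planted as category-level Bernoulli draws.  A
person-year's target mean is
$\mu = u \cdot 3.5 \cdot RR(\text{max level}) \cdot m(x)$, where $u$ is a
person-level frailty (mean 1) and $m(x)$ a covariate multiplier (defaults
1; when covariate effects are configured the intercept is re-centred by
the expected multiplier so planted severity-level means stay
population-averaged).  The severity codes themselves intrinsically flag
Elixhauser categories (F10 → alcohol abuse, K70 → alcohol abuse + liver
disease, …); the generator computes those intrinsic flags with the same
map the scorer uses and spreads the remaining mass $\mu - k$ over the
non-flagged categories proportionally to configurable weights, with
per-category caps at 1 resolved by water-filling.  Extra-category codes
are drawn only from stems that collide with no severity code and map to
exactly one category, so the classifier always recovers the planted
severity sets exactly and the realised ECS has conditional mean exactly
$\mu$ — which is what makes the GEE recovery unbiased.

Note that the planted means are *maximum-level* means, matching what the
subsample-2 regression estimates.  The overlapping descriptive columns
(a level-1 column contains everyone with intoxication codes, including
people whose maximum level that year is higher) therefore sit above the
planted baseline for the lower levels; only the level-5 column, where
maximum and recorded level coincide, equals its planted mean.

**Frailty.** The exchangeable correlation is induced by multiplicative
frailty.  Two refinements over a plain gamma:

1. *Shifted support.*  Because ECS includes the alcohol category, every
   active person-year has an intrinsic count $k \ge 1$ (2 for
   liver-coded level-5 years); a frailty with mass near zero would make
   $\mu < k$ impossible to satisfy and truncate the planted means,
   biasing the rate ratios.  The frailty is therefore gamma shifted to
   the bound $a$ where $a \cdot 3.5 \cdot RR \ge k$ for every level,
   keeping mean 1 and the target variance.  (Rare combination-signature
   years with $k = 3$ can still touch the floor; the induced bias is
   of order 0.02% and ignored.)
2. *Pilot-calibrated variance.*  The variance inducing $\rho = 0.708$
   depends on the level mix and on the sub-Poisson noise of the
   Bernoulli mechanism, so it is solved numerically: a fixed-seed pilot
   simulation of the actual planting mechanism under common random
   numbers, root-solved with `uniroot()` and cached per configuration.
   The pilot measures residuals against the marginal mean (what the GEE
   working model sees), not the frailty-conditional mean.

**What the generator does not emulate.**  The published scale parameter
$\phi = 1.094$ alongside $\rho = 0.708$ implies strongly sub-Poisson
conditional noise; any frailty-count mechanism with these correlations
yields $\phi$ near $1/(1-\rho)$.  The generator plants $\rho$ and lets
$\phi$ land where it lands (≈ 1.8).  Likewise treatment-seeking
dynamics, regional structure, provider identifiers, reimbursement
amounts and year-on-year severity persistence are out of scope; annual
activity is independent across years given the person, so the synthetic
Venn overlaps are flatter than the published ones.  A green
parameter-recovery test therefore establishes correctness of the
*pipeline*, not realism of every marginal of German claims data.

## Numerical and design choices

* **Severity matching is exact string matching** on normalised codes
  (trim, uppercase, dot retained); K85.2 and K85.20 are both listed and
  both matched literally (ICD-10-GM).  No prefix wildcarding: "K70+" is
  interpreted as the enumerated K70.x family.
* **Elixhauser matching is prefix matching** with the Quan et al. ICD-10
  map, shipped as CSV and swappable (`elixhauser_map(path=)`); the
  source material names the score but not the coding algorithm, so the
  map is a documented choice, and the ECS is the unweighted category
  count (0–31), not a van-Walraven-weighted index.
* **IQRs** use linear-interpolation (type-7) quantiles.
* **Year enters the regression categorically** (5 levels); nothing in
  the source fixes the functional form, and categorical year is the
  conservative choice at 5 time points.
* **Age strata** are 18-24 / 25-34 / … / 75+; a stray "15–34" label in
  the source's results text is treated as a typo for 25–34.
* **Convergence**: Fisher scoring to a relative step below 1e-10,
  maximum 100 iterations, explicit error with diagnostics otherwise;
  working correlation clamped to the valid exchangeable range.
* **Determinism**: every stage draws from a sub-stream derived from the
  single config seed; identical config ⇒ byte-identical tables; the
  frailty pilot uses its own fixed seed so the solved variance is
  config- (not run-)dependent.

## Worked example

```{r, eval = FALSE}
library(audsev)

pl <- run_pipeline(sim_config(n_persons = 2000, insured_pool_size = 10000,
                              seed = 7))
pl$table2                 # descriptive table by severity level
pl$average_prevalence     # mean annual prevalence per level
tidy(pl$gee)              # adjusted rate ratios with robust CIs
glance(pl$gee)            # rho, phi, convergence
autoplot(pl$gee)          # forest plot
```

## Known limitations

* The severity phenotype inherits every bias of billing data: only
  treated, billed disease is visible, so low-severity AUD is
  under-ascertained and the severity distribution is shaped by
  care-seeking, not population epidemiology.
* The generator's independence of activity across years understates
  within-person severity persistence; quantities that depend on
  study-window accumulation (Venn overlaps, distinct-person counts) are
  structurally flatter than published ones and are not acceptance
  targets.
* The Quan Elixhauser map is an assumption, not a reconstruction of the
  original study's (unnamed, likely ICD-10-GM-specific) mapping.
* `gee_poisson()` supports the Poisson/log case needed here, not the
  general GLM family zoo of a full GEE package.
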