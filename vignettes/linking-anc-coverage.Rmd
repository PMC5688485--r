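---
title: "Estimating ANC intervention coverage by linking household and facility surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ANC intervention coverage by linking household and facility surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Household surveys (DHS-style) ask women about antenatal care (ANC) for a
recent live birth, but a woman can rarely report reliably whether she was,
say, screened for syphilis. Facility assessments (SPA/SARA-style) record
whether a facility had the drugs, tests and equipment needed to deliver an
intervention on the day of assessment, but say nothing about who sought
care there. Mortality-projection tools such as the Lives Saved Tool (LiST)
need a baseline coverage value per intervention per country and, absent
better data, fall back on proxy rules driven entirely by ANC4+ coverage
(the share of women attending four or more ANC visits).

This package implements the linking approach: combine the two survey types
at the *stratum* level — facility type × managing authority × urban/rural
location — to estimate *availability coverage*, the proportion of women for
whom the intervention was available at the point where they sought care.
It covers five interventions: syphilis detection and treatment, and case
management of diabetes, hypertensive disorders, malaria and pre-eclampsia.

## The estimator

Three quantities per country:

* $r_{s}$ — facility readiness in stratum $s$: the weighted proportion of
  facilities with **all** checklist items for the intervention observed,
  $r_s = \sum_i w_i\,\mathrm{ready}_i / \sum_i w_i$ (`stratum_readiness()`).
* $c_{s}$ — the weighted share of all eligible women who attended ANC4+
  and sought care from a source in stratum $s$ (`stratum_careseeking()`).
  Eligibility restricts to births within the last 36 months to limit
  recall bias.
* availability coverage
  $\widehat{AC} = \sum_s c_s\, r_s$ (`link_coverage()`), which can never
  exceed ANC4+ coverage.

Linking happens between population aggregates, not individuals: the
estimator assumes women are exchangeable across facilities *within* a
stratum. Large readiness heterogeneity within a stratum degrades the
estimate — a stated limitation of the approach, visible in the
micro-simulation tests.

On top of the linked estimates, the package fits *fractional logit*
predictive models (`fit_fractional_logit()`, `stepwise_select()`): for
country panels where both survey types exist, coverage is regressed on
country-level ANC covariates that household surveys measure well
(ANC4+ rate, blood-sample rate, urine-sample rate, blood-pressure rate,
early-enrolment rate), so coverage can then be *predicted* for countries
with only a household survey. The package also carries the published
coefficient set for the five interventions (`published_models()`) and the
current default proxy rules (`default_proxy()`) for comparison.

## Key parameters and conventions

* **Recall window** — half-open, `months_since_birth` in $[0, 36)$:
  "within the 3 years prior" is read as strictly fewer than 36 completed
  months. The boundary is unit-tested (35 kept, 36 dropped).
* **Early enrolment** — first visit in pregnancy months 1–4 inclusive
  (`first_visit_month <= 4`).
* **Covariate denominators** — component and early-ANC rates are computed
  over *all* eligible women by default (non-attenders contribute zero),
  the convention under which they act as country-level predictors next to
  the ANC4+ rate. The source analyses do not state their convention, so
  an `"anc_attenders"` switch is provided; the default is documented, not
  asserted as the original choice.
* **Non-facility ANC sources** — ANC4+ women reporting care outside
  formal facilities form an explicit bucket with availability
  contribution zero (readiness is undefined there), reported via
  `non_facility_share`; the partition
  $\sum_s c_s + \text{non-facility share} = \text{ANC4+}$ holds exactly.
* **Readiness checklists** — strict conjunctions over items, shipped as
  editable YAML (`default_checklist()`). The exact national checklists
  are not public; the defaults (e.g. syphilis = test + treatment drug;
  pre-eclampsia = BP apparatus + urine protein test + magnesium sulphate)
  are transparent stand-ins, and a missing item flag counts as "not
  available" — conservative, matching observed-on-the-day semantics.
* **Stratum matching cascade** — care-seeking strata without an exact
  readiness match reuse readiness collapsed first over location, then
  over managing authority, never over facility type (the strongest
  determinant of service availability). Still-unmatched shares contribute
  zero and are reported, never imputed.
* **Proxy tiers** — the tiered syphilis rule uses left-closed tiers:
  ANC4+ of exactly 40 falls in the 50%-multiplier tier, 75 in the 70%
  tier, 95 in the 100% tier ("less than 40" is strict). Proxy rules take
  ANC4+ in percent, as stated; everything else in the package is on the
  proportion scale, converted explicitly at the boundary.

## The fractional logit

For a fractional outcome $y \in [0,1]$ the model maximises the Bernoulli
quasi-likelihood $\sum_i w_i[y_i \log \mu_i + (1-y_i)\log(1-\mu_i)]$ with
$\mu_i = \mathrm{logit}^{-1}(x_i'\beta)$ by IRLS. Numerical choices:

* start at $\beta = 0$; converge when the maximum relative coefficient
  change drops below `tol` (default 1e-10, usually 5–10 iterations);
* $\mu$ clamped to $[10^{-10}, 1-10^{-10}]$ inside the weights only —
  outcomes exactly 0 or 1 are admitted without clipping, since the
  quasi-likelihood is finite there for finite $\beta$;
* divergence (|coefficient| above $10^6$, e.g. separation) or a singular
  system returns `converged = FALSE` with a diagnosis, never a silent
  estimate;
* inference uses HC1 sandwich standard errors (fractional outcomes
  violate the binomial variance function) with two-sided normal-reference
  p-values. The intercept-only fit equals `logit(weighted mean of y)` in
  closed form, tested to 1e-10, and full fits match
  `stats::glm(quasibinomial)` — used only as a cross-check — to ~1e-12.

**Stepwise selection.** The sources state only "stepwise, exit at
p = 0.1"; the flavor here is a design choice: forward addition of the
smallest-p candidate below 0.1, followed by backward pruning of any term
at or above 0.1, iterated to a fixed point, never exceeding two
covariates. Ties break on the fixed candidate order (blood, urine, blood
pressure, early enrolment, ANC4+), so selection is deterministic given
the data. A published-coefficient note: the hypertensive-disorders slope
is labeled "urine sample taken" in the source table while the prose
credits blood-pressure measurement; `published_models()` transcribes the
table and carries the discrepancy as a note rather than resolving it.

## The synthetic world

No microdata behind the original analyses are redistributable, so the
package ships a seeded generator with closed-form ground truth:

* two-stage household sample (default 400 clusters × 25 women;
  lognormal(0, 0.3) weights), months since birth uniform on 0–59 so the
  36-month filter keeps ~60%;
* visit counts split at the ANC4+ margin (default $p_{ANC4+} = 0.55$,
  typical of the sub-Saharan surveys this emulates): ANC4+ women get
  $4 + \mathrm{Poisson}(1.5)$ visits, the rest a zero-inflated count on
  0–3 — the margin is the only feature downstream stages use;
* care-source strata drawn from a configurable distribution for ANC4+
  women only (the analysis conditions on ANC4+), including an optional
  non-facility share (default 4%);
* facility item flags drawn per stratum so that every configured
  per-intervention readiness rate holds *exactly* in expectation: item
  rates are solved as $q = r^{1/k}$ within each checklist, conditioning
  on items shared with earlier checklists (the BP apparatus shared by
  the hypertensive and pre-eclampsia checklists makes those two
  readiness events positively correlated, as in real facilities);
* ground truth $p_{ANC4+}\sum_s \text{share}_s\, r_{s}$ available in
  closed form (`true_availability_coverage()`), so consistency of the
  whole chain is testable; the suite checks convergence over three
  increasing sample sizes.

Component receipt is independent of facility readiness by default —
components act as country-level predictors, not individually linked
outcomes; a `couple_components` switch ties them to facility-sourced
care-seeking for sensitivity work. `simulate_countries()` adds a
country-level latent quality factor shifting component rates and
readiness together, which is what gives the predictive models genuine
signal in the end-to-end pipeline.

What the generator does **not** emulate: nonresponse, interviewer
effects, native questionnaire encodings, geographic clustering of
facilities, or readiness heterogeneity *within* a stratum beyond
Bernoulli sampling. A green test therefore establishes correctness of
the estimators under the stated world, not robustness to those
real-data features.

The panel generator (`generate_country_panel()`) draws country covariates
from Beta laws and coverage as
$\mathrm{logit}^{-1}(x'\beta + \varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$. One consequence worth stating plainly:
with noise on the logit scale, $E[y|x] \neq \mathrm{logit}^{-1}(x'\beta)$,
so quasi-ML refitting converges to a slightly *attenuated* pseudo-true
coefficient (about 0.3% at $\sigma = 0.15$). Per-replicate confidence
intervals still cover the generating values at close to their nominal
rate, but the bias is detectable when averaging hundreds of replicates —
the test suite documents this rather than hiding it.

## Evaluation conventions

`compute_metrics()` reports RMSE, Pearson's $\rho$, and
$R^2 = 1 - SS_{res}/SS_{tot}$ about the observed mean — the prediction
(not regression) definition, which can be negative; the
squared-correlation variant is returned alongside since both conventions
circulate. The two coincide exactly when residuals are orthogonal to
predictions, and *not* in general (a shifted perfect predictor has
$\rho = 1$ but $R^2 < 1$) — both facts are tested. Correlations above
0.8 classify as strong, 0.5–0.8 (inclusive) as moderate, below 0.5 as
weak. A constant observed vector leaves $\rho$ flagged undefined, never
silently zero. Reported percentages round half-up; full precision is
kept internally.

## Known limitations

* Point estimates only: no design-based variance for the linked
  estimates (the bootstrap-over-clusters extension is deliberately out of
  scope).
* The linked estimand is *availability* coverage — an upper bound on
  received care; provider knowledge, workload and supervision reduce
  actual receipt.
* The published empirical country estimates cannot be reproduced here:
  they require non-deposited survey microdata and a closed mortality
  model. What is reproduced is every piece of in-scope arithmetic
  (proxy rules, prediction algebra, relative-impact ratios) and the full
  method on synthetic data with known truth.
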