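---
title: "Methods: discovering and temporally validating high-mortality subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and temporally validating high-mortality subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(riskgroups)
```

# Scope and estimand

`riskgroups` analyses child cohorts followed from 6 weeks to 3 years of
age in a demographic surveillance setting. Every effect in the package
is a **mortality risk difference per 100 children** (MRD): the additive
scale is what a public-health reader of such analyses acts on, and it
makes "synergy" a well-defined quantity (risk beyond the sum of
component effects). The workflow is inductive–deductive: candidates are
discovered on an early *hypothesis-generating* cohort (births up to the
split year, default 2011), frozen, and then re-estimated on the later
*temporal validation* cohort — consistency over calendar time, not a
single p-value, is the evidence standard.

# The synthetic cohort and what it emulates

The generator (`sim_config()`, `generate_cohort()`) is a first-class,
tested module, not a fixture: it defines the ground truth that every
estimator is judged against.

Its structure mirrors an urban West-African HDSS cohort:

* **Size and period.** 21,005 children over birth years 2003–2016 by
  default, the published scale of such a cohort.
* **Baseline trend.** A linear per-100 risk decline by birth year. The
  default (intercept 2.4 at 2003, slope −0.18/year, plus the covariate
  burden) yields an overall risk falling from roughly 5 to roughly 3
  per 100 across the period.
* **Covariate hierarchy.** Environmental covariates of the residence,
  household social covariates, and individual/birth covariates, in that
  causal order; household covariates may depend on environmental ones
  and birth covariates on both through configured logistic links.
  Covariates are coded in the risk-increasing direction (e.g. *living
  far from a major road*), so the additive model's bounds are easy to
  reason about.
* **Planted structure.** One circular residential hotspot (default
  +4 per 100 within 200 m, with doubled residential density), one
  two-factor synergy (default *twin × rainy season*, +6.8 per 100 when
  both present), and single-factor increments (e.g. +4.0 for no
  prenatal consultations, +4.3 for twins).
* **Informative emigration.** A logistic model of emigration before age
  3 on baseline covariates (default mean ≈ 25%), making the
  complete-case sample selectively biased, which is what IPCW must
  undo.

**Design choices made once, and why.**

* *Additive risk, not logistic.* Effects are additive on the per-100
  scale, so a planted +4 is exactly the risk difference the estimators
  target; with a logistic generator the marginal estimand would differ
  per covariate pattern and "truth" would need numerical integration.
* *Out-of-bounds patterns are an error, never clamped.* Silent clamping
  would corrupt planted ground truth; `sim_config()` rejects any
  configuration whose most extreme covariate pattern leaves [0, 100],
  and `generate_cohort()` re-checks realized children, naming the
  offending pattern.
* *Dry/rainy season is Bernoulli(0.49), independent of year*, matching
  the near-even split such cohorts report.
* *Emigration wins over death.* For an emigrated child the death
  indicator is undefined (`NA`): the family left, the outcome is
  unobserved. Death and emigration ages are drawn uniformly over
  follow-up; they decorate the Kaplan–Meier risk but the binary
  death-by-age-3 outcome carries the analysis.

What the generator does **not** emulate: real Bissau geography or
ethnic-composition dynamics, registration-system changes over time,
age-varying hazards, seasonally varying exposure during follow-up, or
missing-data patterns (the design is complete-case by construction).
Passing recovery tests on this generator therefore demonstrates the
estimators' correctness under the stated causal structure, not
robustness to every failure mode of real surveillance data.

# Censoring weights

Emigration is treated as a single binary event ("left before age 3")
rather than time-varying censoring, matching a design that excludes
emigrants and reweights the remainder. `fit_censoring_model()` is a
logistic regression of that indicator on all baseline covariates;
`compute_ipcw()` weights each uncensored child by `1/P(uncensored)`.

* *Unstabilized weights* (every `w ≥ 1`) are used deliberately: the
  weighted sample size then represents the full pre-emigration cohort,
  which is how such weighted n's are reported.
* *Truncation* defaults to 10 — far above the weights the default
  generator produces (max ≈ 1.6) — and the diagnostics report the
  truncated count so extreme-weight situations are visible.
* Perfect separation in the censoring model is an error naming the
  covariate; zero censored children yields the trivial model `P = 0`.

The pseudo-population property — weighted means of covariates and of
the death indicator match the full pre-emigration cohort — is tested
directly against the generator's planted selection.

# Risks, synergy, PAF

Kaplan–Meier risk (`km_risk()`) uses `survival::survfit` with
Greenwood-variance log–log intervals. Crude subgroup risks
(`crude_risk()`) are weighted means per 100 with Wald intervals from
the frequency-weight variance `Σ(wᵢ(yᵢ−p̂))²/(Σwᵢ)²`; symmetric Wald
intervals match the per-100 reporting convention of this literature.

The synergy statistic for a conjunction subgroup is the subgroup
indicator's coefficient in a weighted linear-probability model that
also contains each component's main effect and linear calendar time —
and deliberately nothing else. A linear-probability model with HC0
sandwich errors is used instead of an identity-link binomial GLM
because the latter routinely fails to converge near the probability
boundary while targeting the identical coefficient.

`paf(prevalence, aMRD, overall_risk)` returns
`100 · prevalence · aMRD / overall_risk` at full precision (the
one-decimal rounding conventional in reporting is applied by callers),
so that PAF's exact linearity in both arguments holds and is tested.
The overall risk used when pooling two cohorts is the
weighted-size-weighted mean of their risks.

# Spatial scan

`scan_surface()` slides a `window × window` square (default 250 m) in
`step` increments (default 10 m). Numerical and semantic choices:

* *One global trend, window-level residuals.* A single weighted linear
  trend of death on centered birth year is fitted once; each node adds
  the weighted mean trend residual of its children to the global
  adjusted risk. Per-window trend fits would be unstable exactly at the
  100-child masking threshold.
* *Reference year* defaults to the midpoint of the cohort's birth-year
  range (the anchor is otherwise arbitrary; the midpoint minimizes
  extrapolation both ways).
* *Half-open windows* `[x, x+250) × [y, y+250)` make the overlapping
  window system partition-consistent; boundary behaviour is part of the
  tested contract (`window_membership()`).
* *Masking uses the unweighted child count* (a disclosure/stability
  rule about actual children), while the risk value itself is weighted.
* The implementation bins children into `step`-sized cells and uses 2-D
  cumulative sums; equality with the brute-force double loop is an
  oracle test, not an assumption.
* Export is the plain-text ESRI ASCII grid (`.asc`, `NODATA_value`
  for masked nodes), written at full double precision so a write–read
  round trip is exact. It is the package's single raster interchange
  format; requests for other formats error.

`surface_peaks()` (greedy maxima with a separation radius) is a
non-inferential convenience for proposing candidate circles — mirroring
how such areas are in practice drawn by eye — and the inferential step
is always `area_effect()`'s calendar-adjusted comparison of children
inside versus outside a circle.

# Backdoor adjustment and TMLE

`adjustment_set()` encodes the domain hierarchy: environmental
exposures adjust for calendar time only; household exposures add all
environmental covariates; individual/birth exposures add the household
covariates too. Sex and birth season are treated as unconfounded (no
adjustment) — nature randomizes them.

`tmle_risk_difference()` is written from first principles:

1. initial outcome predictions from a weighted **main-effects logistic**
   regression of death on the subgroup indicator and W (no ensemble
   learner: determinism and auditability at this scale matter more, and
   the double-robustness against the propensity model carries the
   consistency argument; the initial learner is a swappable step);
2. propensity `g(W)` by weighted logistic regression, truncated to
   [0.01, 0.99] — the truncated fraction is kept in the fit diagnostics
   and a warning is raised above 5%;
3. one logistic fluctuation with *two* clever covariates `A/g` and
   `(1−A)/(1−g)` and the initial logit as offset, so both score
   equations are solved and the weighted mean influence curve is zero
   to numerical precision (the fit stores it; tests require
   `|mean(IC)| < 1e−8`, with GLM convergence tightened to 1e−12);
4. `ψ = Σwᵢ(Q*(1,Wᵢ) − Q*(0,Wᵢ))/Σwᵢ · 100`, with the standard error
   `sqrt(Σ(wᵢ ICᵢ)²)/Σwᵢ` — IPCW weights enter all regressions as
   frequency-type weights and scale the influence curve accordingly.

With an empty adjustment set the whole construction collapses
algebraically to the crude weighted risk difference, which is asserted
to numerical precision. Rare subgroups (1–2% prevalence) naturally pin
`g` near its lower truncation bound; that is expected and visible in
the diagnostics rather than silenced.

The cross-cohort **similarity test** is a two-sample z-test,
`z = (e₁−e₂)/sqrt(se₁²+se₂²)`. This functional form was adopted because
it reproduces the printed p-values of the motivating study's summary
table from the printed estimates and intervals (reconstructing SEs as
CI-width/3.92) to within rounding; it is documented as inferred, and it
refuses estimates tagged as coming from the same cohort. The
**combined estimate** pools individual-level data from both cohorts
into one TMLE with calendar time forced into W (pooled TMLE was chosen
over inverse-variance meta-analysis of the two estimates; with
individual data available, pooling uses it).

No multiple-testing correction is applied anywhere: the workflow is
explicitly exploratory, and the temporal validation stage is the
replication filter.

# Non-negative risk decomposition

The multifactorial stage models each child's risk as a baseline plus
non-negative excess terms:

`p_i = R_b + Σ_h w2_h · relu(Σ_f W1_{fh} x_{if} + b_h)`,
with `W1 ≥ 0`, `w2 ≥ 0`, `b ≤ 0`, `R_b ∈ [0,1]`.

Hidden units can only *add* risk and only when their feature
requirements are met, which makes them interpretable as candidate
synergy detectors; a unit whose bias is more negative than any single
weight fires only for feature *combinations*.

Numerical and design choices:

* **Loss and optimizer.** Weighted squared error, full-batch projected
  gradient descent (negative `W1`/`w2` entries zeroed, `b` capped at 0,
  `R_b` clamped to [0,1] after each step). Training operates on the
  *collapsed unique binary patterns* with aggregated weights — the
  gradients are algebraically identical and the cost becomes
  independent of cohort size.
* **Intercept step size.** The intercept's quadratic curvature is 2
  (every child contributes), so its update uses half the layer learning
  rate; at the default `lr = 1` a full step would sit exactly on the
  stability boundary and oscillate.
* **Ridge-breaking decay.** A tiny L2 penalty (`decay = 1e-6`) on `W1`
  and `w2` breaks the exact flat ridge between the baseline intercept
  and an always-active hidden unit. The value is orders of magnitude
  below the data curvature of even rare-pattern units, so planted
  effects are not visibly shrunk (tested).
* **Initialization and restarts.** `W1, w2 ~ U(0, 0.05)`,
  `b = −0.01`, `R_b` at the weighted outcome mean; the best of 10
  seeded restarts by final loss is returned, and results are
  bit-reproducible given (data, hyperparameters, seed). Divergence
  (non-finite loss) is an error advising a smaller learning rate.
* **Calendar handling.** Calendar time is never an ordinary feature; it
  enters as birth-year *band* indicators (default 3-year bands) with
  the most recent band as reference, so period effects are absorbed by
  the network without polluting covariate contributions — under a
  declining trend the non-negative band weights point the right way.
  Rules consisting only of calendar bands are dropped as candidates.
* **Attribution contract.** Each unit's output is attributed to the
  child's active features proportionally to their share of the positive
  pre-activation `W1_{fh}x_{if} / Σ_{f'} W1_{f'h}x_{if'}`; an active
  relu guarantees the denominator is positive. Completeness
  (`R_b + Σ_f c_{if} + clamp = p_i`) is exact and asserted at 1e−10.
* **Clustering.** Ward linkage (`ward.D2`) on Euclidean distances
  between the *unique* contribution profiles, with multiplicity
  weights via `hclust(members=)`; the tree is cut at `max_groups`
  (default 8). Groups under 0.5% prevalence are kept but flagged
  "very few children" and excluded from validation candidates.
* **Rules.** A group becomes the conjunction of the features whose
  group-mean contribution reaches `threshold` (default 0.5) of the
  group's top feature; `threshold = 0` returns every active feature and
  `threshold ≥ 1` returns a single feature with alphabetical
  tie-breaking — both ends of the contract are tested.

Known behaviour worth stating: when a causal feature co-occurs with
correlated neighbours, a slice of its credit can leak to them before
the unit fully specializes (total excess risk per child is fitted well
before its within-unit split settles). Total effects of single factors
can also be diluted across units; the single-factor regression stage is
the instrument for those, and the decomposition stage is aimed at
combinations.

# Pipeline and freezing

`run_discovery()` returns the union of spatial circles (peaks exceeding
the global adjusted risk by a configurable excess, default +3 per 100),
single factors whose adjusted CI excludes 0 (no multiplicity
correction, by design), and decomposition rules above the prevalence
floor — each candidate carrying its provenance. The candidate list is
fingerprinted (FNV-1a over its serialization); `validate_candidates()`
recomputes the fingerprint and refuses artifacts modified after
discovery, which is the enforcement of "rules frozen before validation
outcomes are touched". Cells with fewer than 20 children on either side
of either cohort (configurable) are reported as "very few children"
with estimates suppressed, the convention such summary tables use.

Candidate-type-graded adjustment sets in validation: spatial areas
adjust for calendar time; single factors for their backdoor set;
multifactorial rules for calendar + environmental + household.

# Problem sizes in the test suite

The suite's simulation sizes are chosen so that each check is sharp at
3-standard-error tolerances while the whole suite stays desk-scale:
parameter-recovery and bias checks at n = 50,000; TMLE CI coverage over
200 replicates of n = 50,000; hotspot localization over 20 cohorts of
n = 21,005; synergy-pair rule recovery over 10 cohorts of n = 50,000
(hidden layer of 10); the end-to-end demonstration at n = 10,000 with a
reduced training schedule. Randomized checks fix their seeds.

# Limitations

* Censoring is binary, not time-varying; there is no longitudinal or
  cross-validated TMLE.
* The similarity test's form is inferred from reproduced printed
  values, not taken from a published formula.
* The spatial stage is a masked moving-window mean — deliberately not a
  likelihood scan statistic — and candidate circles are a fixed-radius
  convenience.
* The decomposition stage's architecture (hidden units, loss,
  clustering linkage) is a documented default, configurable but not
  tuned per dataset; hyperparameter search is out of scope.
* All validation of estimator correctness is against the synthetic
  generator's causal structure; real surveillance data can violate it
  in ways the generator does not represent.
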