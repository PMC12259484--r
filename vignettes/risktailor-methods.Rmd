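---
title: "Methods: behavioural risk scoring, message tailoring, and determinant relevance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural risk scoring, message tailoring, and determinant relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risktailor)
```

risktailor implements the computational core of a questionnaire-based
behavioural risk tool for respiratory-infection control: a short
risk-estimation questionnaire, a three-factor risk model, a tailored-message
engine structured as an acyclic behaviour change diagram (ABCD), and the
determinant analytics (CIBER summaries and Potential-for-Change indices)
used to decide which psychological determinants future interventions should
target. This vignette is the package's account of the models, the defaults,
and the choices made where the design was genuinely open.

## The questionnaire model

A respondent record holds demographics (country, decade age bands plus an
explicit "declined" code, gender), six multi-select behaviour questions
(work contexts, current self-isolation behaviours, triggers for isolating
more, behaviours the respondent would stop, handwashing situations,
handwashing thoroughness), one ordinal distance-keeping item, and a sparse
map of determinant-item scores. Determinant items follow the Reasoned
Action Approach (RAA): each item measures one sub-determinant of attitude,
perceived norm, or perceived behavioural control, for one of three target
behaviours (social distancing, self-isolation, hand washing).

The packaged bank contains exactly 276 items: 3 behaviours × 23
sub-determinants (9 attitude, 7 perceived norm, 7 perceived behavioural
control) × 4 phrasing variants, each on a 1–7 bipolar scale — the usual
convention for RAA items. The item *texts* are generated placeholders; the
*structure* (counts, identifiers, construct coverage, scales) is what every
downstream computation depends on, and that is exact. Users with their own
operationalisations load them with `load_item_bank()`.

Two coding decisions matter downstream:

* **Opt-in**: respondents choose how many determinant items to answer, an
  even number from 0 to 20, and receive a uniformly random item subset of
  that size. `n_items_opted` bounds the number of stored scores.
* **"Never in public"**: the distance item offers a sixth answer for people
  who are never in public places. It is stored faithfully but coded as
  missing whenever the item serves as the behaviour measure
  (`distance_to_numeric()`): someone with no exposure has no defined
  distance-keeping frequency, and coding it as either extreme would bias the
  correlations.

## The three-factor risk model

Risk is decomposed into *exposure* ("risk of getting the virus": work
contexts, self-isolation behaviours, distance keeping), *hygiene* ("risk
from not removing the virus": handwashing), and *uncontrollable* factors
(demographics). For factor $f$ with weight map $w_f$ and answer set $A$,

$$\mathrm{score}_f = \mathrm{clamp}_{[0,100]}\left(\frac{100 \cdot m \cdot \sum_{a \in A_f} w_f(a)}{\mathrm{scale}_f}\right)$$

where $m \le 1$ is the product of modifiers attached to endorsed
self-isolation triggers (for the exposure factor only; $m = 1$ elsewhere).
Choices behind this form:

* **Additivity.** Answers contribute additive non-negative weights.
  Protective answers carry weight 0 and lower risk only by displacing
  risk-conferring answers. This is the minimal aggregation rule consistent
  with a per-answer "degree of contribution", and it makes monotonicity
  (adding a risk answer never lowers the score) provable rather than
  incidental.
* **Weights are configuration, not code.** The deployed tool's weights were
  expert-elicited; they are not a computable object. The engine's contract —
  which answers touch which factor, how scores normalise and clamp — is the
  reproducible part. A documented default ships: uniform weight 1 on
  risk-conferring answers, 0 on protective ones, with the ordinal distance
  item graded 4 ("almost never") down to 0 ("almost always"), and trigger
  modifiers of 0.95 per endorsed trigger (reported willingness to retreat
  slightly lowers expected exposure).
* **Categories.** Scores map to low / moderate / high by lower-inclusive
  half-open intervals with default cuts at 33 and 66 — tertiles of the score
  range, configurable, since the deployed scale granularity is a
  presentation choice rather than a model property.

## The tailoring engine

Messages live in an ABCD table: each row links a behaviour change principle
(BCP), its conditions for effectiveness, and a concrete application (the
message text) to the sub-determinant and behaviour it is assumed to
influence. Selection is rule-driven: declarative triggers
(field/operator/value over respondent answers) make a behaviour's messages
eligible; eligible entries are ordered by the risk score of the factor
behind their behaviour, with ties broken in a fixed order (self-isolation,
distance keeping, hand washing), then by fired-rule priority, then by
stable table order, and truncated to `max_messages` (default 6, two per
behaviour). A respondent for whom no rule fires — fully protective answers
on all fronts — receives a positive-reinforcement set instead of
risk-reduction messages.

Two design points were open and are resolved as follows: the deployed tool
emitted an opaque string encoding the selection; risktailor instead records
explicit provenance (ABCD row, fired rule, factor score) on every emitted
message, because traceability is the property worth testing. And since no
ordering between behaviours was specified, the engine prioritises the
behaviour with the highest factor risk — the choice that puts the largest
modifiable risk first.

## CIBER and the Potential-for-Change indices

For each determinant item, against the behaviour measure (by default the
distance item):

* the **mean** with a **99.99% t-interval** — deliberately ultra-wide so
  that many items can be inspected jointly without per-comparison optimism;
* the **zero-order Pearson correlation** with a **95% CI** via the Fisher
  z transform, $\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$,
  computed on pairwise-complete observations;
* two **Potential-for-Change indices**:

$$P\Delta_1 = \begin{cases}(\max x - \bar x)\, r & r > 0\\ (\min x - \bar x)\, r & r < 0\\ 0 & r = 0\end{cases}
\qquad
P\Delta_2 = \begin{cases}(q_{.95}(x) - \bar x)\, r^2 & r > 0\\ (q_{.05}(x) - \bar x)\, r^2 & r < 0\\ 0 & r = 0\end{cases}$$

$P\Delta_1$ multiplies the observed room for improvement (distance from the
mean to the observed extreme, not the theoretical scale bound) by the
association. $P\Delta_2$ replaces the extreme with a 5%-trimmed one and
squares the correlation, damping sample idiosyncrasies at both ends. The
test suite confirms both mechanisms numerically: a single injected extreme
score moves $P\Delta_2$ less than $P\Delta_1$, and under rare (1%)
contamination the $P\Delta_2$ ranking is the more bootstrap-stable one.
The advantage is tied to that regime — trimming only helps when extremes
are rare enough to fall outside the 0.95 quantile, and squaring makes the
ranking *less* stable among uniformly weak associations, where $r^2$
compresses the differences.

Numerical conventions that the values depend on:

* Quantiles interpolate linearly between order statistics (R's default
  type 7). A different convention shifts $P\Delta_2$ for small samples.
* On the negative-correlation branch, $P\Delta_2$ follows its definition
  literally: $r^2 > 0$ while $q_{.05} \le \bar x$, so negatively associated
  items get values at or below zero and sort below unassociated items in
  the descending ranking. ($P\Delta_1$ stays non-negative on both
  branches: its two factors always carry matching signs.)
* All statistics for an item are computed on the same pairwise-complete
  subset, so the mean, extremes and correlation describe the same
  respondents.
* Items with fewer than `min_pairs` (default 10) pairwise-complete
  observations, or with undefined correlations (constant input), are
  reported in a separate insufficient-data table — never silently dropped
  and never coerced to zero.
* No multiple-testing correction is applied. CIBER's logic is estimation
  under wide intervals, not null-hypothesis testing; correcting the 95%
  association CIs would conflate the two.

`ciber_table()` emits three orderings (by $P\Delta_1$, by $P\Delta_2$, by
$r$, each descending); `select_targets()` flags items whose association CI
excludes zero in the favourable direction *and* whose mean leaves room for
improvement (below 90% of the scale range by default) — a strong
correlation at the scale ceiling is not a useful intervention target.
`ciber_plot()` draws the two-panel display: raw score distributions with
mean-CI diamonds on the left, association CIs on a fixed $[-1, 1]$ axis on
the right; the point jitter is deterministic given its seed.

## The synthetic cohort generator

Real deployment data are not required anywhere: `simulate_cohort()`
generates cohorts with known structure. The generative model is a latent
Gaussian (copula-style) construction: each completer has a latent behaviour
tendency $b \sim N(0,1)$, discretised to the five distance levels through
thresholds matching the configured marginal; each answered item draws
$x = \rho b + \sqrt{1-\rho^2}\,\varepsilon$ with the planted latent
correlation $\rho$, then is rescaled, rounded and clamped to the item's
1–7 scale. Item subsets are uniformly random at the opted-in size, so
missingness is ignorable by construction and pairwise-complete estimates
are unbiased for the discretised association.

The defaults *are* the study conditions: the distance marginal
(0.9 / 1.9 / 8.7 / 23.6 / 61.5% plus 3.4% never-in-public), the
multi-select endorsement rates, the demographic margins, and the funnel
proportions (26.6% first-page-only, 11.3% started-not-completed, 62.0%
completed) follow the deployment's reported response structure. The opt-in
distribution (35% answer none, a long middle, 10% answer all 20) and the
item latents (mean at 70% of the scale range, sd 1.2 — the usual positive
skew of endorsement items) are package defaults chosen once and documented
here.

Two properties of the generator deserve emphasis:

* **Attenuation.** Discretising both variables attenuates correlations:
  with the strongly skewed distance marginal, a planted latent 0.6
  yields an observed Pearson correlation near 0.48. Sign and ordering are
  preserved — which is why the validation targets ordering recovery and
  sign/coverage of weak values, and why `recoverability_report()` reports
  the CI-covers-truth flag against the *latent* value together with this
  caveat: at large $n$ the CI of a strongly correlated item concentrates
  below its latent value. That is a property of ordinal data, not an
  estimation error.
* **What is not emulated.** Country-level heterogeneity, temporal usage
  spikes, response styles (acquiescence, straight-lining), non-ignorable
  opt-in (e.g. more engaged respondents answering more items), and
  item-level wording effects. Passing tests therefore certify the
  estimators and the pipeline under clean planned missingness — not
  robustness to the messiness of field data.

## Validation problem sizes

The test suite and the acceptance script validate against independent
oracles at these sizes, chosen to make Monte-Carlo error negligible
relative to the property being checked: 1,000 random Likert datasets for
the $P\Delta$ brute-force equivalence; 2,000 replicates at $n = 100$ per
$\rho \in \{0, 0.3, 0.7\}$ for Fisher-z coverage (binomial SE ≈ 0.5
percentage points); 200 seeded replicates at $n = 1{,}000$ for recovery of
the planted ordering (0.6, 0.4, 0.2, 0.0); exhaustive enumeration of small
answer-set lattices for risk-engine monotonicity and factor separation;
and 100 simulated respondents against an exhaustive rule evaluator for the
tailoring engine.

## Known limitations

The default risk weights are a testing convention, not an elicitation:
absolute scores under the default configuration have no epidemiological
interpretation, only the monotone structure does. The item bank's texts
are placeholders. Only an English message fixture ships, although all
tables are locale-keyed. The determinant analysis is deliberately
bivariate (CIBER's estimation logic); it does not adjust determinants for
one another, and a multivariate re-analysis can reverse apparent relevance
when determinants are strongly intercorrelated.
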