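---
title: "Two-step meta-epidemiology of preclinical meta-analyses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step meta-epidemiology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaepi)
```

## The question and the model

Preclinical (animal) studies are routinely synthesized by systematic
reviews with meta-analyses, and the included studies are rated for risk
of bias on items adapted from the SYRCLE tool: randomization, baseline
similarity, allocation concealment, random housing, blinding of
caregivers, blinding of the animal model, random outcome assessment,
blinding of assessors, attrition, and selective outcome reporting.
Meta-epidemiology asks whether studies with poor (or unreported)
methodology report systematically different effect sizes than studies
with adequate methodology.

`metaepi` implements the standard two-step approach for standardized
mean differences (SMDs):

**Step 1.** Within each meta-analysis $k$, regress the
direction-aligned SMDs $y_{ik}$ of its experimental arms on a binary
moderator $x_{ik}$ ($1$ = the study is at *high or unclear* risk for
the characteristic, $0$ = *low* risk) by random-effects
meta-regression with weights $1/(v_{ik} + \hat\tau^2_k)$. The slope
$\hat\beta_k$ is the **difference in standardized mean difference
(DMSD)** for that meta-analysis, with standard error
$\mathrm{se}(\hat\beta_k)$.

**Step 2.** Pool the $\hat\beta_k$ across meta-analyses by
random-effects meta-analysis with weights
$1/(\mathrm{se}^2(\hat\beta_k) + \hat\tau^2)$. A positive pooled DMSD
means high/unclear-risk studies report larger (more beneficial)
effects.

Before step 1, all SMDs are sign-aligned so that positive values mean
benefit (`align_direction()`); otherwise a "bias" that inflates effects
toward benefit would cancel across meta-analyses whose outcomes run in
opposite directions.

### Eligibility and skip rules

A meta-analysis contributes to the analysis of a characteristic only if
it has at least `min_studies = 3` studies carrying a rating, among them
at least one high/unclear and at least one low (otherwise the within-MA
contrast does not exist). A characteristic is analysed only when at
least `min_mas = 10` meta-analyses are eligible; below that the result
is reported as *skipped*, which is a data finding, not an error — in
real corpora, items that reviews rarely assess (random housing,
blinding of caregivers or of the model, random outcome assessment,
allocation concealment) are exactly the ones that fail this rule.
Arms without a rating are excluded from the contrast; the rest of the
meta-analysis still contributes.

### The unit of analysis

Step-1 regressions run at the level of the *experimental arm*, not the
study: multi-arm studies contribute each arm, and the primary analysis
treats arms as independent. The dependency induced by arms of the same
study (notably shared control groups) is addressed by the sensitivity
analysis (`run_sensitivity_robust()`), which replaces the step-1
model-based standard errors with cluster-robust (sandwich) standard
errors clustered on `study_id`, using the CR2 small-sample adjustment
with Satterthwaite degrees of freedom. CR0 and CR1 are selectable for
comparison. An analysis where robust and primary results agree supports
the arm-level primary specification.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_mas` | 10 | minimum eligible meta-analyses per characteristic |
| `min_studies` | 3 | minimum rated studies per eligible meta-analysis |
| `tau2_method` | `"REML"` | heterogeneity estimator (DL selectable) |
| `ci_method` | `"wald"` | step-2 CI; `"knapp_hartung"` gives t-based CIs |
| `robust` | `"none"` | step-1 robust variance (`"CR2"`, `"CR1"`, `"CR0"`) |
| `unclear_direction_policy` | `"exclude"` | handling of MAs without a known direction of benefit |

REML is the default $\tau^2$ estimator because it is less biased than
DerSimonian–Laird under heterogeneity; DL is retained (closed form,
reproducible against older meta-epidemiological software) and is used
internally wherever only Cochran's $Q$ and $I^2$ are needed, since
those are defined on fixed-effect weights regardless of the estimator.
Wald intervals are the step-2 default; Knapp–Hartung is available when
the number of meta-analyses is small.

Meta-analyses whose expected direction of benefit is unclear cannot be
aligned and are excluded by default (with a logged reason). The
alternative `"pooled_sign"` policy aligns them by the sign of their own
pooled random-effects estimate; it keeps more data but uses the data
twice, so it is not the default.

## Effect-size conventions

`compute_smd()` returns Hedges' $g$ by default (Cohen's $d$ by flag),
with variance $(n_t+n_c)/(n_t n_c) + g^2/(2(n_t+n_c))$. Reported SMDs
with confidence intervals are converted by `smd_from_ci()` under a
normal (Wald) interval assumption; $t$-based intervals are not
auto-detected, and this assumption is logged rather than guessed at.
Shared control groups in multi-arm studies are handled by the standard
splitting correction: `split_shared_control()` assigns
$\lfloor n_c / k \rfloor$ control animals to each of the $k$ arms
(means and SDs unchanged, remainder dropped — conservative and
reproducible).

## What the synthetic-data generator emulates

The extraction dataset behind a real meta-epidemiological corpus is
typically not public, so `simulate_dataset()` generates datasets with
known ground truth whose *structure* matches the audited corpus this
package was built around:

* 63 meta-analyses; studies per meta-analysis follow a discretized
  log-normal with median 9 (IQR roughly 5–16), capped at [3, 60];
* studies contribute 1–3 experimental arms (probabilities 0.7/0.2/0.1,
  giving a median near 13 arms per meta-analysis) that share one
  control group, split via `split_shared_control()`;
* group sizes are uniform integers on [5, 15] — typical preclinical
  scale, chosen once since corpora rarely report them;
* per-characteristic rating prevalences default to the audited
  distribution of 763 preclinical studies (e.g. randomization rated
  for every study, 17% high / 53% low / 30% unclear; random housing
  unassessed for two thirds of studies and almost never rated low) —
  under these defaults the rarely-assessed characteristics genuinely
  fall below the 10-eligible-MA threshold, reproducing the skip
  pattern seen in practice;
* true study effects are $\psi_{sk} \sim N(\theta_k, \tau_w^2)$ with
  $\theta_k \sim N(\mu, \tau_b^2)$, $\mu = 0.8$, $\tau_b = 0.4$;
  $\tau_w = 1.2$ was calibrated by pilot simulation so that the median
  within-MA $I^2$ sits near the 77% observed in the corpus (the
  acceptance script recomputes this calibration);
* the bias mechanism is an additive shift: every arm of a study rated
  high/unclear on characteristic $c$ has $\delta_c$ added to its true
  effect — the same functional form the DMSD estimator targets. The
  default is $\delta = 0$ (no bias);
* sampling errors of arms sharing a control are drawn *correlated*
  (covariance $1/n_c$ per split control), so the robust sensitivity
  analysis faces a real within-study dependency;
* half the meta-analyses are generated as `benefit_negative` and have
  their observed SMDs sign-flipped, exercising the alignment step.

What it deliberately does **not** emulate: publication bias and
small-study effects; correlation of ratings *across* characteristics
(independence is a stated simplification; real ratings are correlated
because they share a rater and a reporting culture); review-level
clustering of "not assessed" (a review that skips an item skips it for
all its studies — the generator assigns missingness per study); and
confounding of ratings with study size, unless `confounded_mode = TRUE`
is set, which ties exposure probability to group size as a stress test.
Passing tests on this generator therefore show the estimator recovers
an additive bias under the corpus's structure — not that real rating
data are this clean.

## Numerical choices and degenerate inputs

* REML maximizes the restricted likelihood by bounded scalar search on
  $\tau^2 \in [0, 10\cdot\max(\mathrm{var}(y), \max v_i)]$ with
  tolerance $10^{-8}$; deterministic, no random starts, truncated at 0.
* The CR2 adjustment matrices solve
  $A_j(\Phi_j - X_j M X_j')A_j' = \Phi_j$ under the working covariance
  $\Phi = \mathrm{diag}(v_i + \tau^2)$; near-singular within-cluster
  blocks are pseudo-inverted (eigenvalues below $10^{-12}$ dropped).
  Satterthwaite degrees of freedom match the first two moments of the
  variance estimator under the working model.
* All-zero sampling variances raise a validation error rather than
  pooling; a meta-regression without both moderator values raises a
  "no contrast" error, which the pipeline converts into a logged
  per-MA exclusion rather than a failure.
* Percentages in descriptive tables round half-up to one decimal,
  matching how printed audit tables round; quantiles are type-7
  (linear interpolation).
* Validation resolves each arm's variance in a fixed order — explicit
  `var`, then confidence interval, then arm-level summaries — and logs
  (rather than guesses about) any ambiguity.

## Problem sizes used in validation

The test suite validates parameter recovery at 50 meta-analyses of 20
studies with $\delta = 0.3$ (mean over 200 replicates within $\pm$0.05;
CI coverage over 1000 replicates), the permutation null with 500
within-MA label shuffles, the robust-vs-naive comparison on simulations
with four-arm studies, and the $I^2$ calibration over 200 default-sized
replicates. These sizes are the package's validation design; larger
runs only tighten the Monte-Carlo error.

## Known limitations

* The two-step DMSD estimator assumes the bias acts additively on the
  aligned SMD scale and identically across meta-analyses up to the
  step-2 heterogeneity; multiplicative or outcome-dependent bias is
  outside the model.
* Weights depend on $v_i$, which for SMDs is itself a function of the
  estimate; with small groups this induces a small correlation between
  effect and weight and a slight attenuation of recovered shifts.
* Risk-of-bias ratings are taken as given inputs; disagreement between
  raters or reviews is heterogeneity the model absorbs, not a quantity
  it corrects.
* Only SMD effect sizes are supported; ratio measures are out of scope.
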