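---
title: "Conformal quality control for diagnostic classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal quality control for diagnostic classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformalqc)
```

## The problem

An AI system for grading prostate biopsies outputs, for every core, a
probability vector over the diagnostic classes (benign and ISUP grade groups
1–5, or simply benign vs cancer). Point predictions carry no statement of
reliability: when the system meets tissue it has never seen, or slides from a
different scanner or laboratory, it still produces a confident-looking argmax.
`conformalqc` wraps such probability outputs in a Mondrian inductive conformal
predictor (ICP) that (i) converts each prediction into a *prediction region* —
a set of labels guaranteed, under exchangeability, to contain the truth with a
user-chosen confidence, per class — and (ii) turns violations of that
guarantee into a statistical alarm for dataset shift.

## The conformal model

Let the labeled calibration set contain, for class $k$, the nonconformity
scores $\alpha_i = 1 - \hat p_{y_i}(x_i)$ of the $n_k$ examples whose true
label is $k$ (one minus the predicted probability of the true class). For a
new example $x$ and candidate label $k$ with score
$\alpha^* = 1 - \hat p_k(x)$, the class-conditional p-value is

$$
p_k(x) \;=\; \frac{\#\{i : \alpha_i \ge \alpha^*\} + 1}{n_k + 1}
\qquad\text{(non-smoothed)},
$$

or, with a tie-breaking draw $\tau \sim U(0,1)$,

$$
p_k(x) \;=\; \frac{\#\{i: \alpha_i > \alpha^*\} +
\tau\,(\#\{i : \alpha_i = \alpha^*\} + 1)}{n_k + 1}
\qquad\text{(smoothed)}.
$$

The region at confidence $c(k)$ is $\{k : p_k(x) > 1 - c(k)\}$, with strict
inequality, so empty regions remain possible at high significance. Stratifying
the calibration scores by *true* class and reading each candidate label
against its own stratum is the Mondrian (class-conditional) construction: the
error rate is bounded by $\varepsilon(k) = 1 - c(k)$ *within every class*,
which matters under the heavy class imbalance typical of screening cohorts
(ISUP 3 is ~4% of biopsies).

Design choices that were genuinely open:

* **Smoothed vs non-smoothed.** Both are implemented. Non-smoothed is the
  default: it is deterministic and conservative
  ($\Pr\{p \le \varepsilon\} = \lfloor \varepsilon (n_k+1)\rfloor / (n_k+1)
  \le \varepsilon$). Smoothed p-values are exactly $U(0,1)$ under
  exchangeability and drive the distributional diagnostics below.
* **Nonconformity direction.** "One minus the predicted probability" and "the
  predicted probability" with a flipped comparison give identical regions; the
  package fixes the former and documents it.
* **Ties.** Handled by the counting definitions above, never by rank
  midpoints; the synthetic generator produces continuous scores so ties occur
  only through deliberate construction (and are unit-tested exactly).
* **Small strata.** A stratum with $n_k$ scores cannot produce
  $p \le 1/(n_k+1)$; `mondrian_calibrate()` warns below `min_per_class = 25`
  because at, say, 99.9% confidence a 24-score class makes the region
  trivially full.
* **Grouped splitting.** `split_train_calibration()` assigns whole subjects
  to one side (biopsies from one man are not exchangeable with each other),
  defaulting to a 90/10 proper-training/calibration split. The calibration
  share is then exact only up to one subject's worth of rows.

## Evaluation surfaces

Every evaluated example falls into exactly one of four categories: **error**
(non-empty region excluding the truth), **empty**, **correct single**,
**correct multiple**; `tally_regions()` reports counts and whole percents per
class and overall, and **efficiency** = correct singles / n. Note two error
notions: the tally's `error` row excludes empty regions so the four rows
partition $n$; the *validity* error on the calibration curve — the fraction
of true labels outside the region, plotted against $\varepsilon$ — counts
empty regions as errors. `calibration_curve()` implements the latter;
`tally_regions()` the former; the identity
$(\text{error} + \text{empty})/n = \text{curve}(\varepsilon)$ is enforced by
test.

`panel_coverage()` scores regions against a panel of independent raters (the
share of individual votes falling inside the region), and
`human_in_loop_auc()` runs a thought experiment for binary detection: examples
the predictor flags as unreliable (empty or multiple region) are re-read by a
simulated expert who is correct with probability `expert_accuracy`, and the
AUC (midrank Mann–Whitney) is compared before and after. The expert model is
an explicit, seeded stand-in; no claim is made that real pathologists behave
like a Bernoulli coin.

## Drift detection and power

Exchangeability fails when deployment data come from a new scanner,
laboratory, or tissue spectrum. `drift_test()` compares the calibration set's
pooled nonconformity scores with the deployment set's by a two-sided
two-sample Kolmogorov–Smirnov test (`stats::ks.test`; exact p-value when both
samples have ≤ 100 observations and no ties, asymptotic otherwise, with the
method recorded). "Distribution of the predictions" is operationalized as
nonconformity scores in two labeled modes — at true labels (`labeled`) or at
argmax labels (`predicted_label`, the monitoring setting where deployment
data arrive unlabeled) — and the mode is always recorded, since either is a
defensible reading.

`power_curve()` estimates, by drawing `n_reps` subsamples of each size `n`
without replacement from a shifted pool and re-running the drift test, the
probability of detecting the shift at significance `alpha`, and reports the
smallest grid size reaching `power_threshold` (default 0.80, an explicit
parameter — the threshold behind a published "N observations suffice" claim
is rarely stated).

## What the synthetic generator emulates — and what it does not

Real nonconformity distributions come from a CNN ensemble we do not model.
The generator produces the *statistical skeleton* the conformal argument
needs:

* **`calibrated` mode** draws a probability vector from a symmetric Dirichlet
  with per-class concentration `1/discriminability` and then samples the
  label *from the vector*. Scores are perfectly calibrated and rows i.i.d.,
  so exchangeability holds by construction regardless of score quality —
  exactly what validity experiments require. Its label marginal is uniform;
  prevalences cannot be imposed in this mode.
* **`class_conditional` mode** draws the label from a prevalence vector
  (raw counts such as 3724/1530/539/263/469/426 are accepted and normalized)
  and the probability vector from
  $\text{Dirichlet}(1, \ldots, 1 + d, \ldots, 1)$ with the extra
  concentration $d$ (`discriminability`, default 4; 8 in the shipped demo
  config, giving argmax accuracy in the 80–90% range typical of strong
  image classifiers) on the true class. Rows are i.i.d., so Mondrian
  validity experiments under realistic imbalance use this mode.
* **Shifts.** `temperature` raises every vector to the power $1/T$ and
  renormalizes ($T = 1$ is an exact identity; $T > 1$ flattens scores, the
  signature of a classifier meeting a new scanner or stain); `contamination`
  replaces a seeded fraction of rows with near-uniform vectors (symmetric
  Dirichlet, concentration 200 — high enough to be near-uniform, random
  enough to avoid degenerate nonconformity ties), standing in for atypical
  tissue; `prevalence_shift` resamples rows to a target class mix.

What passing tests on this generator shows: the conformal machinery delivers
its guarantee whenever exchangeability holds, and the KS monitor detects the
modeled departures at the modeled sizes. What it does not show: performance
on any real slide cohort, realistic correlation between biopsies of one
subject (the generator's rows are independent; subject identifiers exist only
to exercise grouped splitting), or realistic shapes of CNN score
distributions.

## Numerical and scale choices

* P-values are computed by `findInterval()` against the sorted stratum — the
  counting definition, vectorized; equality with a naive counting oracle is
  tested exactly on 1,000 random instances including ties.
* Probability rows are renormalized on ingest when their sum is within
  `1e-6` of 1 and rejected otherwise; argmax ties break toward the earlier
  label in label-set order and the count of such ties is reported.
* Validity experiments in the test suite use: binary marginal validity at
  99.9% confidence with 5,500 calibration scores per class (so
  $\varepsilon(n_k+1) = 5.501$ is non-integer and the non-smoothed error is
  strictly conservative, expected rate $5/5501 \approx 0.091\%$) and
  20 × 100,000 pooled test examples; per-class validity with 5 pooled
  replicates of 40,000 calibration / 10,000 test rows at screening-cohort
  prevalences; uniformity with 20,000 pooled smoothed p-values. These sizes
  put the Monte-Carlo noise of each check well inside its assertion band.
* All randomness flows through explicit integer seeds; the pipeline derives
  per-stage seeds by hashing stage names against the master seed
  (`derive_seed()`), so adding a stage never perturbs existing streams, and
  two runs with one master seed produce hash-identical artifacts.

## Known limitations

Only inductive, offline, classification-type conformal prediction is
provided — no transductive/online updating, no regression intervals, and no
nonconformity measures built from predictor-variable distributions. The KS
monitor pools scores across classes; a per-class drift test would need larger
deployment samples but could localize the shift. The human-in-the-loop
experiment is deliberately simple and should be read as an upper-bound style
illustration, not a clinical claim.
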