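---
title: "Reliability- and entropy-weighted fusion of diagnostic submodels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability- and entropy-weighted fusion of diagnostic submodels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A differential diagnosis is a ranked set of hypotheses held simultaneously,
with probabilities attached. `retfuse` targets the setting where several
heterogeneous submodels — language models reasoning over clinical
narratives, optionally a convolutional image classifier — each emit a
probability vector over the five retinal classes
`{NoDR, MildDR, SevereDR, Glaucoma, AMD}`, and a single calibrated
distribution must be produced per case. The submodels differ in accuracy,
in how decisively they commit, and in which cases they cover at all (image
evidence exists only for a minority of cases). The fusion layer has to
exploit those differences without ever collapsing the uncertainty.

## The two fusion rules

**Rank baseline.** Each submodel ranks the diseases by descending
probability; the disease at 0-based rank $r$ accrues $1/(r+1)$; accumulated
scores are normalized. The rule is transparent and quality-blind, which is
exactly its role: a reference that any quality-aware aggregator should
beat. We read the rank as 0-based so the top disease receives weight 1 and
the sequence is harmonic ($1, 1/2, \dots, 1/5$); with a 1-based reading the
"1/r" shorthand used for this baseline denotes the same harmonic sequence.
All five candidates participate (no truncation).

**Reliability-plus-entropy aggregator.** For case-level inputs
$p_i(\cdot)$ the fused score of disease $d$ is

$$\mathrm{Score}(d) = \sum_i \alpha_i \, p_i(d) \left(1 -
\frac{H_i}{H_{\max}}\right), \qquad H_{\max} = \ln 5,$$

normalized over $d$. Two multiplicative penalties shape each submodel's
effective weight $w_i = \alpha_i (1 - H_i/H_{\max})$:

* $\alpha_i$ is the submodel's *reliability*: its top-1 match rate on a
  disjoint calibration split. It is a per-submodel constant, estimated
  once, never tuned on test data.
* $1 - H_i/H_{\max}$ is the *entropy penalty*, computed per case from the
  Shannon entropy $H_i$ of the submodel's distribution (in nats). A
  submodel that is decisive for this particular case speaks loudly; one
  that emits a near-uniform vector is damped, reaching exactly zero at the
  uniform distribution.

Normalizing the summed scores by $\sum_d \mathrm{Score}(d)$ is
algebraically identical to first renormalizing the weights $w_i$ to sum
to 1 — the test suite asserts this equivalence numerically — so the
formulation behaves consistently when submodels are missing: an absent
submodel is excluded from the sum and the remaining weights renormalize.
Fusing a case without image evidence is therefore *exactly* the fusion of
its text submodels, a neutrality property tested on thousands of random
cases.

Assumptions worth stating: the aggregator is a linear opinion pool — it
presumes submodel errors are diverse enough that weighted averaging helps,
and it cannot exploit systematic error correlations (a Bayesian or
log-linear pool could; both are out of scope). Reliability is a single
scalar per submodel, so class-conditional quality differences are invisible
to it.

## Pseudo-loss confidence scoring

Text submodels may report, per disease candidate, the length of a
free-text response elicited for that candidate. The package converts
lengths to a distribution via a pseudo-loss: $\ell(d) = \mathrm{len}(d)/10$
and $\mathrm{conf}(d) = 1/(\ell(d) + \epsilon)$, normalized across the five
candidates. This is a deliberate heuristic — a reactivity surrogate, not a
calibrated probability estimator — and the package treats it as such: it
lives behind a config (`confidence_config()`), and nothing downstream
depends on its particular shape beyond monotonicity (shorter response,
higher probability).

Configuration choices, fixed once:

* `epsilon = 1e-9`. Small enough to be invisible for any realistic length
  (a one-character response has pseudo-loss 0.1, nine orders of magnitude
  larger), large enough that a zero-length response yields a finite
  confidence of $10^9$ rather than an error — robustness to empty API
  replies is a requirement, not an edge case.
* `length_divisor = 10`, lengths counted in characters by default; a token
  mode exists for sensitivity analysis but changes nothing structurally
  (the divisor cancels under normalization except through `epsilon`).

## Calibration protocol

`split_dataset()` shuffles the labeled corpus once under a fixed seed and
cuts it into calibration / development / test. Defaults: calibration 20
cases, test fraction 0.3 — on a 200-case corpus, 20 / 120 / 60. The split
is uniform, not stratified: the intended corpora are moderately balanced
across the five classes, and stratification would complicate
reproducibility for little gain; callers with skewed corpora can stratify
upstream. `estimate_reliability()` computes $\alpha_i$ as the fraction of
calibration cases where the submodel's argmax equals the truth, and
refuses case ids outside the calibration partition — reliability computed
on test data would silently invalidate the evaluation, so this is enforced
structurally rather than by convention. For a partial-coverage submodel
(the image branch) the pipeline computes $\alpha$ over the calibration
cases it covers; a submodel covering none of them gets $\alpha = 0$ (it
then contributes nothing) with a warning, since its reliability is simply
unknown.

## Evaluation metrics

* **Top-k accuracy**: truth within the $k$ highest-probability classes.
* **MRR**: mean of $1/\mathrm{rank}(\mathrm{truth})$, ranks 1-based, so
  MRR $\in (0, 1]$ and MRR $\ge$ top-1 accuracy.
* **ECE**: confidence is the top-1 probability; $M = 10$ equal-width bins
  over $[0,1]$, half-open with the last bin closed; empty bins contribute
  zero. The top-1 convention is the standard one; the bin count is the
  conventional default and configurable.
* **Brier**: the literal multiclass form
  $\frac{1}{N}\sum_i \sum_c (\hat p_{i,c} - \mathbb{1}\{y_i = c\})^2$,
  without the $\div 2$ convention, so its algebraic range is $[0, 2]$
  (0.8 for a uniform five-class prediction). We do not clamp or rescale it
  to $[0,1]$.

Point estimates only: at the sample sizes this package targets
(tens of test cases), interval estimates would be unstable enough to
mislead, so uncertainty is left to seed-level replication (see the
acceptance analysis, which repeats the whole study over ten seeds).

## Deterministic tie-breaking

Probability ties — exact ones arise from degenerate inputs, uniform
fallbacks, and quantized length-derived distributions — are always broken
by label-set order (lowest index first): in argmax, in per-submodel
rankings, and in metric rank computations. The choice is arbitrary but
fixed, which is what matters: reliability estimates and metrics are
reproducible to the byte. Zero-sum score vectors (possible when every
contributing submodel is exactly uniform, or every weight is zero)
normalize to the uniform distribution with a warning rather than erroring:
downstream consumers always receive a distribution. Zero *available*
submodels, by contrast, is a hard error — silence and fabricated uniformity
are different things. Probability vectors are validated to sum to 1 within
`1e-9` at I/O boundaries; internally produced vectors are renormalized.

## The synthetic ensemble generator

The simulator exists so the full pipeline — scoring, calibration, fusion,
evaluation, triage, I/O — runs and is tested with no model APIs and no
clinical data. A scenario specifies the corpus size (default 200 labeled
cases, uniform class weights), and a submodel roster. Each synthetic
submodel has:

* `target_accuracy`: the probability its emitted mode is the true label;
  errors are uniform over the other four classes (no confusion structure —
  real ensembles confuse *similar* classes preferentially, which the
  default generator does not emulate).
* `sharpness` $\kappa$: the emitted vector is a Dirichlet draw with
  concentration $\kappa$ on the mode and 1 elsewhere, with the largest
  coordinate swapped into the mode position so the argmax-match rate equals
  `target_accuracy` exactly in expectation.
* `wrong_sharpness_factor` (default $1/3$): wrong-mode draws use
  $\kappa \cdot$ factor, i.e. the submodel is flatter when it is wrong.
  This confidence–correctness link is the load-bearing design choice of
  the generator. If sharpness is independent of correctness, per-case
  entropy carries no information about correctness, the entropy penalty
  has nothing to exploit, and *no* entropy-aware linear pool can
  systematically beat the best single submodel — we verified this with
  brute-force simulation across wide ranges of constant-$\kappa$
  assignments before settling the design. Real diagnostic submodels
  (language models included) are empirically less decisive when wrong, and
  that is precisely the regime the aggregator is built for. Setting the
  factor to 1 recovers a correctness-independent generator, useful for
  studying the aggregator where its premise fails.
* `coverage`: the fraction of cases with output (default 0.3 for the image
  submodel, mirroring image availability for only a minority of cases).

The default roster is six text submodels with target accuracies
(0.45, 0.60, 0.35, 0.30, 0.30, 0.40) and sharpness (6, 8, 4, 3, 5, 6) —
spanning the weak-to-moderate range the fusion methods are designed to
arbitrate, with decisiveness loosely tracking accuracy — plus the optional
image submodel (accuracy 0.55, sharpness 7). Text submodels materialize
per-candidate response lengths by inverting the pseudo-loss transform
(`length ∝ 1/p`, shortest response 100 characters) and their distribution
is then *recomputed through* `lengths_to_distribution()`, so the length
path is the live path, exercised end to end; after integer rounding the
mode's length is nudged to stay the strict minimum, preserving the
argmax guarantee. Round-trip distortion is bounded in tests at total
variation $\le 0.02$. Synthetic narratives are label-free placeholder
stubs, so no text ever leaks a label token.

All randomness flows from one scenario seed through per-submodel
substreams; adding a submodel never perturbs the others' draws (tested).

What passing tests do **not** show about real data: the generator has
independent submodel errors, no class-confusion structure, no narrative
content, and a clean Bernoulli coverage process. Conclusions about fusion
*mechanics* (weighting, neutrality, calibration recovery, metric
behavior) transfer; conclusions about absolute accuracy numbers on
clinical corpora do not.

## Triage mapping

`map_to_action()` converts a fused distribution into
`screening | monitoring | referral | none` by per-tier probability
thresholds, defaulting to 0.15 / 0.35 / 0.60. These defaults are
explicitly non-clinical documentation values — the mapping is an
application-aligned decision support, not a validated endpoint — and every
component is configurable. By default `NoDR` (the no-disease hypothesis)
cannot trigger any tier, and only `SevereDR`, `Glaucoma` and `AMD` can
trigger referral. The highest tier reached by any eligible class wins;
the full distribution always accompanies the action, so no consumer ever
sees the action without the uncertainty that produced it. Co-factor logic
(e.g. conditioning referral on comorbidity signals) is deliberately out of
scope: it has no operational definition we would defend.

## Reproducibility and provenance

Every pipeline artifact (JSONL cases, outputs, fused diagnoses; JSON
reliability profile; JSON/CSV report) is reproducible byte-for-byte from
the configuration and seed, with one documented exception: the evaluation
report embeds a `generated_at` timestamp for provenance, and comparisons
of reports should strip that field (the tests do). Probabilities are
serialized at full double precision; the CSV report rounds to 4 decimals
for display only.

## Problem sizes

The test suite and the acceptance analysis use the scenario defaults:
200-case corpora, 20-case calibration splits, 60-case test splits, ten
scenario seeds for replicated claims, 1,000–2,000 random instances for
oracle-equivalence and neutrality properties, and 1,500 cases for binomial
accuracy-recovery checks — sizes at which the binomial error bars are tight
enough to be informative while the whole suite runs in well under a minute
per module.

## Known limitations

* The aggregator is a linear pool with scalar reliabilities; correlated or
  class-conditional submodel errors are not modeled.
* The pseudo-loss is a heuristic surrogate; nothing recalibrates it
  (temperature scaling and similar are deliberately absent).
* ECE of the *fused* distribution can be large even when ranking metrics
  are strong: an aggregated top-1 probability is not automatically
  calibrated, and the package reports this honestly rather than adjusting
  it.
* The simulator's independence assumptions flatter ensemble methods;
  treat synthetic accuracy gains as mechanism demonstrations, not
  clinical estimates.
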