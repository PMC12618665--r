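---
title: "Methods: reliance metrics and the behavioural simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliance metrics and the behavioural simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woar)
```

# The study design

`woar` targets three-stage reader studies of advice-taking: a cohort of
clinicians estimates gestational age (GA, weeks) from ultrasound images,
first unaided, then with a model's prediction, then with the prediction
plus an explanation. The model predicts intervals — thirteen bins of about
two weeks spanning 13–42 weeks — and all behavioural metrics are built on
that interval structure.

All internal computation is in weeks (fractional allowed); MAE is reported
in days (×7) because that is the unit GA accuracy is quoted in.

# Metric definitions and the choices behind them

## Weight of Advice

`weight_of_advice(prior, posterior, model)` returns
$(prior - posterior)/(prior - model)$, the fraction of the distance to the
advisor that the judge moved. Points with $|prior - model| < 1$ week are
excluded: the model's two-week intervals mean such a prior already agrees
with the advice, and the ratio degenerates as the denominator vanishes.
The threshold is one week — half the interval width — and is configurable
(`exclude_lt`). The exclusion applies *only* to WoA; agreement and
reliance typing use every image, since nothing in their definitions
requires it.

Two further choices:

* **The prior is the stage-1 estimate for both advised stages.** The prior
  is meant to be the estimate formed before any information from the
  model, and only stage 1 satisfies that. Using the stage-2 estimate as
  the stage-3 prior is available via `prior_stage = 2` for sensitivity
  analysis, but conflates the incremental effect of explanations with
  anchoring on an already-advised value.
* **The model's scalar value is the bin midpoint.** The model emits an
  interval; wherever a scalar $\hat y_m$ is needed (WoA, reliance typing)
  the package defaults to the midpoint, the only point estimate that is
  symmetric within the bin. Any other convention can be supplied through
  the `point_weeks` column of the predictions table.

## Reliance typing

`classify_reliance(y, p1, p2, m)` computes the per-image errors and
distances, then relied $\mathcal{R} = \mathbb{1}[\delta_2 < \delta_1]$ and
model-better $\mathcal{E}_m = \mathbb{1}[\epsilon_m < \epsilon_{p_1}]$,
both with *strict* inequalities. Ties therefore resolve to "did not rely"
and "model not better": an unchanged estimate is not reliance, and an
equally-accurate model does not warrant deference, so both tie cases land
in the appropriate class. The classifier is validated in the test suite
against a literal re-evaluation of the definitions over the full integer
grid $y, p_1, p_2, m \in \{13, \dots, 42\}$ (810&nbsp;000 cases).

## Agreement and bins

A bin scheme is 13 contiguous bins covering 13–42 weeks with 2-week
interior bins and wider outer bins. Thirteen contiguous bins over 29 weeks
with eleven 2-week interior bins force outer widths of 3 and 4; the
package's canonical scheme, `default_bin_scheme()`, is
$[13,16), [16,18), \dots, [36,38), [38,42]$, giving the extra week to the
late-GA end where scans are sparsest. The exact published edges of any
particular study are rarely printed, so the scheme is overridable
everywhere a `bin_scheme` argument appears. Membership is half-open
$[lo, hi)$ with the last bin closed, so every GA in range belongs to
exactly one bin; an estimate exactly on an interior upper edge counts as
the *next* bin, and agreement is the fraction of estimates inside the
model's bin under that convention.

## Log-ratios of reliance proportions

Within-stage comparisons of reliance types use natural-log ratios of
per-participant proportions: $\ln(p_a/p_b)$, so that the exponential of a
reported ratio reads directly as a fold difference (e.g. $e^{1.21} > 3$).
Counts are Haldane-smoothed — 0.5 added to every category before forming
proportions — *uniformly*, not only when a zero occurs, so the estimator
is identical across participants; raw counts are reported alongside in
`reliance_summary()`.

# The statistical battery

`run_full_battery()` emits one row per comparison (18 primary rows on a
complete study). Choices that deserve justification:

* **Independent t-tests across stages, with paired companions.** The
  stage-wise accuracy, agreement, WoA and timing comparisons are run as
  two-sample t-tests on per-participant values, mirroring the analysis
  convention of the reader studies this package reproduces, even though
  the design is paired. Because the paired test is the statistically
  appropriate one, every such comparison also emits a labelled
  `variant = "paired"` row; reproduction first, correctness alongside.
* **Confidence comparisons pair per-estimate values.** Confidence is
  recorded per image, so the stage-wise Wilcoxon signed-rank tests pair at
  the participant × image level (n = 650 on a full study), which is what
  gives these ordinal comparisons their resolution. Questionnaire items,
  in contrast, pair at the participant level (n = 10).
* **Exact small-sample nonparametrics.** `wilcoxon_signed_rank()` drops
  zero differences (Wilcoxon's original procedure; the Pratt variant is an
  option), assigns midranks to ties, and for up to 25 non-zero pairs
  computes the exact two-sided p-value from the full $2^n$ sign
  distribution via integer convolution (midranks doubled onto an integer
  lattice). `mann_whitney_u()` enumerates all assignments of pooled
  midranks for up to 12 pooled observations. Beyond those sizes both fall
  back to normal approximations with tie corrections and continuity
  correction. Both exact paths are tested against brute-force enumeration
  oracles and, in the tie-free case, against `stats::wilcox.test`.
* **No multiplicity correction.** The battery reports raw p-values plus
  the number of tests computed, leaving any correction to the analyst —
  matching how such study batteries are conventionally reported.
* **Graceful degradation.** A comparison whose inputs are missing or
  degenerate (one participant, no questionnaire, constant values) yields a
  row with NA statistics and a `note` naming the reason, never an error.

# The behavioural simulator

Reader-study data are rarely shareable, so the package ships a simulator
whose defaults are calibrated to the aggregate statistics such a study
reports. It is first-class, tested code, and the package's own test data.

## Generative model

**Images and model.** True GAs are uniform on 13–42 weeks. The model's
raw estimate is truth plus a two-component normal mixture error — SD 1.3
weeks with probability 0.945, SD 7.5 weeks otherwise — clamped to range
and then binned; its point value is the bin midpoint. The gross component
captures the occasional completely-wrong prediction that a single normal
cannot produce while keeping the mean error near 9 days.

**Participants.** Each participant has a profile: stage-1 bias and noise,
an advice weight $w \in [0,1]$, a helped flag, a stage-3 advice-weight
shift, stage-3 confusion noise, and a latent confidence anchor. Estimates
are:

* stage 1: $p_1 = \mathrm{clamp}(y + bias + \mathcal{N}(0, noise))$
* stage 2: $p_2 = p_1 + w\,(\hat y_m - p_1) + \mathcal{N}(0, 0.3)$
* stage 3: as stage 2 with $w_3 = \mathrm{clip}(w + shift)$, where helped
  readers get a positive shift and hindered readers a small negative one
  plus 0.8 weeks of confusion noise.

Helped readers additionally *discount* grossly wrong advice in stage 3:
on images where the model errs by more than 5 weeks, their advice weight
is multiplied by 0.2. This encodes the mechanism by which explanations
help — an explanation attached to a wildly wrong prediction looks
implausible, and the readers who engage with explanations notice — and it
is what gives already-compliant readers room to improve in stage 3.

**Population structure.** The cohort is bimodal: strong advice-takers
($w \approx 0.96$) and sceptics ($w \approx 0.20$), with advice-taking
anticorrelated with unaided skill (stage-1 noise 3.1 vs 6.2 weeks) — the
readers who lean on the model most are, on average, the least accurate
without it. That anticorrelation is what lets mean agreement (~0.70) and
mean WoA (~0.65) coexist with a stage-2 MAE near 15.7 days; a homogeneous
population cannot satisfy all three at once.

The cohort is *stratified*: the strong/weak type follows a deterministic
low-discrepancy sequence carrying a 0.65 share, and the helped flag is
balanced the same way within each type (5 of 10 helped). Only the
continuous jitter (weight, bias, anchor) is random. With ten readers per
study, i.i.d. type draws would add substantial cohort-composition noise
to every between-study average; stratification removes it while keeping
all within-participant behaviour stochastic, the way a designed cohort
would be recruited to balance known factors.

**Confidence and questionnaires.** Confidence is a latent normal (anchor
per participant, SD 0.55) with additive stage shifts (+0.15, +0.23),
discretised at cutpoints 1.5–4.5. In stage 3 helped readers' latent SD is
multiplied by 1.8 — polarising scores toward 2 and 4 — while hindered
readers' shrinks to 0.6, concentrating them on 3. Questionnaire items are
drawn per participant: trust drifts slightly down and distrust up after
stage 3, comfort with clinical adoption drops after the study, and the
explanation-helpfulness rating is ≥ 4 exactly for helped readers (with
within-group randomness), which makes the helpfulness-vs-ΔMAE correlation
negative by construction of the population, not by fiat on any statistic.

**Randomness.** One seed drives a run; images, each participant, and each
participant's questionnaire get deterministically derived substreams, so
enlarging the cohort never perturbs existing participants. All noise for a
participant is drawn up-front in fixed order, which makes mean WoA exactly
monotone in the advice weight on a shared stream — a property the test
suite asserts.

## Calibration

The defaults in `default_config()` were frozen after a Monte-Carlo
calibration: a grid over the population parameters (type share, advice
weight means, stage-1 noise levels, model mixture), each candidate scored
on 20-seed averages of six statistics — per-participant MAE at stages 1–3
(targets 23.5, 15.7, 14.3 days), model MAE (9.4 days), mean stage-2
agreement (0.70) and mean stage-2 WoA (0.65) — then verified on 100
held-out seeds. The verified long-run means are 23.6, 16.1, 13.8, 9.3
days, 0.67 and 0.65. An early fit against a single 20-seed block
overfitted its sampling noise; the shipped constants were re-estimated on
independent seeds and have not been revisited since.

## What the simulator does and does not emulate

It reproduces: the aggregate accuracy ladder across stages, the
heterogeneous and bimodal response to explanations, stage-increasing
ordinal confidence with the helped/hindered polarisation split,
trust-questionnaire drift, log-normal response times (stage 1 slower, and
flagged non-comparable because the unaided stage required extra
annotation work), and stage-1 feature citations (mean ≈ 2.76 per image,
repertoires ≈ 7.8 per participant).

It does not emulate: estimate rounding (real readers answer in whole
weeks or weeks+days; simulated estimates are continuous), any shared
image-difficulty component between reader and model errors, learning or
fatigue across a session, image content of any kind, or free-text
responses. Passing calibration therefore shows that the pipeline recovers
the intended statistics from data *with this structure*; it is not
evidence about any real cohort.

# Numerical and interface conventions

* Estimates outside 10–45 weeks are validation errors, not silently
  clipped: out-of-range values in a real dataset indicate unit mistakes.
* Undefined quantities are explicit markers, never numbers: an
  all-excluded WoA mean is NA with its exclusion count, an all-zero
  difference vector leaves the signed-rank undefined, and a battery row
  that cannot run carries a reason string.
* Problem sizes used by the shipped checks: the classifier oracle runs the
  full 810k integer grid; calibration and recovery checks average 20–25
  simulated studies of 10 × 65 × 3 estimates; exact-test oracles enumerate
  all cases up to n = 8. These sizes make the whole suite run in about a
  minute while leaving Monte-Carlo error well inside the asserted bands.
* The pipeline (`cmd_simulate()` → `cmd_analyze()` → `cmd_report()`) is
  file-driven with no hidden state; data outputs are byte-reproducible for
  a fixed seed. Run manifests carry a timestamp and config digest and are
  the one deliberately non-reproducible artifact.

# Known limitations

* The reliance classifier is defined for point-valued regression advice;
  probabilistic or classification advice would need a different notion of
  "moving toward" the model and is out of scope.
* With ten participants, the stage-wise group tests are low-powered, and
  the independent-samples convention understates that further; the paired
  companion rows exist for exactly this reason.
* Simulator calibration matches aggregate targets; individual-level
  quantities (a particular participant's WoA trajectory) are one of many
  populations consistent with those aggregates.
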