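---
title: "Measuring implicit visual statistical learning online: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implicit visual statistical learning online: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slonline)
```

## The paradigm

In a serial reaction time (SRT) statistical-learning task, a participant
categorizes every image of a continuous stream in a speeded
two-alternative forced choice (e.g. Large/Small or Object/Animal).
Unknown to the participant, the stream is built from *information
chunks*: associated stimulus pairs, whose second member always and only
follows its first (within-pair transition probability 1), and unpaired
single stimuli.  Three conditions result: **P1** (first pair member, an
anticipation marker), **P2** (second pair member, a priming marker), and
**S** (singles, the reference).  Implicit learning of the pair structure
shows up online as a priming effect: P2 responses get faster than S
responses, increasingly so as the chunks repeat.

`slonline` implements this paradigm end to end: constrained sequence
generation, a generative observer for simulation, the trial-exclusion
cascade, and the two inference layers (group contrasts for 6-cycle
designs; mixed-effects learning trajectories for the long warm-up
design).

## Sequence designs

Three presets are provided (`design_spec()`):

| preset  | chunks                         | stimuli | cycles       | runs | ITI           |
|---------|--------------------------------|---------|--------------|------|---------------|
| `exp1a` | 4 alternating pairs + 4 singles| 12      | 6            | 8    | fixed 500 ms  |
| `exp1b` | 2 alt. + 2 repeating pairs + 4 singles | 12 | 6          | 8    | fixed 500 ms  |
| `exp2`  | 2 alt. + 2 repeating pairs + 8 singles | 16 | 10 warm-up + 15 | 2 | uniform 500–1200 ms |

Each structured cycle presents every chunk exactly once in randomized
order.  Orders are drawn by rejection resampling (uniform over valid
orders, budget 10,000 redraws per cycle, exhaustion is an explicit
error), subject to:

* **Juncture constraint** (`exp1a`/`exp1b`): across a cycle boundary a
  stimulus may reappear only after at least 3 distinct other stimuli.
  Within a cycle every stimulus occurs once, so only boundaries need
  checking.
* **Pair followed by single** (`exp2`): the chunk after any pair is a
  single.  We enforce this across cycle boundaries too — the run-level
  reading — because only then does the P2-to-specific-single transition
  probability equal the design value of 1/8 exactly.

The `exp2` warm-up phase presents all 16 stimuli in independent uniform
permutations per warm-up cycle, with no immediate repeat across warm-up
cycle boundaries.  ITI jitter is uniform on [500, 1200] ms.  Category
labels are abstract (`A`/`B`); trial and repetition indices are 1-based
throughout, including CSV output.

These rules give verifiable transition structure
(`empirical_transition_stats()`): within pairs the transition
probability is exactly 1; in the 12-chunk designs any one particular
eligible successor chunk follows a chunk-final stimulus with probability
1/7 ≈ 14.3%; in `exp2` a particular single follows a P2 with probability
1/8 = 12.5% and a particular other eligible chunk follows a single with
probability 1/11 ≈ 9.1%.  The `exp1b` inventory balances category
transitions: the long-run category-repetition rate is ≈ 47.6%, against
≈ 33% for `exp1a` whose pairs all alternate — the structural origin of
the motor confound discussed below.

## The synthetic observer

`observer_params()` defines a generative model with exactly the variance
structure the downstream mixed model assumes:

$$RT = \beta_0 + b_{subj} + (\beta_{rep} + b_{slope}) f(rep) + b_{pic}
 + \beta_{ITI}\, ITI - A_{prime} f(rep) [P2] + A_{ant} f(rep) [P1]
 - A_{motor} \ln(1+t) [alt] + \delta_{NVAR} + \varepsilon$$

with $f(rep) = \ln(rep)$ by default (a `"linear"` switch, $f(rep) =
rep - 1$, exists to exercise the model-shape comparison), $t$ the number
of trials seen so far in the session, $[alt]$ indicating a
category-alternating response, and $\varepsilon \sim N(0,
\sigma^2_{resid})$ truncated below at 0.05 s.  Warm-up trials receive no
repetition or condition terms.  Correctness is Bernoulli with a
condition-specific lapse probability; the NVAR class (current/previous
correctness: 1 = both correct … 4 = both incorrect) adds post-error
slowing offsets.

Defaults and rationale (all times in seconds):

| parameter          | default | rationale |
|--------------------|---------|-----------|
| `beta0`            | 0.60    | grand mean RT of speeded size/animacy categorization |
| `beta_rep`         | +0.001  | task-general drift per ln-repetition, the scale of the S condition's trend |
| `prime_amp`        | 0.005   | P2 trend ≈ 0.001 − 0.005 = −0.004 s/ln-unit, the priming scale the trajectory design targets |
| `anticip_amp`      | 0       | no anticipation effect is generated by default |
| `motor_amp`        | 0       | confound generator, switched on explicitly; 0.008 reproduces a ≈ 0.019 s spurious P2−S gap under `exp1a` |
| `sd_subject_int`   | 0.08    | typical between-subject RT spread |
| `sd_subject_slope` | 0.003   | between-subject learning-rate spread |
| `sd_picture`       | 0.02    | per-image categorization difficulty |
| `beta_iti`         | 5e-5 /ms| a 700 ms ITI range moves RT by ≈ 35 ms |
| `sigma_resid`      | 0.12    | trial-to-trial RT noise |
| `lapse_rate`       | 0.06    | ≈ 94% accuracy |
| `nvar_effects`     | 0.03/0.02/0.04 | post-error slowing by NVAR class |

The motor-priming accrual $\ln(1+t)$ encodes that procedural
key-alternation learning builds over the whole session, independent of
the (per-run fresh) stimulus sets.  The growth law is a stand-in: no
empirical accrual function is established for this confound, only that
it strengthens from run to run.

What the generator does *not* emulate: sequential RT autocorrelation
beyond the NVAR offsets, lognormal RT skew (residuals are Gaussian on
the seconds scale, consistent with fitting linear models to raw RT),
fatigue or attention drift, and explicit-strategy contamination.
Passing simulation tests therefore demonstrates that the pipeline's
inferences are correct *under the assumed generative model*, not that
the model captures every property of human RT data.

## Exclusion cascade

`preprocess()` applies, in fixed order: NVAR coding (on the full
presented sequence, since later removals destroy adjacency), subject
exclusion (session accuracy < 60%), run exclusion (run accuracy < 80%),
fast-RT trim (< 200 ms), slow-RT trim (> mean + k·SD, k = 3 for the
6-cycle designs and 2 for the warm-up design, computed per subject over
correct structured trials), warm-up removal, and first-presentation
removal (repetition 1 carries no possible learning effect).  Thresholds
are strict inequalities ("under 80%" excludes only < 0.80).  Accuracy is
always computed before RT trimming.  The exclusion report carries
per-rule counts and percentages of the input total, which sum exactly to
the overall exclusion percentage.

Numerical notes: the trimming reference population is configurable
(`trim_group`: per subject, per subject × run, or per subject ×
condition) and defaults to per subject, the standard reading for RT
trimming.  One-pass trimming is deliberately not iterated to a fixed
point; re-applying the cascade re-estimates a slightly smaller limit
from the already-trimmed sample and removes ≈ 1% more at k = 2
(truncated-normal arithmetic), which the test suite bounds rather than
hides.

**Trimming attenuates trends.**  Removing RTs above a fixed
subject-level limit $L$ maps a cell mean $\mu$ (with residual SD
$\sigma$) to $m(\mu) = \mu - \sigma\,\phi(z)/\Phi(z)$ with $z =
(L-\mu)/\sigma$, whose derivative at $z = 2$ is $1 + (\phi/\Phi)'(2)
\approx 0.886$: any condition-specific RT trend is flattened by roughly
9–11% under a k = 2 trim, *independent of the noise level* (≈ 1% at
k = 3).  The recovery simulations measure exactly this — the S−P2
trend-contrast estimate is unbiased on untrimmed data and ≈ 9% low
after the k = 2 cascade, which sits at the edge of a ±10% recovery
band.  Analysts wanting unattenuated trend amplitudes should prefer
k = 3 or model-based outlier handling; the package keeps the
conventional cascade as specified and documents the distortion instead
of correcting it silently.

## Group inference (6-cycle designs)

Per-subject condition summaries (mean RT over correct trials, accuracy)
feed a one-way repeated-measures ANOVA (df = (k−1), (k−1)(n−1); no
sphericity correction by default, a Greenhouse–Geisser option exists)
with Tukey–Kramer pairwise comparisons on the ANOVA error term, $q =
(\bar m_i - \bar m_j)/\sqrt{MSE/n}$, and Friedman plus pairwise Wilcoxon
signed-rank tests (tie-corrected normal approximation, effect size
$r = |z|/\sqrt{n}$) for accuracy.  Pairwise Cohen's d is the mean
difference over the pooled SD of the two conditions' subject means.
Between-experiment comparisons difference the subject-level P1−P2,
P2−S, P1−S scores and use pooled-variance t tests (RT) and Mann–Whitney
U tests (accuracy) with Holm–Bonferroni adjustment within measure.

### The motor confound, in silico

With all-alternating pairs (`exp1a`), P2 always demands a response-key
alternation while P1 and S often repeat keys, so pure procedural
learning (`motor_amp > 0`, `prime_amp = 0`) forges a P2 < S "priming"
effect.  Two resolutions are built in and tested: excluding
category-repeating trials equalizes alternation between P2 and the
surviving S trials exactly, so the spurious contrast collapses to the
nominal false-positive rate; and the balanced `exp1b` inventory shrinks
it drastically.  Note the balanced design's null is not exact: P2
stimuli alternate with probability exactly 1/2, but each single faces 4
opposite-category chunk finals among its 7 possible predecessors
(alternation 4/7), leaving a ≈ 0.003 s residual at `motor_amp = 0.008`
— about a 0.15 rejection rate at n = 33 versus ≈ 1 under `exp1a`.  A
small residual tendency is exactly what balanced-design data show in
practice.

## Trajectory inference (warm-up design)

The RT model (`fit_rt_trajectory()`, REML via `lme4`/`lmerTest`) is

```
rt_s ~ log(repetition) * condition + ITI + (1 + log(repetition) | subject)
       + (1 | picture) + (1 | NVAR)
```

on correct structured trials with repetition ≥ 2, S as the reference
level.  Covariates are centered at their sample means before fitting,
so type-III F tests (Satterthwaite degrees of freedom) and EMMs refer to
the average log-repetition and ITI rather than to repetition 1; the
interaction test is invariant to this choice.  EMMs and EMM linear
trends (slope of RT in ln-repetition per condition) come from `emmeans`
with asymptotic (z) pairwise contrasts, Tukey-adjusted — the EMM trend
contrast S−P2 equals the interaction coefficient, which the tests assert
as an internal consistency check.  Non-convergence raises a structured
error advising the conventional reduction (dropping the random slope);
`on_nonconvergence = "reduce"` applies it automatically, and the result
records that it happened.  Trials with a missing NVAR code (each run's
first trial) are dropped rather than imputed.

Accuracy uses a binomial GLMM (`correct ~ log(rep) * condition + ITI +
(1 | subject) + (1 | picture)`) with type-III Wald chi-squared tests;
all-correct input is a structured error, never a silent fit.

### Linear versus logarithmic learning

`sp2_encompassing()` computes per subject × repetition the mean S−P2 RT
difference and fits it by OLS against repetition (model a) and
ln(repetition) (model b).  Each is F-tested against the combined model
containing both predictors; a model "suffices" when the rival predictor
adds nothing.  The verdict is `"log"` when a is rejected and b is not,
`"linear"` in the mirror case, `"indeterminate"` otherwise — the
asymmetric-F logic rather than AIC.  The combined model's R² is
asserted ≥ both nested R²s on every call.  Because repetition and
ln(repetition) correlate at ≈ 0.98 over repetitions 2–15, shape
discrimination needs a strong trend-to-noise ratio: at a 0.04 s/ln-unit
priming amplitude, 0.03 s residual SD and 16 subjects the verdict
follows the generating shape in ≈ 88% of replicates, and the rate
rises with amplitude.

## Simulation sizes and calibration

The test suite validates, under a fixed master seed: exact structure
(72-trial and 400-trial runs, 96 stimuli per 8-run session); transition
convergence over 1,000–2,000 generated runs (±1 percentage point);
the confound reproduction over 3 × 200 cohorts of 33 subjects;
type-I calibration of the RM-ANOVA and Friedman tests over 500 cohorts
of 20 subjects and of the LMM interaction test over 500 single-run
cohorts of 12 subjects (rejection rate within 0.05 ± 0.02); and
trend-contrast recovery over 200 two-run cohorts of 20 subjects at
0.05 s residual SD, where the mean S−P2 trend-contrast estimate is
compared against the generating 0.005 s/ln-unit within 10% — a band
that the k = 2 trimming attenuation described above nearly exhausts by
itself, so this check sits deliberately at the boundary and documents
the attenuation rather than hiding it.  The other sizes were chosen so
each Monte-Carlo check has standard error well below the margin it
asserts.

## Limitations

* The observer is the analysis model's mirror; it cannot detect
  misspecification of that model against real data.
* The motor-confound accrual law is assumed, not estimated.
* The encompassing comparison treats subject × repetition cells as
  exchangeable observations (matching the conventional df ≈ n·reps − 2
  analysis); subject-level dependence is not modeled there.
* Sphericity corrections are off by default to match common reporting
  practice for the 3-level within-subject factor.
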