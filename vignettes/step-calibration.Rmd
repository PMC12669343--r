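---
title: "Calibrating subliminal thresholds with STEP: model, method, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating subliminal thresholds with STEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcalib)
```

## The problem

Masked-priming studies of unconscious processing hinge on presenting a
prime at an intensity where the participant's objective discrimination is
at chance while keeping the prime as strong as possible (weaker primes
produce weaker priming). The quantity to estimate is therefore not the
conventional psychophysical threshold (an intensity sustaining some
above-chance accuracy) but the *upper subliminal threshold*: the top of the
flat chance region of the psychometric function. This vignette documents
the model the package simulates, the STEP controller it implements, the
benchmark harness, and every place where the design was genuinely open.

## The observer model

Objective 2AFC accuracy is a two-part Weibull
$$P(x) = \begin{cases} 0.5 & x \le \theta_1 \\
0.5 + (0.5-\lambda)\left(1 - e^{-(x-\theta_1)/\theta_2}\right) & x > \theta_1
\end{cases}$$
with task threshold $\theta_1$ (intensity units: ms for inter-stimulus
interval, unitless for contrast), rise rate $\theta_2$, and lapse rate
$\lambda$ fixed at 0.02, capping accuracy at 0.98. The flat chance branch is
what makes the estimation problem hard: below $\theta_1$ the data carry no
information about location, so a purely mathematical criterion for the
boundary of the chance region does not exist, and the procedure must
instead approach it from above.

Subjective visibility is logistic,
$P(\text{seen} \mid x) = 1/(1 + e^{(\theta - x)/\sigma})$, representing the
probability of a Perceptual Awareness Scale rating above 0. `correct` and
`seen` are drawn independently given the intensity; nothing in the model
couples them beyond their shared dependence on $x$.

### The virtual population

`population_spec()` draws all four parameters ($\theta_1$, $\theta_2$,
subjective $\theta$, $\sigma$) independently from normal distributions
truncated to positive values, by default mean 25 and sd 5 for each. These
defaults are the mildly informative priors appropriate for metacontrast
ISI calibration on a 0–200 ms scale; with the truncation point five
standard deviations below the mean, the truncated and untruncated means
agree to well under 0.01. Independence across parameters is an assumption:
in real observers the objective and subjective curves are correlated. The
generator also cannot emulate non-stationarity (drifting criteria,
learning, fatigue) or serial dependence between trials, so passing
simulation benchmarks demonstrates correctness of the procedures under a
stationary observer, not robustness to everything a live participant does.

Truncated-normal sampling uses the inverse-CDF construction
(`qnorm(lo + (1-lo) u)`), which is exact and vectorises; `sd = 0`
degenerates to the (necessarily positive) mean.

## The STEP controller

A calibration is `n_runs` (default 2) independent runs of `trials_per_run`
(default 78) trials; every run restarts at the scale maximum with fresh
state and the final threshold averages the per-run estimates. Within a
trial the order of operations is: present at the current intensity, ingest
`(correct, seen)`, update the CWIR bookkeeping, re-test the boundary,
adjust the intensity, shrink the step.

**CWIR estimation.** The counter follows $CWIR(t) = 0$ after a correct
trial and $1 + CWIR(t-1)$ after an error, so a maximal run of $k$
consecutive errors accumulates the triangular weight $k(k+1)/2$. The run
threshold is $\hat\theta = \sum_i w_i \bar s_i / \sum_i w_i$ over the
run's error sequences, $\bar s_i$ the mean presented intensity within
sequence $i$. Long error sequences are precisely the events that separate
chance from weakly-above-chance performance, which is why they, rather
than reversals, carry the estimator. A run with no error at all (possible
only for a strongly supraliminal observer) has no estimator support; the
run falls back to the scale minimum and is flagged (`run_flags`).

**Subjective exemption.** While the step is above its floor, a seen-but-
incorrect trial does not raise the intensity. The window is deliberately
limited: an observer who never reports "unseen" would otherwise never
descend.

**Dynamic boundary.** Every trial, the run's trials with intensity inside
the inclusive interval [current intensity, boundary] are tested against
chance with the exact binomial upper tail $P(X \ge x \mid n, 0.5)$ at the
adaptive criterion $\alpha = 0.05/(CWIR+1)$, where CWIR is the run's
cumulative sequence weight including the open streak. The accumulation
makes the test conservative exactly where false positives are most
damaging - deep in the run, near the threshold. On significance the
boundary moves to $(1-s)B + s\,x$ with $s$ the seen ratio among the
selected trials (fixed at 0.5 when the subjective measure is disabled).
The boundary never rises within a run, and proposed intensities are
clamped to it.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `scale` | [0, 200] | ms | calibrated intensity range; contrast preset [0.1, 1] |
| `initial_step` | 32 | ms | first adjustment size |
| `step_decrement` | 4 | ms | removed from the step each trial |
| `min_step` | 4 | ms | step floor; ends the subjective-exemption window |
| `trials_per_run` / `n_runs` | 78 / 2 | — | 156 trials total |
| `alpha_base` | 0.05 | — | numerator of the adaptive boundary criterion |
| `use_subjective` | TRUE | — | exemption + seen-ratio boundary weighting |
| `paired_trial_mode` | FALSE | — | experiment-style pair updates |

`isi_experiment_config()` reproduces the display-locked variant (8.33-ms
frame quantum, 32/8/8 step schedule, paired updates);
`contrast_experiment_config()` the contrast variant (0.2/0.05/0.05 on
[0.1, 1]).

### The step-decrement schedule

The step shrinks by `step_decrement` until it reaches `min_step`. When
this shrinkage happens was an open design point; the package supports both
a per-trial schedule and the transformed-staircase convention of
decrementing on reversals, and defaults to **per trial**. The reasons are
twofold. First, the per-reversal trigger keeps large steps active deep
into the chance phase of a run — reversals are the trigger, but at chance
reversals are what shrink away the step too slowly relative to the
remaining trials — which inflates the random-walk excursions of the
intensity trace and drags the CWIR estimate far below the true threshold
(in population simulations, roughly tripling the bias and nearly doubling
RMSE). Second, the schedule description ("the step size was 32 ms, it
decreased by 4 ms until reaching the minimal step size") is a
deterministic recipe; nothing in it conditions on reversals. The
per-reversal variant remains available via `step_decrease_trigger`.

### Numerical choices

Interval membership for the boundary test uses a $10^{-9}$ tolerance so
that grid-snapped intensities compare reliably. On quantised scales the
adjusted intensity snaps to the nearest grid point with exact half-grid
ties going *downward* (toward less visible), conservative against
conscious contamination; after snapping, the value is pushed back inside
[minimum, boundary] by whole quanta if necessary. The binomial tail is
computed with `pbinom(..., lower.tail = FALSE)`, never by summing
densities. The QUEST posterior renormalises every trial and resets to the
prior in the (never observed in testing) zero-mass case.

## Baselines

The benchmark compares STEP against four procedures, configured once and
then left alone:

* **Staircase** — fixed-step 1-up 1-down. The benchmark default emulates
  the deployed practice in unconscious-processing studies: an 8-ms step
  (one 120-Hz frame) with the threshold taken as the second-highest
  intensity of the final 10 trials. A reversal-averaging estimator and an
  adaptive-step variant are available through `baseline_config()`.
* **PEST** — Wald sequential bound $|c - n p_t| \ge W$ (default $W = 1$,
  $p_t = 0.62$) with the classic step heuristics: halve on reversal,
  double from the third same-direction step.
* **QUEST** — gridded Bayesian posterior over the threshold *defined at
  the criterion level* $p_t = 0.62$ of a two-part Weibull template
  (assumed $\theta_2 = 20$); placement and estimate are the posterior
  mean. This is the conventional QUEST semantics and the quantity QUEST
  actually hands to an experimenter. Targeting exactly 0.5 is rejected
  with an explanatory error: the criterion level does not identify a
  unique intensity on the flat chance branch.
* **ASA** — Kesten-accelerated stochastic approximation
  $x \leftarrow x - \frac{c}{2+m}(z - \phi)$ with $c = 40$, $\phi = 0.62$
  and $m$ the number of update-direction reversals. $\phi$ must exceed
  0.5 for the same degeneracy reason as QUEST.

The criterion targets of 0.62 are the conventional near-threshold choice
for 2AFC adaptive methods; they are also exactly why these methods
overestimate the *upper subliminal* threshold — they converge on the 62%
point, which lies above $\theta_1$ by $-\theta_2\ln(1 - 0.12/0.48)
\approx 0.29\,\theta_2$. The benchmark asserts *rankings*, never value
matches against any published figure, because the baselines' exact
published variants are not fully specified.

## Evaluation metrics

Over $N$ (estimate, truth) pairs: RMSE in intensity units; NRMSE with each
error divided by its true threshold (undefined at a true threshold of 0;
such participants, measure-zero under the truncated-positive population,
would be excluded with a count); and PRMSE,
$\sqrt{\frac1N\sum (P(\hat\theta_{1i}) - 0.5)^2}$, evaluating each
estimate through its participant's *true* objective curve. Because that
curve is flat at 0.5 below $\theta_1$, PRMSE penalises only
overestimation and is bounded by 0.48 at the default lapse: it is the
direct measure of conscious contamination. Distribution summaries use
type-7 (linear interpolation) quantiles.

## Benchmark protocol and problem sizes

`run_benchmark()` samples the population once, then runs every method on
every participant with paired seeds: the same per-participant seed is
restored before each method, so methods face identical response
randomness wherever their intensity placements coincide, and the ranking
comparison is paired rather than independent. The package's acceptance
simulations use 1,000 virtual participants with 156 trials per method,
and the boundary type-I check accumulates 10,000 boundary tests; these
sizes give the ranking and bias assertions comfortable margins (the
observed metric gaps between STEP and every baseline are several times
the replicate-to-replicate noise at this scale) while keeping a full
suite run in the low minutes. Larger populations change the estimates
only in their third decimal.

## Known limitations

* A 156-trial reversal-averaging staircase (`threshold_estimator =
  "mean_of_reversals"`, small fixed step) is competitive with STEP on
  RMSE and NRMSE on the synthetic population, though not on PRMSE, where
  its reversal criterion costs it roughly the same contamination as the
  criterion-targeting methods. The benchmark's staircase default instead
  reflects the final-level estimators actually deployed in the literature
  being emulated; users comparing against a best-case staircase should
  configure it explicitly.
* `fit_psychometric()` is a per-participant MAP fit under truncated-normal
  priors, not a hierarchical model: it shares no information across
  participants and will shrink noisy individual fits toward the prior
  mode rather than toward the population. It exists to close the loop
  from constant-stimuli data to simulator curves, not to reproduce a
  hierarchical analysis.
* At-chance data cannot pin $\theta_1$ from below; the MAP fit then rides
  the prior upward past the tested range, which tests assert as a
  property (the estimate exceeds the prior mode) rather than as a value.
* The interactive line protocol is deliberately minimal (one outcome line
  per trial); timeouts, retries, and hardware synchronisation belong to
  the presentation software on the other side of the pipe.
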