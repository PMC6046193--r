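---
title: "Models and methods behind syncstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind syncstop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncstop)
```

## The paradigm

`syncstop` simulates and analyses a paced synchronization task combined with
a stop-signal task. A session comprises two phases of four blocks; each
block has 80 trials of 1,250 ms with an auditory pacing tone 400 ms into
every trial, 20 stop trials (visual stop signal before the tone), an all-go
familiarization prefix of 10 trials, and between one and ten go trials after
any stop trial. Blocks cross two response modalities (finger tapping,
vocalization) with two stop-block types: in *relevant* blocks the stop
signal must be obeyed, in *irrelevant* blocks it is ignored. Block order is
pseudo-randomized under two rules: within a phase a modality is immediately
followed by the other modality under the same stop-block type, and the block
type switches only once both modalities have run.

## The generative model

### Go process

On every trial the participant plans a synchronized response at

$$t_{go} = \mu_m + \delta_m \,[\text{relevant block}] + \varepsilon, \qquad
\varepsilon \sim \mathcal N(0, \sigma_m^2),$$

relative to the pacing tone. $\mu_m$ is the modality's baseline mean
asynchrony (negative = anticipation), $\delta_m$ the proactive shift induced
by stop relevance, and $\sigma_m$ the trial-to-trial SD. Gaussian noise is
the default because only condition means and standard errors constrain the
generator; a mean/SD-matched shifted log-normal (`go_dist = "lognormal"`) is
available for studying skew sensitivity. Proactive inhibition is modelled as
a pure location shift because the pipeline measures it as a difference of
condition means — any shape change would be invisible to that estimator.

### Stop process and the race

On relevant-block stop trials a stopping latency is drawn as
$\mathcal N(\text{SSRT}_m, \text{ssrt\_sd}_m)$ truncated at 1 ms, and the
response is emitted iff the go process finishes strictly before
$\text{SSD} + \text{SSRT}$ (trial clock). Exact ties resolve to a successful
stop: under continuous noise a tie has probability zero, and a fixed rule
keeps simulation bit-reproducible. The trial-level SSRT SD defaults to a
small 10 ms because the integration-method estimator targets a summary
SSRT; making it large would conflate estimator bias with generator spread.

### The SSD staircase

The stop-signal delay starts 200 ms before the pacing tone and moves in
nominal 30 ms steps — up after a successful stop (harder), down after a
failed one (easier). Stop signals can only appear on a display refresh, so
both the SSD and the step live on the 8.3 ms frame grid (120 Hz): the
initial 200 ms snaps to 199.2 (24 frames) and the step to 33.2 ms (4
frames), "nearest multiple" with midpoints rounding up. We read the
quantization as nearest-frame rather than truncation (24.9 ms) because a
physically realizable tracker must land on the grid in both directions;
both step and grid are configurable. Bounds default to
$[0, \text{pacing} - \text{frame}]$ — the stop signal must precede the
tone — and saturation snaps inward to the nearest grid multiple inside the
bound so the grid invariant survives clamping. The staircase starts fresh
in every block (`carry_over_blocks = FALSE` by default): carrying state
across non-adjacent blocks of the same modality would leak information
through interleaved blocks, though carry-over is available as a flag. Each
modality always has its own independent staircase.

In irrelevant blocks stopping is never attempted, so no staircase outcome
exists; the presented (ignored) stop signals keep the block-initial SSD.
Summary SSD statistics are therefore meaningful only for relevant blocks,
which is also the only place SSRT is defined.

### Cohort structure

`reference_profile()` fixes the study conditions: 30 participants, baseline
asynchronies −128.29 ms (finger) and −61.47 ms (vocal), proactive shifts
58.05 and 26.10 ms, SSRTs 152.95 and 187.81 ms, go-miss probabilities 3%/9%
(finger, relevant/irrelevant) and 1%/0.4% (vocal). Between-participant SDs
are recovered from the reported standard errors as $SE \sqrt{30}$. Each
latent parameter's finger and vocal values are drawn from a bivariate normal
with correlation 0.6: timing anticipation and stopping speed are
participant-level traits shared across effectors, and the magnitude is what
the reported within-subject contrasts imply (a cross-modality paired
difference of proactive shifts with mean 31.95 ms and $t(29)=4.50$ gives a
paired-difference SD near 39 ms, i.e. $\rho \approx 0.57$ given the marginal
SDs; independent draws would contradict those contrasts). The
within-participant trial SD defaults to 30 ms — a conventional value for
paced tapping at this tempo, flagged as such because no trial-level spread
is reported for the paradigm; it matters mainly for the race's censoring
strength and for staircase jitter. Misses are drawn only on trials where a
response would be emitted (go trials and ignored stop signals); relevant
stop trials are never missed, so p(respond) reflects the race alone. The
generator encodes no phase effect: asynchronies are stationary across
phases, so phase terms in the ANOVAs act as a built-in negative control.

Emitted raw response times are deliberately *uncalibrated*: the audio
pipeline delay (67.43 ms) is added to both modalities and the keypad delay
(8.4 ms) additionally to finger responses, so the calibration stage of the
analysis is exercised end to end. The offsets are configuration, not code
constants — they are properties of a particular rig.

### What the generator does and does not emulate

It reproduces the design geometry, staircase dynamics, condition mean
structure, between-participant spread, cross-modality correlation, go-miss
rates and the race-model censoring signature. It does **not** model
phase-correction/period-correction timekeeping (serial dependence between
successive asynchronies), drift or fatigue, context effects of a preceding
stop signal on the next go trial (go types differ only through sampling
noise), attentional lapses beyond uniform misses, or trigger failures.
Passing tests therefore show that the *pipeline* recovers what this
generator encodes, not that real data satisfy these assumptions.

## The analysis pipeline

* **Calibration** subtracts 75.83 ms from button presses (67.43 + 8.4) and
  67.43 ms from vocal responses. Being a rigid within-modality shift, it
  cancels exactly in the proactive-inhibition difference — a property the
  tests exploit.
* **Asynchrony** is `t_r − t_ps`: positive means the response followed the
  tone. (The convention is fixed by the stated semantics and by the
  uniformly negative reported means.)
* **Go types**: familiarization (trials 1–10), first and second go after
  each stop signal (a new stop restarts the count), other go, stop. Ignored
  stop signals keep the `stop` label but carry an asynchrony; they do not
  enter go-type condition means. The headline condition means drop the
  first go after each stop (it is the one go type that can differ across
  phases in the paradigm's own data); the four-factor ANOVA keeps all three
  go types.
* **Inclusion**: participants are kept iff their stop-success percentage
  over relevant blocks — pooled across modalities and phases — falls in
  [40, 60] inclusive. "Between 40% and 60%" is read inclusively, and
  pooling is the default because the criterion is stated for the
  participant, not per modality (`per_modality` switches this).
* **Proactive inhibition**: per participant and modality, mean relevant
  minus mean irrelevant asynchrony over second-go and other-go trials.
* **SSRT (integration method)**: per relevant block, p(respond) = failed
  stops / stop trials; the go synchronized-response distribution (calibrated
  times-into-trial of analyzable go trials of the same block) is rank
  ordered and the $n$-th value selected with $n = \lceil p N \rceil$,
  clamped to $[1, N]$; the block's mean realized SSD is subtracted; block
  estimates are averaged per participant. The ceiling rule is the standard
  integration-method convention where no rounding rule is stated
  (`rounding` switches to floor/round). The mean realized SSD is used
  because the SSD varies within a block under the staircase and is reported
  as a block summary. Misses are dropped from the go distribution by
  default (`miss_replace = TRUE` substitutes the block maximum, the
  conservative convention); responses emitted on failed stop trials never
  enter the go distribution.
* **Race check**: per participant, mean failed-stop asynchrony vs mean go
  asynchrony in relevant blocks; under the race the failed stops are the
  censored fast tail and must lead.
* **Statistics**: the fully within-subject ANOVA projects each
  subject × cell matrix onto orthonormal effect contrasts (Kronecker
  products of per-factor contrasts and averaging vectors); effect SS from
  the projected means, error SS from the subject-by-effect interaction,
  Greenhouse–Geisser $\varepsilon$ from the covariance of the projected
  scores, partial $\eta^2 = SS_e/(SS_e + SS_{err})$. Single-df effects have
  $\varepsilon = 1$ by construction; for larger effects both uncorrected
  and GG-corrected p values are always reported, and the caller chooses —
  no Mauchly gate is applied, since any such threshold is arbitrary.
  `stats::aov` with Error strata is the independent cross-check in the test
  suite, and `F = t^2` on two-level factors ties the ANOVA to the paired t
  test. Paired t tests and Bonferroni clamping delegate to base R.

## Numerical and degenerate-input choices

* Frame quantization uses `floor(t/frame + 0.5)`, immune to
  floating-point wobble at grid points; midpoints round up.
* Schedule generation is constructive (distribute go trials over gap slots
  with per-gap capacity), so no rejection sampling; the max-gap constraint
  is waived after the final stop, otherwise 20 stops cannot always fit in
  70 post-familiarization trials. A block may end in a stop trial.
* `p = 0` in the integration method is degenerate (no failed stops — the
  quantile is undefined); the fastest go SR is returned with a warning.
* Constant input to the ANOVA returns F = 0 across the board rather than
  0/0.
* Cells with one participant report `NA` SE/CI; empty cells are absent,
  never zero.

## Problem sizes

The test suite validates schedule constraints over 1,000 seeded draws,
session-design rules over 500 draws, staircase convergence over 300–400
stop trials, SSRT recovery against a fixed 150 ms truth over 10,000
staircase-tracked stop trials (tolerance ±10 ms), ANOVA null calibration
over 1,000 simulated datasets, and full-pipeline pattern recovery on
30-participant cohorts — sizes at which the Monte-Carlo error of each check
is several times smaller than its tolerance.

## Known limitations

Asynchronies are treated as exchangeable within a cell (no serial
dependence), the staircase model assumes no response-time drift, SSRT
recovery at 20 stop trials per block is noisy and slightly biased low (the
well-known small-sample behaviour of the integration method — visible here
as recovered SSRTs a few ms below the generating means), and the inference
layer requires complete balanced designs (participants missing a cell must
be excluded before calling `rm_anova`).
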