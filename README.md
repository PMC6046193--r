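# syncstop

Simulation and analysis of sensorimotor synchronization under stop-signal
demands.

## The problem

In sensorimotor synchronization (SMS) tasks people tap (or vocalize) in time
with a metronome, and their responses systematically *anticipate* the pacing
tone — the negative mean asynchrony (NMA), typically 20–100 ms for finger
tapping to an auditory beat. One way to probe what controls this anticipation
is to embed a stop-signal task in the paced sequence: on a quarter of the
trials a visual stop signal appears shortly before the pacing tone, and in
*relevant*-stop blocks the participant must try to withhold the synchronized
response (in *irrelevant*-stop blocks the same signals are ignored). Stop
relevance induces **proactive inhibition** — anticipatory slowing of the go
response, visible as a reduction of the NMA — and the latency of outright
stopping (**reactive inhibition**) is indexed by the stop-signal reaction
time (SSRT).

`syncstop` provides both halves of this paradigm for R:

* a **generative participant model**: an independent horse race in which a
  Gaussian go process (mean asynchrony μ, trial SD σ, plus a proactive shift
  δ in relevant blocks) races a stopping process of latency SSRT on stop
  trials — a response escapes inhibition iff the go process finishes before
  `SSD + SSRT` — with the stop-signal delay (SSD) tracked by a
  one-up-one-down staircase in frame-quantized ~30 ms steps (8.3 ms grid),
  per-block pseudo-randomized session designs (2 phases × 4 blocks × 80
  trials, 20 stop trials each), device-offset–contaminated raw response
  times and realistic go-miss rates;
* the **analysis pipeline**: device-timing calibration (−75.83 ms button
  press / −67.43 ms vocal), asynchrony `t_r − t_ps`, go-type classification
  (familiarization / first and second go after a stop / other go),
  stop-success inclusion screening (40–60%), proactive inhibition as the
  relevant-minus-irrelevant difference of condition means, integration-method
  SSRT (the p(respond) quantile of the rank-ordered go distribution minus the
  block's mean SSD, per block then averaged), the race-model censoring check,
  and a repeated-measures inference layer: fully within-subject ANOVA with
  Greenhouse–Geisser correction and partial η², paired t tests, Bonferroni
  post hocs.

## Worked example

Simulate a 30-participant cohort from the default reference profile and run
the full pipeline:

```r
library(syncstop)

events <- generate_cohort(n_participants = 30, seed = 42)
res <- analyze_events(events)

res$inclusion[!res$inclusion$included, ]
#>  participant_id stop_success_pct included
#>             p08            33.75    FALSE

res$condition_summary
#>  block_type modality  n mean_ms  se_ms ci95_lo_ms ci95_hi_ms
#>  irrelevant   finger 29 -119.99 10.314    -141.12    -98.865
#>    relevant   finger 29  -61.48 15.361     -92.95    -30.020
#>  irrelevant    vocal 29  -55.18  6.898     -69.31    -41.046
#>    relevant    vocal 29  -24.44  9.475     -43.85     -5.032

aggregate(proactive_inhibition_ms ~ modality, res$proactive, mean)
#>  modality proactive_inhibition_ms
#>    finger                   58.51
#>     vocal                   30.73

aggregate(ssrt_participant_ms ~ modality, res$inhibition$participants, mean)
#>  modality ssrt_participant_ms
#>    finger              161.80
#>     vocal              192.89
```

One participant stopped successfully on only 33.75% of relevant stop trials
and is screened out (valid race-model estimates need roughly even racing).
The remaining 29 reproduce the qualitative structure the generator encodes:
vocal responses are more synchronous than finger taps (−55 vs −120 ms in
irrelevant blocks), stop relevance delays both modalities, the perturbation
is smaller for vocalization (30.7 vs 58.5 ms of proactive inhibition,
cross-modality paired `t(28) = −4.23`, `p < .001`), and stopping a finger
tap is faster than stopping a vocalization (SSRT 162 vs 193 ms). The
within-subject ANOVA on asynchronies (block type × modality × phase, first
go after each stop excluded) shows the block-type and modality main effects
and their interaction, mirroring the pattern above:

```r
res$anova_condition[, c("effect", "df_num", "df_den", "F", "p", "partial_eta_sq")]
#>                      effect df_num df_den      F        p partial_eta_sq
#> 1                block_type      1     28 47.974 1.57e-07         0.6315
#> 2                  modality      1     28 33.355 3.35e-06         0.5436
#> 3                     phase      1     28  0.351 5.58e-01         0.0124
#> 4       block_type:modality      1     28 17.918 2.24e-04         0.3902
#> ...
```

The race-model assumption check confirms the censoring signature: failed-stop
asynchronies lead go asynchronies by 18.4 ms on average
(`t(28) = −21.5`, `p < .001`) — responses that escape inhibition are the fast
tail of the go distribution.

A thin command-line wrapper over the same functions ships in
`inst/scripts/smstop.R` (subcommands `schedule`, `simulate`, `analyze`,
`recover`; YAML config, `--seed`, `--out`).

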