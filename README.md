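# pephys

Axiomatic prediction-error analysis of psychophysiological outcome
responses in Pavlovian fear conditioning.

## What this package is for

When a conditioned stimulus (CS) is only partially paired with an aversive
unconditioned stimulus (US), every outcome carries a prediction error
(PE): on a US-delivery trial with reinforcement rate *r* the signed PE is
*1 − r*, on an omission trial it is *−r*. Whether autonomic signals —
skin conductance (SCR), pupil size (PSR), heart period (HPR) and
respiration amplitude (RAR) — encode signed or unsigned PE can be decided
model-agnostically: a monotone signed-PE code must order a small battery
of condition contrasts consistently (US+ vs US− at fixed probability;
same-outcome contrasts across probabilities), and an unsigned (surprise)
code must order a different battery. `pephys` implements the full
pipeline for researchers in psychophysiology and computational
psychiatry:

* **Simulation** — trial schedules and multi-modal recordings for
  differential (50% CS+, CS−) and parametric (20/50/80% CS+) designs,
  with gamma-shaped evoked kernels, between-/within-subject variability
  and artifact injection (`generate_schedule()`,
  `generate_recordings()`).
* **Preprocessing** — the exact per-modality chains: SCR range/slope QA
  (0.05–60 μS, 10 μS/s), first-order bidirectional 5 Hz Butterworth,
  10 Hz downsampling, session z-transform; gaze-deviation (±5°) pupil
  masking; heartbeat-to-heart-period conversion with a 0.6–1.5 s
  validity range; respiratory-cycle amplitude series.
* **Statistics** — outcome-locked 0.1-s-bin epochs (SCR 2–10 s, HPR/RAR
  0–10 s, PSR 0–4 s post-US; 0.5 s pre-US baseline), per-bin linear
  mixed-effects contrasts (`lme4`, `value ~ condition + (1 | study/ppid)`),
  cluster-based permutation inference with within-participant label
  shuffling, trough-to-peak scoring with paired t-tests, and the
  signed/unsigned axiom evaluator.
* **Power analysis** — a simulation-based estimate of the cluster test's
  sensitivity to a 20% peak-amplitude difference at n = 29.

The statistic at the core of the inference is the **cluster mass**: for a
contrast tested in every 0.1-s bin, maximal runs of contiguous bins with
p < 0.05 and a common sign form clusters whose summed statistic is
compared against the permutation distribution of the maximum absolute
mass, `p = (1 + #{null ≥ |obs|}) / (1 + n_perm)`.

## Worked example

Simulate a differential-conditioning study (12 participants, 50% CS+ vs
CS−) with the empirically motivated amplitude map — US responses plus
*same-sign* omission responses that grow with omission unexpectedness —
and run the full SCR analysis:

```r
library(pephys)

cfg <- run_config(design = "dataset1", n_participants = 12,
                  modalities = "SCR", n_perm = 500, seed = 11)
bundle <- run_pipeline(cfg)
bundle
#> <pipeline_result> dataset1, 1 modalities, seed 11
#>   SCR: signed inconsistent | C1 indeterminate C2 violated C3 indeterminate

bundle$results[, c("contrast", "sign", "p_cluster",
                   "start_post_cs_s", "end_post_cs_s")]
#>                     contrast sign p_cluster start_post_cs_s end_post_cs_s
#> 1 A1: US+ (50%) vs US- (50%)    +     0.002             5.5          13.5
#> 2  A2: US- (0%) vs US- (50%)    -     0.002             5.5          13.1

bundle$verdicts$SCR
#> <axiom_verdict> SCR
#>   signed PE: inconsistent (A1 a_greater)
#>     A2: US- (0%) vs US- (50%): b_greater
#>   unsigned PE: C1 indeterminate | C2 violated | C3 indeterminate | C4 not testable
#>   A3: not testable
```

Reading the output: the A1 cluster (positive, p = 0.002, spanning
5.5–13.5 s after CS onset, i.e. 2–10 s after the US at 3.5 s) shows a
larger SCR to US delivery than omission. The A2 cluster is *negative*:
unexpected omission (on 50% CS+ trials) produces a larger response than
expected omission (CS− trials) — the same direction as the US response.
A signed-PE code would require the opposite direction, so the verdict is
`inconsistent`; and because US and omission responses differ at 50%,
where both outcomes are equally unexpected, condition C2 of the unsigned
code is `violated`. Swapping `amplitude_scheme = "signed_pe"` in the
configuration generates data from a true signed-PE code and flips the
verdict to `consistent`.

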