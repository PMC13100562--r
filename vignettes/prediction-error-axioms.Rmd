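---
title: "Axiomatic prediction-error analysis of autonomic outcome responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axiomatic prediction-error analysis of autonomic outcome responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In Pavlovian fear conditioning, a conditioned stimulus (CS) that is only
partially paired with an aversive unconditioned stimulus (US) creates, on
every trial, a mismatch between expectation and outcome — a prediction
error (PE). Whether peripheral autonomic signals — skin conductance
responses (SCR), pupil size responses (PSR), heart period responses (HPR)
and respiration amplitude responses (RAR) — *encode* such prediction errors
is an empirical question that can be answered without committing to any
particular learning model. If a signal is a monotone function of the
**signed** PE (outcome minus expectation), it must satisfy a small set of
directional axioms over contrasts of US-delivery (US+) and US-omission
(US−) trials at different reinforcement rates; if it encodes the
**unsigned** PE (surprise), a different set of directional conditions
applies. `pephys` implements this axiomatic test battery end to end:

1. a synthetic-data generator that emulates partial-reinforcement
   conditioning experiments with known evoked-response structure,
2. modality-specific preprocessing to a common 10 Hz analysis rate,
3. outcome-locked, baseline-corrected epoching on 0.1-s bins,
4. per-bin linear mixed-effects contrasts with cluster-based permutation
   inference,
5. an evaluator that maps directional cluster results onto the signed
   axioms (A1, A2) and unsigned conditions (C1–C3),
6. trough-to-peak robustness scoring with paired t-tests, and
7. a simulation-based power analysis for the cluster-level test.

## The directional logic in brief

Write $r$ for the reinforcement rate of a CS. On a US+ trial the signed PE
is $1 - r$; on a US− trial it is $-r$. A monotone signed-PE code therefore
requires (taking the case where the US response is a signal increase):

* **A1** — at fixed $r$, US+ trials exceed US− trials;
* **A2** — responses *fall* as $r$ rises, separately for US+ trials
  ($1-r$ decreasing) and US− trials ($-r$ decreasing); in particular, an
  omission response must point in the *opposite* direction to the US
  response, because an omission is a better-than-expected outcome.

The mirrored case (US response is a decrease, as for heart period, where
the US produces tachycardia and hence a shorter heart period) flips every
inequality. The evaluator in `evaluate_signed()` encodes exactly this: a
verdict of `consistent` requires a unidirectional A1 and every non-null A2
contrast (always oriented with the lower rate as `level_a`) pointing the
same way as A1.

An unsigned (surprise) code instead requires larger responses to less
likely outcomes: US+ responses exceed US− responses at a 20% rate and the
reverse at 80% (C1), equality at 50% (C2), US+ responses maximal at 20% and
US− responses maximal at 80% (C3). A third signed axiom (no response to a
fully predicted US) and its unsigned counterpart are untestable without a
100% reinforced condition; the verdict reports them as `not testable`.

The empirically established pattern in all four autonomic modalities — a
strong US response together with an omission response of the *same* sign
that grows with the unexpectedness of the omission — violates the signed
ordering (both outcomes cannot be "worse than expected") and, because the
US response dominates at 50%, violates C2 as well. The package's default
generator (`amplitude_map_observed()`) reproduces this pattern;
`amplitude_map_signed_pe()` generates a true signed-PE code. The test suite
verifies that the full pipeline returns `inconsistent` for the former and
`consistent` for the latter — an end-to-end check that the evaluator's
logic, the contrast orientation and the cluster inference compose
correctly.

## The synthetic-data generator

The generator is a first-class, tested component, not a fixture. It
emulates two study designs:

* `dataset1_design()` — differential conditioning: one 50%-reinforced CS+
  and one never-reinforced CS−, CS duration 4 s, US onset 3.5 s after CS
  onset;
* `dataset2_design()` — parametric probability: three CS+ reinforced at
  20/50/80% and no CS−, CS duration 6.5 s, US onset at 6 s, 29
  participants by default.

Both use a 0.5 s US and inter-trial intervals drawn i.i.d. uniform from
7–11 s. Outcome counts are exact per condition (rate × trials, rounded to
the nearest integer with ties toward more reinforced trials) and trial
order is permuted per participant. On omission trials the evoked response
is time-locked to the *expected* US onset, which is what makes omission
responses analysable at all.

Published trial counts per CS vary widely across differential-conditioning
studies (from 10 to 96); the default of 40 trials per CS is a
representative mid-range choice. For the parametric design, 23/22/23
trials across the three rates reproduce a realistic 68-trial session.

Evoked responses are gamma-density-shaped kernels normalised to peak
amplitude 1 at a modality-typical latency (SCR 3 s, PSR 1.5 s, RAR 2 s);
the heart-period kernel is a difference of two gamma components (peaks
near 2 s and 6 s), giving the canonical biphasic morphology. These shapes
are the package's own modelling choice: they match the qualitative
morphology of published evoked autonomic responses, and nothing downstream
depends on the exact parametric family because the analysis is
distribution-free over time bins.

Variability has four generator knobs, each mapped to a feature of real
data:

| knob | emulates | default |
|---|---|---|
| `between_subject_sd` | log-normal participant gain (skin properties, electrode contact) | 0.3 |
| `within_subject_sd` | trial-to-trial evoked-amplitude variability | 0 (calibrated for power runs) |
| `noise_sd` | broadband sensor noise | small (units of the signal) |
| `drift` | slow baseline wander (AR(1)) | off |

The multiplicative between-subject gain is precisely the phenomenon that
motivates the per-session z-transform of skin conductance.

What the generator does **not** emulate: blink morphology in the pupil
channel, ECG waveforms (heart period is generated directly, and real
heartbeat timestamps enter through `heartbeats_to_heart_period()`),
non-stationary habituation of US responses, and movement artifacts beyond
simple plateau episodes. Passing tests on synthetic data therefore
demonstrate that the *statistical machinery* is correct and calibrated;
they do not certify preprocessing robustness against every artifact class
found in real recordings.

Recordings are generated at 100 Hz by default. The evoked responses live
well below 5 Hz, so this rate is generous for the analysis while keeping
simulated cohorts small; the preprocessing accepts any rate that is an
integer multiple of 10 Hz. When a configured low-pass cutoff (e.g. the
50 Hz pupil cutoff, defined for 500 Hz hardware) is not supported by the
synthetic rate, the pipeline caps it below the Nyquist frequency.

## Preprocessing contracts

Each rule is implemented exactly as stated and covered by a dedicated
test:

* **SCR quality assessment** — samples outside 0.05–60 μS or with a local
  slope magnitude above 10 μS/s are flagged (central differences on the
  raw grid, one-sided at the edges, strict inequalities). Flagged spans
  are linearly interpolated for filtering but remain excluded from
  statistics via the missing mask.
* **Filtering** — first-order bidirectional (zero-phase) low-pass
  Butterworth, 5 Hz for SCR; the squared one-pass magnitude response means
  a tone at the cutoff emerges with amplitude exactly 1/2. Odd-symmetric
  edge padding suppresses the start/end transients of the two passes.
* **Downsampling** — averaging within non-overlapping 0.1 s bins (not
  decimation), chosen for robustness to residual noise; a 10 Hz bin is
  missing iff any source sample in it was missing.
* **z-transform** — per participant over the whole session, valid samples
  only, sample SD (n − 1). Applied after downsampling; the order is
  immaterial for the affine-invariant contrasts downstream.
* **Gaze** — pupil samples are masked when gaze deviates beyond 5° visual
  angle from fixation (`atan(offset / viewing distance)`); the boundary
  itself is retained, since only deviation *beyond* the limit is excluded.
  The full five-criterion pupil validity procedure is simplified to range
  plus dilation-speed filtering because the synthetic data contain no
  blink morphology; this is a documented narrowing.
* **Heart period** — inter-beat intervals timestamped at the later beat,
  values outside 0.6–1.5 s (40–100 bpm) removed, linear interpolation to
  10 Hz with edge-hold extrapolation.
* **Respiration** — cycles detected as successive troughs bracketing a
  peak; per-cycle amplitude (peak minus preceding trough) assigned at the
  peak time and interpolated to 10 Hz.

The SCR chain (`preprocess_scr()`) enforces the stage order QA →
interpolate → filter → downsample → z-transform, logs flag counts, and
refuses to run twice on the same recording.

## Epochs and analysis windows

Response windows are modality-specific, relative to (expected) US onset:
SCR 2–10 s, HPR and RAR 0–10 s, PSR 0–4 s, all preceded by a 0.5 s pre-US
baseline. Bins are half-open `[t, t + 0.1)`, which makes bin counts exact
(the SCR window has exactly 80 bins) and avoids double-counting. Baseline
correction defaults to subtracting each participant's mean baseline over
all trials; a per-trial mode exists for sensitivity analysis, and the raw
per-trial baseline is retained as a candidate model covariate. The
wording "per participant" could in principle mean either mode; both are
implemented and the default is documented rather than guessed. Results
tables report cluster extents both US-locked and CS-onset-locked (the
latter is the convention of published cluster tables).

"Second half" trial filtering retains trials whose index exceeds the
participant's median index — for 80 trials, trials 41–80; for 67 trials,
the later 33. The half label is assigned once at extraction, which makes
the filter idempotent.

## Bin-wise models and cluster inference

Every 0.1-s bin is tested with a random-intercept linear mixed model,
`value ~ condition + (1 | ppid)`, or with study-nested participants
(`(1 | study) + (1 | study:ppid)`) when several studies are pooled, fit by
REML. Inference at the bin level uses the Wald z statistic: bin-level
p-values only gate cluster membership, and the cluster-level error rate
comes from the permutation null, so small-sample df corrections would add
cost without changing the controlled quantity. Singular or failed fits
fall back to the model without the study intercept, then to ordinary least
squares (with its t-based p), with the fallback depth recorded.

Clusters are maximal runs of temporally contiguous bins with p < 0.05
(strict) and a common statistic sign; absent bins break contiguity; the
cluster mass is the summed statistic. The null distribution records, per
permutation, the maximum absolute mass after shuffling condition labels
across trials *within* each participant — the conservative scheme that
preserves participant and study structure; pooling |mass| over both signs
controls the family-wise error across both directions. Cluster p-values
use the add-one formula `(1 + #{null ≥ |obs|}) / (1 + n_perm)` for sampled
nulls (exact under exchangeability, never zero) and the plain proportion
for exhaustive enumeration, where the identity relabelling is already
included.

Because a full REML fit per bin per permutation is the dominant cost, the
permutation engine defaults to a fast collapsed statistic: the
per-participant condition-mean difference tested across participants (a
paired t per bin). This is the classical mass-univariate statistic for
nested designs, it is exactly the mixed model's Wald test in the balanced
collapsed limit, and — importantly — it is applied to the observed data
*and* the permuted data alike, so observed and null masses are always on
the same scale. `method = "lmm"` runs the full mixed model throughout for
both; mixing statistics between the observed and null sides is
deliberately not offered.

Tests verify: cluster formation against hand-computable patterns; exact
agreement of the sampled machinery with brute-force enumeration of all 36
within-participant relabellings on a 2-participant × 4-trial instance;
family-wise error within [0.02, 0.08] over 200 null simulations; monotone
growth of detected mass with injected amplitude; and invariance to
participant ordering.

## Peak scoring

As a model-light robustness analysis, skin conductance responses are
scored trough-to-peak: the onset is the minimum within 1–4 s post-US
(operationalising "response onset" as the trough, a documented choice),
the peak is the maximum within 0.5–5 s after the onset (clipped to the
epoch, with clipping logged), and the amplitude is their difference.
Pupil responses are scored as the 1–4 s post-US maximum minus the mean
over the second before US onset. Paired t-tests compare per-participant
condition means; a zero-variance difference vector is flagged rather than
yielding a spurious p-value.

## Power simulation and its calibration

The power analysis asks: with 29 participants and a 20% peak-amplitude
difference between two within-subject conditions, how often does the
cluster-based permutation test on the 2–10 s post-US window detect the
difference? Each of 30 repetitions simulates a full cohort, preprocesses,
epochs and tests it; power is the significant fraction with an exact
binomial CI. (The original formulation of this analysis bootstrapped real
evoked skin-conductance responses; here the calibrated generator stands in
for the bootstrap source, which removes any download dependency and makes
the result conditional on the calibration below.)

The calibration contract is *single-trial peak SNR ≈ 1*: the mean evoked
peak amplitude equals the SD of single-trial peak amplitudes. Single-trial
skin-conductance variability is dominated by trial-to-trial amplitude
fluctuations rather than broadband sensor noise (which barely survives
the 5 Hz low-pass, while any white noise large enough to matter at 10 Hz
would violate the generator's own slope QA), so the calibration sets the
within-subject amplitude SD to `peak_amplitude / target_snr` and keeps a
small fixed sensor-noise floor. `measure_single_trial_snr()` verifies the
achieved SNR empirically through the full preprocessing chain; the test
suite requires agreement with the target.

Trials per condition is the second calibration constant. Because the
amplitude jitter is fully correlated across time bins within a trial, the
cluster test behaves, under this generator, like a paired t-test on the
per-participant condition-mean difference, whose effect size is
`effect / sqrt(2 * SNR^-2 / n_trials)`. The calibration solves this for a
true detection probability around 0.98 — so that a 30-repetition estimate
exceeds 95% reliably rather than by luck — giving 36 trials per condition,
in line with the 72–96-trial sessions typical of this literature. Both
constants are documented here precisely because the published scenario
does not pin them down; the calibration procedure, not the numbers, is
the contract.

Under these conditions the effect-present detection rate exceeds 95% and
the effect-absent rate stays within the binomial band around 5% — both
asserted in the acceptance tests, and the former recomputed from scratch
by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the QA thresholds and the cluster
  inclusion threshold (a bin with p exactly 0.05 is excluded).
* Interpolation uses edge-hold (`rule = 2`) beyond the first/last valid
  sample.
* Bins where fewer than two participants contribute both levels are
  *absent* (NA), never zero, and break cluster contiguity.
* All-flagged recordings, all-invalid inter-beat intervals, cycle-free
  respiratory traces, zero-variance sessions and empty contrast levels
  raise informative errors rather than propagating NaN.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical schedules,
  recordings and null distributions.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise the full pipeline faithfully: the headline power
run uses the complete 29-participant × 72-trial × 30-repetition design
with 1000 permutations per test; the family-wise-error check uses 200
epoch-level null simulations with 399 permutations each; unit tests use
cohorts of 2–16 participants. The exhaustive-enumeration check is exact by
construction.

## Known limitations

* The axiomatic verdicts operate on cluster directions only; the
  published analyses additionally resolved biphasic (mixed-direction)
  pupil and heart-period results by inspecting full time courses. The
  `dominant` policy in `direction_of()` offers a mechanical approximation
  (largest-mass cluster wins), but genuine narrative adjudication is out
  of scope; the default `strict` policy treats mixed directions as
  violating any required ordering.
* QRS detection from raw ECG and vendor file formats (EyeLink, Spike2,
  WinDaq) are out of scope; heartbeat timestamps and long-format tables
  are the ingestion boundary.
* The power result is conditional on the generator calibration; it is a
  statement about the test's sensitivity under a stated noise model, not
  about any particular hardware.
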