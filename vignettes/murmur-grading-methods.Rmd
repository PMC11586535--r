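---
title: "Grading canine heart murmurs and staging preclinical MMVD: methods"
author: "caninemurmur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading canine heart murmurs and staging preclinical MMVD: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Auscultation of a dog's chest is one of the cheapest and most widely
available cardiac examinations, and the presence and intensity of a heart
murmur carries real diagnostic information: murmur intensity correlates
with the severity of myxomatous mitral valve disease (MMVD), the most
common cardiac disease of adult dogs, and with several congenital diseases
(pulmonic and aortic stenosis, patent ductus arteriosus).  Under the ACVIM
staging scheme, preclinical MMVD dogs with echocardiographic remodeling
(stage B2: LA/Ao ≥ 1.6 **and** LVIDDN ≥ 1.7, where LVIDDN =
LVIDD(cm)/weight(kg)^0.294) benefit from pimobendan, while B1 dogs do not
— so a cheap, observer-independent estimate of murmur intensity is a
useful triage signal for echocardiography referral.

`caninemurmur` implements a machine-learning pipeline for this problem:
electronic-stethoscope phonocardiograms, recorded for about 15 s at each of
three auscultation sites (left apex, left base, right side), are converted
to normalized log-spectrograms and graded on the five-level reduced murmur
intensity scale — none, soft (Levine I/II), moderate (III), loud (IV),
thrilling (V/VI) — by a bidirectional gated-recurrent-unit (GRU) network.
The grade distribution then drives two clinical reductions: murmur
detection, `P(murmur) = 1 − P(none)`, and B1-vs-B2 staging through the
*loud-or-greater* probability `P(loud) + P(thrilling)` at the left apex,
the expected point of maximal intensity of mitral regurgitation.

Because no annotated canine heart-sound corpus is publicly deposited, the
package is built around a synthetic phonocardiogram and cohort generator:
every stage of the pipeline is developed and tested against data whose
ground truth is known by construction, and whose joint structure mirrors
the published cohort tables that the package ships as fixtures
(`load_table_fixtures()`).

## Synthetic phonocardiograms

Each heartbeat is two damped-sinusoid transients — S1 (70 Hz, ~90 ms) at
the start of systole and S2 (90 Hz, ~60 ms) at its end, systole occupying
one third of the beat interval — plus, for murmur grades above none, a
band-limited Gaussian-noise murmur (Butterworth band-pass, 100–400 Hz)
with a crescendo–decrescendo envelope filling systole.  The grade is
encoded exactly as the reduced scale defines it, through the murmur-band
RMS relative to the S1 transient RMS:

| grade     | murmur/S1 RMS ratio | extra                           |
|-----------|--------------------:|---------------------------------|
| none      | 0                   |                                 |
| soft      | 0.4 (quieter)       |                                 |
| moderate  | 1.0 (equal)         |                                 |
| loud      | 2.0 (louder)        |                                 |
| thrilling | 2.5                 | 45 Hz component (the "thrill")  |

The default sample rate is 4 kHz (heart sounds and murmurs live below
1 kHz) and ambient noise is white with RMS 0.02 relative to the unit S1
peak.  A thrill is a *palpable* vibration, so representing it by an added
low-frequency (< 80 Hz) component is a modelling convenience: in real
recordings thrilling murmurs need not be acoustically louder than loud
ones, which is exactly why the clinical distinction is hard and why
passing tests on synthetic data say nothing about that particular boundary
on real dogs.  The generator also makes no attempt at respiratory noise,
sensor transfer functions, or arrhythmic beat morphology (arrhythmia is a
metadata flag only); murmur frequency bands are the implementer's choice,
as no canine spectral reference was available.

`synthesize_cohort()` draws dogs whose disease mix (54% MMVD, 18% normal,
the rest congenital/other), MMVD stage mix (B1:B2:C:D = 225:131:44:7),
per-stage left-apex grade distributions, per-diagnosis maximal-grade and
point-of-maximal-intensity distributions, medication and arrhythmia
rates all follow the published tables; ages, weights, LA/Ao and LVIDDN are
log-normal with the printed medians and IQR-matched spread, and B1/B2
echo values are constrained to their defining criteria (B2 dogs satisfy
both thresholds, B1 dogs fail at least one).  Each dog receives one
recording per site whose synthesized grade equals the reduced form of its
Levine grade at that site.  Diastolic murmurs are not synthesized — the
in-scope diseases present predominantly systolic murmurs — and continuous
(whole-cycle) murmurs are reserved for patent ductus arteriosus.

## Features

`compute_log_spectrogram()` cuts the recording into Hann-tapered half-open
frames starting at sample 0 (last partial frame dropped), takes short-time
magnitude spectra (FFT 256), keeps 20–800 Hz, log-compresses with a floor
(`log(pmax(mag, 1e-6))`), and z-scores over the whole recording.  Defaults
are a 50 ms window and 20 ms hop: long enough to resolve the S1/S2
transients from the murmur band, short enough that systole spans several
frames.  The original hyperparameters of the human-data model are
unpublished, so all of this is configuration with stated defaults.
Per-recording z-scoring is the default normalization because it removes
stethoscope gain differences; the amplitude-invariance this buys is tested
as a property (scaling the waveform shifts raw log values by a constant
and leaves the z-scored output unchanged).

## The grading network

The model is a stacked bidirectional GRU (standard gating, candidate
hidden term gated by reset) over spectrogram frames, followed by a linear
head on the temporal mean of the top layer's concatenated forward/backward
outputs.  Training is minibatch Adam on the softmax cross-entropy — grades
are treated as unordered classes, no ordinal-specific loss — with early
stopping on a held-out loss (patience 10 by default, best parameters
restored).  Forward and backward-through-time passes are implemented in
RcppArmadillo; the gradients are verified against central finite
differences in the test suite at tolerance 1e-6.

Transfer learning follows the head-surgery recipe: a 2-class base model is
first pretrained on a binary murmur-present/absent task
(`surrogate_pretrain()`, standing in for pretraining on the large human
heart-sound corpora, which are out of scope); then
`transfer_head_surgery()` copies every recurrent parameter verbatim and
replaces the final layer by a zero-initialized 5-output head, so that
immediately after surgery the model emits the uniform grade distribution
(softmax of zero logits) for any input.  Nothing is frozen: fine-tuning
(`finetune_crossval()`) updates all parameters, with patients — never
recordings — partitioned into k = 5 folds stratified by each patient's
maximum grade, and each fold model early-stopped on its held-out fold.
The k fold models predict at test time as an ensemble whose output is the
mean of the member softmax distributions; how the original 5
cross-validation models were combined at test time is unstated in the
source work, and averaging is the standard resolution.  The training unit
is the whole recording (not fixed-length crops), the other open choice.

The default architecture (2 layers, hidden size 64) is deliberately small;
the experiments in the tests and the acceptance script use an even smaller
scale — one layer of 24 units over 6×-average-pooled frames (≈ 120 ms per
step) — because the synthetic grading task is linearly separable in band
energy at that resolution and the smaller model fine-tunes in seconds per
fold on a single CPU.  Temporal pooling (`time_pool`) is exposed in
`model_config()` for this purpose.

## Cohort splitting

`minimization_split()` implements Pocock–Simon covariate minimization over
the six balancing variables: recruitment site, disease group
(MMVD/normal/other), heart rate, maximum murmur intensity over sites, body
condition score, and body weight.  Continuous variables are binned into
full-cohort terciles, BCS at < 5 vs ≥ 5; missing values form their own
stratum.  Patients are processed in a seeded random order derived per
patient from `hash(seed, patient_id)` — so each patient's assignment
depends only on patients ordered before it, and adding a patient never
flips earlier assignments (for a fixed arm capacity) — and each patient
goes to the arm minimizing the summed level-wise |train − test| imbalance
plus a soft arm-size term (weight 2), ties broken by a per-patient coin.

Equal arm sizes are guaranteed by a *hard capacity bound* of ⌈n/2⌉ per arm
rather than by a dominant size weight.  This is a deliberate design
choice: a dominant size term forces per-step alternation, and traces
showed that it can strand both members of an identical covariate pair on
the same arm (a forced size-balancing step arrives before the pair's
second member).  With the capacity bound the size constraint binds only
when an arm is full, covariates steer every other assignment, and
identical pairs end up split across arms.  A genuine limitation remains:
when distinct pairs share stratum levels on correlated variables, an
online minimizer can be steered away from the globally optimal balance by
an adversarial arrival order — no sequential rule can avoid this, because
the decisive choice can precede the information that settles it.  The test
suite therefore checks exact zero imbalance where the sequential optimum
is attainable, bounds the residual imbalance where it is not, and verifies
by Monte Carlo that minimization is stochastically better balanced than
simple randomization.

## Evaluation protocol

`nested_repeated_evaluation()` repeats, for each of `n_repeats` (50 at
full scale): a fresh seeded minimization split into equal halves → head
surgery from the fixed pretrained base → 5-fold fine-tuning on the
training arm → prediction on the test arm only.  With balanced 50/50
splits each patient appears in the test set `n_repeats`/2 times in
expectation (25 at full scale), and no test-arm recording influences any
training step of its repeat — both properties are asserted directly in the
tests, including a per-repeat hash intersection of train and scored
recording sets.

Uncertainty is quantified by percentile bootstrap (no normality
assumption, no BCa): patients — not recordings, to respect within-dog
correlation — are resampled with replacement within each run, and
intervals are percentile intervals of the pooled draws (the pooling
convention across repeats being the package's resolution of an ambiguity).
ROC curves are empirical with trapezoidal AUC; tied scores move along the
curve together so the trapezoid equals the pair-counting AUC with ties
counted 1/2, an equivalence the tests check exhaustively against an
independent pair-counting oracle for small inputs.  Curves from different
runs are combined by vertical averaging on a 101-point false-positive-rate
grid with linear interpolation.  Grading quality is summarized by
micro-averaged exact-match accuracy, the within-one-grade proportion, and
a column-normalized 5×5 confusion matrix (columns = expert grade).
Operating points on pooled out-of-sample scores are selected as "sensitive"
(max specificity subject to a sensitivity target) or "specific" (the
converse); the targets are configuration.

At test scale the protocol runs with 10 repeats and 100–200 bootstrap
iterations; confidence-interval widths scale predictably and the full
50/1000 protocol is available through `evaluation_config()`.

## Staging layer

`reduce_levine()` maps Levine 0–VI onto the reduced scale (0 → none, I/II
→ soft, III → moderate, IV → loud, V/VI → thrilling).  `stage_mmvd()`
applies the echo criteria with inclusive thresholds; congestive heart
failure (stage C/D) is an input label, not computed, because its clinical
assignment requires findings (radiographs, clinical signs) outside this
package's inputs.  Normal-hearted dogs under 15 kg are stage A (at risk);
larger normal dogs receive stage "none".  `partition_preclinical()`
excludes non-MMVD, C/D, and loop-diuretic dogs, then labels the remaining
B1/B2 dogs *confounded* if body weight is outside 2–25 kg, age < 6 years
(strict inequalities, as the gates are defined), or pimobendan is given —
and *clean* otherwise.  `classify_b1_b2()` thresholds the loud-or-greater
probability at the left apex; the default threshold 0.5 corresponds to the
rule "a predicted loud or thrilling murmur decides B2", and the exact
threshold behind the specific operating point of the source analysis is
not printed, so it is exposed as configuration.  A missing left-apex
recording is an error, not imputed.

## Experiment scale and what the tests show

The acceptance computations use, as the package's own choice of scale: a
200-dog cohort (600 recordings, 15 s at 4 kHz, ambient noise RMS 0.02) for
parameter recovery, an independent 40-dog cohort for surrogate
pretraining, a 150-dog B1/B2-only cohort for the staging ROC, a 40-dog
cohort with a deliberately minimal model for the 50-repeat protocol
invariants, and 200 simulations × 200 bootstrap draws for interval
coverage.  On held-out dogs the fine-tuned ensemble reaches within-one-
grade accuracy ≥ 0.99 and murmur-detection AUC ≈ 1.0, and the
loud-or-greater rule separates B1 from B2 with AUC ≈ 0.82–0.85.  That
staging ceiling is a property of the published grade-by-stage tables
themselves — given the per-stage left-apex grade distributions, a perfect
grader's expected pair-ordering AUC is ≈ 0.83 — so the model essentially
saturates the information the synthetic generator encodes.

These results validate the machinery, not the clinic: the synthetic task
is far easier than real auscultation (no respiratory or handling noise, a
deterministic grade-to-amplitude mapping, a single cardiologist-free
ground truth), so the recovered accuracies are upper bounds that say the
pipeline is implemented correctly, nothing more.  The headline clinical
metrics of the motivating study are not reproducible here because its
recordings are not deposited.

## Numerical choices and degenerate inputs

Log-spectrograms clamp magnitudes at a positive floor before the log, so
all-zero recordings map to a constant (and z-scoring guards against zero
variance); recordings shorter than one window are errors.  GRU parameters
initialize uniformly in ±1/√H from the config seed; Adam uses the
conventional (0.9, 0.999, 1e-8).  Ensembles require equal-length
spectrograms within a batch.  Bootstrap resamples that produce a
degenerate (NA) statistic are redrawn, and a statistic degenerate 100
times in a row is an error.  All multi-stage randomness derives from one
seed through FNV-hash-based sub-seeds (`derive_seed()`), so cohorts,
splits, fold assignments, and training shuffles are independently seeded
yet exactly reproducible, and WAV and cohort-CSV round-trips are lossless
to 16-bit quantization and to missing-value preservation respectively.
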