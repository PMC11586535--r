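# caninemurmur

Detect and grade heart murmurs in electronic-stethoscope recordings of
dogs, and stage preclinical myxomatous mitral valve disease (MMVD).

Heart murmur intensity is a sensitive, cheap indicator of canine cardiac
disease: almost every MMVD, pulmonic-stenosis and aortic-stenosis case has
a murmur, and in preclinical MMVD a loud-or-thrilling murmur at the left
apex strongly suggests the echocardiographically remodeled stage B2 — the
stage at which pimobendan is indicated.  Grading murmurs well, however,
takes cardiologist-level skill.  This package implements a
machine-learning pipeline that automates it, aimed at veterinary
cardiology and ML researchers who want a fully testable, end-to-end
reference implementation.

## What's inside

* **Grading model** — phonocardiograms are converted to normalized
  log-spectrograms and graded on the five-level reduced murmur scale
  {none, soft, moderate, loud, thrilling} by a bidirectional GRU network
  (forward and backprop-through-time hand-implemented in RcppArmadillo; no
  deep-learning framework required).  Transfer learning follows the
  head-surgery recipe: pretrain a 2-class murmur detector, copy all
  recurrent weights verbatim, replace the head by a zero-initialized
  5-class layer, fine-tune everything with patient-level 5-fold
  cross-validation and early stopping.  From the predicted grade
  distribution *p* the clinical reductions are

  * murmur detection: `P(murmur) = 1 − p(none)`
  * B1-vs-B2 staging: the *loud-or-greater* probability
    `P(loud) + P(thrilling)` at the left apex, thresholded (default 0.5).

* **Clinical rules** — Levine 0–VI → reduced grade; LVIDDN =
  LVIDD(cm)/weight(kg)^0.294; ACVIM staging (B2 iff LA/Ao ≥ 1.6 and
  LVIDDN ≥ 1.7, inclusive); preclinical clean/confounded partition
  (exclude non-MMVD, C/D, loop diuretics; confounders: weight outside
  2–25 kg, age < 6 y, pimobendan).

* **Evaluation machinery** — Pocock–Simon covariate-minimization 50/50
  splits (six balancing variables, hard ⌈n/2⌉ arm capacity), repeated
  split/fine-tune/test protocol with strict train-test isolation,
  patient-level percentile bootstrap CIs, empirical ROC with trapezoidal
  AUC (tie handling matches exhaustive pair counting), vertical ROC
  averaging, micro-averaged accuracy / within-one-grade agreement /
  column-normalized confusion matrices.

* **Synthetic data** — a phonocardiogram synthesizer (damped-sinusoid
  S1/S2 transients, band-limited systolic murmur whose RMS ratio encodes
  the grade, 45 Hz thrill component) and a cohort generator whose disease,
  stage, grade, medication and echocardiographic joint structure mirrors
  the published cohort tables, which ship as fixtures
  (`load_table_fixtures()`).  Everything is seed-deterministic.

## Worked example

```r
library(caninemurmur)

# a 15 s left-apex recording with a loud murmur at 110 bpm
cfg <- synthesis_config(heart_rate = 110, murmur_grade = "loud", seed = 8)
rec <- synthesize_pcg(cfg, patient_id = "demo", site = "left_apex")
rec
#> <pcg_recording> demo @ left_apex: 60000 samples @ 4000 Hz (15.0 s)
murmur_band_ratio(rec, cfg)   # loud = murmur louder than S1/S2
#> 1.87

# the published cohort tables as queryable fixtures
s2 <- cohort_summary(load_table_fixtures("table2"))
summary_pct(s2, "MMVD", "max_intensity",
            c("soft", "moderate", "loud", "thrilling"))
#> 98        # percent of MMVD dogs with a murmur of any grade

# clinical reductions of a predicted grade distribution
dist <- c(none = 0.02, soft = 0.08, moderate = 0.20,
          loud = 0.55, thrilling = 0.15)
binary_murmur_probability(dist)   #> 0.98
loud_or_greater_probability(dist) #> 0.7
classify_b1_b2(dist)$stage        #> "B2"
compute_lviddn(3.1, 9.8)          #> 1.58  (>= 1.7 would support B2)
```

The murmur/S1 ratio of 1.87 realizes the definition of a loud murmur
(louder than the heart sounds); the distribution above would flag a murmur
with probability 0.98 and call the dog B2 because most predicted mass sits
at loud or thrilling.

The full pipeline — synthesize a cohort, pretrain, repeated
split/fine-tune/evaluate, staging report — runs from one config:

```r
run_pipeline(default_run_config(seed = 1), "artifacts/")
```

A thin CLI over the same functions lives at
`system.file("cli/caninemurmur.R", package = "caninemurmur")` with
`synth`, `split`, `train`, `predict`, `evaluate`, `stage`, and `run`
subcommands.

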