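---
title: "Methods: heart-sound screening for valvular heart disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-sound screening for valvular heart disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pcgscreen` implements an auscultation-based screening pipeline for
left-sided valvular heart disease (VHD): aortic and mitral stenosis (AS,
MS, graded 0–3) and aortic and mitral regurgitation (AR, MR, graded 0–4).
The input is a set of four ~10 s phonocardiogram (PCG) recordings per
participant — aortic, pulmonic, tricuspid and mitral auscultation positions
— plus murmur-grade annotations from two annotators (integers 0–6, with a
noise flag), echocardiographic labels, and clinical covariates.

The pipeline has five stages:

1. **Conditioning** — iterative maximum-absolute-amplitude (MAA) spike
   removal and anti-aliased downsampling to a working rate of 2,205 Hz.
2. **Segmentation** — a duration-dependent hidden semi-Markov model (HSMM)
   decodes the cyclic state sequence S1 → systole → S2 → diastole at a
   50 Hz envelope rate, with the heart rate estimated by *fusing* envelope
   autocorrelations across the participant's non-noisy recordings.
3. **Features** — each recording is cut into up to six 50 %-overlapping
   blocks of four cardiac cycles; each block becomes a 13 × 200
   Mel-frequency-cepstral-coefficient (MFCC) matrix, standardized to zero
   mean and unit variance.
4. **Murmur-grade regression** — a two-layer LSTM (50 units each) with a
   30-unit rectified fully connected head regresses the annotator-mean
   murmur grade per block; the recording grade is the median over blocks.
5. **Screening** — the four position grades feed (a) a BIC-selected
   multiposition linear model of the mean aortic-valve pressure gradient
   (AVPGmean, mm Hg), whose 15/20/40 mm Hg cutoffs grade AS; (b) joint
   screening rules over the maximum predicted grade; and (c) logistic
   fusion models combining audio predictions with clinical covariates.
   Evaluation uses participant-level eightfold cross-validation with a ~10 %
   holdout, stratified by AS status.

Because the clinical study data this design targets are access-restricted,
the package ships a first-class synthetic cohort generator
(`generate_cohort()`) that emulates the statistical structure the analysis
assumes; every stage is exercised and tested against it.

# The synthetic cohort: what it emulates, and what it does not

`cohort_config()` fixes the study conditions. Disease prevalences default
to the published cohort's: P(AS ≥ 1) = 2.1 %, P(MS ≥ 1) = 0.6 %,
P(AR = 3)/P(AR = 4) = 5.3 %/1.8 %, P(MR = 3)/P(MR = 4) = 10 %/3.7 %.
Noise-flag prevalences per position default to 6.1, 5.3, 2.8 and 7.1 %.
Clinical covariates shift with disease (age +7 y, heart rate −3 bpm for the
VHD subgroup, directions from the cohort demographics table), and
questionnaire missingness rates follow the published percentages (e.g.
4.24 % for breathlessness items, 6.03 % for mMRC).

Each participant draws a mean aortic pressure gradient: non-stenotic mass
near 3–8 mm Hg (a shifted gamma truncated below 15), stenotic values from
the mild/moderate/severe bands above 15/20/40 mm Hg. The AS grade is then
*derived* from the gradient through the cutoff function, so labels are
consistent by construction. True continuous murmur grades are mapped from
severity: AS drives an aortic-dominant systolic murmur (grade
`1 + 4.3·(AVPG − 15)/65`, radiating to the pulmonic, tricuspid and mitral
positions at factors 0.85/0.5/0.4), MR a mitral-dominant systolic murmur,
MS a diastolic mitral component, and AR a weak diastolic component whose
loudness grows with a latent "expression" variable that also raises
symptom probabilities — this is what makes symptomatic regurgitation more
detectable, mirroring the analysis the screening harness performs.
Innocent murmurs occur in 12 % of participants. Two annotator grades are
the true grade plus Gaussian noise (SD 0.5 grade units), rounded and
clipped to 0–6; noisy-flagged recordings are rendered with low-SNR
broadband interference and annotated grade 0.

Audio synthesis (`synthesize_pcg()`) renders S1/S2 as Hann-windowed
band-limited bursts (~122 ms and ~92 ms, 40–200 Hz), sets the systolic
interval as a linear function of cycle length (`0.15 s + 0.2·cycle`), and
renders murmurs as 100–440 Hz band-passed noise with a diamond envelope.
The murmur-to-S1 RMS ratio is `0.12·grade`: the field's loudness scale
gives no quantitative calibration, so this linear map is a generator
convention chosen so grade 1 sits near the audibility floor and grades 5–6
dominate the signal.

What the generator does **not** emulate: real acoustic propagation,
respiration and movement artifacts, ECG timing, inter-beat variability
beyond small Gaussian jitter, device/positioning variation, or the
annotators' perceptual nonlinearities. Passing tests therefore demonstrate
that the pipeline's machinery is correct and recovers structure it was
designed for — not that the trained network would reach the published
performance on clinical recordings.

# Conditioning

Spike removal follows the iterative MAA scheme: 500 ms non-overlapping
windows (last partial window kept); while the maximum window MAA exceeds
three times the median MAA, the loudest sample in the offending window is
located, expanded to the nearest zero crossings (or window edges), and the
span is zeroed. Zeroing (rather than interpolation) matches common
reference implementations and makes the operation idempotent. Spike
removal is applied *before* downsampling, following the order in which the
steps are described for the original pipeline.

Downsampling is a polyphase-style rational conversion: zero-stuffing,
a Hamming-windowed sinc FIR (cutoff at 92 % of the target Nyquist,
20·max(p, q)+1 taps) applied by FFT convolution with group-delay
compensation, then decimation. Tones below the target Nyquist keep their
spectral peak to within one FFT bin, and 0–400 Hz band power is preserved
within 5 % on synthetic PCGs (both are tested).

# Segmentation

Four envelopes are computed at 50 Hz: the homomorphic envelope
(exponentiated 8 Hz-low-passed log magnitude of the analytic signal), the
analytic-signal magnitude, 40–60 Hz band power, and a level-3
Daubechies-4 stationary-wavelet detail envelope; each is z-scored per
recording.

The heart rate is the inverse of the argmax lag of the mean-removed,
normalized autocorrelation of the homomorphic envelope within lags
0.5–2.0 s (forcing 30–120 bpm); the systolic interval is the argmax within
0.2 s to half the cycle lag. For a participant, the normalized
autocorrelations of all non-noisy recordings are averaged pointwise before
peak picking (`fuse_heart_rate()`); with one usable recording this reduces
exactly to the single-recording estimate. Averaging autocorrelations was
chosen over the alternative (median of per-recording rates) because it
uses the full evidence and degrades gracefully when one recording is pure
noise; the strategy sits behind its own function so the alternative can be
swapped in. A peak below 0.15 in normalized units flags low confidence.

Decoding uses duration-dependent Viterbi over the four cyclic states with
per-state diagonal-Gaussian emissions on the four envelope features and
Gaussian duration priors: S1 mean 122 ms and S2 mean 92 ms (SD 22 ms,
published defaults for this model family), systole = systolic interval −
S1, diastole = cycle remainder (SD 25 % of the mean, floor 30 ms; support
truncated at mean + 3.5 SD). The emission model is *injected*
(`fit_emission_model()` trains it on labelled synthetic frames), so a
logistic-regression emission variant could replace it without touching the
decoder. The first and last segments may be truncated, so their duration
prior is the running maximum of the distribution tail — a partially
observed state is not penalized for its unobserved remainder. The C++
decoder is checked against an independent plain-R dynamic-programming
reference to 1e-9 relative log-probability.

Blocks are four consecutive cycles with stride two (50 % overlap), at most
six per recording (the first six when more exist). A recording decoding to
fewer than four cycles yields one short block covering all complete cycles
rather than being dropped: no exclusion rule exists for short decodes, and
median aggregation tolerates the occasional short block. Whether six
blocks were guaranteed in the original recordings (10 s needs ≥ 14 cycles)
is unstated; the ≤ 6 rule here is a documented choice.

# Features

MFCCs use Hann windows of 35 ms with a 25 ms hop — the stated "step size
of 25 ms and window overlap of 10 ms" is read as hop 25 ms and window
35 ms, the only reading in which both numbers are simultaneously
meaningful; both are config-exposed. The filterbank is 26 triangular
filters on the HTK Mel scale spanning 0 to Nyquist, log floor 1e-10,
followed by an orthonormal type-II DCT. "The 13 first coefficients" is
read literally as c0–c12 (a flag drops c0). Filter count, frequency range
and the c0 convention are not specified by the source analysis; the
defaults are conventions and are exposed.

Resizing to 13 × 200 interpolates along time only with a cubic spline
(Forsythe–Malcolm–Moler end conditions, which reproduce polynomials up to
degree 3 exactly — the property the tests assert); the matrix is then
standardized by its scalar mean and standard deviation. Zero-variance
blocks are rejected.

# Murmur-grade network

The regressor consumes 200 timesteps of 13-dim vectors: two LSTM layers of
50 units, the final hidden state into a 30-unit rectified fully connected
layer, then a linear scalar output; squared-error loss. The initial
learning rate is 0.002, halved every five epochs
(`lr(e) = 0.002 · 0.5^⌊e/5⌋`, exact in tests). Choices the source leaves
open, resolved here: the optimizer is Adam (0.9/0.999); the fully
connected nonlinearity is a rectifier; every block inherits its
recording's annotator-mean grade as label (the only label available per
block); one training sample per block; positions are pooled with no
position feature; the default epoch count is 30, and desk-scale runs use
15 (or fewer in the CV harness — see problem sizes below). Training uses
only recordings both annotators marked non-noisy, with the murmur class
(grade ≥ 1) resampled with replacement to an approximately 1:1 ratio.
Initialization and shuffling run on a private seeded generator, so
training is bit-reproducible. The C++ implementation's forward pass and
analytic gradients are verified against an independent R forward
implementation and central finite differences.

Predictions are raw (unclipped) reals; thresholds operate on raw scores.
The recording grade is the median over blocks; participant-level
aggregation assigns noisy positions grade 0, and participants with all
four recordings noisy are excluded.

# Gradient model, screening and evaluation

The multiposition model predicts AVPGmean from the four predicted grades
with terms up to second degree plus noise-indicator interactions. The
published fitted model is available as a preset
(`avpg_preset_model()` = 3.5 + 0.6·MG_A² + 1.1·MG_P² + 0.5·MG_T +
0.9·MG_A²·noise_P + 8.9·MG_M·noise_A·noise_P·noise_T); the publication's
ellipsis indicates elided terms, and the preset implements exactly the
printed ones. Stepwise selection starts from the four linear terms,
evaluates all single additions (requiring p < 0.05 for the entering term)
and removals (candidates have p > 0.05) jointly, takes the global BIC
minimizer (`BIC = n·ln(RSS/n) + k·ln(n)`, k counting terms, intercept and
variance), and stops at a local optimum; phase 2 repeats over noise terms.
Move ordering is not specified by the source; the joint-minimizer rule
with index tie-breaks makes selection deterministic. Inside
cross-validation only coefficients are re-estimated per training split;
the preset structure is used (terms whose design column is constant in a
split are dropped for that split as unidentifiable).

Decision thresholds maximize sensitivity + specificity over score
midpoints subject to sensitivity > 50 %, ties toward higher specificity
then lower threshold; midpoints exhaust all distinct confusion matrices.
Joint screening definitions: (1) grade ≥ 3 regurgitation or any stenosis,
(2) grade ≥ 4 regurgitation or any stenosis, (3) symptomatic grade ≥ 3
regurgitation or any stenosis, with "symptomatic" = breathlessness at rest
or walking calmly on level ground, or mMRC ≥ 2. Clinical fusion models
(logistic): AR ~ max grade + age + gender + breathlessness uphill + heart
rate; MR ~ mitral grade + age + heart rate; AS ~ multiposition gradient
prediction + gender + gender×prediction; MS ~ max grade + age + heart
rate. Audio predictors are out-of-fold CV predictions, never in-fold.
Categorical gaps are imputed with the most frequent answer; numeric
covariates (whose handling the source does not state) with the median.
Continuous covariates enter untransformed. The symptomatic-subgroup
comparison uses a two-sided Fisher exact test (the source names no test;
small counts make the exact test preferable).

Metrics: rank-based AUC with ties counted one half; Clopper–Pearson
intervals by beta-quantile inversion; fold-based intervals as mean ±
t(k−1)·sd/√k (the iid-folds assumption is stated by the source, the
interval form is not — the t form is standard small-k practice); Cohen's
kappa and percent agreement on the binary murmur-present variable. Pooled
AUC is used when folds contain no positives.

# Problem sizes and numerical choices

The test suite runs everything on seeded synthetic cohorts at sizes chosen
to keep a full run on one CPU comfortable: segmentation accuracy on 50
clean recordings (50–90 bpm); murmur-grade recovery on a 400-participant
cohort at 2,205 Hz with 15 training epochs and a 100-participant held-out
split; the end-to-end CV harness on a 150-participant cohort with 3 epochs
per fold (murmur-grade regression on the clean synthetic audio converges
in a few epochs, and the harness's purpose is the orchestration, not peak
accuracy). The emission model is fitted from 12–24 labelled synthetic
recordings. Duration priors are truncated at 3.5 SD; emission variances
are floored at 1e-4; the MFCC log floor is 1e-10; all-zero signals and
degenerate blocks raise errors rather than propagating NaNs.

# Known limitations

Noise is flagged by annotators, never detected automatically. The
synthetic audio is stylized (see above), so absolute performance numbers
on it do not transfer to clinical recordings; published cohort-level
results are not reproducible without the restricted data and are not
claimed. The printed coefficient magnitudes of the clinical-fusion models
are not reproduced (their scale/link documentation is insufficient); only
the model structures are. Exact numerical parity with the original
MATLAB segmentation implementation is a non-goal.
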