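---
title: "Decoding latent social context from baseline LFP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding latent social context from baseline LFP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpcontext)
```

## The scientific problem

In a blocked tactile paradigm, a monkey receives alternating blocks of
non-social airflow stimuli and social grooming ("touch") delivered by a
trusted human partner. The hypothesis this package operationalizes is that
the *context* of a block — the latent social/autonomic state, not the
stimuli themselves — leaves a decodable trace in the **baseline** local
field potential (LFP) recorded between stimuli. The package provides the
complete analysis chain on **synthetic sessions**: no recordings ship with
it, so a generator module produces sessions with the statistical structure
the analysis assumes, and every downstream stage is tested against it.

The chain is: simulate → clean heartbeats and estimate RSA → extract
baseline windows → wavelet spectrograms → CNN/SVM decoding with a
shuffled-label null → band ablation → spike-triggered averages.

## The synthetic-session generator

`simulate_session()` emulates the paradigm's experimental design:

* **Schedules.** Airflow blocks deliver 11 presentations × 10 repeats
  (110 total), touch blocks 20 stimuli × 5 repeats (100 total); stimuli
  last 1 s, separated by ~4 s. A session holds alternating blocks
  (default 3 of each) separated by an inter-block gap (default 120 s,
  "a few minutes").
* **LFP.** Each channel is 1/f background noise (exponent 1, SD 50 µV)
  plus band-limited components at 10–17 Hz and 17–25 Hz (SD 15 µV) whose
  power is multiplied by a gain (default 2.0) inside blocks of the
  favoured type — touch favours 10–17 Hz, airflow 17–25 Hz — plus
  Poisson-timed transient oscillatory bursts and brief broadband
  transients during stimuli (never analysed). Setting both gains to 1 and
  equal autonomic parameters gives a context-free *null world*.
* **Heartbeats.** An integrate-and-fire generator whose instantaneous
  rate is the block's heart rate (defaults 130 airflow / 110 touch BPM)
  modulated sinusoidally at the respiratory frequency (0.35 Hz) with the
  block's RSA depth (0.05 airflow / 0.15 touch).
* **Spikes.** Bernoulli-thinned inhomogeneous Poisson trains whose rate
  can be modulated by the channel's band-passed LFP, so spike-triggered
  averages have controllable spectral content.

Several quantities the paradigm leaves unstated are declared here as
package defaults, not inferences: the LFP sampling rate (1 kHz, which
comfortably covers the 1–50 Hz analysis band), the number of blocks per
session, the inter-block gap, and a 32-contact probe split across nuclei
(C 4, L 10, B 10, AB 6, Pl 2). One master seed fans out to per-component
substreams (`substream_seeds()`), so any module can be re-run
independently and a session is fully reproducible from `(parameters,
seed)`.

What the generator does *not* emulate: biophysical forward modelling,
volume conduction, electrode drift, cross-channel covariance structure
beyond shared block timing, non-stationary heart-rate trends, or
movement artifacts. Passing tests therefore demonstrate that the
*analysis chain* behaves correctly on data with the assumed structure —
they are not evidence about real recordings.

## Baseline selection

Baselines live in inter-stimulus intervals (ISIs) between two stimuli of
the *same* type: 200 ms after one offset to 200 ms before the next onset
(`isi_segments()`); nothing before a block's first stimulus is used. With
1 s stimuli and 4 s gaps every candidate spans 3.6 s, and a block of *n*
stimuli yields *n − 1* candidates.

`select_stable_window()` implements the stability criterion: align the
candidates, compute the across-trial SD at each timepoint (per channel,
averaged over channels), and slide a 0.5 s window to the offset with the
lowest mean SD, breaking ties toward the earliest offset. One offset is
chosen **per session** (not per channel) so every spectrogram shares a
time base; the alternative reading — per-channel selection — would give
channels unaligned windows and was rejected for that reason. The 0.5 s
default window matches the single-trial spectrogram length; it is a
parameter.

## Spectrograms

`cwt_spectrogram()` computes the squared modulus of a continuous wavelet
transform with a standard complex Morlet (ω₀ = 5) on a 1–50 Hz grid at
1 Hz spacing. The scale for grid frequency *f* is `a = ω₀·fs/(2π·f)`,
which places the wavelet's peak response exactly at *f*; the wavelet is
L1-normalized so equal-amplitude tones at different frequencies produce
equal power. (A printed scale expression of the form `2·fs/f` floats
around for this transform; it does not localize tones at their own
frequency for ω₀ = 5, so the standard scale rule is used and verified by
tone-localization tests.) No cone-of-influence masking is applied — the
windows are short and the lowest rows are acknowledged as edge-dominated.

The CWT of a 1 kHz signal is heavily oversampled in time, so the power
image keeps every 16th column by default (`time_decim`), giving ~31
columns per 0.5 s window; the tests and acceptance runs use 32 (16
columns). This is a resolution/compute trade-off of the package, and the
classifiers see identical information content in practice.

`fit_normalizer()`/`apply_normalizer()` implement dataset-level min–max
scaling **fitted on the training split only**; test values outside the
training range are clipped to [0, 1] and a pixel constant across the
training set maps to 0. A per-image variant is available behind the
`per_image` flag.

## Decoding protocol

One dataset per (session, nucleus): all baseline spectrograms of that
region, labelled by block type (`build_dataset()`). The protocol
(`training_protocol()`): each class's unique windows are partitioned
into a stratified 80/10/10 train/validation/test split, then the
minority class (touch in the standard design) is bootstrap-resampled
*within each subset* to class parity, and the whole procedure is
repeated 50 times with fresh splits and initializations. Ordering the
partition before the resampling matters: balancing an imbalanced dataset
to parity *before* splitting places bootstrap duplicates of single
windows on both sides of the split, and a flexible classifier then
scores above chance on a context-free dataset by pure memorization (we
measured ~61% median "accuracy" for the RBF-SVM on null-world data under
that ordering). Partition-first preserves the subset arithmetic (300 +
200 windows per class still give 480/60/60 after balancing) while
keeping balancing blind to the test items. 5th/50th/95th accuracy
quantiles summarize each repeat distribution.

* **CNN** (`cnn_init()`/`cnn_train()`): conv 3×3 ×24 + ReLU → batchnorm →
  conv 3×3 ×48 + ReLU → maxpool 2×2 **stride 1** (as published; a
  stride-2 variant sits behind `pool_stride`) → batchnorm → FC 64 →
  dropout → FC 2; Adam on cross-entropy, minibatches of 20, 40 epochs.
  After each epoch the model is scored on the validation set and the
  best-validation parameters are kept ("best" = highest validation
  accuracy; the alternative reading — lowest — contradicts the
  save-on-improvement rule and is treated as a typo). Unstated
  hyperparameters are declared defaults: dropout 0.5, learning rate
  1e-3. The implementation is native (compiled im2col/pool kernels + BLAS
  products) and is verified against finite-difference gradients.
* **SVM** (`e1071::svm`): RBF kernel on flattened spectrograms, `C = 1`,
  kernel width by the median heuristic (1/median squared pairwise
  distance); both exposed in the protocol.
* **Null distribution**: identical data and protocol, but training (and
  validation) labels are permuted; evaluation uses the true-labelled test
  set. "Separation" means the real 5th percentile exceeds the null 95th
  percentile (`separates_from_null()`).

`band_ablation()` re-trains on spectrograms restricted to 10–17, 17–25
and 10–25 Hz (inclusive bounds) and compares with the full grid.
`cross_nucleus_test()` applies the Kruskal–Wallis H-test across
per-nucleus accuracy samples and, given contact counts, the Spearman
correlation of median accuracy with contacts.

## Physiology

`clean_heartbeats()` removes beats creating inter-beat intervals outside
[250, 1500] ms — equivalently heart rates outside [40, 240] BPM; the
bounds are inclusive on the retained side, since only values *below*
250 ms or *above* 1500 ms are rejected — and interpolates instantaneous
heart rate to a 1 ms grid with a modified Akima cubic Hermite
interpolant (implemented in the package and validated against a
reference implementation). Long gaps are treated as dropout: the beats
are kept but the spanned interval is excluded from the rate series.

`rsa_strength()` estimates respiratory sinus arrhythmia in sliding 60 s
windows with 7 Slepian tapers. Two readings of the published setup are
resolved as follows:

* "an overlap of 3 s" is read as a 3 s **hop** (57 s shared between
  consecutive windows): a 3 s overlap of 60 s windows would make the
  windows nearly disjoint and "sliding" vacuous. The hop is a parameter.
* The time-bandwidth product is set to NW = 4 so that 2NW − 1 = 7 tapers
  are well concentrated; only the taper count is prescribed.
* The normalization constant μ across windows is the **median** of the
  per-window strengths (a power scale), with the sum — which appears in
  the printed formula but is not a power scale — available as
  `mu_mode = "sum"`.

Each window's spectrum is normalized to unit area on 0.25–0.5 Hz
(15–30 breaths/min); RSA strength is the mean power over the highest
band-interior peak ± its half-width at half prominence, or the band mean
when no peak exists. Peak prominence (rather than raw amplitude) is used
because the band edge can dominate amplitude without being a peak. The
1 ms heart-rate series is decimated to 10 Hz (boxcar means) before
spectral estimation — the band of interest ends at 0.5 Hz, so Nyquist
margin is a factor of 10, and the 600-point Slepian eigenproblem is exact
and fast. `compare_blocks()` runs paired one-sided t-tests across
sessions (RSA: touch > airflow; heart rate: touch < airflow), reporting
t = 0, p = 0.5 in the degenerate all-zero case.

## Spike-triggered averages

`spike_triggered_average()` averages ±80 ms of the unit's channel LFP
around spikes falling **inside extracted baseline windows** (not merely
the ISI), per block label. `sta_spectrum()` averages per-snippet Welch
PSDs — the conditional expectation of LFP power given a spike. A 160 ms
snippet cannot support a 1 ms Welch segment resolving 1–50 Hz, so the
default segment is the whole snippet under a single Hann window
(`segment_length` remains configurable); this preserves the stated
Hann/50 %-overlap machinery while producing meaningful spectra.
`mean_sta()` averages STAs and spectra over the units of one nucleus.

## Numerical choices and degenerate inputs

* CWT: generous zero padding (≥ 4 scales of the lowest frequency) avoids
  circular wrap; windows are demeaned before transforming.
* Stability scan ties break to the earliest offset; constant signals are
  valid input.
* Batchnorm uses ε = 1e-5 and momentum 0.1; minibatches of one are
  skipped (batch statistics undefined).
* Max-pool ties route the gradient to the first maximal cell.
* A class absent from a dataset, a window longer than its candidate
  interval, an empty frequency band, fewer than 3 valid heartbeats, or a
  series shorter than one RSA window are errors; short ISI gaps and empty
  nuclei are skipped with a message.

## Problem sizes used in the tests

The shipped tests and the acceptance script run desk-scale versions of
the study conditions: 1–4 contacts in a single nucleus, datasets capped
at 200–500 windows per class, spectrogram time axes decimated to 16
columns, SVM repeats of 20, and CNN repeats of 10–20 at 2–8 epochs.
Calibration and ablation checks use one block per type; the
signal-detection check uses the full 3+3 alternating design — with a
single block per class, class labels coincide with session halves, and
a label-shuffled model can exploit slow 1/f drift whenever a shuffle
happens to align with time, widening the null's upper tail; multiple
blocks per class force any such feature to generalize across blocks,
which is also the regime the paradigm actually uses. All *effect*
parameters (band gains, heart rates, RSA depths, cutoffs, bands) keep
the defaults stated above. With these sizes the signal-world checks
separate cleanly from their nulls; the reduced CNN epoch counts lower
absolute accuracy but leave the calibration and separation properties
intact.

## Known limitations

* The CNN is CPU-bound R + compiled kernels: faithful, tested, and fast
  enough for the shipped protocol sizes, but not a GPU training stack.
* Classifiers are session- and nucleus-specific by design; no
  cross-session generalization is attempted.
* The generator's band-gain effect is stationary within blocks; it does
  not model slow drifts of context strength.
* `max_per_class` subsampling and spectrogram decimation are pragmatic
  caps for bounded run times; removing them recovers the full protocol.

## A worked miniature

```{r, eval = FALSE}
session <- simulate_session(
  designs = default_designs(3),
  channel_nuclei = rep("B", 4), effect = effect_spec(), seed = 204,
  spikes = FALSE, heartbeats = FALSE)
baselines <- extract_baselines(session)
stack <- spectrogram_stack(baselines, wavelet_config(session$fs,
                                                     time_decim = 32))
dataset <- with_seed(211, build_dataset(stack, "B", max_per_class = 500))
dist <- accuracy_distribution(dataset, "svm",
                              training_protocol(repeats = 20), seed = 205)
print(dist)
separates_from_null(dist)
```
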