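---
title: "Methods: channel importance and compact convolutional classification for motor-imagery EEG/EOG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel importance and compact convolutional classification for motor-imagery EEG/EOG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Motor-imagery brain–computer interfaces decode imagined limb movement from
the event-related modulation of sensorimotor rhythms (mu, ~8–12 Hz; beta,
~12–30 Hz). Practical systems want few electrodes. Electrooculogram (EOG)
channels — electrodes placed around the eyes, conventionally used only to
detect and remove ocular artifacts — sit in every standard montage, and
there is growing evidence that they also pick up class-relevant neural
signal (volume-conducted leakage from frontal and motor sources). This
package provides the tooling to ask, quantitatively, *how much*
class-relevant information EOG channels carry: five channel-importance
methods, a compact 1D convolutional classifier to measure what a reduced
montage can achieve, and a synthetic generator with planted ground truth so
that every method can be validated against a known answer.

## The data model

Everything operates on an `epoched_dataset`: a `trials x channels x
samples` array (microvolts) with integer labels `0..K-1`, per-channel
EEG/EOG modality tags, and a sampling rate. The two public benchmarks the
tooling is shaped around are a 4-class recording (22 EEG + 3 EOG channels,
250 Hz, 576 trials of 1000 samples per subject) and a 7-class recording
(60 EEG + 2 EOG, 200 Hz, 560 trials of 800 samples). Epoch windows for the
loaders are seconds 2–6 of each trial for the former (cue at 2 s, imagery
until 6 s) and 3–7 for the latter (task cue shown for 4 s from 3 s).

Splits are stratified 80/20 by default. The published protocol says only
"random"; stratification preserves class balance at the ~115-trial test
size, and a non-stratified mode is a flag away. The training-set size is
`round(0.8 * n)` in total, distributed over classes by largest fractional
remainder (ties to the lowest class index) — e.g. 576 trials give
461/115 as 116+115+115+115.

Accuracy tables are summarized with the arithmetic mean, the midpoint
median for even counts, and the *population* standard deviation (divide by
N). These conventions are not a matter of taste here: they are the only
combination under which the published per-subject tables shipped in
`inst/extdata/` reproduce their own printed Mean/Median/SD rows (the
sample SD gives 9.87 and 13.15 where 9.3 and 12.47 are printed), and the
test suite pins all thirty cells at printed precision.

## The synthetic generator

`simulate_dataset()` builds recordings with the statistical structure the
analyses assume, plus planted ground truth:

* **Background**: every channel is 1/f^a-shaped Gaussian noise (default
  a = 1), synthesized by frequency-domain amplitude shaping of white
  noise — the target spectrum is exact in expectation, unlike AR
  approximations. `spectral_slope()` recovers a on log–log axes.
* **Class effects**: informative channels carry a band-limited oscillation
  (default alpha, 8–12 Hz per the classical band table) whose variance is
  scaled by `1 + depth` for the channel's preferred class — a band-power
  (ERD/ERS) effect, not an evoked waveform, matching how motor imagery
  actually expresses itself and what mutual-information and CSP analyses
  assume. Preferred classes are assigned cyclically.
* **EOG channels**: each EOG channel receives `leakage x` one informative
  source's oscillation (the *same* signal instance, so EEG–EOG dependence
  is real), large Hann-windowed low-frequency (< 4 Hz) ocular transients
  at `artifact_rate` per second with amplitude 5x the background SD, and
  its own independent background. The leakage model is a deliberately
  simple surrogate for volume conduction; no biophysical forward model is
  attempted.

Two presets mirror the public benchmarks exactly (trial counts, channel
counts, rates); two more define the desk-scale study conditions:

* `sim_config_planted()` — 9 EEG + 3 EOG channels, **4 classes**, 320
  trials of 2 s at 100 Hz, three planted EEG channels at modulation depth
  0.6, no leakage. Four classes with one channel per class (and a
  baseline class) make each planted channel *individually* necessary:
  with fewer classes the planted channels are mutually redundant, and a
  well-trained classifier can ignore one of them entirely — which is
  exactly what permutation importance would then (correctly) report.
  This redundancy trap is worth remembering when interpreting permutation
  scores on real montages.
* `sim_config_leakage()` — the same layout with leakage 0.6, one source
  per EOG channel, for the EOG-only classification experiment.

These sizes are chosen so the whole recovery study (10 seeds, four
methods, one network fit per seed) runs on a laptop CPU in about ten
minutes; they are stated here as the package's study conditions, and the
test suite runs them unchanged.

What the generator does *not* emulate: inter-subject variability,
non-stationarity within a session, EMG contamination, realistic electrode
geometry or correlated noise across channels. Passing the planted-recovery
tests therefore shows the estimators are correct and sensitive at
realistic SNR — not that they will rank channels correctly under every
real-world confound.

## Spectral estimation and filtering

`multitaper_psd()` averages periodograms over discrete prolate spheroidal
(Slepian) tapers, computed from the classical symmetric-tridiagonal
eigenproblem and cached per epoch length. The time–bandwidth product
defaults to 4 (7 tapers); the estimate is one-sided, in uV^2/Hz, over
0.1–40 Hz by default. The method is named for its variance reduction:
trial-averaged estimates of smooth 1/f-type spectra are what the
PSD-inspection figures in this literature show.

`bandpass_filter()` is a zero-phase (forward–backward) Hamming-window FIR
band-pass, order `3.3 * fs / low` rounded to even — the standard
window-design rule placing the transition width near the low edge. The
default 7–35 Hz band brackets the mu and beta rhythms and is applied
before CSP fitting. Zero-phase matters because CSP and band-power features
are phase-blind but alignment across channels must be preserved.

`zscore_normalize()` standardizes each channel with train-set statistics
only. Normalization is ON for network training (stabilizes optimization)
and OFF for CSP/MI, which operate on filtered raw amplitudes; both are
explicit in the call sites.

## The five importance methods

**Mutual information** (`mi_matrix()`): plug-in `I(X;Y) = H(X) + H(Y) -
H(X,Y)` on equal-width histograms (64 bins per variable, each over its own
range; log base 2), between every EOG–EEG channel pair over all
concatenated trial time series. This measures *channel–channel* shared
information — the argument that EOG electrodes record overlapping signal —
not channel–class relevance, which is why it sits outside the
planted-recovery scoreboard. The plug-in estimator's positive bias is
about `(bins-1)^2 / (2 N ln 2)`; at the sample sizes involved (>= 10^5)
it is negligible relative to the effects of interest.

**CSP patterns** (`csp_fit()`, `csp_importance()`): common spatial
patterns maximize the variance ratio `w'Sw / w'Rw` between two classes'
trace-normalized average covariances, solved as the generalized
eigenproblem `S w = lambda R w` by whitening-plus-symmetric-eigen.
Channel importance is read from the *patterns* `(W^-1)'` — how each
extracted source projects onto the electrodes — not the filters; the
per-channel score is the maximum absolute pattern coefficient over the
leading patterns. The defining equations are two-class; for multi-class
data the package fits one-vs-rest per class and pools all patterns
re-ranked by eigenvalue contrast `|lambda - 1|` (an assumption, stated as
such: the published analyses do not say how they handled 4 and 7 classes).
Shrinkage `reg * I` (default 1e-6 on trace-normalized covariances) guards
near-singular estimates.

**Permutation importance** (`permutation_importance()`): accuracy drop
when one channel's trials are permuted across the trial axis — waveforms
intact, trial-label pairing broken. Whole-trial permutation (rather than
within-trial shuffling) keeps the permuted channel physiologically
plausible, so the score isolates the *association* with labels rather than
punishing distribution shift. It is computed on the held-out split by
default, works with any classifier exposing `predict()`, and is averaged
over repeats (default 10).

**Attention gates** (`attention_importance()`): the channel-attention
front end pools each channel over time (average and max), passes both
pooled vectors through a shared bottleneck (`C -> ceiling(C/r) -> C`,
ReLU between, r = 4), sums the two paths and squashes them through a
sigmoid into per-channel gates in (0, 1) that multiply the input. After
training, the gate averaged over trials is the importance score. The
second bottleneck layer is zero-initialized so every gate starts exactly
at sigmoid(0) = 0.5 and moves only under consistent gradient pressure;
with a random start, gates of harmless channels drift with initialization
noise and the ranking partly reflects the draw rather than the data.
Because a gate reflects what one particular trained network relies on —
and two equally good networks can lean on different subsets of usable
channels — the recovery experiment scores channels by the gate averaged
over a small ensemble of short trainings (5 networks, 20 epochs each),
each on its own random split and initialization, on band-pass-filtered
input; the ensemble mean over runs is a markedly more stable importance
estimate than any single model's gates at this data scale.

**Random search** (`random_search()`): k channels drawn uniformly per
iteration (defaults 6 of C, 500 iterations), a classifier trained and
scored on each subset, the subset's accuracy shared as a weight by its
members, and each channel scored by its mean weight over occurrences.
The occurrence-*mean* (not sum) reading is the one consistent with
averaging; channels never drawn get `NA`, never a silent zero. The
`trainer` is a handle: the reduced-scale experiments use a band-power LDA
trainer (fast enough for hundreds of fits), and `make_micnn_trainer()`
wraps the network when fidelity matters more than wall-clock.

## The network

`micnn()` fits the compact classifier: three parallel 1D temporal
convolutions over the time axis (kernels 3/5/9, 32 filters each,
length-preserving zero padding — required for concatenation, though the
source description omits it) concatenated into 96 maps; ReLU then batch
normalization (in that stated order; a flag swaps to the conventional
BN-first); a depthwise convolution (kernel 25, padding 7, one filter per
map, no bias) shortening the time axis by 10; a depthwise-separable stage
(same depthwise shape plus a pointwise 1x1 mixing convolution, keeping 96
maps); batch norm, ELU, average pooling (default 8), dropout (default
0.5), flatten, and a single dense layer to the class logits. Optimization
is Adam (lr 0.001) with cross-entropy loss, 500 epochs and batch size 64
at full scale. The depthwise economy is the point: 96 x 25 = 2,400
weights where a full convolution of equal shape would need 96 x 96 x 25 =
230,400 — a factor of exactly the map count.

Held-out accuracy is recorded after every epoch and the reported
`peak_test_accuracy` is the maximum of that trace. This mirrors the
published protocol and is *model selection on the test set* — an
optimistic measure, labelled as such; the honest alternative (peak-pick on
a validation split) is a straightforward variant the evaluation grid
supports by passing an explicit `test` set.

All forward and backward passes are written out explicitly (grouped 1D
convolutions in C, everything else in R); the correctness oracle is a
finite-difference gradient check over every parameter group, kept in the
test suite. Reduced-scale defaults used throughout the tests (8 filters
per kernel, pooling 16, batch 16, lr 0.002, 50–70 epochs) exist purely to
fit CPU budgets; the full-scale defaults match the published protocol.

## Numerical and design choices worth knowing

* Rankings break score ties by ascending channel index — reports are
  deterministic.
* The histogram MI of a constant channel is 0 with a warning (single
  occupied bin), not an error; zero-variance channels *are* an error in
  z-scoring, named explicitly.
* `split_trials`, `micnn`, `random_search`, `permutation_importance` and
  the generator all take seeds; the evaluation grid derives split seeds as
  `seed + split_index`. Identical seeds give bit-identical traces and
  reports.
* Batch-norm running statistics use momentum 0.1; evaluation always uses
  running statistics, training always uses batch statistics.
* Training aborts with a diagnostic if the loss goes non-finite rather
  than silently returning garbage.
* The bundle format (`write_bundle`/`read_bundle`) is raw little-endian
  doubles plus a JSON sidecar; round trips are bit-exact, which the tests
  assert.

## Known limitations

The generator's planted effects are stationary within a trial; none of the
estimators is validated here against non-stationary or artifact-heavy
regimes beyond the injected ocular transients. The multi-class CSP
pooling is one defensible convention among several. Real-data
reproduction of the published per-subject accuracy tables requires
downloading the public recordings and long GPU training; the package
supports that path (`import_public_dataset()` plus the full-scale
defaults) but its desk-scale evidence is the planted-recovery suite, the
oracle equivalences, and the exact reproduction of the published summary
statistics.
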