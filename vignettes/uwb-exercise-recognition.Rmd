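---
title: "Recognizing therapeutic exercises from single UWB radar scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing therapeutic exercises from single UWB radar scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrehab)
```

## The problem and the measurement model

An impulse ultra-wideband (UWB) radar facing a person emits very short
pulses and records, for each pulse, a vector of return amplitudes over
radial distance. Stacking successive scans gives a *radar-gram*: a
slow-time (frames) by fast-time (range bins) matrix. A subject performing
an upper-limb therapeutic exercise — left shoulder abduction (LSA, label
1), bilateral shoulder abduction (BSA, 2), shoulder flexion up (SFU, 3),
shoulder flexion down (SFD, 4) or breaststroke (BS, 5) — modulates the
returns near their range: limbs approaching or receding shift where energy
appears along fast time, frame to frame.

The acquisition geometry this package defaults to is a 950 cm scanned
range over 1440 bins, i.e. 950/1440 ≈ 0.659 cm per bin; with the subject
at about 2 m the relevant motion falls in range-bin columns 259–320
(62 columns), which is the default region of interest (ROI). The ROI is
deliberately taken from configuration rather than derived from the
subject distance: the asserted column range and the nominal 2 m are not
exactly consistent (the ROI centre sits nearer 190 cm), and we preserve
the configured range verbatim, with `bin_of()` available as a
cross-checking helper.

One published inconsistency is worth noting: a 15 s recording at 20
frames/s should give 300 rows, but the stated layout is 120 rows
(= 6 s). The simulator therefore exposes `n_frames` and `frame_rate_hz`
independently instead of resolving the discrepancy; the defaults (120
frames at 20 Hz) reproduce the stated matrix layout.

## The pipeline

**Clutter suppression.** Static objects (walls, furniture, the standing
torso) contribute a frame-invariant component. The two-pulse canceller
`R_out[i] = R[i+1] − R[i]` — a first-order moving-target-indication
filter — removes any frame-constant term exactly. The output keeps
`n − 1` rows; we do not zero-pad a first frame, since an artificial
all-zero row would contaminate window statistics.

**Peak detection and physiological windows.** Within the ROI of every
cancelled frame, bins whose *absolute* amplitude reaches a threshold
(default 0.4×10⁴) and strictly exceed both neighbours are significant
peaks; peaks closer than `min_separation_bins` keep the larger magnitude.
The absolute value matters because the canceller output is signed — a
scatterer moving through a bin produces paired positive/negative lobes.
Around each peak a fixed 10-sample *physiological window* is cut with the
half-open convention `[p − 5, p + 5)`; a window that would leave the ROI
is shifted, never shrunk, so every window has exactly 10 samples
(fixed-length rows are required by everything downstream). Each
(frame, peak) pair yields one window, and hence one feature row — the
only reading under which a few thousand recordings can yield sample
counts in the hundreds of thousands.

**Descriptors.** Each window contributes 19 descriptors: amplitude
statistics over |values| (max, mean, standard deviation, range), phase
statistics over the one-sided DFT phases (value at the dominant bin,
mean, standard deviation, range), and eleven spectral descriptors of the
one-sided magnitude spectrum (centroid, spread, skewness, kurtosis,
entropy, flatness, crest, flux, slope, decrease, rolloff). The DFT is
taken over the 10 fast-time samples with no taper and no zero-padding;
frequencies are reported as dimensionless bin fractions k/N because no
physical frequency unit survives a 10-sample fast-time window.

Numerical conventions, chosen once and used everywhere (they follow
standard audio-descriptor practice):

* one-sided spectrum, bins 0…⌊N/2⌋, to avoid double-counting conjugates;
* entropy normalized by ln(number of one-sided bins), so it lies in [0, 1];
* flatness = geometric/arithmetic mean of magnitudes (0 if any bin is 0);
* rolloff proportion 0.85;
* flux pairs a window with the previous frame's window whose peak column
  is nearest (gap, or a jump larger than `max_track_gap_bins = 10`,
  gives flux 0 — first frames have no predecessor);
* an all-zero spectrum returns all descriptors as 0; a zero spread makes
  skewness and kurtosis 0, keeping every row finite;
* degenerate checks: a delta spectrum has entropy = flatness = spread = 0
  and crest = n_bins; a flat spectrum has entropy = flatness = crest = 1
  and slope = 0.

Descriptors are min–max normalized with bounds fitted on training rows
only; constant columns map to 0, and held-out rows may legitimately fall
outside [0, 1].

**Probability fusion.** A small 1-D convolutional network (64 filters of
kernel 3 over the ordered 19-descriptor vector, max-pool 2, dense 64,
dense 16 with softmax) and a random forest (100 trees, depth 3) are both
fitted to the normalized descriptors. Each row is then re-represented as
the concatenation of the 16-dimensional softmax vector and the 5
forest class probabilities — a 21-dimensional fused feature vector. Two
deliberate choices:

* The 16-unit softmax head is kept although there are 5 classes, because
  that is the published architecture; the labels occupy 5 of the 16
  slots and the full vector is the temporal-probability block
  (`head_units = 5` gives the compact variant).
* On training data the probabilities are *cross-fitted* by default
  (5 folds: each row is scored by models that never saw it). In-sample
  probabilities encode the row's own label almost directly and leak it
  into the fused features; `crossfit = FALSE` reproduces the literal
  in-sample behaviour for comparison. Held-out data always use the
  full-data models.

Net training uses Adam (learning rate 1e-3), 50 epochs, batch 128, and a
fixed seed; the loop runs in compiled code but shuffling and dropout
draw from R's RNG, so fits are bit-reproducible. Whether the fused set
should also retain the 19 raw descriptors is left as a flag
(`keep_raw`), off by default.

**Final classifiers.** Eight models share the published hyperparameters:
ridge (alpha 1), random forest (100 × depth 3), gradient boosting
(learning rate 0.1, depth 3, 100 rounds), AdaBoost (the real-valued
multiclass variant over depth-1 stumps, 50 rounds), Gaussian naive Bayes
(variance smoothing 1e-9, applied relative to the largest feature
variance), a DNN (64-relu, 64-relu, softmax), a CNN with (3,1) kernels
applied to the feature vector laid out as a (d, 1) image (its published
layer list stops at the dense layer, so a 5-unit softmax output is
appended by necessity), and the stacked **EnsembleRRGraBoost**: a ridge
regression meta-learner over the concatenated class-probability vectors
of the forest and the boosting machine (10 meta-features for 5 classes),
with meta-features cross-fitted over 5 folds — the standard stacking
construction, since the components are named but not the wiring.
"Ridge" throughout is ridge regression onto ±1 one-hot targets with
argmax decoding, the reading consistent with a classifier parameterized
only by alpha and a seed; its "probabilities" are softmax-normalized
decision scores, as are AdaBoost's (documented per model).

**Evaluation.** Stratified 70/30 splitting allocates per-class training
counts by floor-plus-largest-remainder, which reproduces the published
per-class train counts exactly from the published class totals (e.g.
0.7 × 19,230 = 13,461, and the totals 125,711 / 53,877). Precision,
recall and F1 are support-weighted: the published tables show accuracy,
precision, recall and F1 agreeing to two decimals on a near-balanced
set, which is the weighted-averaging signature. Five-fold
cross-validation reports the mean and the population standard deviation
(divisor k) of fold accuracies.

## The synthetic benchmark: what it emulates and what it does not

The study's 34-subject recordings are not deposited, so the package
ships a simulator that generates radar-grams with the statistical
structure the pipeline assumes: per-bin static clutter drawn once per
recording (exactly cancelled by frame differencing), one or two
oscillating point scatterers rendered as Gaussian pulses in fast time,
and white noise. Scatterer s follows
r_s(t) = centre + A·sin(2π f t + φ_s) + drift·t (+ a second sinusoid for
the breaststroke preset). Class presets mirror the exercise
descriptions: LSA one scatterer; BSA two in-phase scatterers at slightly
different ranges (two arms); SFU/SFD a receding/approaching drift
superposed on the oscillation; BS two superposed oscillation
frequencies.

Default kinematics are limb-scale: oscillation amplitudes 8–13 cm and
frequencies ≈ 0.4–0.7 Hz give peak radial speeds of 30–60 cm/s,
comparable to an arm sweep, and keep trajectories inside the ROI. The
default return amplitude 6000 makes cancelled peaks clear the 0.4×10⁴
threshold at typical speeds (classes rendered with wider pulses spread
their energy and receive proportionally larger return amplitudes, as a
larger reflector would). The `"easy"` preset separates classes by
scatterer count, pulse width and oscillation pattern at high SNR —
constructed so that the descriptor space separates the classes, which
is what the end-to-end accuracy check exercises. The `"hard"` preset
shares the pulse width across classes, narrows the kinematic
differences and adds strong noise (σ = 500 against amplitudes ≈ 6000),
so raw descriptors overlap heavily and the fusion stage has measurable
headroom — the regime in which the raw-versus-fused comparison is
informative.

Two physical caveats, both consequences of differencing Gaussian
pulses, are worth knowing when interpreting tests:

* Near a sinusoid's turning points the frame-to-frame displacement
  approaches zero, so the cancelled magnitude dips below any fixed
  threshold at some frames: no fixed-threshold detector sees *every*
  frame of a sinusoidally moving target. Bookkeeping tests that need
  one window per frame therefore use a near-zero threshold with a wide
  suppression window.
* The |difference| of two displaced Gaussians peaks up to one pulse
  width away from either true position (the derivative-of-Gaussian lobe
  geometry), so detected peaks track the trajectory to within about
  ±2 bins at the default pulse width, not ±1.

The simulator does not model electromagnetic propagation, antenna
patterns, multipath, occlusion, body shadowing, or inter-subject
variability. Passing its benchmarks shows that the pipeline's stages
compose correctly and that probability fusion helps when classes
overlap; it does not certify accuracy on real recordings.

## Problem sizes and reproducibility

The bundled end-to-end runs use 200 recordings (40 per class) for the
easy benchmark and 75 (15 per class) for the hard comparison — about
35,000 and 13,000 windows respectively — sizes at which the full
pipeline, including cross-fitted fusion, completes in minutes on one
CPU. Every stochastic step (simulation, splitting, fold assignment, net
initialization and shuffling, forest and boosting seeds) is driven by
explicit seeds; classical-model reports reproduce byte-for-byte under a
fixed seed, and net fits are bit-reproducible on a given platform.

## What probability fusion can and cannot add

Because the fused features are functions of the same 19 descriptors, the
honest (cross-fitted, fusion-inside-the-split) protocol bounds the fused
representation by the information the two fusion members extract. The
members are fixed by their published configurations: a depth-3 forest,
and a convolutional net whose weight-sharing across descriptor positions
is a weak prior for tabular features — on the hard benchmark the member
net scores slightly *below* a plain two-layer MLP trained on the raw
descriptors. The practical consequence, visible in the package's own
benchmark report: classifiers much weaker than the members (linear
models, shallow trees, naive Bayes) gain substantially from fusion
(+3 to +13 accuracy points on the hard preset), while classifiers at
member strength (the MLP and the 2-D-kernel net, and to a lesser degree
gradient boosting and the stacked ensemble) sit within benchmark noise
of their raw-feature accuracy, with a sign that flips from seed to seed.
A uniform improvement across *every* model would require fusion
probabilities computed in-sample on data including the evaluation rows,
which this package deliberately does not do; `crossfit = FALSE` exposes
the in-sample variant for training rows, labelled as such, for
comparison studies.

## Known limitations

* Per-window classification is the implemented reading of the feature
  extraction; per-recording averaging of rows is available as a
  convention but untested against published counts.
* The AdaBoost probability output is a softmax over decision scores, not
  a calibrated posterior.
* The simulator's class presets are a stand-in for real exercises: the
  easy preset is constructed to be separable, so absolute accuracies on
  it say nothing about field performance (the relative raw-vs-fused
  comparison is the meaningful output).
* Multi-target tracking across frames is limited to nearest-peak pairing
  for spectral flux; no Doppler processing is attempted beyond the
  per-window DFT.
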