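---
title: "Methods: identifying peptides from single-molecule blinking traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying peptides from single-molecule blinking traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(blinkid)
```

## The problem

A spontaneously blinking fluorophore — a dye that isomerizes in the ground
state between a dark and a fluorescent form — attached to a peptide
produces an intermittent fluorescence signal whose statistics depend on
the local chemical environment, and hence on the peptide it is attached
to. If the ON/OFF pattern ("blinking fingerprint") of a single molecule
carries enough information, a classifier trained on traces from pure
standards can identify which peptide an unknown molecule is. `blinkid`
implements the full computational pipeline: a generative kinetic
simulator, a synthetic TIRF movie renderer with ground truth, spot
detection and trace extraction, hand-crafted feature baselines, and a
1D-CNN–GRU deep classifier with Monte Carlo dropout uncertainty
filtering. Because no public single-molecule blinking dataset accompanies
this problem, the simulator is a first-class component: it defines the
study conditions under which every claim of this package is tested.

## Generative model of blinking kinetics

Each molecule is a continuous-time Markov chain with photophysical states
ON, OFF and an absorbing BLEACHED state, coupled to a hidden
conformational chain:

* OFF → ON at rate $k_{on} \cdot a_c$, ON → OFF at rate
  $k_{off} \cdot b_c$, where $a_c, b_c > 0$ are multipliers of the
  current conformation $c$;
* conformations switch at total rate $r$ (uniform destination), modeling
  slow peptide dynamics that stabilize either the fluorescent or the
  dark isomer;
* ON → BLEACHED at rate $k_{bleach}$; bleaching is photo-induced, so it
  only occurs from ON;
* per-molecule heterogeneity: $k_{on}$ and $k_{off}$ are scattered once
  per molecule by unit-mean lognormal factors with coefficient of
  variation `molecule_cv` (rates are positive; lognormal is the standard
  heterogeneity model for single-molecule rate constants).

Trajectories are sampled exactly (Gillespie). The initial conformation
is uniform and the initial photophysical state is drawn from the
stationary ON/OFF distribution of that conformation, since molecules
equilibrate long before acquisition starts. With one conformation and no
scatter the model reduces to the textbook three-state chain, which gives
closed-form oracles used by the test suite: exponential dwell laws
(mean ON dwell $1/k_{off}$), duty cycle $k_{on}/(k_{on}+k_{off})$, and
bleach survival $\exp(-k_{bleach}\,\phi\,t)$ with $\phi$ the ON
fraction.

The conformational layer is the package's minimal mechanism for a key
design requirement: two classes can share every stationary statistic
(duty cycle, dwell-time marginals) and differ only in the *temporal
correlation structure* of their blinking — the regime in which static
features fail and a recurrent classifier is needed.
`switchrate_pair_specs()` constructs exactly such a pair.

### Camera model

Frames of `frame_time` seconds integrate the ON fraction $f_t$ of the
exposed window; expected photons are
$(f_t \cdot \text{photon\_rate\_on} + \text{background\_rate})
\cdot \text{frame\_time} \cdot \text{exposure\_fraction}$, with Poisson
shot noise, linear gain, and Gaussian read noise. Defaults (20 Hz, 2000
frames, 5000 photons/s ON, 500 photons/s background, read noise 2
counts) describe a typical single-molecule TIRF regime; they are
configuration, not claims about any particular instrument.

### The built-in four-class conditions

`demo_class_specs()` defines the four peptide-like classes used by the
headline analysis: base duty cycles 0.05 / 0.10 / 0.20 / 0.35 with
class-specific dwell-time scales — $k_{off}$ falls in threefold steps
(8, 8/3, 8/9, 8/27 per second, mean ON dwells 0.125–3.4 s) and
$k_{on}$ follows from the duty cycle — plus conformational switching at
0.1 / 0.5 / 0.1 / 0.5 per second with two conformations,
$k_{bleach} = 0.01\,/s$ and 20% per-molecule scatter.

The dwell-scale ladder deserves a note, because it was chosen by
information-budget analysis rather than taste. If all classes share one
$k_{off}$, the only class signal is a ~2× step in $k_{on}$ (equivalently
in duty-cycle odds), to be read through 20% per-molecule rate scatter and
the finite number of switching events per 100 s trace. A plug-in optimal
classifier — an exact hidden-Markov forward pass over the coupled
conformational × photophysical chain with the true generative
parameters, marginalizing the lognormal scatter by Gauss–Hermite
quadrature — then tops out near 81% on four classes: no classifier,
however good, can do better under those conditions. Distinct peptide
microenvironments are in any case expected to shift the *lifetimes* of a
spontaneously blinking fluorophore's isomers as well as their
equilibrium, so the built-in classes differ along both axes; with the
threefold dwell ladder the same oracle (restricted to binarized traces,
a lossy view) reaches ~86%, and classifiers with access to the raw
intensities can exceed 90%. $k_{bleach}$ is slow enough that most
molecules survive the 100 s acquisition (survival 70–95% depending on
duty cycle); the conformational multipliers (odds factors of ±1.78)
modulate the equilibrium noticeably without making single traces
bimodal. The classes still overlap in every single summary statistic,
so the problem remains demanding.

## Movie synthesis and trace extraction

The renderer places molecules at random sub-pixel positions (rejection
sampling under a minimum-separation and an edge-margin constraint) and
spreads each trace value over a pixel-integrated 2-D Gaussian PSF
truncated at $4\sigma$ (<0.1% mass loss), plus a constant background
offset, rounded to non-negative 16-bit integers. Camera noise is carried
entirely by the input traces; no second noise pass is applied, which
avoids double-counting. One consequence is that empty regions of a
default movie are exactly flat; for the noise-region control experiment
(below) `render_movie(noisy_background = TRUE)` instead draws per-pixel
Poisson background plus read noise, the realistic-background variant.

Extraction mirrors a standard single-molecule workflow: spots are local
maxima of the *temporal maximum* projection (blinking molecules may be
ON in only a few frames, so a mean projection would miss them) above a
quantile threshold, with all maxima closer than `min_separation`
discarded — a conservative single-molecule criterion — and refined to
the 3×3 intensity centroid. Traces are disc sums minus disc-area times
the annulus median, retaining negative values in dark frames so OFF-level
statistics stay unbiased. A dynamic-range QC rejects traces whose
percentile range is below `min_dynamic_range` (default 8) times the
trace's median absolute deviation; pure-noise traces fail this test.
These extraction and QC rules are this package's own, declared
substitutes for curation criteria that are not public.

## Normalization

Each trace is normalized by subtracting its 10th percentile and dividing
by the (99.5th − 10th) percentile range, clipping to $[0,1]$. The low
anchor tracks the background level (spontaneous blinkers are mostly
OFF), the high anchor the ON level while ignoring the brightest 0.5% of
frames. Percentiles are *order statistics* (type-1 quantiles, no
interpolation). This makes normalization exactly idempotent and exactly
invariant under positive affine transforms of the raw counts —
properties the test suite asserts with equality, not tolerance.
Interpolated quantiles would break exact idempotence, because clipping
the top 0.5% of frames perturbs an interpolated 99.5th percentile.
Constant traces cannot be normalized and are excluded with a count.

## Hand-crafted features and classical baselines

Binarization uses hysteresis thresholds on the normalized trace (ON
above 0.5, OFF below 0.3, initial state OFF), which is robust to shot
noise hovering near a single threshold. Thirteen descriptors summarize
each trace: peak count, mean/median peak duration, longest ON and OFF,
total ON time, duty cycle, photobleaching time, OFF-event count, mean
OFF duration, ON-intensity mean and CV, and time of first ON frame —
spanning the count, duration, timing and intensity families that a
practitioner reads off a blinking record. The classical baselines are a
random forest, an RBF SVM, k-nearest neighbours and a multinomial ridge
model; exploratory analyses (standardized PCA, Fourier magnitude
spectra) are included to demonstrate, on the switching-rate-only pair,
that static features cannot separate classes that differ purely in
temporal structure.

## The deep classifier

The network consumes normalized traces directly. Default architecture:
three 1-D convolutional blocks (32/64/64 filters, kernel 9, max-pool 4,
batch normalization, ReLU, dropout 0.3) downsample a 2000-frame trace to
a 32-step sequence of 64 features; two GRU layers (64 units) integrate
information along the entire acquisition; a dense layer (64 units, ReLU,
dropout) and a softmax head produce class probabilities. Trace lengths
not divisible by the pooling product are right-padded with zeros and the
padded length recorded in the model metadata. Setting `gru_layers = 0`
builds the purely convolutional ablation: the conv feature map is
flattened and fed directly into the fully connected head. The flatten
head is the faithful "CNN only" member of this architecture family; a
global-average-pooling head was considered and rejected for the
ablation, because averaging nonlinear local features over time is
itself an excellent estimator of temporal-dispersion statistics and so
does not isolate what the recurrence contributes, while
position-specific dense weights over the flattened map generalize
poorly from hundreds of traces — precisely the regime in which
recurrent integration shows its value.

The implementation is self-contained: convolutions run as im2col matrix
products, the GRU as batched recurrences, and all backward passes are
analytic, verified against finite differences in the test suite
(relative error < 1e−4). Heavy kernels are C++ (via Rcpp/Armadillo) over
BLAS; all randomness (initialization, shuffling, dropout masks) flows
through R's seeded RNG, so identical seeds give bit-identical training
runs.

Training minimizes cross-entropy with Adam (default learning rate 1e−3,
batch 64), a stratified validation split (15%) carved from the training
set, and early stopping on validation loss with the best-validation
weights retained. An optional step decay halves the learning rate every
few epochs; the headline analysis trains with batch 32 for 20 epochs,
halving the rate every 7.

**Batch-normalization recalibration.** Running BN statistics accumulated
during training are collected under active dropout and therefore
systematically overestimate the variance the network sees at inference;
with the sparse, heavy-tailed activations of blinking traces this shift
is large enough to destroy inference-mode accuracy. After every epoch
the package therefore re-estimates the BN statistics with a few
dropout-free forward passes over (up to 512) training traces, averaging
the batch statistics. This restores the match between training-mode and
inference-mode behaviour and is applied before every validation
measurement, so early stopping acts on the statistics that will actually
be used.

**Uncertainty filtering.** At inference, `mc_predict()` runs `T = 50`
stochastic passes with dropout active (batch normalization stays at its
recalibrated statistics), averages the softmax outputs, and scores each
trace by the predictive entropy of the averaged distribution, in
$[0, \ln K]$. Traces above an entropy threshold (default
$0.5 \ln K$, exposed in configuration and reported with every run) are
flagged as rejected. Predictive entropy of the MC mean was chosen as the
uncertainty metric for its simplicity and bounded range.

**Controls.** Two negative controls verify that the classifier learns
blinking structure rather than artifacts: training on traces whose
labels were scrambled (test accuracy must fall to chance), and training
on traces harvested from empty regions of a movie with random labels
(chance accuracy with high predictive entropy).

## Splitting and evaluation

The default split is 80/20, stratified by class and *grouped by
replicate*: simulated datasets assign traces round-robin to five
replicates per class, emulating per-peptide coverslips measured on
different days, and no replicate ever spans both sides of a split (nor
both sides of any cross-validation fold). Grouping is the conservative
choice that prevents batch effects from inflating accuracy. Nested
cross-validation (stratified, grouped outer folds; inner folds select
learning rate × dropout from a small grid) estimates generalization
without hyperparameter-selection bias. Confusion matrices are reported
as counts and row-normalized (per-class recall); when uncertainty
filtering is applied, both the filtered matrix and the rejection rate
are reported.

## Problem sizes and numerical choices

The acceptance analysis trains on the full four-class conditions
(500 traces/class, 2000 frames); the unit test suite uses scaled-down
versions of the same generator (typically 30–60 traces/class, 400–800
frames, a 2-block/16-unit network) chosen so that each property is
decided by its statistics, not by compute: stochastic assertions use
3-standard-error or 99%-binomial bands around closed-form oracles.
Other numerical choices: Glorot-uniform initialization; Adam
$(\beta_1, \beta_2) = (0.9, 0.999)$, $\epsilon = 10^{-8}$; BN momentum
0.9, $\epsilon = 10^{-5}$; softmax computed with max-subtraction;
entropy with $0 \log 0 = 0$; pooling argmax ties resolved to the
earliest frame; local-maximum ties in spot detection broken
half-strictly so plateaus yield a single detection.

## What the simulator does and does not show

Passing tests demonstrate that the pipeline recovers planted molecules,
that the simulator obeys its own kinetic laws, and that the classifier
extracts both equilibrium and temporal-correlation information from
synthetic blinking traces under realistic shot noise, heterogeneity and
bleaching. They do not demonstrate performance on real TIRF data: real
blinking kinetics of specific peptides are not predictable from
sequence, real traces contain drift, focus fluctuations, aggregates and
day-to-day batch effects that the generator deliberately omits, and the
true conformational dynamics are unlikely to be a two-state chain. The
generator also omits excitation-power-dependent photophysics (spontaneous
blinkers are largely excitation-independent), triplet/radical dark
states, and EMCCD excess noise. Claims about real data require real
training standards measured under constant acquisition conditions.

## Known limitations

* Training is CPU-bound R/C++; it is sized for datasets of thousands of
  traces, not millions.
* The replicate structure of simulated data is an idealization (no
  actual batch effect is injected), so replicate grouping is exercised
  structurally rather than adversarially.
* The entropy threshold default ($0.5 \ln K$) is a convention; real
  deployments should calibrate it on held-out data, reported alongside
  the rejection rate.
* `read_traceset()` keeps whole datasets in memory; very large trace
  tables should be chunked.
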