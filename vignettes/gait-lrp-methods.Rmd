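---
title: "Explainable classification of running-gait waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable classification of running-gait waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Runners who accumulate high weekly mileage and runners who train little
show different overuse-injury profiles, and their stance-phase gait
waveforms — joint angles and joint moments of the ankle, knee and hip in
the sagittal, frontal and transverse planes — carry enough information for
a classifier to tell the two groups apart. A deep classifier alone,
however, is a black box: it reports *that* two gait patterns differ, not
*where* in the stance phase or *in which* trajectory. This package couples
a fully-connected tanh network with Layer-wise Relevance Propagation (LRP)
so that every classification decision can be decomposed into per-trajectory,
per-timepoint contributions, and it ships a synthetic cohort generator with
known ground truth so the whole chain can be validated end to end.

The data model is hierarchical: subjects (each labelled higher- or
lower-mileage; the higher-mileage class is coded positive) contribute
several trials; each trial consists of 18 trajectories (3 joints x 3
anatomical planes x angle/moment), each time-normalized to 100 stance
points. The reference design is 40 subjects per class with 10 trials each,
so the kinematic and kinetic feature matrices are 800 x 900 and the
combined matrix is 800 x 1800.

## Signal preparation

The preprocessing functions implement the standard biomechanics chain for
force-plate and motion-capture series:

* **Stance detection.** Stance runs from the first vertical GRF sample
  above 10 N to the first subsequent sample at or below it. The same
  threshold is used at toe-off as at contact: a literal "force equals
  zero" criterion is not realizable on noisy force-plate data, and
  threshold symmetry is the conventional reading.
* **Filtering.** A fourth-order zero-phase Butterworth low-pass filter
  (10 Hz for kinematics, 20 Hz for kinetics at typical capture rates),
  realized as a forward-backward pass of a second-order design — the
  standard interpretation of "fourth-order zero-phase" in gait analysis;
  a forward-backward fourth-order pass (net eighth order) is available via
  the `order` argument. Edges use odd-reflection padding and steady-state
  initial conditions, so a constant series passes through bit-exactly.
* **Time normalization.** Resampling onto 100 equally spaced stance points
  by natural cubic spline (waveforms are smooth; linear interpolation is
  available), endpoints preserved.
* **Hip joint centers.** The regression `RHJC = (0.36 d, -0.19 d, -0.30 d)`
  on the inter-ASIS distance `d`, with the left center mirrored in the
  first coordinate.

## The synthetic cohort generator

Real gait recordings of this kind are not publicly deposited, so the
package treats the simulator as a first-class module. Each trajectory of
each trial is built as

> template + subject offset + trial noise (+ class effect).

The *template* is a fixed low-order sinusoid mixture per trajectory —
deterministic, seed-independent, loosely shaped like published
stance-phase curves. The *subject offset* is one smooth random curve per
subject and trajectory, shared by all of that subject's trials; it is what
makes trials within a subject correlated and a subject-grouped train/test
split mandatory. The *trial noise* is a fresh smooth curve per trial. Both
random components are Gaussian processes realized by convolving white
noise with a raised-cosine kernel (default half-width 10 timepoints,
normalized so the stated sd is the marginal sd): gait curves are smooth,
and the relevance-smoothing step downstream assumes temporally correlated
inputs. *Class effects* are mean offsets (boxcar or raised-cosine bumps)
added to named trajectories inside half-open timepoint windows for the
positive class only — the generator's ground truth for relevance-recovery
experiments.

Units are abstract waveform units; the generator makes no attempt to match
physiological magnitudes, because only relative structure matters for
classification and attribution. Default noise scales are subject sd 0.5
and trial sd 0.25, reflecting that between-subject variability dominates
within-subject variability in real gait data. What the simulator does
*not* emulate: biomechanically valid curve shapes, marker- or GRF-level
measurement processes, heteroscedastic or phase-jittered variability, and
class differences in variance rather than mean. Passing recovery tests
therefore demonstrate that the pipeline attributes mean differences to the
right place under realistic smoothness and hierarchy — not that it would
rank real anatomical structures the way any particular study does.

### Desk-scale study conditions

Two simulated scenarios are exercised routinely (tests and the acceptance
script):

* **Relevance recovery** — 16 + 16 subjects x 10 trials, one boxcar effect
  on the knee transverse (internal-external rotation) angle over 10-35% of
  stance, amplitude 0.75 = 3x the trial noise sd, subject sd 0.05, split
  12 train / 4 test subjects per class (16 subjects cannot be split 80/20
  into whole subjects, so the nearest grouped split is used). A reduced
  3 x 64 network is trained for up to 60 epochs.
* **Combined-input comparison** — the full 40 + 40 x 10 design with the
  reference 32/8 grouped split, independent effects of amplitude 0.5 on
  one kinematic and one kinetic trajectory, and the same reduced network
  per input scope (kinematics / kinetics / combined).

The small between-subject sd in these scenarios is deliberate. With only
12-32 training subjects and 900-1800 features, the between-subject offset
curves act as a high-dimensional nuisance that no classifier can average
away — an information limit of the subject-grouped design, not of any
particular learner: every held-out subject carries its own offset curve
inside the injected window too, so per-trial accuracy is bounded well
below 100% once the subject sd approaches the effect amplitude at this
cohort size. Scaling the subject variability down makes the injected
effect the dominant between-subject structure, which is the regime the
full-size reference design (more subjects, strong real class differences)
occupies. Problem sizes were chosen so each trained network takes seconds
on a single CPU.

## The classifier

The network is a plain fully-connected stack: input layer (900 or 1800
units), hidden layers computing `z = W'x + b` followed by
`tanh(z) = (e^z - e^-z)/(e^z + e^-z)`, and a 2-unit linear output layer
whose raw scores `f(x)` feed both the softmax (for probabilities and the
cross-entropy loss) and relevance propagation (which consumes pre-softmax
scores). The reference architecture is 10 hidden layers of twice the input
width; batch size 25 and an epoch cap of 3000 are the reference training
protocol. Because the loss, optimizer, learning rate and initialization
are not part of that protocol, the package fixes conventional choices and
records them in the training log: softmax cross-entropy, Adam (optionally
with decoupled weight decay), uniform fan-in-scaled initialization, and
early stopping on a training-loss plateau below the epoch cap. Training is
bit-deterministic given the config seed, which drives both initialization
and batch shuffling. Hard labels break score ties toward the negative
class.

Inputs are standardized per feature on training-set statistics before
fitting (switchable off). The reference protocol states no input scaling,
but tanh units saturate on raw degree and newton-metre scales; this is
recorded as a deviation. Note one side effect relevant to simulations:
standardization divides each feature by its total sd *including* the
between-class separation, so the standardized effect size of a
discriminative feature saturates as the raw amplitude grows.

## Layer-wise relevance propagation

LRP decomposes a prediction `f(x)` into per-input relevances by a
conservative backward pass. The selected output neuron (by default the
predicted class, which equals the true class on the correctly classified
rows that are explained) is seeded with its pre-softmax score. At each
layer, neuron `j` sends the message

    R_{i<-j} = z_ij / z_j * R_j,   z_ij = w_ij x_i,  z_j = sum_i z_ij + b_j

to each lower neuron `i`, and a lower neuron's relevance is the sum of its
incoming messages. The tanh nonlinearity is relevance-transparent:
redistribution uses only the linear pre-activations, the standard z-rule
for tanh stacks. Three properties pin the implementation down and are
enforced in tests:

* **Conservation.** With zero biases the layer sums are all equal to
  `f(x)`; on a single linear layer the decomposition is exactly
  `w_i x_i`.
* **Bias absorption.** With biases, layer `l` retains
  `R_j (1 - b_j / z_j)` summed over `j`; the per-layer deficit
  `sum_j R_j b_j / z_j` is audited message-by-message. Bias relevance is
  absorbed, not redistributed (an option exists to spread it uniformly).
* **Stabilization.** The raw rule divides by `z_j`; the package adds
  `epsilon * sign(z_j)` with `epsilon` expressed relative to the layer's
  largest `|z|` (default 1e-6). With `epsilon = 0` the implementation
  refuses to divide relevance by an exactly-zero pre-activation. A unit
  with `z_j = 0` carries no relevance itself (tanh(0) = 0), so the
  stabilizer matters for near-zero denominators, where the raw rule can
  amplify relevance without bound.

Relevance is computed for correctly classified rows only — an explanation
of a wrong decision explains the wrong thing. By default the test split is
explained; the training split or all rows can be selected, since the
reference protocol does not state which rows fed its maps.

## From raw relevance to contribution maps

Raw per-sample relevance is signed and scaled by each sample's own output
magnitude. The post-processing pipeline, in this order: (1) divide each
sample's vector by its own maximum absolute value (signed maxima can be
negative and would flip patterns); (2) average across samples;
(3) rectify — the map answers "where is relevant information", not "in
which direction"; (4) smooth along time within each trajectory with the
kernel (0.25, 0.5, 0.25), repeated three times, approximating a Gaussian;
(5) rescale to [0, 1]. Rectification happens after averaging (a
pre-averaging option exists). Smoothing never crosses trajectory
boundaries — the 18 curves are independent measurements — and endpoint
weights are renormalized over the in-range kernel support, so interior
mass is conserved exactly and no relevance leaks between body parts.

From the processed map the package derives the top-k variables (default
k = 200, ranked by score with ties broken in canonical feature order; the
minimum score of the set is reported) and contribution percentages over
four partitions: joints, planes, the 18 trajectories, and stance windows
(default early 1-47% vs late 48-100% of stance; timepoints are 0-99
internally and 1-100% externally). Percentages are computed after the full
processing pipeline, including the 0-1 rescale, and each partition sums to
100.

## Evaluation

The metric suite implements the standard confusion-matrix formulas
literally: accuracy, sensitivity/recall, specificity, precision, F1
(harmonic mean of precision and recall), TPR/FPR, MCC (undefined marginals
yield `NA` with a warning, never a silent 0), and *two* AUCs reported side
by side: the closed form `(TPR - FPR + 1)/2` of a single operating point —
algebraically `(sensitivity + specificity)/2` — and the trapezoidal area
under the full ROC staircase swept over unique score thresholds (equal to
the Mann-Whitney pair-counting estimate). The two differ whenever the ROC
is informative beyond one operating point, and conflating them is a common
source of inconsistent reported values, which is why both are labelled
explicitly. ROC scores default to the softmax probability of the positive
class.

## Numerical choices and degenerate inputs

* Zero-variance features standardize to 0 with a warning (unit scale), not
  an error.
* An all-zero relevance collection cannot be rescaled and raises an error,
  as does an empty set of correctly classified rows.
* Score ties in `top_k` and class-score ties in prediction resolve
  deterministically (canonical order; negative class).
* The split requires whole subjects per side at the 80/20 class ratio and
  errors otherwise rather than silently rounding.
* All randomness (cohort generation, splitting, initialization, batch
  shuffling) flows from explicit integer seeds; the experiment driver
  derives stage seeds from one master seed.

## Known limitations

The simulator's mean-offset effects are the easiest realistic target for
attribution; effects expressed in variance, timing jitter or
cross-trajectory coupling are untested. LRP here covers the z-rule for
fully-connected tanh stacks only — no alpha/beta rule, deep Taylor, or
convolutional architectures. The full-size 10 x 1800 architecture is
supported but impractical to train routinely on one CPU; all shipped
experiments use reduced networks, and conclusions about the full
architecture's behavior are extrapolations. Real-data percentages (which
trajectory contributes how much) depend on data this package cannot ship;
only the computations that produce such tables are validated.
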