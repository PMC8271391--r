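---
title: "Virtual IMU simulation and neural-network gait regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual IMU simulation and neural-network gait regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

Optical motion capture is the laboratory gold standard for gait analysis,
but it does not travel. Inertial measurement units (IMUs) do, and a
regression model that maps the raw signals of a few body-worn sensors to
three-dimensional joint angles and joint moments would carry laboratory
quality analysis into the field. Training such a model needs paired data —
IMU signals together with reference joint curves — and the coverage
problem is acute: a network trained on one sensor-to-segment mounting
generalises poorly to another. `imugait` implements the full pipeline that
addresses this with *virtual* inertial sensors: segment kinematics (from
motion capture, or here from a parametric gait generator) are converted
into exact accelerometer and gyroscope signals at arbitrary sensor
placements, multiplying a sparse measured dataset into a placement-diverse
training corpus. Three network families — a multilayer perceptron (MLP),
a long short-term memory network (LSTM) and a convolutional network (CNN)
on image-encoded signals — are trained on the same data and compared under
leave-one-subject-out (LOSO) validation.

## Rigid-body virtual sensors

A segment pose is a uniformly sampled sequence of unit quaternions
$q(t)$ (body to global, Hamilton convention, scalar first) and origins
$p(t)$ in metres. Quaternion series are hemisphere-corrected on
construction so that consecutive frames have non-negative dot products;
single rotations are canonicalised to $w \ge 0$.

The gyroscope signal is the body-frame angular velocity obtained from the
quaternion derivative,

$$\omega(t) = 2\,\mathrm{vec}\!\left(q^*(t) \otimes \dot q(t)\right),$$

with $\dot q$ from central differences and second-order one-sided stencils
at the endpoints. The accelerometer reports specific force,

$$f(t) = R(q(t))^{\mathsf T}\left(\ddot p(t) - g\right),
\qquad g = (0, 0, -9.81)\ \mathrm{m\,s^{-2}},$$

with $\ddot p$ from second-order central differences. Including gravity is
a deliberate convention: it is what physical accelerometers measure (a
static, level sensor reads $+9.81\ \mathrm{m\,s^{-2}}$ on its vertical
axis, a free-falling one reads zero), and it is required when fitting
placements against measured data. Both differentiation stencils are
second-order accurate; the test suite verifies the $\sim 4\times$ error
reduction when the sampling interval is halved, and checks the gyroscope
against an independent oracle built from rotation-matrix finite
differences. Spline differentiation was considered and rejected: finite
differences have a provable convergence order, which makes the simulator
testable.

A sensor placement is a rigid offset — translation $t_s$ (metres, segment
frame, bounded at 0.5 m) and rotation $q_s$ (segment to sensor). The
sensor pose is $q_{\mathrm{sens}} = q_{\mathrm{seg}} \otimes q_s$,
$p_{\mathrm{sens}} = p_{\mathrm{seg}} + R(q_{\mathrm{seg}})\, t_s$, and a
virtual IMU is the composition of the three maps above.

### Placement fitting and augmentation

`fit_placement()` recovers the offset of a physical sensor by minimising
the mean squared discrepancy between the simulated and the measured
six-channel signal (gyroscope channels weighted by a configurable factor,
default 1) with bounded L-BFGS-B from a supplied initial guess; an
optional coarse grid over rotation offsets guards against poor rotational
initialisation. On noiseless synthetic trials the optimiser recovers
random placements to well under 1 mm and 0.01 degrees; the acceptance
suite asserts the much looser 1 cm / 2 degree contract. The fit is
deterministic given the initial guess and reports its final residual and a
convergence flag.

`augment_trial()` applies a *library* of placement sets (one set = five
sensors, one per segment) to a single motion trial, producing one
simulated five-sensor trial per library entry. At full study scale the
library holds the fitted placements of the 23 ground-truth subjects, so
every motion trial becomes 23 training samples — the augmentation factor
the pipeline is built around.

## Joint angles

Joint rotations are relative orientations
$q_{\mathrm{rel}} = q_{\mathrm{parent}}^* \otimes q_{\mathrm{child}}$,
decomposed into intrinsic Cardan angles. The default order `"zxy"`
follows lower-limb joint-coordinate practice — flexion-extension about
the mediolateral axis first, ab-adduction about the floating axis,
axial rotation about the long axis last — but the order is a
configuration argument, not hard-coded anatomy. Angles are unwrapped
across frames; frames whose middle angle is within 1 degree of
$\pm 90^\circ$ are flagged as gimbal-proximal, and exact lock falls back
to the degenerate formula with the third angle set to zero. Round-trip
tests (decompose, recompose, compare rotation matrices) hold to $10^{-9}$
for random rotations in several axis orders.

## The synthetic cohort

No public dataset ships with the package, so a generator stands in for
the study population and makes every downstream stage testable. It
emulates a walking cohort with the following fixed conditions:

* anthropometrics drawn from Gaussians with mean mass 72.5 kg (SD 11.9)
  and height 1.73 m (SD 0.09), truncated to [40, 120] kg and
  [1.4, 2.1] m; segment lengths as fixed height fractions;
* self-selected walking speeds uniform on 0.8–2.0 m/s; stride period
  decreasing linearly with speed (1.39 s at 0.8 m/s to 0.89 s at
  2.0 m/s) and stance fraction decreasing from 63% to 59%;
* five sensor sites (pelvis, both thighs, both shanks) with
  subject-specific placements sampled around nominal mounting points
  (1.5 cm translation SD, 5 degree rotation SD);
* a flagged subset of subjects carrying "measured" IMUs — the virtual
  signal at the subject's own placement plus white Gaussian noise
  (defaults $\sigma_a = 0.2\ \mathrm{m\,s^{-2}}$,
  $\sigma_\omega = 0.02\ \mathrm{rad\,s^{-1}}$) and a per-trial constant
  bias. At full scale the cohort has 116 subjects of whom 23 are flagged.

Joint-angle curves are truncated Fourier series over the stride cycle
(four harmonics) around population templates whose amplitudes give
physiologic ranges — roughly 40 degrees of hip flexion and 60 degrees of
knee flexion — with sagittal ranges largest and transverse smallest by
construction. Subjects perturb template amplitudes (8% SD), offsets and
phases; amplitudes additionally grow mildly with speed. Right-side
channels are the left templates shifted by half a stride. Segment poses
follow from forward kinematics along the chain pelvis → thigh → shank
(hip rotation composed on the pelvis, knee on the thigh, origins along
the distal axis), and the closed loop — extract relative orientations,
decompose — recovers the commanded angles to $10^{-6}$ degrees.

Joint moments are stance-phase templates: zero at foot contact and
toe-off, double-humped sagittal shapes, expressed in the dimensionless
units $M / (m\,g\,h)$ of body-weight-and-height normalisation. Each
subject's moment amplitudes are tied deterministically to that subject's
angular excursions (the amplitude ratio against the population template).
This choice matters: joint kinetics in a real cohort covary with the
kinematics that drive the sensors, and a generator that instead drew
moment amplitudes independently would make the kinetics partly
unpredictable *in principle* from IMU input — a property of the
generator, not of any model under test.

What the generator does **not** emulate: soft-tissue artefact, marker
noise, ground-reaction forces, sensor temperature drift, pathological or
asymmetric gait, and the broad shape diversity of real populations (all
subjects share one template family). Passing the end-to-end suites
therefore demonstrates that the pipeline is internally correct and that
the networks can learn the kinematics-to-signal inverse on stereotyped
gait — not that any particular accuracy will be reached on real data.

## Preprocessing

* **Filtering.** `zero_lag_butter()` designs a Butterworth low pass at
  the requested order and applies it forward and backward (zero net
  phase; squared magnitude response). Defaults mirror standard practice:
  fourth order, 6 Hz for motion-capture-derived curves; first order,
  5 Hz for IMU channels. Edge transients are suppressed by odd-reflection
  padding (pad length derived from the slowest filter pole) with
  steady-state initial conditions, so constants pass through bit-exactly.
* **Synchronisation.** `sync_lag()` maximises the normalised
  cross-correlation of two series over integer lags, ties broken toward
  the smallest magnitude. The pipeline's simulated data are already
  aligned; the operation exists for measured recordings.
* **Time normalisation.** Linear interpolation onto 101 points spanning
  the window inclusively. Kinematic samples use the step window (left
  foot contact to the next left contact) for inputs and targets.
  Kinetic samples keep the inputs on the full stride and normalise each
  side's moment channels to that side's own stance window — a left-stance
  window alone would leave the right channels mostly zero and the sample
  ill-posed. Linear interpolation preserves endpoints and monotonicity;
  nothing in the data demands a higher-order kernel.
* **Moment normalisation.** Division by $m \cdot 9.81 \cdot h$, with the
  exact inverse provided.
* **Confidence filtering.** `ci_filter()` scores each sample by its mean
  absolute pointwise z-deviation from the ensemble (per channel and time
  point, skipping zero-variance points). Under independent Gaussian
  deviations the score of a clean sample is approximately
  $\mathcal N\!\big(\sqrt{2/\pi},\; \sqrt{1 - 2/\pi}/\sqrt{K}\big)$ for
  $K$ points. A sample is excluded when its score, *relative to the
  ensemble's 10th-percentile score*, exceeds the corresponding relative
  null quantile at the configured level (default 0.95). The relative
  form is what makes the filter idempotent: after one pass removes the
  upper tail, the low-quantile anchor is nearly unchanged, so a second
  pass excludes (almost) nothing, while the exclusion rate under the
  null remains $1 - \mathrm{level}$. The null assumes independent
  deviations; for strongly time-correlated deviation patterns the
  `effective_points` argument substitutes a smaller effective $K$.

## Tensor layouts

All three layouts are built from the same time-normalised samples and
carry identical information. The channel order is a frozen contract
(trained weights depend on it): sensors pelvis, thigh_L, thigh_R,
shank_L, shank_R; accelerometer before gyroscope; axes x, y, z; time
fastest-varying when flattened.

* *flat* — inputs $[n \times 3030]$ ($30 \times 101$), outputs
  $[n \times 1818]$; the MLP's view.
* *sequence* — $[n \times 30 \times 101]$ / $[n \times 18 \times 101]$;
  the LSTM's view. Flattening it reproduces the flat layout bitwise.
* *image* — each sample becomes a 10-row native RGB image (5 sensors
  × {accel, gyro} as rows, time as columns, x/y/z as colour channels),
  bilinearly interpolated to $224 \times 224 \times 3$; the CNN's view.
  Pixel values are min-max scaled to $[0, 1]$ per colour channel; since
  both the scaling and the interpolation are affine, scaling after
  interpolation with training-partition statistics is equivalent to
  scaling before.

Standardisation (flat/sequence: per feature; image: per colour channel)
is always fitted on the training partition only and inverted for
predictions. Output features that are constant on the training partition
carry no signal; their inverse transform pins predictions to the known
constant (relevant at stance boundaries, where moments are identically
zero).

## Networks

All families are trained with minibatch Adam (default batch 64; the
scaled test profiles use 16) on mean absolute error, the loss also used
for reporting. Training stops early when the validation loss has not
improved for `patience` epochs (default 5, cap 40 epochs) and the
best-epoch weights are restored; with no validation set (the LOSO
protocol) the cap applies. All initialisation and shuffling flows
through the R RNG, so runs are reproducible given a seed and
single-threaded BLAS. The optimiser, batch size and initialisation
scheme (He for ReLU layers, Glorot otherwise) are package choices
exposed in the configuration.

* **MLP** (flat): two hidden dense layers with dropout, linear output.
  The shipped full-size configuration is 6000–4000 units, learning rate
  3e-4, dropout 0.5, ReLU for angles (3000–1000 for moments).
* **LSTM** (sequence): two recurrent layers (standard gates,
  forget-gate bias initialised to 1), shared per-timestep linear head;
  32–32 hidden units for angles, 128–1024 for moments. The `activation`
  field is ignored here — gates use their standard sigmoid/tanh forms.
* **CNN** (image): five 3×3 convolution blocks with ReLU and 2×2 max
  pooling after blocks 1, 2 and 5 (a compact analogue of the classic
  five-block image-classification stack), then two dense layers and a
  linear output. `cnn_frozen_conv` freezes the convolution parameters at
  their seeded random initialisation and trains only the dense head — the
  structural stand-in for transferring pretrained convolutional weights,
  which would require an external download. True weight transfer is out
  of scope; the frozen mode preserves the trainable/frozen parameter
  split so the comparison machinery is exercised.

`hyperband_search()` implements successive halving with elimination
factor $\eta = 3$: each bracket samples configurations from the open
search space, trains them on a small epoch budget and promotes the best
third. Samples are drawn strictly inside the bounds (log-uniform
learning rate), and the winner is verified against the bounds — a
search whose optimum sits on a boundary needs a wider space. The search
bounds themselves are configuration defaults, not published values.

The engine is implemented in plain R matrix algebra with explicit
backward passes (verified against finite-difference gradients to
$\sim 10^{-8}$ relative error); no deep-learning framework is involved,
which keeps the package self-contained and the arithmetic deterministic.

### Desk-scale profile

The full-size configurations are impractical on a laptop CPU, so the run
configuration exposes a `scale` factor that shrinks dense widths and the
image side (minimum 8, kept divisible by 8 for the pooling chain). At
`scale = 0.01` the angle MLP becomes 60–40, the CNN head 30–60 on
32×32×3 images with 8-channel convolutions. The LSTM's 32–32 hidden
units are already desk scale and are left unchanged. The test and
acceptance suites run an 8-subject noiseless cohort (2 flagged subjects,
3 trials each, 2 strides per trial at 100 Hz) with these scaled models;
every family reaches a mean held-out per-channel correlation of at
least 0.9 across 3 seeds in a few minutes of CPU time. These problem
sizes are the package's test conditions, chosen to keep the full suite
fast while leaving the learning problem non-trivial.

## Evaluation

Per test trial and channel the package reports the root-mean-square
error normalised to the range of the ground-truth series of that trial
(nRMSE as a fraction; per-trial ranges, then averaged — the choice that
matches per-sample distribution plots) and the Pearson correlation
coefficient. Aggregation uses the median for correlations and the mean
for nRMSE. nRMSE is undefined for constant truth and flagged `NA`;
correlations are undefined for zero-variance series.

`loso_run()` executes the LOSO protocol: one fold per measured-IMU
subject; the fold's training set contains all simulated trials and all
other subjects' measured trials, and *every* trial of the held-out
subject — simulated or measured — is excluded, keeping folds strictly
subject-disjoint (the audit attribute records the composition of each
fold). Scalers are refitted inside each fold on its training rows.
Model comparison uses
$100\,(\mathrm{nRMSE}_{\mathrm{base}} - \mathrm{nRMSE}_{\mathrm{other}})
/ \mathrm{nRMSE}_{\mathrm{base}}$ per channel, computed on fold means
(ratio of fold-means, not mean of per-fold ratios; the former is stable
when individual folds have small denominators); positive values favour
the challenger.

## Numerical choices and degenerate inputs

* Non-unit quaternions are normalised with a warning; zero quaternions
  are an error.
* Pose sequences require at least 3 frames (4 for accelerometer
  endpoint stencils) and finite values.
* Filter inputs must exceed three times the filter order; cutoffs at or
  above Nyquist are rejected.
* Zero-variance series are rejected by `sync_lag` and flagged by the
  metrics; constant features are guarded in the scalers.
* The placement optimiser's translation box (±0.28 m per axis) keeps
  iterates inside the 0.5 m placement ball.
* `train_model` aborts with a diagnostic on non-finite losses or
  gradients rather than continuing silently.

## Known limitations

* The synthetic cohort is stereotyped; results on it bound internal
  correctness, not field accuracy.
* The CNN is a compact analogue, not a weight-compatible replica, of
  the classic architecture; transfer learning with downloaded weights
  is out of scope.
* LSTM inference on arbitrary-length sequences is excluded: all layouts
  share the time-normalised 101-point representation so the families
  see identical information.
* Study persistence is plain CSV/JSON; there is no HDF5 container.
* Resampling between heterogeneous capture rates is not implemented;
  the generator produces one rate.
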