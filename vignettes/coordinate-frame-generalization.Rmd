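---
title: "Coordinate frames of force-field generalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate frames of force-field generalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachgen)
```

## The scientific problem

When people reach while holding a robotic manipulandum that applies a
velocity-dependent force field, they rapidly learn to produce compensating
forces. How the nervous system *represents* what it learned is revealed by
generalization: after training in one arm posture, what forces does the
subject produce when reaching at a different posture? If the field is stored
in **extrinsic (Cartesian)** hand coordinates, the expected force is the same
everywhere. If it is stored **intrinsically**, as a map from joint angular
velocities to joint torques, the expected hand force warps with the arm's
Jacobian. If it is stored in **object-centered** coordinates — as a property
of the grasped handle — it rotates with the hand's orientation in space.

`reachgen` implements the machinery for this inference: prediction of
channel-trial forces under each candidate frame, constrained fitting of
mixture and locally decaying generalization models, model comparison, and a
synthetic-data generator that emulates the two experiment designs so the
whole chain can be validated end to end.

## The arm, the field, and the channel

The arm is planar with three segments; the default lengths 0.30, 0.25 and
0.07 m (upper arm, forearm, hand) describe an average adult arm. Joint
angles are *relative*: each segment's orientation is measured against the
previous segment, the upper arm against the workspace +x axis, so the hand's
orientation in external space is the sum of the three angles. The training
posture is a 35° shoulder, a 75° elbow and a wrist angle of 12.3° (the group
mean of the experiment; it was set per subject in practice, and is
configurable here).

The field is the skew viscous map

$$F = B\,\dot{x}, \qquad
B = \begin{bmatrix} -10.1 & -11.2 \\ -11.2 & 11.1 \end{bmatrix}
\ \mathrm{N\,s/m}.$$

Unlike a curl field, `B` has unique (stable and unstable) axes, so different
movement directions experience genuinely different forces — this is what
makes the coordinate-frame predictions separable. Its joint-space analog is
$W = J_\mathrm{train}^\top B\, J_\mathrm{train}$, a map from joint angular
velocities to joint torques; rendered back at the hand at some other posture
it produces $F = (J^\top)^{-1} W \dot{q}$, which coincides with $B\dot{x}$
exactly at the training posture and diverges elsewhere. Channel trials are
simulated as a stiff one-dimensional spring–damper (5000 N/m, 2 N·s/m)
perpendicular to the start–target line; the damping unit is read as N·s/m
(the force opposes lateral velocity), which is the only dimensionally
consistent reading of the apparatus description.

## Test movements and model predictions

Generalization is probed at 15 postures: three shoulder/elbow configurations
(35°, 75°), (35°, 120°), (80°, 75°) crossed with five hand-orientation
offsets (0° to −45° in 11.25° steps, applied at the wrist relative to the
training wrist angle). Within a configuration the wrist position and its
translation are identical across the five orientations, so only the hand's
orientation varies. Movements are 10 cm, planned as minimum-jerk profiles
(400 ms, 1 kHz sampling), executed with constant hand orientation: the joint
velocities therefore satisfy the stacked linear system
$[J_{3}; (1,1,1)]\,\dot{q} = [\dot{x}; 0]$.

The movement *direction* at each configuration is not part of the posture
grid and had to be chosen. Configuration 1 reaches directly ahead.
Configurations 2 and 3 share one direction, and we select it by the stated
design goal of the original protocol — maximal informativeness: among the
eight experiment directions, the down-left diagonal maximizes the minimum
pairwise separation of the three models' prediction vectors over the full
grid (minimum RMS separation 1.03 in normalized units). This choice affects
only the default grid; any direction can be supplied to `test_movements()`.

Each model predicts a channel-trial force series:

* Cartesian: $F(t) = B\dot{x}(t)$, independent of posture;
* object-centered: $F(t) = R(\theta) B R(\theta)^{-1}\dot{x}(t)$, where
  $\theta$ is the change in *hand orientation in external space* (not the
  wrist angle);
* joint-based (three-joint): $F(t) = (JJ^\top)^{-1} J\,W \dot{q}(t)$ with
  the 2×3 Jacobian re-evaluated at every sample;
* a virtual-segment variant replaces the forearm and hand by the straight
  elbow-to-hand chord, giving an invertible 2×2 Jacobian and
  $B_\mathrm{gen} = (J^\top)^{-1} J_\mathrm{train}^\top B\,
  J_\mathrm{train} J^{-1}$.

The summary statistic is the mean force projected on the channel normal over
50–450 ms after movement onset (onset: speed first exceeding 0.5 cm/s), with
the pre-exposure baseline subtracted, normalized so that each model's value
at the training-posture movement is exactly 1. Note that the *series*
coincide across models only at the training posture itself: over a 10-cm
reach the elbow angle changes by tens of degrees, so the joint-based series
drifts away from $B\dot{x}(t)$ late in the movement. The normalization
contract — every model equals 1 at the training movement — is exact, and it
is what the fitting stage relies on.

## Mixture and decay models

Generalization data (subjects × 15 movements of normalized adaptation) are
fit with convex mixtures of the three single-frame predictions, optionally
with Gaussian decay in each frame's own metric:

$$F = k_j J e^{-d_j(\Delta\theta_s^2+\Delta\theta_e^2+\Delta\theta_w^2)}
    + k_c C e^{-d_c(\Delta x^2+\Delta y^2)}
    + k_o O e^{-d_o \Delta\theta_\mathrm{hand}^2},$$

with $k \ge 0$, $\sum k = 1$ (so the training posture is fully accounted
for) and $d \ge 0$ (rad⁻² for the joint and object metrics, m⁻² for the
Cartesian one). Degrees of freedom follow the standard accounting: 0/1/2 for
one/two/three-component mixtures without decay, 1/3/5 with decay.

**Optimizer.** For fixed decay rates the weights solve a least-squares
problem over a ≤3-simplex, which we solve *exactly* by enumerating the
simplex faces (active-set). Decay rates are then the only genuinely
non-convex part; they are searched by Nelder–Mead over log rates with ten
seeded restarts (a 1-D golden-section search when only one component is
present). One restart is pinned at a numerically zero rate, so a decay model
can never fit worse than its no-decay counterpart — the nesting the model
family implies. This exact inner solve reaches true zero weights (mixtures
often sit on a simplex face), which a soft reparameterization cannot.

Models are compared by $\mathrm{BIC} = n\ln(\mathrm{MSE}) + k\ln n$ over the
concatenated subject × movement points, reported relative to the best model
(half the BIC difference approximates a log Bayes factor) and relative to a
no-generalization reference that predicts zero at every test posture.
Ties break toward fewer degrees of freedom, then lexicographic component
order. Per-subject predictive performance uses leave-one-subject-out
cross-validation: each model is fit to the per-movement average of the
remaining subjects and scored by variance explained on the held-out subject
(negative when it predicts worse than that subject's mean).

## Trajectory metrics

For the workspace-transfer experiment the package provides the four standard
trial metrics — maximum perpendicular error from the start–target line (with
a signed variant for aftereffect analyses), angular error at the
peak-velocity point, path length normalized by the 10-cm reach distance, and
correlation of position + velocity channels with the direction-matched
baseline average over a −125 ms…+750 ms window around the alignment point
(speed first reaching 0.1 m/s) — plus the windowed inner-product similarity
ρ. The corrected published definition of ρ is not reproduced in the source
we follow, so the package operationalizes it explicitly: the mean over
100-ms sliding windows of the trial–baseline velocity inner product, divided
by the same quantity for the baseline against itself. This makes
ρ(baseline, baseline) = 1 by construction, 0 for orthogonal velocities, and
scales linearly with velocity gain; the window length is a parameter.
Velocities are estimated by central differences followed by a 20-Hz
3rd-order Butterworth filter applied forward and backward (zero phase),
matching the 400-Hz robot pipeline.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

* **Schedules.** The posture-generalization design: 128 preexposure trials
  (113 null + one channel trial per test movement), 496 exposure trials, and
  600 generalization trials (525 field + 5×15 channel trials), with training
  movements forming a pseudorandom walk of 10-cm reaches in 8 directions
  confined to the 15×15 cm training area and every channel trial followed by
  a training-area movement. The workspace-transfer design: 250 + 250
  baseline trials (48 no-vision each), two (or three, in the extended
  variant) 500-trial adaptation blocks with 96 no-vision trials per block of
  which half are null-field catch trials, and 80 no-vision generalization
  reaches as randomized center-out pairs, 10 per direction, with field
  assignment by subgroup (27/27/26 extrinsic/intrinsic/null, or 40/40). The
  no-vision count per adaptation block is stated for two blocks (192/1000)
  and applied per block (96) in the extended variant.
* **Channel datasets.** Per subject and movement,
  `scale_s × mixture prediction + N(0, σ²)`, with `scale_s ~ N(1, s²)`
  (default spread 0: subjects identical in expectation). σ defaults to 0.1
  of the training-posture magnitude, the level at which parameter-recovery
  checks are run.
* **Reaches.** A point-arm simulation: an effective hand mass (2 kg) tracks
  the minimum-jerk plan under the external field, a learned feedforward
  force (a fraction λ of the ideal compensation for the *learned* field) and
  a plan-tracking spring–damper (2 kN/m, 40 N·s/m). λ follows a single-rate
  exponential update toward an asymptote of 0.8 — the level of compensation
  channel-trial forces approach in practice — at 0.01/trial. The learning
  rule and controller are explicitly scaffolding for qualitative curve
  shapes (error decreasing over exposure; mirror-image deviations on
  null-field catch trials); they are not biomechanical claims, and nothing
  downstream estimates them.

What the generator does *not* emulate: subject-specific arm geometry and
its interaction with the field, trial-to-trial force variability on channel
trials beyond additive Gaussian noise, visual feedback, or the idiosyncratic
variance structure of real subjects. Passing tests therefore certify the
*analysis machinery* — geometry, field algebra, optimizer correctness,
selection behavior — not the fidelity of any learning model to human data.

## Numerical choices

* Angles are radians internally; constructors accept degrees via a flag.
* Singularity guard: a warning when the shoulder/elbow 2×2 Jacobian
  determinant falls below 1e-9 (straight or folded arm); hard errors when a
  matrix to be inverted is singular, naming the posture.
* Movement plans: 0.4 s, 1-ms steps, padded 0.2 s past movement end so the
  450-ms analysis window is always covered.
* Decay-rate search bracket: log-uniform restarts over [1e-2, 1e3]
  (rad⁻²/m⁻²), 1-D bracket [e⁻¹⁴, e¹⁰]; inner-solve tolerance 1e-12 on the
  simplex KKT system; Nelder–Mead relative tolerance 1e-12.
* A perfect fit (MSE = 0) yields BIC = −∞ with a warning rather than an
  error, so noiseless identifiability checks remain expressible.
* The two-joint inverse kinematics returns the elbow-positive branch, the
  configuration in which all protocol postures lie.
* Workspace geometry of the transfer experiment: workspace centers at
  (+0.15, +0.40) m and (+0.45, +0.40) m from the shoulder (the testing
  workspace reached by translating the shoulder 0.30 m leftward); the
  intrinsic field's `W` is built from the Jacobian at the training-workspace
  center. The published description of the shoulder–robot geometry is
  ambiguous as printed; this reading keeps both workspaces comfortably
  inside the two-link arm's annulus.

## Problem sizes used in the test suite

The suite validates optimizer fidelity against a 0.01-resolution simplex
grid on 20 synthetic datasets, parameter recovery over 50 replicate
9-subject cohorts at σ = 0.1 (median decay-rate error ≤ 25%), and model
selection over 100 low-noise replicates (the generating frame preferred in
≥ 90%). These sizes give stable pass/fail behavior for the stochastic
checks while keeping a full run around half a minute.

## Known limitations

* The generalization movement directions for configurations 2 and 3 are a
  modeling choice (maximal model separability), not a published value;
  conclusions that depend on the exact direction should set it explicitly.
* ρ is an operationalization (see above); absolute ρ values are comparable
  within this package but not necessarily to other implementations.
* The simulator's learning dynamics are a stand-in; only qualitative
  properties (monotone improvement, mirror aftereffects) are meaningful.
* All kinematics are planar; no trunk motion, 3-D posture, or limb dynamics
  (inertia, Coriolis) are modeled — the fields are rendered, not integrated
  through a biomechanical arm.
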