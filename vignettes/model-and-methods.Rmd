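---
title: "A hierarchical dorsal-stream model of biological-motion direction judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical dorsal-stream model of biological-motion direction judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A goalkeeper facing a penalty kick reads the kicker's body: from a sparse
point-light display of the major joints, human observers can report whether a
kick deviates left or right of straight ahead, with an accuracy that grows
with the deviation angle and a decision that takes about a second.
`kinemotion` simulates this two-alternative forced-choice (2AFC) task with a
four-level detector hierarchy modelled on the dorsal visual stream, and
reports the three observables a psychophysicist measures: the 75% angular
threshold, the psychometric slope, and the reaction time (RT).

The model is *descriptive*: each level is a simple, physiologically
inspired computation, and four observer-level parameters — internal noise
$\delta$, decision time constant $\tau$, inhibitory gain $k$, and adaptation
onset $\tau_a$ — are tuned per observer to reproduce individual differences.

## The stimulus

No motion-capture data are bundled; `generate_kick()` synthesises a
keyframed 14-joint point-light kicker (head, shoulders, elbows, wrists,
mid-hip, knees, ankles, toes), 90 frames at 20 fps (4.5 s), subtending about
12 degrees of visual angle.  The movement is a bilaterally symmetric
two-legged ballistic kick: a short static stance (the first tenth of the
sequence — a kicker stands quietly before the run-up, and the stance carries
no direction information), then a crouching wind-up, then a fast leg swing
during which the feet rise and spread while hip, head and arms drop.  The
left/right signal is a rigid rotation of the whole figure about the depth
(z) axis through the hip root: a kick with deviation $+a$ is the base
movement rotated clockwise (viewer's perspective) by $a$ degrees, and the
leftward kick at $a$ is its exact mirror image.

Two design choices deserve emphasis:

* **Bilateral symmetry.**  Left and right stimulus classes are pure
  rotations of *one* base movement.  During development we found that an
  asymmetric (one-legged) kicker whose left class is the mirrored body leaks
  a deviation-independent "which leg" identity cue into the features: at 0
  degrees the two classes were already separable, flattening the
  psychometric curve at small angles.  With the symmetric base the 0-degree
  drive asymmetry is numerically zero and all direction information is
  carried by the rotation sign, as in the task the model is meant to
  emulate.
* **Opposed motion in the strike.**  The opponent-motion level (below) only
  responds to locally antagonistic motion.  The strike phase therefore
  includes counter-movement — feet rising while arms, hip and head drop,
  legs spreading — which real kickers also exhibit as counter-balancing.

What the generator does *not* emulate: biomechanical realism (no
motion-capture), perspective foreshortening (projection is orthographic),
occlusion, or scrambled/inverted control stimuli.  Passing tests therefore
show that the *mechanism* behaves as specified on a kicking-like synthetic
signal, not that the model reproduces human data on the original recorded
stimulus.

## Level 1: local motion energy

`motion_grid()` places 1116 receptive fields in a 36 x 31 grid (about 0.4
degrees each, one-sixth linear overlap) over the stimulus area.  The field
size follows from the pitch and the overlap fraction,
`size = pitch / (1 - overlap)`, so zero overlap partitions the area exactly.
Local activity is approximated from optical flow between consecutive
frames: each cell averages the flow in its field and projects the mean onto
the four cardinal directions with half-wave rectification, so opposite
channels are mutually exclusive.  Two flow modes exist:

* **ground truth** (`flow_exact()`): joint displacements from the known
  kinematics, splatted at the joints' positions — the mode used by the
  simulation pipeline, so model validation is decoupled from flow-estimation
  artifacts;
* **classic dense** (`compute_flow()`): a Lucas–Kanade least-squares
  estimator on rendered frames, provided for completeness and tested on
  synthetic translations.

Whether the original model rectified the mean flow or pooled rectified
per-pixel flow is not determinable; both coincide for coherent point-light
motion, and mean-then-rectify is used.

## Level 2: opponent motion

`opponent_layout()` builds 100 detectors: four kinds of expansion and
contraction detectors (horizontal/vertical, each a 5 x 4 assembly, 80
detectors) plus 20 rotation detectors (10 clockwise, 10 counterclockwise).
Each expansion/contraction detector pools two opposed subfields by
max-pooling (positional invariance inside the field) and combines them with
a soft AND (`min`; `product` is available).  Each rotation detector has four
contiguous quadrant subfields of about 4 x 5 cells (upper-left, upper-right,
lower-left, lower-right; quadrants of neighbouring detectors overlap).
Because the lower level only signals the four cardinal directions, a
clockwise rotation is detectable in exactly two configurations — upper
subfields moving right while lower ones move left, or left subfields moving
up while right ones move down — and either configuration triggers the
detector (conjunctive within a condition, disjunctive across).

Counts in the source material are ambiguous (20 rotation detectors in one
place, 20 per sense in another, and a 140-neuron figure caption); the
default follows the 100-detector total, and `n_rotation = 40` instantiates
the 20-per-sense variant.  All placements are symmetric under reflection
about the vertical midline, so mirroring a stimulus permutes the feature
vector exactly and swaps cw with ccw (`mirror_permutation()`), a property
the test suite asserts to machine precision.

## Level 3: template matching and temporal-order dynamics

The 18 optic-flow-pattern neurons split into two chains of nine, one per
direction; neuron $j$ of a chain is tuned to frames $10(j-1)+1 \dots 10j$.
`fit_templates()` learns, for each (direction, window), the mean and
diagonal dispersion of the opponent feature vectors over the training set
(kicks at 7–20 degrees, both sides).  The instantaneous match is a
diagonal-Gaussian log-likelihood with an extra dispersion penalty weighted
by $\lambda$ (risk aversion: high-variance templates are down-weighted even
where they fit).  This classifier is a *reconstruction* — the original's
exact form is not published — and only its contracts are guaranteed:
monotonicity in likelihood, left/right symmetry, and invariance of the
ranking to common affine feature rescalings.

Evidence is rescaled by one common affine map derived at training time (the
mean per-frame best match maps to 1, the grand mean to 0), so evidence
differences between templates keep their relative scale.  (A per-template
normalisation was tried and rejected: it over-amplifies windows whose
in/out evidence contrast is small and saturates the left-right asymmetry.)  The
neurons then integrate

$$\tau_{OFP}\,\dot H_i = -H_i + G_i(t) + \sum_m w(i-m)\, f(H_m),$$

with $\tau_{OFP} = 150$ ms, a step threshold $f(H) = \mathbf 1(H >
\theta_f)$, and a compact asymmetric kernel: the active neuron excites the
neuron tuned to the next window ($w(+1) = w_+ > 0$) and inhibits the
previous one ($w(-1) = -w_- < 0$), within each direction's chain only.  The
printed form of this equation in the source is dimensionally garbled; the
canonical neural-field form above is the only reading consistent with its
own prose ("excites the future templates, inhibits the past").  Whether $f$
gates the emitting or the receiving neuron is likewise ambiguous; the
emitting (source) reading is the default and the self-gated variant is
available (`f_arg = "self"`).  Temporal-order selectivity — in-order
evidence produces more suprathreshold activity than reversed evidence — is
asserted in the tests; it is the mechanism's purpose.

Internal noise enters the model only here: each neuron's *output* is drawn
from $\mathcal N(H_i(t), \Delta t\, \delta^2)$, sampled once per integration
step; the latent trajectory and the two lower levels are noise-free.

## Level 4: decision by robust mutual inhibition with disremembering

Two decision neurons (left, right) race.  Each direction's pooled evidence
is the mean of its nine rectified noisy outputs, and the drive is the gain
times the pooled evidence minus the opponent direction's (feed-forward
opponent subtraction).  Two rejected alternatives explain this choice:
max-pooling the chain gives whichever chain has more near-zero activities an
`E[max]` noise bonus that systematically favours the wrong direction near
threshold, and omitting the opponent subtraction lets stimulus phases that
match both directions equally drive both neurons strongly, at which point
the winner-take-all instability commits to a random winner long before any
discriminative evidence arrives.  The dynamics are

$$\tau \dot T = -T + S(P_T) + DiS_T, \qquad
  P_T = g_T - \theta_I - k D - a T,$$

symmetrically for $D$, with $S(x) = \beta \max(x,0) / (\gamma + \max(x,0))$
a modified Michaelis–Menten gain.  $P_T$ is the neuron's *information
threshold*: when it is negative the lateral connection is off and the output
is silent, and activities are clamped to zero after every step (the robust
rule).  The engagement baseline $\theta_I$ matters: without it the race
commits on rectified output noise within tens of milliseconds, before any
evidence has accumulated.  The adaptation ("disremembering") input

$$DiS_T = u(t - \tau_a)\,[\,T - S(P_T) - k_a T\,]$$

switches on at $\tau_a$ and cancels the S-terms, reducing each neuron to a
pure exponential decline $\tau \dot T = -k_a T$ that drives the winner out
of excitation — decisions are transient, and the reaction-time definition
below becomes well posed.  (The weighting coefficient is read as $k_a
\cdot T$, i.e. proportional to the activity: a constant would give a linear,
not exponential, decline.)

The system is integrated with classical fixed-step RK4 ($\Delta t = 1$ ms
default, $\Delta t \le \tau/10$ enforced), the adaptation gate held constant
within a step so the discrete flow switches exactly at the grid point; the
test suite checks the integrator against `deSolve`'s adaptive `lsoda` at
trajectory scale.  The winner is the first neuron to exceed the decision
criterion; simultaneous crossings leave the trial undecided (recorded, never
silently randomized).  The reaction time is the mean of all time points at
which the winning signal is within `eps_plateau` (default $10^{-6}$,
relative) of its global maximum; motor time is treated as zero.

$P_T/P_D$, $\theta_I$, $a$, $\beta$, $\gamma$ and $k_a$ are reconstructions:
the originals live in an unpublished predecessor formulation.  The contracts
kept are robustness (non-negativity), the role of $k$ as mutual-inhibition
gain, left/right equivariance, and the post-onset exponential decline.

## Calibration

Four constants tie the stages together; all are fixed model constants set
once by deterministic rules in `calibrate_model()` (never per observer):

* **evidence scale** — all evidence-unit quantities are rescaled so that the
  mean drive asymmetry evoked by an 8-degree stimulus equals `snr_ref = 0.9`
  times the per-sample output noise at the reference level $\delta = 0.030$.
  The published $\delta$ range (0.022–0.038) is meaningful only relative to
  the activity scale of a particular stimulus set and classifier; this rule
  places it where it produces gradual psychometric functions over the tested
  2–15 degree range.
* **$\theta_f$** — half the mean per-window peak activity of a clean
  0-degree stimulus, so each window's neuron activates in sequence.
* **drive gain** — normalises the maximal clean 15-degree drive to 1.
* **criterion** — 0.7 of the winner's plateau under a clean 15-degree
  stimulus, so a clean large-deviation trial is always decided within the
  4.5 s stimulus.

With these rules and the central observer parameters ($\delta = 0.030$,
$\tau = 0.025$, $k = 4$, $\tau_a = 1.22$), one 960-trial block yields a
threshold near 7–8 degrees and a mean RT near 0.93 s, and moving $\delta$
across its published range (0.022–0.038) moves the threshold from about 3
to about 14 degrees while shortening the reaction time.

## Protocol, psychometrics, tuning

`run_block()` runs the 2AFC protocol (deviations 2, 4, 8, 15 degrees, both
sides, 120 trials per cell, 960 per block, randomized order under a seed).
Everything below the decision stage is deterministic per condition and
cached; the decision stage is vectorised across a cell's trials.
`fit_psychometric()` fits proportion correct against $|$deviation$|$ by
maximum likelihood with a logistic of lower asymptote 0.5 and no lapse term
(cumulative Gaussian available); the threshold is the 75% point and the
slope is the derivative of proportion correct there (units 1/degree), with
standard errors from the observed information.  Pooling left and right into
$|$angle$|$ is a choice; the signed-angle alternative was not needed for any
reported quantity.  Degenerate data (all correct, at chance, separation) are
flagged, not fitted.  Undecided trials are excluded from RT summaries and
counted.  `grid_search()` exhaustively scores a grid over $(\delta, \tau, k,
\tau_a)$ by weighted relative error against a target (threshold, slope, RT)
triple, evaluating every candidate under the same seeds so the leaderboard
is invariant to row order.

`correlate_reference()` reproduces the published correlation analysis over
the bundled 36-athlete table: Spearman rank correlations with average-rank
ties (required — grouped athletes share simulated values) and p-values from
the t approximation.  On the bundled transcription the threshold and RT
coefficients reproduce the printed values (0.9848 → printed 0.984, their
p-values agree to three figures; 0.5129 → printed 0.513); the slope column
of the printed table yields 0.967, whereas the printed slope coefficient
0.955 is consistent only with its own printed p-value and evidently derives
from a different revision of that table.  The package reports what the table
implies.

## Numerical choices and degenerate inputs

* Integration step 1 ms ($\tau_{OFP}/150$); enforced $\le \tau/10$.
* Template variances floored at $(0.05\,\mathrm{rms})^2$ of the training
  features, so near-static windows do not become brittle delta functions.
* Rotation-detector quadrants split at fractional centres, so the split is
  unambiguous and mirror symmetry is exact.
* Ties in the race (same-step crossing) are undecided trials, reported as
  such.
* Zero-joint sequences render to all-dark frames; joints projecting outside
  the frame are clipped with a warning; non-finite angles and evidence are
  rejected.

## Problem sizes used by the test and acceptance suites

The trend suite simulates 1920 trials per parameter setting (twelve
160-trial sub-blocks), six settings in all; the adaptation, symmetry and
integrator suites use 20-trial batches and 20 random parameterizations; the
psychometric recovery study uses 1000 replicates of 480-trial experiments.
These sizes were chosen to give the sign tests power at $\alpha = 0.01$
while keeping a full run of the suite within a coffee break.

## Known limitations

* The classifier, the information thresholds and the adaptation bracket are
  reconstructions of an unpublished formulation; only their stated contracts
  are guaranteed.
* The synthetic kick is not biomechanically valid; absolute thresholds and
  slopes depend on it and on the calibration rules, and should not be read
  as predictions for the original recorded stimulus.
* In this reconstruction the losing decision neuron collapses quickly once
  the drive asymmetry resolves; the near-deadlock regime the published model
  shows at small $\tau$ and large $k$ (reaction times up to 2.8 s) is a
  property of its unpublished decision algebra and does not reproduce here.
  Thresholds fall with $\tau$ and rise with $k$ and $\delta$ as reported,
  and reaction times rise with $k$ and $\tau_a$ and fall with $\delta$ as
  reported, but the reported *decrease* of reaction time with $\tau$ comes
  out weakly reversed.
* Template generalization below the training range (7–20 degrees) is
  imperfect: at the top of the published noise range, accuracy at 2 degrees
  can fall below 50% (a deterministic onset-epoch artifact), and observers
  with adaptation onset $\tau_a \lesssim 0.8$ s leave many trials
  undecided because the race engages only about 0.5–0.8 s after stimulus
  onset with this stimulus.
* No long-range opponency between distant receptive fields, no process
  noise in levels 1–2, no learning of priors — deliberately out of scope.
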