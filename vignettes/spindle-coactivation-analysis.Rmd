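---
title: "Simulating Ia afferent feedback and clustering reaching muscle activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Ia afferent feedback and clustering reaching muscle activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindleclust)
```

## The scientific question and the modelling approach

Antagonist muscles co-contract in a task-dependent way during reaching:
co-contraction stiffens joints and stabilizes movements whose passive
dynamics would otherwise perturb them. One candidate source of that
co-contraction is monosynaptic feedback from muscle-spindle primary
(Ia) afferents, whose sensitivity the nervous system can retune through
fusimotor (γ) drive. Because Ia firing cannot be recorded from many
muscles at once in behaving humans, the question is approached
computationally: simulate Ia activity from muscle kinematics under
different fusimotor strategies, and ask whether the simulated afferent
profiles share the cluster structure of the muscle activation (EMG)
profiles — in particular of their co-contracting groups.

`spindleclust` implements that complete analysis as composable stages,
plus a synthetic data generator that stands in for the (non-public)
motion-capture and EMG recordings such studies use. Every stage is a
plain function over data frames; `run_hypothesis_suite()` chains them.

## The spindle model

The Ia firing model is static and phenomenological:

$$Ia(v, l) = A\,\mathrm{sgn}(v)\sqrt{|v|} + B\,l + C$$

with muscle length $l$ in *rest-length units* and its rate of change
$v$ in rest-lengths per second. Defaults $A = 65$, $B = 200$, $C = 10$
imp/s are the values validated against human microneurography for this
model family. Three conventions deserve note:

* **Shortening velocity.** The model is usually written with
  $v^{0.5}$, leaving negative $v$ undefined. We use the odd extension
  $\mathrm{sgn}(v)\sqrt{|v|}$, the standard continuous treatment:
  shortening reduces the firing rate symmetrically.
* **Clamping.** Firing rates cannot be negative; rates are clamped at
  0 imp/s after evaluation and the number of clamped samples is
  recorded in an attribute. Inside the clamp the model is no longer
  affine in $(A, B, C)$, which is why the affinity checks in the test
  suite restrict themselves to clamp-free kinematics.
* **Rest length.** $l_\mathrm{rest} = (l_{\min} + l_{\max})/2$ over
  the *full physiological posture range* (not the task workspace),
  computed in closed form from the linear length model; lengths are
  divided by it so $l \approx 1$ at rest. An explicit `l_rest`
  argument accepts the alternative median-based definition used in
  robustness re-analyses.

Fusimotor variation takes two forms. *Static set* holds γ drive
constant within a movement but changes it between tasks; it is modelled
by the four corner parameterizations $A \in \{33, 200\}$,
$B \in \{50, 400\}$ (`static_set_grid()`). *α–γ coactivation* couples
spindle sensitivity to the homonymous motor command; it scales the two
kinematic terms (never the baseline) by the muscle's normalized EMG
profile $a$:
$Ia(a,v,l) = a\,65\,\mathrm{sgn}(v)\sqrt{|v|} + a\,200\,l + 10$, which
reduces exactly to the reference model at $a \equiv 1$.

## Signal processing

EMG is conditioned the standard way: zero-phase 4th-order Butterworth
high-pass at 10 Hz, full-wave rectification, zero-phase low-pass at
20 Hz. Zero-phase (forward–backward) filtering matters because all
downstream analyses are correlations between time courses; a phase lag
would bias them. Forward–backward application of a 4th-order filter is
used as the package's definition of these cutoffs. End transients are
controlled by odd-reflection padding, without which bidirectional
filtering corrupts traces that do not start and end at zero.

Movement onset and offset are prominent local maxima of the third time
derivative (jerk) of the wrist endpoint displacement: the first
prominent peak of $|d^3x/dt^3|$ before peak speed and the last after
it. The third derivative is estimated by Savitzky–Golay differentiation
(quintic fit, default window 9 samples, prominence threshold 10% of
the global maximum). A quintic Savitzky–Golay kernel reproduces
minimum-jerk segments exactly, so on clean kinematics the detected
onset is within ±2 samples of the true movement corner; repeated
finite differencing of a low-pass-filtered trace was rejected because
it amplifies residual pass-band energy by $(2\pi f)^3$ and produced
spurious end-of-trace peaks. The window is a tuning parameter: widen it
for noisy recorded kinematics.

Each trial's signals are then interpolated onto `n_phase = 100`
uniformly spaced points of normalized movement phase (shape-preserving
PCHIP, which cannot overshoot), averaged across trials, and
amplitude-normalized to each channel's maximum across all tasks of the
same participant, so profiles are unitless with a per-participant
maximum of 1. One hundred phase samples keeps the correlation degrees
of freedom explicit (`df = 98`) and matches the resolution at which
such profiles are usually plotted. Co-contraction of an antagonist
pair is *wasted contraction*: the sample-wise minimum of the two
normalized envelopes, over the seven pairs AD-PD, Pec-TM, BicL-TriLo,
BicS-TriLa, Br-TriLa, FCR-ECR, FCU-ECR.

## Arm dynamics

Task dynamics are verified with a three-segment planar chain (arm,
forearm, hand) in the vertical plane, built from body height and weight
with Winter's anthropometric proportionality coefficients and solved by
recursive Newton–Euler. Although a five-degree-of-freedom description
of the arm exists, the tasks are designed to be planar and only
flexion–extension torques enter the analysis, so out-of-plane degrees
of freedom are omitted. Derivatives of recorded angles, when not
supplied, come from central differences. The implementation is checked
against closed-form statics (horizontal arm gravity moment, machine
precision) and an energy balance
$\sum_j \int \tau_j \dot\theta_j\,dt = \Delta KE + \Delta PE$ that
holds to better than 0.1% on minimum-jerk reaches at 480 Hz.

Three descriptors summarise each task per joint: the *postural torque
change* (mean torque over 100 ms after offset minus 100 ms before
onset), the *peak torque change in the acceleration phase* (the
maximal signed $|d\tau/dt|$ between onset and the movement's halfway
point — the derivative reading is adopted because the quantity is
reported in N·m/s), and *mechanical muscle work*
$\int \tau \dot\theta\,dt$, positive for concentric and negative for
eccentric action. The wrist does not move in any task, so wrist work is
identically zero and wrist torque reflects isometric stabilization.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces the full study design: 9 participants
(heights uniform on 1.55–1.90 m, weights on 55–95 kg, matching a
typical adult cohort), 3 tasks × 24 trials, kinematics at 480 Hz and
EMG at 2000 Hz. The three tasks differ in the role of passive dynamics:
Control and Assistive move shoulder and elbow in opposite directions
(assistive interaction torques; shoulder excursions −60° and −40°,
elbow +60° and +100°), Resistive moves them in the same direction
(+45°, +10°), and the wrist never moves. Movement time is 1 s with
0.3 s rest padding — a typical unhurried reach, and enough margin for
the 100 ms postural windows.

Joint kinematics are minimum-jerk; muscle lengths follow a first-order
model $l_m = \mathrm{base}_m - \sum_j r_{mj}\theta_j$ with constant
signed moment arms (1–4 cm; flexors positive), which is kinematically
consistent — exactly linear in the angles — without claiming anatomical
fidelity. EMG is synthesized from the physics: the participant-specific
inverse-dynamics torque, minus its pre-onset postural level, is the
phasic demand; each joint's demand is normalized to unit peak; each
muscle receives the rectified agonist share of the joints it spans,
plus a common drive (the task's co-contraction level, 0.10 / 0.25 /
0.50 for Control / Resistive / Assistive, shaped as a smooth tonic
plateau over the movement — antagonist stiffening held through the
reach) added identically to both members of every antagonist pair;
the Assistive task gets the most co-contraction by design. The
expected envelope amplitude-modulates a white-noise carrier so the
filtering stage has realistic work to do, and trial-to-trial
variability is smooth zero-mean envelope noise (`noise_sd`, default
0.1 on the unit envelope scale — a stand-in, since trial variability
is rarely quantified in publications, not a claim about real data).

The generator records its own ground truth: the expectation of the
estimated envelope under the analysis chain — for a unit-variance
Gaussian carrier the trial-averaged linear envelope converges to
$\sqrt{2/\pi}\,\mathrm{LP}\!\left(\sqrt{\mathrm{env}^2 * h^2}\right)$
with $h$ the high-pass impulse response — is phase-normalized over the
detected movement window, pushed through the same HVE/UPGMA machinery,
and cut at the cluster count with the widest merge-height gap. That
maximal-margin structure is what the pipeline should recover as noise
vanishes, and the test suite verifies exact recovery (Fowlkes–Mallows
$B = 1$) at `noise_sd = 0` over 20 replicate seeds with monotone
average degradation as noise grows. Defining truth this way (rather
than as classes of exactly proportional raw envelopes) matters because
with a strong common drive many channels become *nearly* collinear;
distinctions below the resolution of the envelope-estimation chain are
not recoverable by any method and are therefore not planted as truth.

What passing these tests shows is that the pipeline is correct and
sensitive under its own generative assumptions. Real recordings differ
in ways the generator deliberately ignores: motor-unit structure and
EMG crosstalk, non-minimum-jerk kinematics, out-of-plane motion,
anatomical moment-arm variation with posture, and trial-to-trial
kinematic variability (the generator repeats identical kinematics
across trials; only the EMG varies).

## The clustering and tree statistics

Correlation p-values use the t approximation with
$df = n_\mathrm{phase} - 2$, treating phase samples as independent —
the field's implicit convention; smooth profiles are autocorrelated, so
these p-values are anticonservative in absolute terms, which is
acceptable because they act only as a relative gate feeding the FDR
stage. The two-stage BKY procedure is applied per correlation matrix
(one family per participant × task × comparison); the family choice is
a convention, adopted because the significance threshold it produces is
matrix-specific. Significant correlations map to HVE distances
($1 - r^2$, $1 + r^2$ for positive/negative $r$; non-significant pairs
to 1; a significant $r = 0$, a measure-zero case, also maps to 1).
Channels with zero variance — the wrist muscles' length profiles, for
instance, since the wrist never moves — are retained with all their
pairs forced to the non-significant branch, keeping channel sets
aligned across tasks. Trees come from UPGMA (`stats::hclust`,
`"average"`), whose lowest-index tie-breaking makes the result
input-order invariant; tree quality is the cophenetic correlation.

Tree similarity is the Fowlkes–Mallows index computed from the match
matrix at each $k$ from 2 to half the number of signals (6 for 12
muscles); undefined values (degenerate marginals) are dropped. Chance
similarity is estimated by uniformly relabeling the leaves of *both*
trees independently 1,000 times — relabeling preserves tree shape while
destroying signal identity, which is the right null for "which signals
cluster together" (whether one or both trees should be permuted is not
standard; permuting both is adopted). Percentile p-values use the
add-one convention, so $p \ge 1/(n_\mathrm{perm}+1)$. Per-participant
p-values across $k$ combine by Fisher's method; the across-participant
gate is Bonferroni ($0.05/9 = 0.0056$).

Between-task comparisons bootstrap the B collections (9 participants ×
$k = 2..6$, resampled with replacement 1,000 times, independently for
the two modalities since EMG and Ia values are not paired by
construction — 45,000 resampled values per modality per task pair).
Each bootstrap replicate contributes one difference sample, the
difference of the two resample means, and the p-value is the two-sided
location of zero in that distribution. The per-replicate *mean*
difference (rather than element-wise differences) is used because the
element-wise spread reflects within-collection variance and never
shrinks with evidence; the mean-difference distribution is the
standard bootstrap test of a location difference. The fusimotor-variant
suite needs no resampling: each variant's B-against-EMG values pair
naturally with the reference model's on the same participant × task ×
$k$ cells, so the difference distribution is formed directly and zero
is located in it.

## Numerical and design choices, collected

* Filters: Butterworth order 4, forward–backward, odd-reflection
  padding; cutoffs 10/20 Hz (EMG). Savitzky–Golay (p = 5, window 9)
  for jerk-based event detection.
* Interpolation: PCHIP for phase normalization (no overshoot);
  linear for resampling torque demands onto the EMG clock.
* Integration: trapezoid rule (deterministic, second-order).
* Degenerate inputs: constant profiles warn and are forced
  non-significant; all-zero channels normalize to zeros with a
  warning; FM with degenerate marginals raises an error (and is
  dropped from curves); zero p-values are clipped before Fisher
  combination with a warning.
* Ties: UPGMA ties break on the lowest merge index (inherited from
  `stats::hclust`), making results order-invariant.
* Seeds: one study seed, split hierarchically per participant, task,
  trial, and analysis stage through a deterministic integer map, so
  any sub-stream is reproducible in isolation; all derived seeds stay
  within the 32-bit range `set.seed()` requires.
* Problem sizes: the full default study (9 × 3 × 24 trials, 1,000
  permutations and bootstraps) runs in about two minutes on one core;
  the recovery analyses in the test suite use 1-participant,
  6-trial studies over 20 replicate seeds per noise level.

## Known limitations

The spindle model is static: it omits intrafusal mechanics, short-range
stiffness, and the transient firing bursts more detailed models
produce. The correlation-based comparison is linear by design, on the
argument that motoneuron pools linearize the transformation from
common synaptic input to EMG at the low contraction levels of unloaded
reaching; nonlinear dependencies between Ia and EMG profiles are
invisible to it. The generator's EMG model has no crosstalk and its
noise model is a stand-in. Finally, correlation p-values ignore the
autocorrelation of smooth profiles, as noted above; treat the FDR gate
as a relative ranking device, not calibrated error control.
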