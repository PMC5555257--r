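---
title: "Methods: an in-silico physiologic wrist simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an in-silico physiologic wrist simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the controllers, the parameter choices
and the numerical decisions behind `wristsim`, and what its synthetic
experiments can and cannot say about real specimens.

## The plant

The wrist is modelled as two rotational degrees of freedom — flexion-
extension (FE, flexion positive) and radioulnar deviation (RUD, ulnar
positive), following the ISB sign conventions — driven by the six primary
wrist muscles through a constant 2×6 moment-arm matrix `R` (mm). Each axis
obeys

\[ I\,\ddot\theta = \tau_\text{muscle} + \tau_\text{gravity}
   - k\,\theta - b\,\dot\theta , \]

with inelastic anatomical stops at ±90° FE and ±45° RUD (velocity zeroed on
contact). Cross-axis inertial coupling is neglected: at the speeds of
interest (0.25 Hz cycles) inertial torques are two orders of magnitude
below the gravitational and passive-elastic ones, so the per-axis model is
the smallest plant that still exhibits the gravity-loading and
muscle-redundancy phenomena the package studies.

The gravitational moment is computed exactly: the hand centre-of-mass
offset is rotated by the current wrist angles and crossed with the gravity
force expressed in the forearm frame; the generalized torques project that
moment onto the FE axis (fixed) and the RUD axis (carried by the FE
rotation). At neutral, the moment vanishes in both vertical orientations
and equals \(m g d\) (flexion sense) with the palm down — so the vertical
postures behave as pendulums (inverted, for hand-up) away from neutral,
and the horizontal posture maximally loads the extensors.

### Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| hand mass `m` | 0.4 | kg | adult hand segment mass |
| COM distance `d` | 0.07 | m | wrist centre to hand COM |
| inertia `I` (per axis) | 0.002 | kg m² | hand segment about the wrist |
| passive stiffness `k` | 0.008 | N m/deg | ≈0.46 N m/rad, mid-range published passive wrist stiffness; exceeds the gravitational gradient \(mgd \approx 0.27\) N m/rad so the vertical postures are statically stable, as for a real wrist |
| passive damping `b` | 0.0006 | N m s/deg | ≈0.5–0.6 damping ratio of the passive plant |
| specific tension | 35 | N/cm² | standard mammalian skeletal-muscle value |
| PCSA (FCR…APL) | 2.0, 3.4, 2.2, 2.7, 2.6, 1.9 | cm² | anatomical literature ranges |
| moment arms | see `default_muscle_set()` | mm | anatomical literature; flexors positive FE row, ulnar deviators positive RUD row |
| lower force bound | 2 | N | tonic load keeping tendons taut (the in-vitro analogue is an EMG-derived minimum whose values live in configuration, not in this package) |

All of these are configuration, not ground truth: they ship in
`inst/extdata/default_specimen.yaml` and can be overridden via
`read_specimen_config()`.

## Moment-arm estimation

Passive sweeps move one axis across ±range (200 samples) while every
tendon carries a constant preload (10 N by default) so no tendon unloads;
excursions are recorded against angle. The moment arm about an axis is
minus the slope of excursion versus angle; the *mean* arm over the range is
estimated by a global least-squares slope, which for linear
excursion–angle data is the variance-minimising estimator of that mean.
Row 1 (FE) comes only from the FE sweep and row 2 only from the RUD sweep;
cross-axis information is deliberately not pooled. For constant-arm plants
the estimator is exact (the test suite verifies identity to 1e-9 relative
error); for arms varying linearly with their own angle, a symmetric sweep
recovers the mid-range arm because the odd term integrates out.

## Controllers

Both controllers run at 200 Hz against a 1 kHz plant integration; every
run begins with a 1 s unrecorded settle hold at the start posture, as a
specimen would be positioned before cycling.

**Hybrid control** maps the joint-angle error through the transposed
moment-arm matrix into per-tendon excursion errors, applies PID per tendon,
adds a co-contraction baseline, and clamps each command into
`[f_lower, f_upper]` — position feedback drives the kinematics while the
clamp is the force-feedback guarantee that forces stay physiologic. Two
design details matter and were chosen after observing the alternatives
misbehave:

* *The baseline is torque-free.* An equal 10 N baseline on all six tendons
  carries a net joint torque with realistic (asymmetric) moment arms, which
  the integrator must cancel, skewing the resting force distribution. The
  requested baseline level is therefore projected onto the null space of
  `R`, so resting co-contraction produces no joint torque.
* *Back-calculation anti-windup.* The integrators live in tendon space but
  are driven by a rank-2 signal (`R`ᵀ×joint error). When commands clamp,
  an unguarded integrator can drift through the null space of `R` and
  strand co-contraction in start-condition-dependent patterns. The
  integral state is pulled back toward the clamp with a 0.1 s tracking
  time constant, which makes the periodic force pattern unique and
  repeatable.

**Cascade control** nests force control within position control: an outer
PID on the joint angles (plus a gravity feedforward computed from the
specimen model, on by default — without it the outer integrator must
absorb the entire gravity moment) commands a joint torque; a quadratic
program distributes it to target tensions; an inner first-order force loop
(time constant 10 ms) drives measured tensions toward the targets. The
outer QP re-solves at 100 Hz — slower than the inner loop, as cascade
architectures are built.

The **force-distribution QP** minimises Σ(Fᵢ/PCSAᵢ)² subject to
`R F = τ`, elementwise bounds, and the muscle-impedance constraint
ρ_min ≤ ΣF ≤ ρ_max (defaults 0 and 400 N, leaving ρ effectively
unconstrained). The objective is strictly convex, so the minimiser is
unique whenever the constraints are feasible and no tie-breaking is
needed. The solver is `pracma::quadprog`; the contract is behavioural —
KKT stationarity/complementary-slackness residuals below 1e-6 and
agreement with a brute-force grid search on random small problems — not a
solver identity. When the torque equality is infeasible within the bounds,
the solver returns the bounded force vector whose achieved torque is
least-squares closest to the request (with a vanishing stress regulariser,
1e-9, to keep it unique) and flags the result; flags propagate to the run
metadata.

**Gains** (hybrid `kp = 15`, `ki = 60`, `kd = 0.3` N per mm of excursion
error; cascade `kp = 0.08`, `ki = 0.6`, `kd = 0.003` N m per deg) were
tuned once on the default specimen for stable, chatter-free tracking of
all five motions in all orientations and then frozen; they are tuned
values, documented as such, not measurements. Substantially higher gains
push the loop bandwidth toward the controller Nyquist rate and produce a
chattering limit cycle against the force clamps — a failure mode worth
knowing about when retuning.

## Trajectories

The protocol fixes each motion's endpoints, not its time profile, so the
package uses sinusoidal interpolation per axis — smooth, bandwidth-limited,
and standard for cyclic in-vitro protocols. DTM is a straight segment in
(FE, RUD) space traversed sinusoidally. The circumductions are the
axis-aligned ellipse (30° FE semi-axis, 10° RUD semi-axis) traversed at a
constant phase rate; "clockwise" is *defined* by the corner order flexion →
ulnar → extension → radial (anticlockwise reverses it), removing any
viewing-convention ambiguity. Cycle period defaults to 4 s — the in-vitro
protocol does not pin the speed, so it is an exposed parameter without any
fidelity claim. Each cycle starts at FE = 0 moving toward flexion (toward
ulnar for RUD-10; toward the extension-radial corner for DTM).

## The synthetic cohort

`generate_cohort()` emulates a set of ten specimens: moment-arm
magnitudes, PCSAs, hand mass and COM distance are multiplied by
independent log-normal factors with mean 1 and documented coefficients of
variation (arms 0.12, PCSA 0.15, mass 0.10, COM 0.08 — plausible
anatomical spreads), preserving moment-arm signs by construction and
recomputing each specimen's upper force bounds from its sampled PCSA.
Optional measurement noise (0.1° on angles, 0.2 N on forces) perturbs only
what the controllers see, emulating optical capture and load cells; the
plant itself is noise-free.

What this emulates — and what it does not: real specimens have
posture-dependent moment arms, nonlinear and anisotropic passive
properties, correlated anatomy (PCSA and arms co-vary), tendon friction
and compliance, and extrinsic finger muscles crossing the wrist. None of
those are modelled. Consequently, passing the cohort-level checks shows the
*control and analysis machinery* behaves correctly and that the
gravity-driven orientation effects follow from mechanics; it does not
certify quantitative fidelity to cadaveric force magnitudes. One concrete
example: with constant arms and linear dynamics the only term that is odd
under time reversal is the passive damping, so the circumduction
direction effect on FCR/FCU peak forces is small (well under 1% of the
peak) though consistently signed — a real wrist, with posture-dependent
arms, shows the same signs at far larger magnitude. The package therefore
treats direction effects as sign properties, not magnitudes.

## Statistics

`compare_conditions()` implements the decision procedure used for all
condition comparisons: Shapiro-Wilk normality is computed and reported per
condition, but the nonparametric path is always taken. Two paired
conditions: Wilcoxon signed-rank, exact null for small samples without
ties (n < 50), normal approximation with continuity correction otherwise;
α = 0.05. Three conditions: Friedman at α = 0.05, and only if significant,
pairwise Wilcoxon tests judged at the Bonferroni-adjusted α = 0.017. With
n = 10 specimens the exact regime applies throughout; the test suite
checks the exact p-values against full enumeration of the 2ⁿ sign
assignments up to n = 12. A fully degenerate input (every specimen
identical across conditions) is reported as Friedman statistic 0, p = 1.

## Numerical choices

* Integration: fixed-step semi-implicit Euler, `dt` = 1 ms — deterministic
  and dissipative-to-within-roundoff for these stiffness/damping values
  (the energy test allows 1e-6 per-step slack and requires net dissipation).
* Controller period 5 ms; recording at 100 Hz; these must be integer
  multiples of `dt` and of each other, enforced at run time.
* Waypoint forces are linearly interpolated at crossing instants; the two
  travel directions are kept separate (hysteresis is a real mechanical
  difference), except at a motion's desired extremum, where the tangency
  counts as a single passage. A waypoint never crossed is omitted, not an
  error.
* Peak force over a motion is the mean of per-cycle maxima — robust to a
  single outlying sample; the time-average is taken over all recorded
  samples.
* Determinism: every source of randomness (cohort jitter, measurement
  noise) flows from explicit integer seeds; per-run seeds are derived from
  the experiment seed and run index, so identical seeds give bitwise-equal
  summary CSVs.
* Instability: a run with more than 10% of samples on an anatomical stop
  is flagged in its metadata and warned about, never silently pooled.

## Problem sizes

The shipped test-suite and acceptance runs use the cohort of ten
specimens, five cycles per run at 4 s per cycle, 200-sample passive
sweeps, 500 random instances for the QP oracle comparison, and full grids
of up to five motions × two controllers × three orientations. These sizes
give stable cohort means while keeping a complete run in the minutes
range on one CPU.

## Known limitations

Beyond the cohort-realism caveats above: forearm rotation and ulnar-length
variation are out of scope (the radius-ulna relationship is fixed);
carpal-level and ligament-level kinematics are not represented (the wrist
is a pure 2-DOF joint); parameters are sampled independently because the
true inter-specimen covariance between PCSA and moment arms is unknown;
and the EMG-derived lower force bounds used in vitro are represented by a
flat 2 N configuration value.
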