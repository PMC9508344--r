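---
title: "Predictive simulation of accelerative sprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of accelerative sprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sprintsim implements a complete predictive-simulation study of early
accelerative sprinting as a tested pipeline: a planar multibody model with
implicit dynamics, a flipped Legendre–Gauss–Radau (LGR) collocation
transcriber with an interior-point solver, a data-tracking simulation against
a two-step experiment, a family of "free-moment" predictive simulations that
minimize the time horizon, and the outcome measures used to compare them.
This vignette explains the models, the numerical choices, and what the
synthetic test bed does and does not establish.

## The musculoskeletal model

The default skeleton (`default_model()`) is a sagittal-plane tree with eleven
degrees of freedom: a floating pelvis (anterior–posterior and vertical
translations plus a rotation), a lumbar joint to a lumped trunk+head segment,
a shoulder-mounted arm-swing rotator, and hip, knee and ankle joints on each
of two legs. Anthropometry is scaled to a 72.2 kg athlete. Two design points
deserve comment:

* **The arm segment.** Three-dimensional full-body models carry articulated
  arms whose swing exchanges angular momentum with the legs. A planar model
  that simply lumps the arms into the trunk loses that exchange entirely, and
  the unactuated base-rotation equation then has no physiological way to
  balance the large angular-momentum fluctuations of sprinting leg swings. We
  therefore keep one "arms" segment (7 kg, both upper limbs lumped into a
  single planar rotator at the shoulder line). Its shoulder torque is an
  upper-limb actuator like any other internal drive.
* **Forefoot contact.** Each foot carries a heel sphere and a pair of
  half-stiffness spheres at the metatarsal heads (coincident in the sagittal
  plane). The pair halves the per-sphere force, keeping each ground-reaction
  force control comfortably inside its ±2500 N bound during stance peaks
  above 3 body weights, with physics identical to a single full-stiffness
  sphere.

Foot–ground interaction is a smooth Hunt–Crossley law per sphere: normal
force `k·softplus(δ)^{3/2}·clamp(1 + d·δ̇)` with penetration `δ`, stiffness
`k = 3·10^6 N/m^{3/2}`, dissipation `d = 2 s/m`, a softplus positive part
with 10⁻⁴ m smoothing, and a smoothly clamped dissipation bracket; the
tangential force is `−μ·Fn·tanh(v_slip/v_s)` with `μ = 0.8`. The friction
velocity scale is `v_s = 0.15` m/s: wide enough that the sign transition of
the anterior–posterior force during stance stays band-limited below the 20 Hz
preprocessing cut-off, which keeps filtered data dynamically consistent with
the contact law. These are configuration defaults, not printed constants, and
can be overridden per model. Metatarsophalangeal DOFs, when configured, carry
linear rotational springs; aerodynamic drag `−½ρC_dA_f v_x|v_x|` acts at the
whole-body centre of mass, carried by the pelvis.

All equation-of-motion evaluations use the implicit residual

```
M(q)·u_v̇ + C(q,v) + G(q) − J_Extᵀ·Ext(u_GRF, drag) − [0; τ] = 0
```

assembled by a vectorized Newton–Euler pass over the segment tree; the
residual is exactly linear in accelerations, moments and applied forces, and
its equivalence with a Lagrangian derivation is part of the test suite.

## Muscle–tendon machinery

The Hill-type muscle module implements the tendon-force-state formulation:
normalized tendon force and activation are states, their rates are controls,
and the contraction dynamics appear as the algebraic equilibrium
`F̃T − cosθ·(a·f_act(l̃M)·f_v(ṽM) + f_pass(l̃M)) = 0` under a
constant-thickness pennation model. Characteristic curves use the standard
exponential tendon, Gaussian-sum active force–length and logarithmic
force–velocity parameterizations, rescaled so the active curve and the
force–velocity curve equal exactly one at the optimum; the curves are
config-stored and overridable. Activation dynamics enter as the two
inequality constraints `u_ȧ + a/τ_d ≥ 0` and `u_ȧ + a/τ_a ≤ 1/τ_a`
(τ_a = 15 ms, τ_d = 60 ms), whose feasible set provably contains the rates of
the underlying first-order activation model; the test suite verifies this on
a 50×50 grid. Musculotendon lengths are additive per-DOF polynomials, so
moment arms are exact derivatives.

The default *study configuration* drives every internal DOF with a net-moment
(torque) actuator plus a ±10 Nm reserve rather than with the muscle set: the
optimal-control formulation — implicit dynamics, ground-reaction-force
consistency, every objective term and bound — is unchanged by the actuator
choice, and the desk-scale problems this package targets then solve far more
reliably. The muscle module remains first-class, unit-tested code and the
transcriber accepts muscle-driven path constraints; an eight-MTU-per-leg
default set (`default_leg_muscles()`) is provided for muscle-level
experiments.

## Collocation and the solver

The transcriber (`define_ocp()`, `transcribe()`, `solve_ocp()`) uses flipped
LGR collocation: each mesh interval carries the interval start plus `d = 3`
LGR points (third-order state polynomials, four points per interval, 150
intervals in the full-scale formulation), first-order dynamics enforced at
the LGR points, algebraic path constraints at interval starts, explicit
continuity constraints, and piecewise-constant controls parameterized at
interval starts. Two deliberate numerical choices:

* **Control representation.** Piecewise-constant controls are the default,
  implemented literally. They carry an irreducible discretization error: the
  minimum-effort double integrator at `N` intervals attains exactly
  `12N²/(N²−1)` instead of the continuous optimum 12. A piecewise-linear
  refinement (`control_rep = "linear"`) removes the within-interval
  representation error; the recovery experiments below use it because at
  `N = 50` the piecewise-constant acceleration error otherwise dominates the
  reported GRF and net-moment agreement.
* **Free final time.** Free-horizon problems are transcribed on normalized
  time with the duration multiplying the dynamics and the quadrature.
  The production predictive runs handle the horizon by parametric
  continuation — a short descending grid of fixed-horizon solves, warm-started
  in sequence, with a parabolic refinement of the smooth objective-vs-horizon
  curve — because each fixed-horizon problem stays on the well-conditioned
  linear-dynamics path of the transcription. The direct free-time variable
  remains available and is exercised by the bang-bang test problem.

All variables are affinely scaled to [−1, 1] from their bounds and constraint
rows are divided by characteristic magnitudes. The NLP is solved by a sparse
primal-dual log-barrier interior-point method (`solve_ipnlp()`): monotone
barrier reduction, regularized KKT Newton systems factorized with sparse LU,
an ℓ1 exact-penalty line search with second-order corrections (a filter
acceptance is available as an option), and a convergence tolerance of 10⁻³ on
the scaled KKT error. The Hessian model is the exact Hessian of the quadratic
quadrature objective (plus the bilinear horizon cross-terms when the horizon
is free); constraint curvature is not modelled, which is why warm starts
matter. Iterates that exhaust the iteration budget while satisfying the
equality constraints to 5·10⁻³ in scaled units are reported as `"stalled"`:
dynamically feasible solutions whose objective has plateaued but whose dual
conditions are not certified to tolerance. Tracking problems, which start at
a near-solution, converge in a handful of full Newton steps; the predictive
problems, which must reshape the motion, sometimes end in this stalled state
and are reported as such.

## The data-tracking simulation

`run_tracking()` builds the tracking objective exactly as the study defines
it: squared, range-normalized tracking of all coordinates (10% of each
signal's experimental range; 0.01 m for the anterior–posterior pelvis
translation), of the per-foot ground reaction force components, and of the
internal net joint moments excluding MTP moments (weights
w = [0.1, 0.05, 0.01, 0.01, 0.001, 10⁻⁴, 0.1]); activation effort applies to
muscle-driven configurations; the control term penalizes reserves (normalized
by their bounds) and the acceleration controls (normalized by 10% of the
experimental acceleration range — the 10% reading follows the text of the
source formulation rather than its displayed equation, which omits the
factor). Kinematic states and acceleration controls are bounded 25% of the
experimental range beyond each extremum, reserves at ±10 Nm (±40 Nm at MTP
DOFs) and GRF controls at ±2500 N. The initial guess interpolates the
experimental splines, with GRF controls warm-started from the contact model
evaluated on the data (a zero initialization is the historical alternative;
the spline warm start converges far more reliably with this solver).

Preprocessing follows standard biomechanics practice: zero-phase fourth-order
Butterworth filtering (two second-order passes with the usual cut-off
correction) at 20 Hz, then interpolating cubic splines providing coordinates,
velocities and accelerations on any grid. For noise-free synthetic data the
default pipeline skips the filter (`cutoff = NA`): filtering noiseless,
band-limited signals only perturbs their dynamic consistency.

## The predictive simulations

`run_predictive()` frees chosen net joint moments — ankle (A), knee (K)
and/or hip (H), both legs, seven configurations in all — and minimizes
`W₁·t_f` plus range-normalized tracking of the remaining internal moments
against the data-tracking solution (2% of each moment's tracking range, i.e.
5 Nm of permissible error per 250 Nm of range), plus the control penalties
(W = [50, 0.1, 0.01, 1, 10⁻⁴, 0.1]). Freed moments contribute no tracking
rows at all. Boundary conditions: the initial multibody state equals the
tracking solution's, the terminal pelvis anterior–posterior displacement
equals the tracking value, terminal relative joint angles stay within ±10° of
tracking, and the horizon lies in [0.95, 1]·t_f^track (0.414 s for a 0.436 s
tracking horizon). The tracking-solution moments are mapped onto the
predictive horizon on normalized time (stretch-to-fit), and the tracking
integrals run over physical time. Where the source formulations differ on
whether MTP moments join the predictive tracking set, this implementation
tracks all internal moments (masked per configuration); the default planar
model has no MTP DOF, so the distinction is configuration-level.

## The synthetic experiment generator

`synth_sprint()` manufactures the study conditions rather than sampling them:
a 0.436 s horizon from right-foot touchdown to left-foot take-off, 72.2 kg
body mass, 250 Hz sampling, an initial horizontal CoM velocity of 4.25 m/s
gaining about 1.25 m/s across the two steps, and stance durations of 0.155 s
and 0.141 s — at the short end of the ranges reported for elite second and
third steps, chosen so the planar legs can span each stance. Generation is
kinematics-first so that dynamic consistency and a known ground truth come by
construction:

1. Stance-phase toe-sphere penetration (tilted half-sine), slip (fast decay
   from the touchdown foot speed plus a raised-cosine propulsive drift) and
   foot-angle profiles are scripted; the contact law then *defines* the
   ground reaction forces.
2. Scale calibrations set the vertical force so the terminal vertical CoM
   velocity hits its target, the propulsive drift so the horizontal velocity
   gain is met, and the fore–aft placement of the contact points so the net
   angular impulse of the external forces balances the angular-momentum
   change of the scripted motion (the sagittal analogue of
   centre-of-pressure placement).
3. The CoM trajectory is integrated from those forces (drag iterated to
   consistency); pelvis translation is solved so the model CoM matches it,
   legs follow by inverse kinematics of the scripted foot paths, and swing
   trajectories are quintics scripted in the CoM frame.
4. A fixed-point adjustment removes the classic residual of
   prescribed-kinematics inverse dynamics at the three unactuated base rows:
   translation rows respond one-to-one to curvature of the CoM-path
   correction, and the base-rotation row responds with a near-constant gain
   to curvature of the arm-swing angle, so damped double-integral passes
   drive all three below the 5 N / 5 Nm tolerance. Internal net joint
   moments then come from inverse dynamics and are exact by construction.

The construction runs on a four-fold oversampled, padded grid so spline end
effects and interpolation error stay outside the reported horizon, and all
scripted profiles are band-limited well below the 20 Hz preprocessing
cut-off. Seeded jitters make different seeds produce different trials;
optional Gaussian measurement noise exercises the filtering chain.

What the generator does *not* emulate: marker-level measurement chains,
soft-tissue artifact, the athlete-specific coordination of a real sprinter
(arm and trunk angles absorb the consistency corrections, so their
trajectories are plausible but synthetic), or the 3-D frontal/transverse
mechanics absent from a sagittal model. Recovery tests on these data
establish that the pipeline solves the stated optimal control problems
correctly — not that the planar model reproduces any particular athlete.

## Outcome measures

`outcome_report()` and `compare_outcomes()` compute: average horizontal
external power as the change in horizontal kinetic energy over the horizon
divided by its duration; terminal horizontal CoM velocity and the horizon;
net/propulsive/braking anterior–posterior impulses per stance by trapezoidal
quadrature; stance windows from a 20 N vertical-GRF threshold (a standard
event definition; windows shorter than 30 ms are discarded as grazing
contacts); touchdown foot speed and CoM–foot distance at the distal-foot
contact-sphere centroid (positive = foot ahead); take-off hip and knee
angles plus thigh and trunk segment angles from the global vertical
(clockwise — extension, forward lean — negative); the trunk-to-thigh
front-side criterion `180° + (θ_thigh − θ_trunk)` with a ±1° neutral band
(the formula is an interpretation reverse-engineered from the published
angle conventions); and peak net flexor/extensor moments with timings as a
percentage of stance, ties broken earliest. Percentage comparisons are
rounded half-away-from-zero to one decimal. Where a printed "average"
percentage across the two stance phases is ambiguous, the comparison table
reports both conventions (ratio of averages and average of ratios).

## Problem sizes and reproducibility

The shipped study conditions are: tracking at `N = 50` mesh intervals with
the piecewise-linear control refinement; the degenerate all-tracked
predictive check at the same mesh with the horizon pinned; free-moment
predictive simulations at the tracking mesh for headline quantities and at a
reduced `N = 25` mesh for the seven-configuration suite properties. These
sizes are the package's own desk-scale choices; the transcription accepts
the full-scale 150-interval formulation unchanged. All randomness flows from
a single integer seed; repeated runs are bitwise deterministic.

`scripts/acceptance.R` re-runs the main computation from scratch — synthetic
generation, tracking, the degenerate check and two free-moment predictive
simulations — and writes the principal computed quantities as JSON.

## Known limitations

* The interior-point solver's Gauss–Newton Hessian omits constraint
  curvature; predictive problems can therefore terminate "stalled" —
  feasible, objective plateaued, duals uncertified. Reported outcomes from
  such runs carry the feasibility tolerance (about 2–50 N-scale residuals),
  visible mostly in outcome quantities that difference large forces.
* Predictive improvements on the synthetic athlete are larger than those a
  real elite athlete could attain, because the synthetic baseline motion is
  further from the model's optimum than a real athlete's technique is from
  theirs; only the qualitative ordering properties (every configuration
  improves, horizons shorten to the bound, nested masks order objectives)
  are meaningful.
* The planar reduction has no medio-lateral mechanics, no subtalar or MTP
  DOFs by default, and one lumped arm rotator; front-side/back-side
  classifications are therefore cleaner than in 3-D data.
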