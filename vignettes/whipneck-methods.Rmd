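---
title: "Methods: planar head-neck dynamics, injury criteria and parameter identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar head-neck dynamics, injury criteria and parameter identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`whipneck` implements an efficient planar (sagittal-plane) multibody model
of the head and neck for rear-impact (whiplash) simulation, in the spirit of
the ENM-2D family of models.  The chain runs bottom-up from the first
thoracic vertebra T1 through the seven cervical vertebrae C7..C1 to the head
C0.  T1 is the moving support: its trajectory is prescribed (the sled/torso
input), and the bodies above it respond dynamically.  Masses, planar
moments of inertia (the Iyy column about the out-of-plane axis), inter-body
offsets and initial absolute angles reproduce a 50th-percentile male
occupant model; the chain mass excluding any massless auxiliary body is
7.18 kg.

Conventions: global X anterior (the direction of the sled acceleration),
Z superior, rotation about +Y; flexion (forward rotation) is a positive
relative joint rotation, extension negative.  All table values (mm, deg)
are converted to SI at build time.  Each body's origin is pinned to its
parent by a revolute joint located at the body's own origin; the body
rotates about that point.

Consecutive bodies are coupled by nonlinear torsional springs

$$ M(\theta) = A\,(e^{\theta B} - 1) $$

with separate coefficient pairs for extension ($A_1 < 0$, $B_1 < 0$,
active for $\theta < 0$) and flexion ($A_2, B_2 > 0$), plus a linear
torsional damper $C$ (1.8 Nms/rad at every joint in the initial model;
the identified model carries per-joint values).  $\theta$ is the relative
joint rotation *measured from the initial seated posture*, so all spring
moments vanish at $t = 0$: the occupant starts at rest in equilibrium, and
any other datum would require unstated preloads.  Active musculature is not
modelled; damping is constant in time.

### The modified (prismatic) variant

The modified model inserts a massless auxiliary body Ca between C1 and the
head to decouple the head's axial and transverse motion: C1 and Ca share
one orientation and are connected by a translation joint along the line
from C1's origin to Ca's origin, closed by a linear spring--damper
($k_v$, $c_v$; trial values 10 kN/m and 100 Ns/m, identified values
1620 N/m and 100 Ns/m).  The head revolute joint is relocated onto Ca
while keeping its initial position.

Where exactly Ca sits is a genuinely open design point: the source
material quotes a coordinate pair for Ca that cannot be reconciled with
the body-offset table under any frame convention we tried (its z-value
matches the global height of C1's origin at the initial posture to
0.01 mm, while the x-value matches no candidate frame).  This package
places Ca's origin at the initial position of the head origin.  That
choice satisfies every stated functional requirement exactly: the
relocated revolute joint keeps its initial position, the prismatic axis is
the unit direction from O_C1 to O_Ca in C1's frame, and the elongation
datum (zero spring force at the initial separation) is well defined.  The
massless body leaves the generalized mass matrix positive definite because
the head's inertia sits above it in the chain; this is asserted at build
time.

### Gravity and preload

Gravity (9.81 m/s^2, -Z) is on by default.  Because a seated occupant is
in static equilibrium before the pulse, constant joint preload moments are
computed at build time (from the CG Jacobians at the initial posture) so
that the initial posture is an exact equilibrium; disabling gravity
disables the preload with it.  Without the preload the chain would droop
during the first milliseconds of a simulation.

## Dynamics and integration

The equations of motion are assembled in relative joint coordinates
(8 revolute rotations, plus one prismatic elongation in the modified
variant) by the virtual-power form: $M(q)\,\ddot q = Q(q, \dot q, t)$ with
the mass matrix built from per-body CG Jacobians and the generalized force
collecting gravity, springs, dampers, preload and the support-excitation
remainder terms.  Because gravity is uniform and the springs depend only on
$q$, the prescribed T1 motion enters the equations only through the base
acceleration.

Prescribed motion is stored as a natural cubic spline through the supplied
displacement samples; velocities and accelerations are evaluated from the
interpolant (never by differencing), and the identical piecewise
polynomial is evaluated on the R and compiled sides so every code path
sees the same excitation.  T1 rotation is held constant by default
(translation-only support), with an optional rotation channel accepted for
generality.

Integration uses deSolve's adaptive Dormand-Prince Runge-Kutta 4(5)
(`ode45`) with rtol = 1e-8 and atol = 1e-10, driving a compiled
right-hand side through deSolve's native compiled-function interface, with
dense output on a uniform grid (10 kHz by default, crash-signal practice).
Accelerations and all derived channels (head kinematics, occipital-condyle
loads, energies) are obtained by re-evaluating the equations of motion at
the output times.  Two extra states integrate the damper dissipation and
the support work, so the work-energy ledger

$$ (T + V) - (T + V)(0) = W_\text{prescribed} - D_\text{damping} $$

can be checked at every output sample; the test suite requires closure to
1e-5 relative on damped, base-excited 300 ms runs of the identified model
(observed residuals are orders of magnitude smaller).

Two independent oracles guard the assembly: on two-body chains the
accelerations must match the textbook planar double-pendulum closed form to
1e-9 relative, and on the full chain the accelerations and the
occipital-condyle reaction must match an independently derived
absolute-coordinate Lagrange-multiplier formulation (1e-6 N on forces).

### Occipital-condyle loads

OC loads are recovered by inverse dynamics of the head body alone
(Newton-Euler on C0 from its CG and angular accelerations): the joint
reaction expressed in the head frame (Fx anterior shear, Fz normal) and
the internal moment My transmitted at the OC revolute joint (positive
flexion).  The head-local frame is a choice; the source material does not
state the frame of its plotted OC forces.

## Injury criteria

HIC uses the universal convention (resultant head CG acceleration in g,
time in seconds):

$$ \mathrm{HIC} = \max_{t_2 - t_1 \le w}\;(t_2 - t_1)
   \left[ \frac{1}{t_2 - t_1}\int_{t_1}^{t_2} a\,dt \right]^{2.5} $$

with $w$ = 36 ms for impacts without direct head contact.  The search runs
over grid-point pairs with trapezoidal integration, accelerated by
cumulative sums over window lengths; the tests require bit-exact agreement
with an exhaustive $O(n^2)$ search.  At the default 10 kHz sampling the
grid-restriction error is negligible.  No channel filtering is applied by
default, since the source states none.

The Nkm criterion combines normalized OC shear and sagittal moment with
the intercept constants $F_{int} = \pm 845$ N and $M_{int} = 88.1$ Nm
(flexion) / $-47.5$ Nm (extension).  Each of the four cases
(Nfa, Nfp, Nea, Nep) sums only sign-matching contributions at each instant
(e.g. $N_{ep}(t) = \max(-F_x,0)/845 + \max(-M_y,0)/47.5$), and the
time-maximum of each case is reported.  This sign-gated reading is the
standard interpretation of the four-case scheme; the constants but not the
gating are stated in the source.

## The synthetic reference

The reference occupant simulation that the original identification used is
proprietary (a TNO-HBM / MADYMO sled run), and its T1 trajectory is not
published.  The `synthref` module therefore generates the study conditions
parametrically: a haversine crash pulse with the stated scalars of the LAB
sled scenario (peak 12 g, delta-V = 10 km/h, closed-form duration
$2\Delta V / a_\text{peak} \approx 47.2$ ms), double-integrated into a
monotone T1 anterior displacement with zero vertical motion, and reference
kinematics (per-body absolute angles, OC-point displacement relative to
T1) produced by simulating a model with known parameters.  Optional
additive white Gaussian noise per channel is seeded and does not touch the
global RNG stream.

What this emulates: the kinematic channel set, sampling and pulse scale of
a rear-impact sled reference.  What it does not: seat-back interaction,
T1 rotation and vertical motion, soft-tissue behaviour of the full
occupant model.  Consequently the published absolute criteria values
(HIC36 = 137.7 etc.) are *not* reproducible here — only the printed
deviation arithmetic is — and passing tests demonstrate correctness of the
pipeline on self-consistent synthetic data, not biofidelity against the
proprietary reference.

## Identification

Objectives are RMS deviations between simulated and reference channels
over the full window, on the reference grid: per-body absolute angles
(w.r.t. the horizontal) for the baseline schedule, and for the modified
model the radial RMS of the OC displacement (x and z combined) plus the
head angle.  The multiobjective problem is decomposed into a sequence of
single-objective bounded optimizations, bottom-up from C7 to C0; one full
pass is a sequence, and sequences repeat until no objective improves by
more than 1% (default cap 6).

The optimizer is L-BFGS-B on variables scaled by their reference values
(so every box is [0.75, 1.25]), with finite-difference gradients at 1e-3
relative steps — a bounded gradient-based local method standing in for the
proprietary MMFD, which the source itself notes is replaceable.  Each step
is guaranteed monotone on its own objective: if the optimizer terminates
on a worse iterate the starting point is kept and flagged.

Bounds are re-centred on each step's starting values rather than fixed at
the original preset.  This is a deliberate design choice: the published
final coefficients lie up to about 3x their initial values, which is
unreachable inside a single fixed 25% box but consistent with 25% boxes
re-centred over five sequences.

The 25% sensitivity screen perturbs one design variable at a time and
records the relative change of every objective.  It reproduces the
expected locality structure: a joint's parameters influence the bodies
above it far more than those below it, which is what justifies the
bottom-up sequential decomposition.

### Identifiability under the synthetic conditions

Two structural limits of the study conditions matter when interpreting
recovery experiments, and both are verified by the test suite:

* Under a translation-only T1 pulse the lower cervical joints remain in
  extension for the whole 300 ms (retraction-phase kinematics), so the
  flexion-branch coefficients (A2/B2) of the lowest joints have exactly
  zero sensitivity and cannot be recovered from such a reference.  A
  reference whose T1 motion includes the torso's rearward rotation would
  exercise the flexion branch.
* The exponential pair (A, B) is sloppy: the RMS objective has a shallow
  valley along the linearized-stiffness product $A \cdot B$, with a floor
  of order 1e-4 rad.  Individual A/B values are therefore weakly
  identified, while the product — and the damping C, which acts through an
  independent rate channel — recover to well under 5% for the one joint
  whose spring moments are dynamically significant (C7/T1).

The acceptance-style recovery test states the published-schedule check
faithfully (and documents where the conditions cannot meet it) alongside
assertions on the quantities the conditions can support: per-step RMS
monotonicity, damping recovery, and stiffness-product recovery.

## Numerical choices and problem sizes

* Integrator tolerances rtol 1e-8 / atol 1e-10; 10 kHz dense output for
  criteria-grade runs, 1 kHz grids for identification objectives and
  reference channels.
* Model tests and oracle comparisons use 25-100 random states per
  configuration; the recovery experiment uses one 25-variable sequence on a
  300 ms, 1 kHz noiseless reference.  These sizes were chosen to exercise
  every branch of the assembly while keeping a full test run in a few
  minutes.
* Ties and degenerate inputs: the spring law is continuous (both branches
  vanish at zero); a zero-length HIC window or non-uniform grid is an
  error; a delta-V of zero produces an identically zero pulse and motion.
* Determinism: identical inputs give bit-identical simulation channels;
  all noise flows through an explicit seed.

## Limitations

The model is planar, passive (no musculature), and validated only in the
sense of the internal oracles and synthetic-reference experiments above;
it has no head-restraint or seat-back contact, so late-time kinematics
(beyond roughly 140 ms, when head-to-backrest contact would typically
occur) overstate the head excursion.  It is a preliminary-design tool, not
a substitute for full occupant models or experimental testing.
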