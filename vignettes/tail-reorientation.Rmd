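---
title: "Modeling mid-air tail reorientation in gliding geckos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mid-air tail reorientation in gliding geckos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailspin)
```

## The problem

A gecko that loses its footing tens of metres up has one large appendage
to work with: its tail. While airborne it can reorient in two distinct
ways. First, inertially: with no net external torque, total angular
momentum about the system centre of mass is conserved, so rotating the
tail one way rotates the body the other way, instantaneously and
regardless of airspeed. Second, aerodynamically: once the animal is
falling fast, pitch or roll deviations from the equilibrium glide posture
generate restoring torques, a slow pathway whose effect accumulates with
tail *position* rather than tail *rate* and therefore trails it in time.
This package implements a minimal but complete modeling stack for both
pathways — a segmented morphology, a free-floating two-body simulator, a
planar swing protocol with tail-length scaling, a trajectory optimizer,
a wind-tunnel kinematics pipeline with a matched synthetic-data
generator, and terminal-velocity ballistics.

## Morphology

The animal is assembled from uniform-density primitives: a rectangular
prism torso, four cylindrical legs in a dorsally splayed "skydive"
posture, and a solid cone tail attached base-first at the vent. Mass
properties are closed-form (the cone's COM sits a quarter length from the
base; its axial moment is $\tfrac{3}{10} m r^2$) and are verified in the
test suite against a brute-force voxel integrator at $10^6$ voxels to
0.5%.

The default parameterization pins every externally known quantity of the
*H. platyurus* study animal: total mass 2.85 g, snout-to-tail-tip length
9.86 cm, tail:SVL ratio 0.93, tail mass fraction 0.10. (The printed total
length is interpreted as centimetres — a 9.86 mm, 2.85 g gecko would be
denser than lead; the YAML config notes this assumption.) The remaining
shape parameters are declared package defaults, chosen to be anatomically
reasonable for a ~5 cm-SVL gecko: torso 5.11 × 1.2 × 0.45 cm, legs
1.5 cm × 1.5 mm radius splayed 30° dorsally, tail base diameter 4.5 mm.
Tail rescaling (`scale_tail()`) holds base diameter and material density
constant, so tail mass grows linearly with length — the convention used
throughout the scaling study. Autotomy is the same transform with a
fraction below one.

## Free-floating dynamics

Let $\omega$ be the body angular velocity (body frame) and $q$ the two
tail joint angles. Writing the kinetic energy with the translational DOFs
eliminated through the centre-of-mass constraint gives a configuration-
dependent $5\times5$ mass matrix with blocks $M_{\omega\omega}(q)$,
$M_{\omega q}(q)$, $M_{qq}(q)$. The rotational dynamics are integrated in
momentum form (the Euler–Poincaré equations of a shape-changing free
body):

$$\dot L = \tau_{\mathrm{ext}}, \qquad
\omega = M_{\omega\omega}^{-1}(L_b - M_{\omega q}\,\dot q),$$

with $L$ the total angular momentum about the system COM in the inertial
frame and $L_b$ its body-frame image. Two consequences follow by
construction: with aerodynamics off, momentum conservation holds to
solver roundoff (observed drift $\sim 10^{-21}$ kg m²/s, versus the
$10^{-6}$ relative bound the tests demand); and a kinematically
prescribed tail trajectory needs only the quaternion and $L$ as states.
Torque-driven joints add the shape momenta $p_q$ with
$\dot p_q = \partial T / \partial q + \tau_{\mathrm{joint}}$, where
$\partial T/\partial q$ is evaluated by central differences of the
analytic mass-matrix blocks (step $10^{-6}$ rad; the error enters the
forces at $\sim10^{-12}$ and never touches the momentum equation).

Conventions, fixed once and tested: quaternions map body to inertial
frame; Euler angles are Z–Y–X (yaw $\psi$, pitch $\alpha$, roll $\beta$);
translation is decoupled and ignored (gravity exerts no torque about the
COM of a free body); the joint axes are configurable, defaulting to
yaw+pitch for planar studies and **roll-outer / pitch-inner** for
two-axis trajectories. The nesting matters: with roll innermost, that DOF
would only spin the axisymmetric cone about its own axis and the tail tip
could never leave the sagittal plane, making body yaw unreachable.

The aerodynamic pathway is a pair of linear torsion spring-dampers on
body pitch and roll, applied as generalized forces
$-(C_1\alpha + C_2\dot\alpha)$ and $-(C_1\beta + C_2\dot\beta)$ conjugate
to the Euler angles and mapped to a body torque, which leaves yaw exactly
unconstrained (the world-$z$ torque component is identically zero). The
sign is restoring — written as printed elsewhere, a positive $C_1$ would
be destabilizing, contradicting the equilibrium-glide narrative the model
abstracts. `default_aero_params()` sets $C_1, C_2$ so the linearized
rigid-animal pitch mode is underdamped with a 0.5 s period and damping
ratio 0.3 — an order-of-magnitude representation of the short-period
oscillation of a ~3 g glider; both constants are user-visible. The test
suite verifies a small-angle pitch release against the damped-harmonic
closed form, and conservation of $T + \tfrac12 C_1(\alpha^2+\beta^2)$
when $C_2 = 0$.

Integration: the reference path uses `deSolve` (lsoda, rtol $10^{-9}$ /
atol $10^{-12}$, quaternions renormalized at output samples); the
kinematic-drive fast path is an own Dormand–Prince RK5(4) in C++
(RcppArmadillo) driven by exact natural-spline coefficients, needed
because the trajectory search runs hundreds of short simulations. The
two engines agree to $\sim10^{-9}$ in the quaternion, and both agree with
an independent fixed-step planar oracle to well under 0.1° on planar
maneuvers.

## Planar swing protocol and tail-length scaling

For a tail sweeping in a plane through a principal axis the dynamics
reduce to body angle $\theta$ and relative tail angle $\phi$ with the
zero-momentum coupling

$$\dot\theta = -G(\phi)\,\dot\phi,\qquad
G(\phi) = \frac{I_t + \mu c^2 + \mu d c\cos\phi}
               {I_b + \mu d^2 + I_t + \mu c^2 + 2\mu d c\cos\phi},$$

($\mu$ the reduced mass, $d, c$ the COM–joint arms). The protocol applies
a constant joint torque until the tail crosses 90°, then the equal
opposite torque; by work–energy balance the tail comes to rest exactly at
180° (event detection on the rate, residual below $10^{-3}$ rad/s), though
*not* at twice the switch time — the effective inertia grows along the
sweep. Maneuver speed is |body angle change| / duration. Two exact
properties anchor the tests: the body angle change is invariant to the
torque magnitude, and the duration scales as $1/\sqrt{\tau}$.

The published protocol holds actuator torque constant but never states
its value, so the package calibrates it once: the default (ratio 0.93)
morphology is pinned to a 60 °/s maneuver speed — the observed planar yaw
turning rate for this species — giving $\tau = 2.02\times10^{-5}$ N m,
and every other planar result is then a prediction. Under these
conditions the 180° swing turns the body 10.85°, the scan over ratios
0.25–6.0 (`scripts/acceptance.R`) shows monotone angle gain, diminishing
speed returns above ratio ~2, and an interior maneuver-speed maximum at
ratio 5.85; lengthening the tail from 0.93 to 1.80 body lengths raises
maneuver speed by 104%, and truncating it to 40% (autotomy) leaves 31% of
the turning rate.

**Known mismatch.** Published figures for this system report a ~50%
speed increase between ratios 0.93 and 1.80 (60 vs 90 °/s), a halved
turning rate at 40% tail length, and an optimum at 5:1. No morphology in
this model family that also satisfies the pinned totals reproduces those
three numbers simultaneously: a sensitivity sweep over body yaw inertia
(0.05–8×) and COM–vent distance (0.5–1.5×) shows the +50% figure requires
a body inertia and COM placement physically impossible for a uniform
torso of the stated SVL, while the 5:1 optimum and the halving pull the
same parameters in opposite directions. The likeliest explanations are
that the published cross-species comparison used species-specific body
models (the two species differ in more than tail length) and unpublished
appendix parameters. The package keeps the declared morphology rather
than tuning it per outcome, and its planar acceptance checks report the
model's own values.

## Trajectory optimization

A candidate tail motion is six collocation points — three pitch, three
roll, each in ±180° — at equally spaced knots over a 0.5 s stroke,
interpolated by natural cubic splines pinned to zero at both ends (the
stroke is cyclic; the tail then holds neutral until the pose is read at
1 s). The optimizer is a real-coded genetic algorithm: population 20,
20 generations (generation 1 is the evaluated random population, so the
search costs exactly 400 simulations), tournament selection ($k=2$),
BLX-0.5 crossover (rate 0.9), per-gene Gaussian mutation (rate 0.2,
σ = 20°), elitism of one — standard choices for a 6-dimensional bounded
real search, made explicit because the original operators are not
published. The objective, also a declared choice, is
$|\psi(1\,\mathrm{s}) - 30°| + 0.5(|\alpha| + |\beta|)$; the weights are
configurable and the qualitative conclusions below are insensitive to
them within reason. Fixed seeds give bit-identical results, and the
best-so-far trace is non-increasing by elitism.

With the restoring springs on, the search reliably reaches the 30° yaw
target (final fitness ≲ 1 on most seeds). Stroke complexity is measured
as direction reversals of the joint rate (episodes below 20% of the peak
rate do not count as strokes). The expected qualitative contrast — that
aerodynamic recovery permits simpler strokes than the conservative case,
which must close its pitch/roll residuals by figure-eight-like motion —
appears only as a tendency here (aero-on ≤ aero-off reversals in ~9/10
paired seeds, strictly fewer in ~5/10). The cause is the same weak tail
authority discussed above: at this coupling a 30° yaw needs large
two-axis strokes with or without springs, so the "one simple sweep"
regime (which hand-probed sweeps show topping out near 15° yaw) is not
reachable and both searches land in the complex-stroke region.

## Wind-tunnel kinematics

Angles follow the tracking conventions of the experiments: body angle is
the camera-frame direction of the vent→snout line; tail angle is the
signed (CCW-positive) angle of the vent→tail-tip line relative to the
caudal body direction, zero when the three landmarks are collinear. Both
are unwrapped. The reader accepts a flat CSV dialect and DeepLabCut-style
three-row headers, refuses duplicated or non-monotone frames, reports
gaps rather than interpolating, and optionally applies a scalar pixel
calibration from the mean tracked body length.

Cross-correlation resamples both series to a uniform 4 ms grid (cubic
interpolation; source videos span 205–300 fps), removes means, computes
the Pearson correlation at every integer shift within the window, and
refines the magnitude peak parabolically, reporting lag with positive =
body follows tail. (The sign convention is fixed by the causal picture —
aerodynamic forcing by tail position makes the body *lag* the tail;
instantaneous inertial coupling gives zero lag.) Swing segmentation takes
maximal single-sign intervals of the smoothed tail rate (zero-phase
5-sample moving average) passing 10° amplitude and 50 ms duration
thresholds; swing regression fits per-swing body angle change on tail
angle change by least squares.

The synthetic generator closes the loop: it programs alternating
cosine-eased tail strokes, renders snout/vent/tail-tip pixel tracks at
250 fps with Gaussian noise, and couples the body by pathway —
instantaneous (`inertial`), delayed (`aero`), or a weighted mix. Two
deliberate abstractions: the aerodynamic pathway is realized as an
explicit transport delay (body ∝ −k·tail(t−lag)) rather than a true
position-integral response, because recovery tests need an unambiguous
ground-truth lag; and an optional smooth extraneous body rotation
(`body_disturbance_deg`) emulates the aerodynamic rotations from feet and
posture that keep real swing regressions well below a perfect fit. With
disturbance 14°, mix 0.6, 1 px noise, the median swing-regression R²
over 20 seeds sits near the 0.57 observed in animals — a statement about
the generator's calibration, not a validation against the (unavailable)
animal videos. What passing these tests shows is that the *pipeline*
recovers known coupling, lags (median error under one 250 fps frame over
8–40 ms programmed lags) and swing counts; it cannot show that real gecko
data have those parameters.

## Ballistics and scaling laws

Quadratic-drag free fall from rest obeys
$\dot v = g(1 - v^2/v_t^2)$ with
$v_t = \sqrt{2mg/(\rho C_d A)}$, giving the closed-form drop distance
$x(f) = (v_t^2/2g)\ln\!\big(1/(1-f^2)\big)$ to reach a fraction $f$ of
terminal speed (tests confirm it against an independent ODE integration
to $10^{-6}$ relative). With the glide parameters 2.9 g, 890 mm² and the
typical glide speed 6 m/s taken as terminal speed, the drag identity
gives $C_d = 1.45$ — the reported 1.9 for the same inputs is not
recoverable from the standard formula and is therefore documented but
never asserted — and the distances to 75% and 95% of terminal speed are
1.52 m and 4.27 m. The distance calculation deliberately uses the printed
6 m/s directly: only that choice approximates the published 1.6 m / 4.1 m
pair, whose exact constants are unavailable.

The torque scaling laws are demonstrated numerically: over a two-decade
geometric series of scaled morphologies, available inertial torque
(muscle cross-section × lever arm) fits a log-log slope of 3.00 and
available aerodynamic torque (terminal dynamic pressure × area × lever,
with $v_t^2 \propto$ mass/area) a slope of 4.00 under isometry, and 1 / 2
when only lengths scale — matching the closed-form exponents.

## Numerical choices and test problem sizes

Default tolerances: rtol $10^{-9}$/atol $10^{-12}$ for reference
simulations, $10^{-10}$/$10^{-13}$ for the planar event-driven swing,
$10^{-6}$–$10^{-4}$ for trajectory-search evaluations (the pose objective
is insensitive below that). Degenerate inputs error early: non-positive
dimensions, over-specified mass/density, coincident landmarks (named by
frame), out-of-bounds collocation points, fractions ≥ 1 of terminal
speed. The test suite sizes are chosen for a single CPU: $10^6$-voxel
oracles on a handful of shapes, 3–5 random morphologies per property,
50-seed lag recovery, 20-seed R² calibration, and 10 paired GA runs; the
complete suite runs in about three minutes.

## Limitations

Rigid bodies only — at large tail-length ratios (the scan extends to 6:1)
a real tail bends and the model's optimum is an extrapolation. The
aerodynamic model is a linearized spring-damper on pitch/roll with no
dependence on tail position, no translational glide path, and no lift
model. The Euler-angle torque mapping degrades near ±90° pitch (guarded,
but trajectories that pass through gimbal lock with springs enabled are
outside the model's intended regime). And as documented above, the
default morphology — every printed total honoured — does not reproduce
the published planar scaling figures; users comparing against those
numbers should read the mismatch analysis first.
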