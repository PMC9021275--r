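---
title: "Model and methods: a lophotrichous bacterium in Stokes flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a lophotrichous bacterium in Stokes flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lophoswim` simulates a single-cell model of a lophotrichous bacterium such
as *Pseudomonas putida*: a rigid capsule-shaped cell body propelled by one
effective polar flagellum (the tuft is treated as a single bundle).  The
flagellum is an unconstrained Kirchhoff rod — a centreline $X(s,t)$ with an
orthonormal director frame $\{D^1, D^2, D^3\}$ — comprising a short
compliant *hook* and an intrinsically left-handed helical *filament*.  A
rotary motor embedded at one cell pole applies a prescribed torque
$\tau(t)$ about the local surface normal $E(t)$; positive $\tau$ drives
counterclockwise (CCW) flagellar rotation, negative $\tau$ clockwise (CW),
and $\tau = 0$ is a pause.  Everything is immersed in zero-Reynolds-number
flow via the method of regularized Stokeslets, so the swimmer is force- and
torque-free as a whole.

Units are grams, micrometres and seconds throughout
($\mu_\text{water} = 10^{-6}$ in these units).

### Rigid body by penalty coupling

The body surface carries two marker sets: fluid-side markers $X^b_i$ that
move with the local flow, and rigid markers $Y^b_i = T + R\,Z_i$
reconstructed from reference markers $Z_i$ (with $\sum_i Z_i = 0$), a
centroid $T(t)$ and a rotation $R(t)$.  Marker pairs are tied by stiff
springs $F^b_i = K(X^b_i - Y^b_i)$; the negated spring forces are body
forces on the fluid.  Because the body is massless, $T$ and $R$ solve the
quasi-static balance of spring forces and external loads each step: $T$ in
closed form, $R$ by a warm-started Newton iteration on an incremental
rotation vector (the spec of this iteration is this package's own choice;
it is validated by exact recovery of known rigid transforms and by residual
contracts of $10^{-10}$ relative scale).

### Kirchhoff rod

Internal force and torque resultants follow the standard constitutive
relations with bending/twist moduli $a_1 = a_2 = a$, $a_3$ and
shear/stretch penalties $b_i$, measured against intrinsic strains
$(\Omega_i, \Gamma_i)$ on a staggered grid: resultants live at segment
midpoints (with midpoint triads given by the exact half-rotation between
neighbouring triads), force/torque densities back at the markers.  Two
discrete choices matter:

* the intrinsic strains are *measured from the discretized reference
  configuration with the same operators*, so the reference helix is an
  exact discrete equilibrium (to round-off), not merely an $O(\Delta s^2)$
  one;
* the positional part of the scheme is exactly variational: the force
  density satisfies $f_j\,\Delta s = +\nabla_{X_j} E_\text{rod}$, which the
  test suite verifies against central-difference gradients of the energy.
  (The sign is the "holding-force" convention of the balance equations: the
  force the rod applies to the fluid is $-f$, and marker slip is
  $-(1/\alpha_1)f$; both channels dissipate the elastic energy.)

### Motor, clamp and alignment

The motor applies the ghost internal torque $N(-\Delta s/2) = -\tau E$ at
the proximal stencil boundary; through the staggered difference the
rod-plus-fluid system receives $+\tau E$ and the same ghost value $-\tau E$
is applied to the body, which therefore counter-rotates (action–reaction
holds exactly per step).  Two penalty constraints complete the motor: a
stiff clamp spring ($K_c$) holding $X(0)$ at the pole marker, and the
alignment feedback moment $\tilde n = -K_m(E \times D^3(0))$ keeping the
proximal tangent normal to the surface.  In the holding-torque convention
the restoring moment enters the density as $n(0) \mathrel{-}= \tilde
n/\Delta s$, so the rotlet source carries $+\tilde n$; a tilt-relaxation
experiment (15° initial misalignment decaying monotonically) is part of the
design validation.

### Fluid: regularized Stokeslets, rotlets, and an exact wall image system

All sources use the blob
$\psi_\varepsilon(r) = 15\varepsilon^4 / (8\pi (r^2+\varepsilon^2)^{7/2})$.
The velocity of a point force is the classical regularized Stokeslet for
this blob; point torques enter as $\tfrac12\nabla\times(T\,\psi_\varepsilon)$,
whose closed-form velocity (regularized rotlet) and angular velocity
$w = \tfrac12\nabla\times u$ were derived analytically and are validated in
the tests against singular far-field kernels and finite-difference
divergence/curl oracles.

For runs above a no-slip plane wall ($z = 0$) the package uses an image
system that is *exact*: for a regularized source at height $h$, singular
image elements (Stokeslet, potential dipole, source-derivative doublets and
rotlets) are placed at depth $d = \sqrt{h^2+\varepsilon^2}$ below the wall.
Because $\rho^2 + h^2 + \varepsilon^2 = \rho^2 + d^2$ on the wall, the
regularized denominators of the primary field match the singular
denominators of the images, and the coefficients can be (and were) solved
for exact cancellation; the residual wall velocity is at round-off
($\sim 10^{-16}$ relative), not merely within a truncation tolerance.  The
derivation was performed symbolically and verified in exact rational
arithmetic; the generated code is `src/wall_image_gen.h`.

### Steric interactions

Flagellum–body contact is prevented by a linear short-range repulsion of
magnitude $C\max(1 - d/D, 0)$ per unit arc length between marker pairs
closer than $D$, switched off for rod arc coordinates $s < L' = 0.4545$ (the
proximal region that legitimately passes near the pole).  As printed, the
source equations would push the rod *toward* the body through both the slip
and the spreading channel; the package implements the (clearly intended)
repulsion consistently in both.  Wall contact uses
$c_w \max(1 - z/D_w, 0)\,e_z$ with $c_w = 2$, $D_w = 0.09$; the wall force
is also spread to the fluid by default (`wall_spread`, configurable).

### Time stepping

Explicit first-order updates of Eqs. of motion with slip coefficients
$\alpha_1, \alpha_2$ (translation) and $\beta$ (rotation); triads are
rotated by the exact rotation map about
$w - (1/\beta) n_3 D^3$, which preserves orthonormality to round-off over
millions of steps.  The entire step is implemented in compiled code; the
pairwise kernel evaluation is the dominant cost and scales quadratically in
the marker count.  On blow-up a run is retried once with half the step.

## Parameters

A few parameters have established reference values for this organism and
model class: $a = 0.003$ (filament bending, comparable to measured
flagellar rigidities), $a^\text{hook} \in [a/50, a/10]$ (default $a/25$),
$c = 2$, $L' = 0.4545$, $c_w = 2$, $D_w = 0.09$, $\mu$ (water), and the
benchmark torques $\pm 0.002$ and $-0.004$.  The remaining physical and
numerical parameters are this package's own reference choices, selected
once so that the benchmark behaviours reproduce (push at $+0.002$ with
$V_f > 0$, pull at $-0.002$ with $V_f < 0$, body counter-rotation, and a
CW super-critical transition above the pull branch) and then frozen:

| parameter | value | note |
|---|---|---|
| body | $2.4 \times 1.0\ \mu m$ capsule | ~70 surface markers |
| helix | $R = 0.35$, pitch $1.76$, axial filament length $4.2$ | contour $\approx 7\ \mu m$, left-handed |
| hook | $L_h = 0.2$, bending $a/25$ | twist modulus uniform $a_3 = a$ |
| $b_{1,2,3}$ | 0.5 | near-inextensible (steady strain < 1%) |
| $K, K_c, K_m$ | 1, 3, 0.3 | penalty/clamp/alignment stiffnesses |
| $\alpha_1, \alpha_2$ | $2\times10^{-4}$ | translational slip |
| $\beta$ | $6\times10^{-6}$ | rotational slip |
| $\varepsilon_f$ | $= \Delta s$ | flagellar blob width |
| $\varepsilon_b$ | $0.9 \times$ body marker spacing | body blob width |
| $\Delta s$ | 0.2 (production-scale 0.0303 available via config) | desk-scale resolution |
| $\Delta t$ | $1.25\times10^{-7}$ s | explicit-stability bound |

The hook length deserves a note.  The hook's torsional buckling threshold
scales as $a^\text{hook}/L_h$; with the benchmark torque $0.002$ and
$a^\text{hook} = a/25$, hooks longer than about $0.35\ \mu m$ buckle
already in the push benchmark, which must remain a stable push mode.  $L_h = 0.2$ (one marker spacing, and physically in line with
real hook lengths of order $0.1\ \mu m$) keeps both directed benchmarks
(push at $+0.002$, pull at $-0.002$) stable with the correct speeds,
frequencies and counter-rotation at desk-scale resolution.

At the default resolution the benchmark runs give a steady push of
$V_f \approx +9\ \mu m/s$ at $f \approx +102$ Hz (body roll $-26$ Hz) and a
steady pull of $V_f \approx -11\ \mu m/s$ at $f \approx -83$ Hz (body roll
$+26$ Hz); speed and frequency grow linearly with $|\tau|$ within a branch.

### Desk-scale limitation: the wrapping transition

The wrapping mode could not be reproduced at desk-scale resolution, and the
package reports this honestly rather than imitating it.  The reason is
geometric: the wrapping transition concentrates a near-$180°$ hairpin fold
in the soft hook, whose equilibrium curvature $\sim M/a^\text{hook}$ is of
order $30\ \mu m^{-1}$ — representable at a production marker spacing of
$\Delta s \approx 0.03\ \mu m$ but far beyond a $0.15$–$0.3\ \mu m$ spacing,
where the fold collapses onto a single joint.  Three mitigations are built
in and documented because they materially improve robustness even where
they do not rescue the transition: a rotation-vector strain measure with
per-segment quaternion continuity (joints cannot silently "skip a tooth"
through the antipode), a smooth fold-angle barrier (`fold_barrier`), and a
short motor-torque blend at schedule transitions (`tau_ramp`).  With these,
a CW torque above the (desk-scale) critical value drives the cell into a
rapidly spinning whirl state instead of the coiled wrap: the motor's twist
flux dissipates in a material-spin channel whose resistance is set by the
blob self-mobility and the slip coefficient rather than by a resolved coil.
Consequently the wrapping benchmark, the wrapped-state rotation period and
the wrapping-based reorientation statistics fail their acceptance checks at
this resolution; the corresponding tests are kept failing rather than
weakened.  Production-scale resolution can be configured
(`helix_spec(ds = 0.0303)` with a correspondingly small `dt`), but such
runs are far beyond desk scale.

## What the synthetic fixtures emulate

`make_synthetic_trajectory()` builds trajectories with closed-form truth —
helical-then-straight paths for the reorientation analytics, monotone or
oscillating heights for the wall classifier, uniform runs for the speed
definition.  They exercise the analytics contracts exactly but contain no
hydrodynamics: passing them shows the measurement pipeline is correct, not
that the simulator reproduces any particular trajectory.

## Design choices in the analytics

* Steady detection: windowed means of $V_f$ and the motor rate must agree
  within 5% between consecutive windows through the end of the run.
* Mode classification: wrap fraction = fraction of flagellar markers
  (beyond $L'$) inside a cylinder of radius (body radius $+ 2D$) around the
  body axis and axially overlapping the body; threshold 0.5 separates
  wrapping/overwhirling from pull/push given the motor sign.  The
  thresholds are configurable; the three benchmark runs are the
  calibration gate.
* Turn angle/longitude: the pre-switch direction is the net displacement
  over an integer number of rotation periods of the pre segment (exact for
  an ideal helix; the principal axis of the positions, an alternative
  definition, degenerates when the coil radius exceeds the axial travel, as
  it does for slow wrapping paths).  The longitude is measured in a fixed
  frame whose polar axis is the pre direction and whose x-axis is the
  projected lab x-axis (fallback y-axis), shared across a sweep so that
  longitude differences are frame-independent.
* Wall outcome: escaping iff the final height exceeds twice the body length
  and the mean height slope over the final 20% of the run is positive.

## Known limitations

* Single effective flagellum; no chemosensory switching (schedules are
  prescribed).
* No filament polymorphism (the filament stays left-handed) and no
  self-contact of the flagellum with itself.
* The explicit stepper requires $\Delta t$ near the stability bound of the
  stiffest penalty; production-resolution runs ($\Delta s \approx 0.03$) are
  possible through the configuration but are not desk-scale.
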