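---
title: "Simulating foot mechanics during stance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating foot mechanics during stance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pedsim is a reduced-order, anatomically structured forward-dynamics model
of the human foot. It simulates how a 23-bone skeleton, suspended in
tension-only ligaments and a plantar aponeurosis and standing on a bed of
nonlinear viscoelastic soft-tissue columns, interacts with a rigid
frictional floor — under three loading protocols: cadaveric-style axial
compression, two-stage quiet standing, and marker-driven stance with
prescribed muscle forces. This vignette explains the model, its
assumptions, the numerical choices, and what the synthetic data can and
cannot show.

## The mechanical model

### Units and frames

Everything internal is expressed in millimetres, grams and milliseconds.
In this system forces come out in newtons and stresses in megapascals, so
constitutive constants quoted in MPa can be used without conversion.
Gravity is 9.81 m/s^2 (9.81e-3 mm/ms^2). Global axes at build time are x
anterior, y medial, z superior; the floor is the plane z = 0. Each
bone-fixed frame coincides with the global axes in the build posture, so
the build posture is the zero of every joint angle.

### Skeleton

`build_foot()` constructs 23 rigid bones — tibia, fibula, talus,
calcaneus, navicular, cuboid, three cuneiforms, five metatarsals, the two
hallucal phalanges, one fused phalangeal segment per lesser ray (2-5),
and three sesamoids — as oriented ellipsoids carrying watertight
triangulated surfaces, landmarks, and every attachment site the tissue
inventories need. The template is parametric in foot length (`scale`,
default 255 mm), arch height ratio (navicular height / foot length,
default 0.16, a mid-range adult value), and side. Attachment points are
snapped to the host surface mesh, so the "attachments lie on the bone"
invariant holds by construction; `validate_model()` re-checks it, along
with bone-bone clearance, watertightness, mass and inertia positivity,
and plantigrade coplanarity of the heel and metatarsal-head pads
(tolerance 5 mm, our choice: the synthetic template keeps the spread
near 4 mm).

The count of 23 requires a reading of the fused lesser-ray phalanges: we
model one fused segment per ray (4 bodies), which is the reading
consistent with the total; a single merged block would give 20.

Bone elasticity (E = 7300 MPa) is four orders stiffer than any soft
tissue in the model, so bones are rigid bodies; the bone constants remain
in the material registry for element-stress reporting.

### Constitutive laws

*Plantar soft tissue* is a one-term Ogden solid with nominal
(first-Piola) uniaxial stress

sigma(lambda) = -(2C/alpha) (lambda^(alpha-1) - lambda^(-alpha/2-1)),

C = 0.0102 MPa, alpha = 8.04. The leading minus sign is implemented
literally, which makes compression (lambda < 1) produce positive stress;
`ogden_uniaxial_stress()` exposes a `tension_positive` flag for users
expecting the opposite convention. Viscoelasticity is a two-term Prony
series (g1 = 0.18, g2 = 0.12, tau1 = 0.57 s, tau2 = 6.03 s, stored in
ms) applied through the standard recursive-convolution update, which is
exact for stress histories that are linear within a step. A held
deformation starts at the full elastic stress and relaxes to
(1 - g1 - g2) = 0.70 of it. Whether the Prony weights scale the full or
only the deviatoric response is not determined by the source data; the
columns are uniaxial, so the distinction is bookkeeping only, and the
registry records the choice (`prony_scope`, default `"full"`).

*Skin* (Ogden, C = 0.122 MPa, alpha = 18) enters through the same column
bed; the 1 mm skin layer is not modeled as a separate shell.
Near-incompressibility (nu = 0.475) affects only lateral-area
bookkeeping of the uniaxial columns, not a 3D pressure field.

*Ligaments* are linear elastic in engineering strain with E = 260 MPa:
each chain has stiffness E A / slack and transmits tension only. The
toe-region nonlinearity of real ligament is deliberately omitted (the
source material gives only a modulus and areas); this makes the model
stiffer at small strain than real tissue.

*The plantar aponeurosis* modulus is derived, not assumed: a tensile
force of 1.5 body weights (70 kg) at 5 % strain over 50 mm^2 gives

E = (1.5 x 70 x 9.81 / 50) / 0.05 = 412.02 MPa,

computed by `pa_elastic_modulus()`. The total area of 50 mm^2 is split
evenly over ten slips.

### Tissue architecture

*Ligament chains* connect origin to insertion through optional small
(0.5 mm radius) spheres that slide frictionlessly over bone surfaces:
spheres are laid along the chain and projected out of any host surface
they penetrate, along the local outward normal, so contact forces are
normal-only and the path wraps smoothly over bony contours
(`resolve_sphere_contacts()`; the engine uses an analytic-ellipsoid
branch of the same projection). The default inventory covers the
explicitly named lateral hindfoot group (slack = reference length),
the plantar group (slack = reference length), the deltoid complex and
interosseous talocalcaneal stabilizers, dorsal counterparts of the
midfoot ligaments, and representative metatarsophalangeal plantar
plates and dorsal capsules — a tension-only skeleton is kinematically
unbounded without them. All cross-sections are representative defaults
and user-overridable. All other slack lengths are 1.1 x the
build-posture length; underestimating slack leaves ligaments permanently
taut and the joints unrealistically stiff.

*The plantar aponeurosis* is ten tension-only slips from the calcaneal
tuberosity to the proximal phalanx bases. Slip 1 routes through the
hallucal sesamoids (a pinned via point on the medial sesamoid); slips
2-10 wrap analytic cylinders recorded on the metatarsal heads, using the
tangent-arc-tangent obstacle-set construction (`wrap_cylinder_length()`).
The effective wrap radius is 1.25 x the metatarsal shaft radius — the
head plus cartilage plus plantar plate — which keeps the band engaged
on the cylinder when the foot pitches over the forefoot; with a smaller
surface the chord clears the head at moderate heel rise and the
windlass tension collapses unphysically.
PA slack is the build-posture path length (no 1.1 factor): the
metatarsophalangeal joints are slightly flexed in that posture. This is
what produces the windlass behaviour: toe dorsiflexion and arch
elongation both lengthen the wrapped path and load the slips.

*Muscles* (triceps surae, tibialis anterior, extensor digitorum longus,
extensor hallucis longus) are straight-segment force paths through
anchored via points, recomputed each step from the current poses; no
muscle wrapping surfaces. The long toe extensors route over a via point
on the metatarsal dorsum (the extensor hood), which keeps their moment
arm at the toe joints anatomically small — a straight pull from the
phalanx to the shank hyperextends the nearly massless toes. Their force profiles are sampled
(stance-%, N) tables interpolated linearly; the shipped profiles
(`default_muscle_profiles()`, also in
`inst/extdata/muscle_profiles_synthetic.csv`) are *synthetic* standins
with physiologic shape — TS rising to a ~1050 N late-stance peak, TA
peaking at heel contact — not subject measurements.

*The plantar soft tissue* is a bed of 14 uniaxial Ogden/Prony columns
(three under the calcaneal tuberosity's weight-bearing patch, one under
the cuboid — the lateral arch bears load, and without it the
heel-to-forefoot transfer would be instantaneous — and one under each
metatarsal head and toe pad).
A column's reference thickness is its build-time plantigrade clearance;
its stretch is the anchor height over that reference; force = stress x
area, compression only. Below 25 % of reference thickness the Ogden law
continues linearly (a numerical guard; the stresses there are already
far beyond physiologic).

### Contact

*Floor contact* acts at the column bases: the Ogden/Prony stress
provides the normal force (with small rate damping), and Coulomb
friction (mu_s = mu_d = 0.6) acts tangentially via a stick-anchor spring
capped at the friction cone — inside the cone the contact sticks, on the
cone it slips with |Ft| = mu Fn opposing the sliding, and the anchor is
dragged so the spring sits exactly on the cone (no hysteresis at the
boundary). A generic penalty point-contact law with the same friction
machinery is exported as `floor_contact_force()`.

*Articulations.* The convex sphere-on-sphere proxy
(`cartilage_contact_force()`) implements the frictionless penalty law
and its unit tests, but a convex point contact transmits no shear, and a
skeleton held only by tension elements and point contacts dislocates
under half body weight (we verified this directly). Real articular
surfaces are congruent: a frictionless congruent joint resists *any*
relative translation of the joint-center point while leaving rotation
free, and that is exactly a penalty spring on the joint-center offset.
The assembled skeleton therefore uses this congruent ball-in-socket
formulation (default penalty 400 N/mm, auto-scaled so standing
penetration stays below ~1 mm), plus a torsional spring per articulation
standing in for articular congruence and the short periarticular
structures that are not modeled individually: large at the wedged
midfoot joints (50-80 N m/rad), moderate at the subtalar joint (20)
and the metatarsophalangeal joints (4-5, the plantar plate and
intrinsic muscles), small at the mobile talocrural joint (4) and
interphalangeal joint, near zero at the sesamoid articulations. Because these springs
represent ligamentous tissue, they scale with the ligament modulus in
the material registry (a rigid-ligament variant is rigid at the
articulations too). Without
the torsional terms the midfoot folds dorsally between the heel and
forefoot supports (the tension-only plantar ties cannot resist a
dorsal-opening moment), the unloaded hindfoot swings wildly after
heel-off, and the toes hyperextend under the extensor pull. These
stiffnesses scale with the cube of the build scale.

The rubber block of the axial rig is a 6-DOF bushing (anisotropic
translational and rotational springs) with stiffnesses derived from the
block dimensions and modulus (70 x 50 x 20 mm, E = 4.0 MPa): axial
E A / t = 700 N/mm, shear G A / t, bending E I / t.

## Dynamics

Integration is semi-implicit (symplectic) Euler: velocities first from
the assembled forces (with the gyroscopic torque in the rotational
update), then positions; orientations advance by incremental quaternion
rotation and renormalization. Prescribed bodies follow their
trajectories exactly at sample times; the fibula is rigidly welded to
the tibia (the rig embeds both in the rubber socket, and gait drives
both from the same three markers), with weld forces transferred to the
parent.

The stable step is estimated per body by a Gershgorin-style sum: every
elastic element contributes its stiffness times the endpoint compliance
(1/m plus lever^2/I) to each body it touches, columns contribute their
worst-case (guard-region) stiffness, and the step is
`safety x 2 / sqrt(max body sum)`, capped at 1 ms (`stable_dt()`). Runs
use safety 0.3, giving about 0.01 ms on the default model. Two forms of
mass scaling, both classic explicit-dynamics devices and both
config-exposed, keep this tractable: bodies lighter than 5 g are floored
to 5 g, and every body gets a 5 mm minimum radius of gyration.

Static solutions use dynamic relaxation (`settle_static()`):
mass-proportional damping (rate-capped so slow modes such as an
attached loading shaft are not overdamped into creep) plus windowed
kinetic-energy resets — velocities are zeroed once kinetic energy has
clearly passed a peak, with a minimum spacing so that fast local modes
cannot mask the slow global ones. Convergence is declared when the peak
residual acceleration of the free, unconstrained components falls below
tolerance (default 2e-4 mm/ms^2, about 2 % of g). Applied loads ramp in
over the first part of a settle to avoid impact transients.

## Protocols

*Axial loading.* The proximal tibia/fibula couple through the rubber
bushing to a 3.3 kg shaft constrained to vertical translation and
rotation. The foot is first placed heel-first (transient upward forces
at the metatarsal heads, default 12 N each — the source describes the
maneuver but not the magnitudes — decayed before the reference settle),
the zero-load reference is the settled state under shaft weight alone,
and the load then ramps to 588 N total with a settle per level.
Reported outputs are translations and y-x-z rotations of calcaneus,
talus, cuboid, navicular and first metatarsal relative to zero load.

*Quiet standing.* Stage 1 applies 353 N (half of 72 kg body weight)
down at the tibia and settles; stage 2 raises the tibial load to 530 N
and adds 177 N upward at the calcaneal tuberosity (the Achilles share,
50 % of the target GRF) and settles again. The tibia is load-controlled
in translation and held upright in rotation — constraining its
horizontal translation instead wedges the foot against friction and
tips all load onto the heel. Static protocols apply no skeletal
self-weight: the staged loads already represent the entire load share
above the plate, and adding bone weight would double-count it (and spoil
the exact force balance the protocol is defined by). The audit per stage
verifies sum(contact) = sum(applied).

*Stance.* The three tibial markers (medial malleolus, lateral malleolus,
tibial tuberosity) are low-pass filtered (4th-order Butterworth,
forward-backward, 20 Hz cutoff — the order is our choice, the cutoff is
the standard one), registered to the model landmarks by closed-form
3-point Procrustes per frame, and the resulting tibia pose trajectory is
prescribed. Initialization follows the anchor scheme: settle at 20 %
stance (tibia near vertical, foot flat), integrate the driven model
*backward* in time to heel contact, then reverse the velocities for the
forward run. Gravity is on; muscle forces follow their profiles; the
forward run uses mass-proportional damping (0.05/ms default,
representing tissue damping; the elastic loop between the plantar
aponeurosis and the toe pads rings for ~100 ms when run undamped).

*Refinement.* Simulated-minus-measured GRF per component over
normalized stance time is fitted with an 8th-order least-squares
polynomial (monomials on [0, 1], QR solve), scaled by a per-component
gain into displacement corrections (correction = -gain x poly: excess
downward GRF lifts the tibia), added to the trajectory, and the plant is
rerun. The scaling coefficients are described as empirically determined
in the source; we auto-estimate them with a one-shot secant probe
(perturb by 1 mm, measure the mean GRF response, take half the inverse
slope for stability margin), which on a linear plant of gain G yields
per-iteration error contraction |1 - gG| = 0.5. Coupling is diagonal
(vertical error to vertical displacement, and so on); the best-seen
iterate is always returned, so refinement can never end worse than it
started.

## The synthetic gait record

No subject recordings ship with the package; `synthesize_gait()`
generates the study conditions: a 72 kg subject, 700 ms stance, 200 Hz
sampling, 255 mm foot. The vertical GRF is two Gaussian bumps peaking at
1.1 BW near 25 % and 75 % stance over a plateau giving a 0.75 BW
mid-stance valley, windowed to zero at the ends; the anteroposterior
component is a braking-then-propulsion wave, odd about mid-stance so its
net impulse vanishes; the mediolateral component is a small medial bump.
The ankle advances about half a foot length relative to the planted
foot (from just behind its neutral position at heel strike to above the
metatarsal heads at toe-off), pitching from an 18 deg posterior lean
through near-vertical at 20 % stance to about 27 deg anterior lean at
toe-off, sitting slightly high at heel strike, dipping with the
vertical-force waveform (10 mm at 1 BW — deep enough that the heel pad
bottoms out and the foot rolls onto the forefoot), and rising 50 mm as
the heel lifts after 55 % stance. The vertical
excursion is calibrated once against the model's plantar compliance so
that the driven skeleton loads the floor at roughly the intended 1 BW
scale; it remains synthetic kinematics, not motion capture. Optional
marker/GRF noise is seeded and off by default.

What this generator does *not* emulate: soft-tissue marker artifact,
subject-specific bone geometry, bilateral coordination, swing dynamics,
and any real correlation structure between kinematics and kinetics
beyond the constructed consistency above. Tests that pass on this record
demonstrate internal consistency of the machinery — force balance, cone
constraints, tension-only behaviour, windlass phenomenology, COP
progression — not agreement with any individual's data.

## Numerical choices and degenerate inputs

- Quaternions are renormalized every step; divergence (any non-finite
  state) aborts with the offending body and time.
- The PA wrap clamps its effective cylinder radius when a phalanx
  attachment transiently grazes the cylinder during dynamics; the
  user-facing `wrap_cylinder_length()` keeps the strict endpoint-inside
  error.
- `pressure_map()` bins contact forces into cells (force conserved
  exactly; divided by cell area), with block-average downsampling to
  emulate coarse pressure sensors; an unloaded map has an undefined COP
  flag rather than NaNs.
- Euler y-x-z decomposition flags proximity to gimbal lock (|about_x| >
  89 deg); joint angles on the default protocols stay far from it.
- Ties and degenerate geometry: zero-length direction vectors raise
  errors rather than returning NaN.

## Problem sizes

The shipped tests and the acceptance checks run the default model
(23 bodies, ~65 tension chains, 14 columns, 24 articulations) at the
stability-bound step (~0.01 ms): a quiet-standing settle is ~10^4 steps,
the axial ramp ~5 x 10^4, and a full 700 ms stance ~7 x 10^4 steps.
These sizes were chosen so every protocol runs comfortably on a single
core; they are the model's native scale, not a downsampled one. The
per-level and per-stage budgets are config arguments.

## Known limitations

- Rigid bones and discrete columns cannot reproduce continuum stress
  fields; element-level spring/column stresses are the observable.
- The articulation model (congruent socket + torsional congruence
  springs) lumps cartilage contact, capsule and short ligaments into two
  constants per joint; it preserves load paths and mobility ordering but
  not contact-patch mechanics.
- Ligament force-length is linear; muscle paths do not wrap.
- The synthetic skeleton is a template, not an individual: quantitative
  displacement magnitudes depend on the representative ligament areas
  and joint stiffnesses, so comparisons against subject data should
  treat them as order-of-magnitude.
- Marker-driven stance inherits any inconsistency between the kinematic
  input and the model's contact compliance; the GRF-tracking refinement
  exists precisely to absorb that inconsistency.
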