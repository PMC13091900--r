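# pedsim

Forward-dynamics simulation of human foot mechanics during stance.

## What this is

Musculoskeletal models of walking usually treat the foot as one or two
rigid links, which makes it impossible to ask how load is shared among
the tarsal bones, the ligaments and the plantar aponeurosis while the
foot rolls over the ground. pedsim is an R implementation of the
opposite approach at desk scale: an anatomically structured,
reduced-order forward-dynamics foot — 23 rigid bones suspended in
tension-only ligament chains and a ten-slip plantar aponeurosis,
standing on a bed of nonlinear viscoelastic plantar columns, in
frictional contact with a rigid floor — driven through the tibia by
marker kinematics and muscle forces, and integrated explicitly through
time. It is aimed at biomechanics researchers who want a transparent,
scriptable sandbox for foot-ground interaction phenomenology (arch
mechanics, windlass loading, center-of-pressure progression, bone
kinematics) rather than subject-specific finite-element prediction.

The model's core ingredients, in the field's standard notation:

- **Plantar soft tissue**: one-term Ogden hyperelasticity, uniaxial
  nominal stress `sigma = -(2C/alpha)(lambda^(alpha-1) -
  lambda^(-alpha/2-1))` with C = 0.0102 MPa, alpha = 8.04, plus a
  two-term Prony relaxation series (g1 = 0.18, g2 = 0.12, tau1 = 0.57 s,
  tau2 = 6.03 s) via exact recursive convolution.
- **Ligaments**: tension-only chains, stiffness `EA/L0` with
  E = 260 MPa; slack length 1.1x the build-posture length, except the
  lateral hindfoot and plantar groups (1.0x). Chains thread
  non-penetrating spheres that slide frictionlessly over bone surfaces.
- **Plantar aponeurosis**: ten tension-only slips, E = 412.02 MPa
  (derived from a 1.5-body-weight tensile force at 5 % strain over
  50 mm^2), wrapping analytic metatarsal-head cylinders; slip 1 routes
  through the hallucal sesamoids.
- **Contact**: Coulomb friction (mu = 0.6) with stick-anchor
  regularization at the floor; articulations as frictionless congruent
  ball-in-socket penalties with per-joint torsional congruence springs.
- **Integration**: symplectic Euler at the per-body stability bound
  (about 0.01 ms), with dynamic relaxation for statics.
- **Protocols**: cadaveric-style axial loading to 588 N through an
  instrumented shaft; two-stage quiet standing (353 N axial, then 530 N
  tibial + 177 N Achilles); marker-driven stance with
  backward-integration initialization from 20 % stance, and an
  8th-order-polynomial GRF-tracking refinement of the tibial
  trajectory.

No subject recordings ship with the package: `synthesize_gait()`
generates seeded stance-phase marker/GRF/muscle records with the
canonical waveform shapes (double-peaked vertical GRF, braking-then-
propulsive anteroposterior GRF), and `build_foot()` generates the
parametric skeleton. See the methods vignette
(`vignettes/foot-mechanics.Rmd`) for the full model description and its
limitations.

## Worked example

```r
library(pedsim)

# the plantar aponeurosis modulus from the cadaveric force-strain datum
pa_elastic_modulus(bw_multiple = 1.5, body_mass = 70,
                   strain = 0.05, area = 50)
#> [1] 412.02

# build and validate the synthetic 255 mm foot
model <- build_foot()
model
#> <foot_model>
#>   23 bones, 64 ligament chains, 10 PA slips, 4 muscles
#>   14 soft-tissue columns, 24 cartilage pairs
#>   foot length 255 mm, arch ratio 0.16, side right
nrow(validate_model(model))   # 0: no violated invariants
#> [1] 0

# two-stage quiet standing (a few minutes of dynamic relaxation)
standing <- run_quiet_standing(model)
standing
#> <quiet_standing_result>
#>   stage 1: vertical GRF 353.0 N (target 353), converged TRUE
#>   stage 2: vertical GRF 353.0 N, COP (108.5, -2.4) mm, converged TRUE
```

The vertical ground reaction of 353.0 N is the per-foot half body
weight of the 72 kg reference subject, balanced against the 530 N
tibial load minus the 177 N Achilles pull — the audit that the model
neither creates nor loses force. The center of pressure sits 108.5 mm
from the heel end, a little anterior of the ankle, as in balanced
standing. `standing$pressure` holds the plantar pressure map (MPa on a
10 mm grid).

A full marker-driven stance run:

```r
gait <- synthesize_gait(model = model)   # 700 ms stance, 72 kg, seeded
stance <- run_stance(model, gait)        # ~9 min on one core
head(stance$summary[, c("pct", "grf_x", "grf_z", "cop_x", "pa_tension")])
```

`stance$summary` tracks the GRF components, center of pressure and
total plantar-aponeurosis tension over stance; `stance$joint_angles`
the y-x-z Euler angles of the talocrural, talonavicular,
calcaneocuboid and navicular-first-metatarsal articulations.

A thin command-line driver wraps these functions:

```sh
Rscript inst/cli/pedsim build --scale 255 --out model
Rscript inst/cli/pedsim synth --seed 1 --out gait
Rscript inst/cli/pedsim stand --out standing
```

## Conventions

Global axes: x anterior, y medial, z superior; floor at z = 0. Euler
sequence y-x-z: plantarflexion-dorsiflexion (y),
inversion-eversion (x), internal-external rotation / adduction-
abduction (z); positive = plantarflexion, inversion, internal rotation.
Units: mm, g, ms (forces in N, stresses in MPa).

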