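# Explicit integrator checks against closed-form mechanics, stability
# bound, static relaxation, and the conservation audits.

test_that("free fall reproduces the ballistic closed form", {
  pm <- point_mass_model(10, c(0, 0, 100))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  loads <- sim_loads(gravity = TRUE)
  dt <- 0.5
  n <- 200
  for (i in seq_len(n)) st <- sim_step(sim, st, loads, dt)
  t <- n * dt
  g <- 9.81e-3
  # symplectic Euler lands within O(dt) of 1/2 g t^2
  expect_equal(100 - st$x[1, 3], 0.5 * g * t^2,
               tolerance = 2 * dt / t + 1e-9)
  expect_equal(st$v[1, 3], -g * t, tolerance = 1e-9)
})

test_that("a hanging mass oscillates at 2 pi sqrt(m/k) within 1 percent", {
  # static elongation mg/k (~10 mm) well above the 2 mm amplitude keeps
  # the tension-only spring taut, hence linear, throughout
  m <- 50; k <- 0.05
  period <- 2 * pi * sqrt(m / k)
  pm <- point_mass_model(c(1e9, m), rbind(c(0, 0, 100), c(0, 0, 60)),
                         data.frame(i = 1, j = 2, k = k, slack = 30))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  loads <- sim_loads(gravity = TRUE,
                     prescribed = list(p1 = list(x = c(0, 0, 100),
                                                 q = quat_identity())))
  # start slightly below equilibrium; track zero crossings of velocity
  st$x[2, 3] <- 100 - 30 - m * 9.81e-3 / k - 2
  dt <- period / 1000
  n <- ceiling(3.2 * period / dt)
  crossings <- c()
  v_prev <- 0
  for (i in seq_len(n)) {
    st <- sim_step(sim, st, loads, dt)
    if (v_prev > 0 && st$v[2, 3] <= 0) crossings <- c(crossings, st$time)
    v_prev <- st$v[2, 3]
  }
  expect_gte(length(crossings), 3)
  measured <- mean(diff(crossings))
  expect_equal(measured, period, tolerance = 0.01)
})

test_that("a fully prescribed body holds its pose exactly", {
  pm <- point_mass_model(c(5, 5), rbind(c(0, 0, 10), c(0, 0, 50)))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  pose <- list(x = c(1, 2, 3), q = quat_identity())
  loads <- sim_loads(gravity = TRUE, prescribed = list(p2 = pose))
  for (i in 1:100) st <- sim_step(sim, st, loads, 0.5)
  expect_equal(st$x[2, ], c(1, 2, 3))
  expect_equal(st$v[2, ], c(0, 0, 0), tolerance = 1e-9)
})

test_that("stable_dt has the closed form for one spring and shrinks for
          stiffer elements", {
  one <- function(k) {
    pm <- point_mass_model(c(20, 20), rbind(c(0, 0, 0), c(0, 0, 30)),
                           data.frame(i = 1, j = 2, k = k, slack = 30))
    stable_dt(compile_model(pm, mass_floor = 0, gyration_floor = 1),
              safety = 0.1)
  }
  # omega estimated from the stiffness and the smaller endpoint mass
  expect_equal(one(5), 0.1 * 2 / sqrt(5 / 20), tolerance = 1e-9)
  expect_lt(one(50), one(5))
  empty <- point_mass_model(10, c(0, 0, 0))
  expect_equal(stable_dt(compile_model(empty, mass_floor = 0)), 1)
})

test_that("settle_static finds the static spring elongation mg/k", {
  m <- 100; k <- 2
  pm <- point_mass_model(c(1e9, m), rbind(c(0, 0, 100), c(0, 0, 55)),
                         data.frame(i = 1, j = 2, k = k, slack = 40))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  loads <- sim_loads(gravity = TRUE,
                     prescribed = list(p1 = list(x = c(0, 0, 100),
                                                 q = quat_identity())))
  out <- settle_static(sim, st, loads, tol = 1e-7, ramp_steps = 0)
  expect_true(attr(out, "converged"))
  elong <- 100 - out$x[2, 3] - 40
  expect_equal(elong, m * 9.81e-3 / k, tolerance = 2e-3)

  # zero load from rest: converges immediately with no displacement
  loads0 <- sim_loads(prescribed = list(p1 = list(x = c(0, 0, 100),
                                                  q = quat_identity())))
  st0 <- simulation_state(sim)
  st0$x[2, 3] <- 100 - 39 # spring slack: no force
  out0 <- settle_static(sim, st0, loads0, tol = 1e-9, ramp_steps = 0)
  expect_true(attr(out0, "converged"))
  expect_equal(out0$x[2, 3], 61)
})

test_that("an undamped tension-loaded spring network conserves energy
          over 1e4 steps", {
  # a pure-tension network has no free taut equilibrium, so two masses
  # hang in a web between prescribed anchors: settle to the taut
  # equilibrium, perturb slightly, then integrate without damping
  masses <- c(1e9, 1e9, 30, 45)
  pos <- rbind(c(0, 0, 0), c(60, 0, 0), c(30, 25, 0), c(30, -25, 0))
  springs <- data.frame(i = c(1, 2, 1, 2, 3), j = c(3, 3, 4, 4, 4),
                        k = c(3, 2, 2.5, 3.5, 2),
                        slack = c(28, 28, 28, 28, 36))
  pm <- point_mass_model(masses, pos, springs)
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  anchors <- list(p1 = list(x = c(0, 0, 0), q = c(1, 0, 0, 0)),
                  p2 = list(x = c(60, 0, 0), q = c(1, 0, 0, 0)))
  st <- settle_static(sim, st, sim_loads(prescribed = anchors),
                      tol = 1e-9, ramp_steps = 0)
  expect_true(attr(st, "converged"))
  st$x[3, ] <- st$x[3, ] + c(0.8, -0.5, 0.3)
  st$v[] <- 0
  st$w[] <- 0

  energy <- function(st) {
    ke <- sum(sim$mass[3:4] * rowSums(st$v[3:4, , drop = FALSE]^2)) / 2
    pe <- 0
    for (r in seq_len(nrow(springs))) {
      L <- norm3(st$x[springs$j[r], ] - st$x[springs$i[r], ])
      pe <- pe + 0.5 * springs$k[r] * max(0, L - springs$slack[r])^2
    }
    ke + pe
  }
  dt <- stable_dt(sim, 0.1)
  e0 <- energy(st)
  drift <- 0
  for (i in seq_len(10000)) {
    st <- sim_step(sim, st, sim_loads(prescribed = anchors), dt)
    if (i %% 500 == 0) drift <- max(drift, abs(energy(st) - e0) / e0)
  }
  expect_lt(drift, 0.01)
})

test_that("the momentum audit matches the applied impulse each step", {
  pm <- point_mass_model(c(10, 25), rbind(c(0, 0, 0), c(35, 0, 0)),
                         data.frame(i = 1, j = 2, k = 3, slack = 30))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  loads <- sim_loads(gravity = TRUE,
                     point_forces = list(list(body = "p1", local = NULL,
                                              force = c(2, 0, 1))))
  dt <- stable_dt(sim, 0.2)
  for (i in 1:500) {
    st <- sim_step(sim, st, loads, dt)
    expect_equal(st$audit$dp, st$audit$impulse,
                 tolerance = 1e-6 * max(1, norm3(st$audit$impulse)))
  }
})

test_that("divergence is reported with the offending body", {
  pm <- point_mass_model(c(1, 1), rbind(c(0, 0, 0), c(10, 0, 0)),
                         data.frame(i = 1, j = 2, k = 1000, slack = 1))
  sim <- compile_model(pm, mass_floor = 0)
  st <- simulation_state(sim)
  expect_error({
    for (i in 1:200) st <- sim_step(sim, st, sim_loads(), 5)
  }, "divergence|fully inside|body")
})

test_that("doubling the articulation penalty and halving the step leaves
          the static contact force unchanged", {
  # a two-body stack: B rests on A through a congruent-socket
  # articulation, A stands on a soft-tissue column on the floor; the
  # settled ground reaction must equal the applied load regardless of
  # the penalty constant (only the penetration changes)
  ms <- material_set()
  base_model <- function() {
    b <- function(name, z, r) {
      m <- 4 / 3 * pi * r^3 * 1.5e-3
      list(name = name, mass = m, centroid = c(0, 0, z),
           inertia = diag(rep(2 / 5 * m * r^2, 3)),
           orientation = c(1, 0, 0, 0), semi = rep(r, 3),
           R_ell = diag(3), surface = NULL, landmarks = list())
    }
    structure(list(
      bones = list(A = b("A", 20, 10), B = b("B", 42, 10)),
      attachments = list(),
      ligaments = list(), pa_slips = list(), muscles = list(),
      columns = list(list(
        name = "pad", bone = "A", anchor = c(0, 0, -10),
        reference_thickness = 10, area = 400,
        ogden = ms$soft_tissue, prony = ms$soft_tissue_prony)),
      cartilage_pairs = list(list(
        bone_a = "A", bone_b = "B", center_a = c(0, 0, 11),
        center_b = c(0, 0, -11), radius = 1,
        contact_point = c(0, 0, 31), rot_stiffness = 0)),
      welds = list(), materials = ms,
      build_params = list(scale = NA, arch_ratio = NA, seed = 0L,
                          side = "right")), class = "foot_model")
  }
  grf_at <- function(penalty, dt_scale) {
    sim <- compile_model(base_model(), cartilage_penalty = penalty)
    st <- simulation_state(sim)
    dt <- stable_dt(sim, 0.3) * dt_scale
    loads <- sim_loads(gravity = TRUE)
    out <- settle_static(sim, st, loads, tol = 1e-5, dt = dt,
                         max_steps = 60000, ramp_steps = 0)
    expect_true(attr(out, "converged"))
    out$audit$grf[3]
  }
  g1 <- grf_at(200, 1)
  g2 <- grf_at(400, 0.5)
  expect_equal(g2, g1, tolerance = 0.005)
})
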