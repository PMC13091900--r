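# Constitutive laws: Ogden uniaxial stress, Prony relaxation, the
# recursive viscoelastic update, and the plantar-aponeurosis modulus.

ogden_oracle <- function(lambda, C, alpha) {
  # independent one-line evaluation of the nominal stress-stretch law
  -(2 * C / alpha) * (lambda^(alpha - 1) - lambda^(-alpha / 2 - 1))
}

test_that("Ogden uniaxial stress matches direct evaluation and sign
          convention", {
  soft <- ogden_params(C = 0.0102, alpha = 8.04)
  skin <- ogden_params(C = 0.122, alpha = 18)

  expect_equal(ogden_uniaxial_stress(1, soft), 0)
  expect_equal(ogden_uniaxial_stress(1.1, soft),
               ogden_oracle(1.1, 0.0102, 8.04))
  expect_equal(ogden_uniaxial_stress(1.1, soft), -3.391e-3,
               tolerance = 1e-3)
  expect_equal(ogden_uniaxial_stress(0.9, skin),
               ogden_oracle(0.9, 0.122, 18))
  expect_equal(ogden_uniaxial_stress(0.9, skin), 3.662e-2,
               tolerance = 1e-3)
  # compression-positive under the printed convention; flag flips it
  expect_gt(ogden_uniaxial_stress(0.8, soft), 0)
  expect_lt(ogden_uniaxial_stress(1.2, soft), 0)
  expect_equal(ogden_uniaxial_stress(1.2, soft, tension_positive = TRUE),
               -ogden_uniaxial_stress(1.2, soft))
  expect_error(ogden_uniaxial_stress(0, soft), "stretch")
})

test_that("Ogden stress is strictly decreasing in stretch with a matching
          small-strain slope", {
  for (p in list(ogden_params(0.0102, 8.04), ogden_params(0.122, 18))) {
    grid <- seq(0.5, 2, by = 0.01)
    vals <- ogden_uniaxial_stress(grid, p)
    expect_true(all(diff(vals) < 0))
    h <- 1e-6
    slope_num <- (ogden_uniaxial_stress(1 + h, p) -
                  ogden_uniaxial_stress(1 - h, p)) / (2 * h)
    slope_an <- -(2 * p$C / p$alpha) *
      ((p$alpha - 1) + (p$alpha / 2 + 1))
    expect_equal(slope_num, slope_an, tolerance = 1e-6)
  }
})

test_that("Prony relaxation has the closed-form limits and bounds", {
  p <- prony_params(0.18, 0.12, 0.57, 6.03, tau_unit = "s")
  expect_equal(prony_relaxation(0, p), 1)
  expect_equal(prony_relaxation(1e9, p), 1 - 0.18 - 0.12,
               tolerance = 1e-12)
  p1 <- prony_params(0.18, 0, 0.57, 6.03, tau_unit = "s")
  expect_equal(prony_relaxation(570, p1), 1 - 0.18 * (1 - exp(-1)))
  tt <- seq(0, 5e4, length.out = 200)
  g <- prony_relaxation(tt, p)
  expect_true(all(diff(g) <= 0))
  expect_true(all(g > 1 - 0.18 - 0.12 - 1e-12 & g <= 1))
  expect_error(prony_relaxation(-1, p), "t must be")
  expect_error(prony_params(0.6, 0.5, 1, 1), "g1 \\+ g2")
})

test_that("viscoelastic update relaxes a held stretch to the long-time
          modulus and reduces to elasticity when weights vanish", {
  soft <- ogden_params(0.0102, 8.04)
  p <- prony_params(0.18, 0.12, 0.57, 6.03, tau_unit = "s")
  sig_e <- ogden_uniaxial_stress(1.05, soft)

  st <- prony_state_init(p)
  dt <- 10
  n <- ceiling(100 * p$tau2 / dt)
  out <- NULL
  for (i in seq_len(n)) {
    out <- viscoelastic_stress_update(sig_e, st, p, dt)
    st <- out$state
  }
  expect_equal(out$stress, 0.70 * sig_e, tolerance = 1e-3)

  # identity stretch: zero stress throughout
  st <- prony_state_init(p)
  for (i in 1:50) {
    out <- viscoelastic_stress_update(0, st, p, 1)
    st <- out$state
    expect_equal(out$stress, 0)
  }

  # g1 = g2 = 0 reproduces the elastic law exactly
  p0 <- prony_params(0, 0, 0.57, 6.03, tau_unit = "s")
  st <- prony_state_init(p0)
  for (lam in c(0.9, 1.02, 1.1)) {
    se <- ogden_uniaxial_stress(lam, soft)
    out <- viscoelastic_stress_update(se, st, p0, 0.5)
    st <- out$state
    expect_identical(out$stress, se)
  }
})

test_that("step refinement under a curved loading history reduces the
          discretization error", {
  # the recurrence is exact for piecewise-linear histories, so a
  # quadratic ramp is used to expose the discretization error
  p <- prony_params(0.18, 0.12, 0.57, 6.03, tau_unit = "s")
  ramp_run <- function(dt) {
    st <- prony_state_init(p)
    tt <- seq(dt, 2000, by = dt)
    out <- NA
    for (t in tt) {
      out <- viscoelastic_stress_update(0.01 * (t / 2000)^2, st, p, dt)
      st <- out$state
    }
    out$stress
  }
  ref <- ramp_run(5)
  e1 <- abs(ramp_run(80) - ref)
  e2 <- abs(ramp_run(40) - ref)
  expect_lt(e2, e1) # refinement reduces the discretization error
})

test_that("plantar aponeurosis modulus reproduces the cadaveric
          derivation", {
  expect_equal(pa_elastic_modulus(1.5, 70, 0.05, 50), 412.02,
               tolerance = 1e-5)
  expect_equal(pa_elastic_modulus(1.0, 50, 0.05, 50), 196.2,
               tolerance = 1e-12)
  # doubling the strain halves the modulus exactly
  expect_equal(pa_elastic_modulus(1.5, 70, 0.10, 50),
               pa_elastic_modulus(1.5, 70, 0.05, 50) / 2)
  expect_error(pa_elastic_modulus(1.5, 70, 0, 50), "finite and > 0")
})

test_that("the material registry carries the tabulated defaults and
          round-trips through YAML bit-exactly", {
  ms <- material_set()
  expect_equal(ms$bone$E, 7300)
  expect_equal(ms$soft_tissue$C, 0.0102)
  expect_equal(ms$soft_tissue_prony$tau1, 570) # ms
  expect_equal(ms$cartilage$E, 10)
  expect_equal(ms$ligament$E, 260)
  expect_equal(ms$plantar_aponeurosis$E, 412.02, tolerance = 1e-6)
  expect_equal(ms$floor_friction$mu_static, 0.6)

  txt <- write_material_set(ms)
  ms2 <- read_material_set(text = txt)
  expect_identical(unlist(lapply(unclass(ms), unlist)),
                   unlist(lapply(unclass(ms2), unlist)))

  ms3 <- material_set(ligament = linear_elastic_params(500, 0.4, 1e-3))
  expect_equal(ms3$ligament$E, 500)
  expect_error(material_set(bogus = 1), "unknown component")
})
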