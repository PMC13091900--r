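# Tension-only tissue elements: slack rules, chain tension, sphere-chain
# contact resolution, cylinder wrapping, muscle interpolation, columns.

test_that("slack length rules follow the reference-posture conventions", {
  expect_equal(assign_slack_length(20, "default"), 22)
  expect_equal(assign_slack_length(20, "lateral_hindfoot"), 20)
  expect_equal(assign_slack_length(20, "plantar"), 20)
  expect_error(assign_slack_length(0, "default"), "reference_length")
  expect_error(assign_slack_length(20, "nope"))
})

test_that("chain tension is linear above slack and zero below", {
  chain <- list(E = 260, area = 10, slack_length = 20)
  expect_equal(chain_tension(19, chain), 0)
  expect_equal(chain_tension(20, chain), 0)
  expect_equal(chain_tension(22, chain), 260)
  # bundle of 10 sub-chains with the same total area gives the same total
  bundle <- list(E = 260, area = 1, slack_length = 20)
  expect_equal(10 * chain_tension(22, bundle), chain_tension(22, chain),
               tolerance = 1e-12)
  expect_error(chain_tension(0, chain), "path_length")
})

test_that("elastic energy stored in a chain equals the integral of
          tension over elongation", {
  chain <- list(E = 260, area = 8, slack_length = 25)
  lengths <- seq(25, 30, length.out = 2001)
  tensions <- chain_tension(lengths, chain)
  work <- sum((tensions[-1] + tensions[-length(tensions)]) / 2 *
              diff(lengths))
  k <- chain$E * chain$area / chain$slack_length
  expect_equal(work, 0.5 * k * 5^2, tolerance = 1e-5)
})

test_that("sphere contacts project out of a flat patch along its normal
          only", {
  # flat square patch at z = 0, normal +z
  patch <- list(
    vertices = rbind(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0),
                     c(-50, 50, 0)),
    faces = rbind(c(1, 2, 3), c(1, 3, 4)))

  # chain passing 5 mm above: untouched
  res <- resolve_sphere_contacts(c(-20, 0, 5), c(20, 0, 5), 3,
                                 list(patch))
  expect_equal(res$length, 40)
  expect_equal(nrow(res$contacts), 0)

  # chain dipping 0.2 mm below: spheres pushed to 0.5 mm clearance
  res <- resolve_sphere_contacts(c(-20, 0, 5), c(20, 0, -0.7), 4,
                                 list(patch), sphere_radius = 0.5,
                                 tension = 10)
  low <- res$positions[, 3]
  expect_true(all(low >= 0.5 - 1e-9))
  expect_gte(res$length, norm3(c(40, 0, -5.7)))
  # contact forces have no tangential component against the +z normal
  if (nrow(res$contacts)) {
    expect_true(all(abs(res$contacts$nx) < 1e-9))
    expect_true(all(abs(res$contacts$ny) < 1e-9))
  }
})

test_that("sphere-chain path over an ellipsoid obeys the triangle
          inequality and detects buried spheres", {
  ell <- list(center = c(0, 0, 0), semi = c(10, 8, 6), R = diag(3))
  res <- resolve_sphere_contacts(c(-20, 0, 5), c(20, 0, 5), 7, list(ell))
  expect_gte(res$length, 40 - 1e-9)
  expect_true(all(ellipsoid_level(res$positions, ell$center,
                                  ell$semi + 0.5, ell$R) > 1 - 1e-6))
  expect_error(
    resolve_sphere_contacts(c(-1, 0, 0), c(1, 0, 0), 1, list(ell)),
    "fully inside")
})

test_that("cylinder wrap length matches a dense shortest-path oracle and
          grows with dorsiflexion", {
  r <- 5
  c0 <- c(0, 0, 0)
  axis <- c(0, 1, 0)
  p1 <- c(-30, 0, -4)
  p2 <- c(25, 0, -4)

  # numeric oracle: dense shortest path around the circle in the x-z
  # plane: straight to a visible boundary point, along the arc, straight
  # out through a visible boundary point (visibility = the segment does
  # not cut the disk: the boundary point is the first intersection)
  oracle <- function(p1, p2, r, n = 2881) {
    th <- seq(0, 2 * pi, length.out = n)[-n]
    cx <- r * cos(th)
    cz <- r * sin(th)
    vis <- function(p) (cx * (cx - p[1]) + cz * (cz - p[3])) <= 1e-9
    d1 <- sqrt((cx - p1[1])^2 + (cz - p1[3])^2)
    d2 <- sqrt((cx - p2[1])^2 + (cz - p2[3])^2)
    v1 <- vis(p1)
    v2 <- vis(p2)
    best <- Inf
    for (i in which(v1)) {
      arc <- abs(th[i] - th[v2])
      arc <- pmin(arc, 2 * pi - arc) * r
      best <- min(best, d1[i] + min(arc + d2[v2]))
    }
    best
  }
  w <- wrap_cylinder_length(p1, p2, c0, axis, r)
  expect_true(w$wrapped)
  expect_equal(w$length, oracle(p1, p2, r), tolerance = 1e-3)

  # clear path: plain Euclidean distance
  w2 <- wrap_cylinder_length(c(-30, 0, 20), c(30, 0, 20), c0, axis, r)
  expect_false(w2$wrapped)
  expect_equal(w2$length, 60)

  # dorsiflexion sweep: the insertion (just distal to the head, as a
  # phalanx base) rotates about the cylinder axis, monotonically
  # lengthening the wrapped path over the physiologic range
  angles <- seq(0, 30, by = 2) * pi / 180
  lens <- vapply(angles, function(a) {
    q <- as.numeric(rot_y(-a) %*% c(6.3, 0, -3))
    wrap_cylinder_length(p1, q, c0, axis, r)$length
  }, 0)
  expect_true(all(diff(lens) > 0))

  expect_error(wrap_cylinder_length(c(1, 0, 0), p2, c0, axis, r),
               "inside the cylinder")
})

test_that("PA slip path length reduces to the straight distance without
          interference and routes via the sesamoid when flagged", {
  slip <- list(index = 1)
  out <- slip_path_length(slip, c(0, 0, 0), c(100, 0, 0))
  expect_equal(out$length, 100)
  expect_equal(out$dir_origin, c(1, 0, 0))

  out2 <- slip_path_length(slip, c(0, 0, 0), c(100, 0, 0),
                           via = c(50, 0, -10))
  expect_equal(out2$length, 2 * sqrt(50^2 + 100), tolerance = 1e-12)

  cyl <- list(point = c(50, 0, 3), axis = c(0, 1, 0), radius = 4)
  out3 <- slip_path_length(slip, c(0, 0, 0), c(100, 0, 0), cylinder = cyl)
  expect_true(out3$wrapped)
  expect_gt(out3$length, 100)
})

test_that("muscle force interpolation is exact at samples and linear
          between them", {
  path <- list(force_profile = data.frame(pct = c(0, 10, 20, 100),
                                          force = c(0, 100, 200, 50)))
  expect_equal(muscle_force_at(10, path), 100)
  expect_equal(muscle_force_at(15, path), 150)
  expect_warning(out <- muscle_force_at(120, path), "clamped")
  expect_equal(out, 50)
  zero <- list(force_profile = data.frame(pct = c(0, 100),
                                          force = c(0, 0)))
  expect_equal(muscle_force_at(c(0, 33, 100), zero), c(0, 0, 0))
})

test_that("soft-tissue columns push in compression only and compose the
          Ogden and Prony laws", {
  ms <- material_set()
  col <- list(reference_thickness = 10, area = 100,
              ogden = ms$soft_tissue, prony = ms$soft_tissue_prony)
  st <- prony_state_init(col$prony)

  out <- column_force(col, 10, st, 0.01)
  expect_equal(out$force, 0)
  out <- column_force(col, 11, out$state, 0.01)
  expect_equal(out$force, 0) # contact-like: no adhesion in separation

  # fast loading (t << tau1): within a few % of the instantaneous
  # elastic response
  st <- prony_state_init(col$prony)
  out <- column_force(col, 9, st, 0.01)
  expect_equal(out$force,
               100 * ogden_uniaxial_stress(0.9, ms$soft_tissue),
               tolerance = 0.02)
  expect_error(column_force(col, 0, st, 0.01), "current_thickness")
})
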