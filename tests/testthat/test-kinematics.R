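# y-x-z Euler decomposition, joint angles, pressure maps, COP, MAE+-SD
# statistics, and the zero-phase marker filter.

random_rotation <- function() {
  # uniform-ish random rotation from a random unit quaternion
  q <- rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

test_that("Euler y-x-z decomposition inverts composition", {
  e <- euler_yxz(diag(3))
  expect_equal(c(e$about_y, e$about_x, e$about_z), c(0, 0, 0))

  e <- euler_yxz(rot_y(10 * pi / 180))
  expect_equal(e$about_y, 10, tolerance = 1e-9)
  expect_equal(abs(e$about_x) + abs(e$about_z), 0, tolerance = 1e-9)

  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    e <- euler_yxz(R)
    R2 <- compose_yxz(e$about_y, e$about_x, e$about_z)
    worst <- max(worst, max(abs(R - R2)))
  }
  expect_lt(worst, 1e-9)

  expect_error(euler_yxz(matrix(1, 3, 3)), "proper rotation")
})

test_that("joint angles are relative to reference poses and invariant to
          common rotation", {
  expect_equal(joint_angles(diag(3), diag(3))$about_y, 0)

  R_dist <- rot_y(5 * pi / 180)
  ja <- joint_angles(diag(3), R_dist)
  expect_equal(ja$about_y, 5, tolerance = 1e-9)
  expect_equal(abs(ja$about_x) + abs(ja$about_z), 0, tolerance = 1e-9)

  set.seed(3)
  for (i in 1:50) {
    G <- random_rotation() # common (whole-body) rotation
    P <- random_rotation()
    Drel <- compose_yxz(7, -3, 12)
    ja <- joint_angles(G %*% P, G %*% P %*% Drel)
    expect_equal(c(ja$about_y, ja$about_x, ja$about_z), c(7, -3, 12),
                 tolerance = 1e-8)
  }
})

test_that("pressure map conserves force, places point loads, and
          downsampling averages blocks", {
  pm <- pressure_map(matrix(c(5, 5), 1, 2), 100, cell = 10,
                     origin = c(0, 0), dims = c(4, 4))
  expect_equal(pm$grid[1, 1], 1.0) # 100 N over 100 mm^2 = 1 MPa
  expect_equal(sum(pm$grid) * pm$cell^2, 100)
  expect_equal(pm$cop, c(5, 5))

  # four equal cells block-averaged 2x2 keep their common value
  pts <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  pm2 <- pressure_map(pts, rep(50, 4), cell = 10, origin = c(0, 0),
                      dims = c(2, 2), downsample = 2)
  expect_equal(dim(pm2$grid), c(1, 1))
  expect_equal(pm2$grid[1, 1], 0.5)
  expect_equal(sum(pm2$grid) * pm2$cell^2, 200)

  # random scatter: exact conservation
  set.seed(11)
  pts <- cbind(runif(40, 0, 90), runif(40, 0, 60))
  f <- runif(40, 0, 30)
  pm3 <- pressure_map(pts, f, cell = 7)
  expect_equal(sum(pm3$grid) * pm3$cell^2, sum(f), tolerance = 1e-9)
  # COP inside the hull of loaded points
  expect_true(pm3$cop[1] >= min(pts[, 1]) && pm3$cop[1] <= max(pts[, 1]))

  pm0 <- pressure_map(matrix(0, 0, 2), numeric(0))
  expect_true(all(is.na(pm0$cop)))
  expect_error(pressure_map(matrix(c(100, 100), 1, 2), 1, cell = 10,
                            origin = c(0, 0), dims = c(2, 2)),
               "does not cover")
})

test_that("center of pressure is the vertical-force-weighted mean", {
  expect_equal(center_of_pressure(matrix(c(3, 7), 1, 2), 10), c(3, 7))
  expect_equal(center_of_pressure(rbind(c(0, 0), c(4, 0)), c(1, 1)),
               c(2, 0))
  expect_equal(center_of_pressure(rbind(c(0, 0), c(4, 0)), c(1, 3)),
               c(3, 0))
  expect_error(center_of_pressure(rbind(c(0, 0)), 0), "must be > 0")
})

test_that("mae_sd gives the hand-worked values and is symmetric and
          shift-invariant", {
  expect_equal(mae_sd(1:5, 1:5), c(mae = 0, sd = 0))
  expect_equal(mae_sd(1:5 + 3, 1:5), c(mae = 3, sd = 0))
  a <- c(1, 2, 3); b <- c(0, 0, 0)
  expect_equal(mae_sd(a, b), c(mae = 2, sd = 1))
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(mae_sd(x, y), mae_sd(y, x))
  expect_equal(mae_sd(x + 2, y + 2), mae_sd(x, y))
  expect_error(mae_sd(1:3, 1:4), "length")
})

test_that("the zero-phase low-pass keeps DC and the passband and
          attenuates above cutoff", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)

  const <- rep(3.5, length(t))
  expect_equal(lowpass_markers(const, fs), const, tolerance = 1e-6)

  hi <- sin(2 * pi * 50 * t)
  out <- lowpass_markers(hi, fs)
  expect_lt(max(abs(out[20:(length(out) - 20)])), 0.1)

  lo <- sin(2 * pi * 1 * t)
  out <- lowpass_markers(lo, fs)
  mid <- 30:(length(t) - 30)
  expect_equal(out[mid], lo[mid], tolerance = 0.01)

  expect_error(lowpass_markers(lo, fs = 30), "twice the cutoff")
})
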