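# Readers/writers for motion and force data, config round-trips, and the
# synthetic gait generator.

test_that("TRC files round-trip and meters are normalized to mm", {
  set.seed(21)
  traj <- array(rnorm(2 * 3 * 3, sd = 100), c(2, 3, 3),
                dimnames = list(NULL, c("A", "B", "C"), c("x", "y", "z")))
  path <- tempfile(fileext = ".trc")
  write_trc(traj, rate = 100, path = path)
  back <- read_trc(path)
  expect_equal(back$markers, c("A", "B", "C"))
  expect_equal(back$rate, 100)
  expect_equal(unname(back$data), unname(traj), tolerance = 1e-6)

  # a meters-unit file scales by 1000 on read
  lines <- readLines(path)
  lines[3] <- sub("\tmm\t", "\tm\t", lines[3])
  writeLines(lines, path)
  back_m <- read_trc(path)
  expect_equal(unname(back_m$data), unname(traj) * 1000,
               tolerance = 1e-3)
})

test_that("TRC parsing rejects malformed or truncated files", {
  path <- tempfile(fileext = ".trc")
  writeLines(c("garbage"), path)
  expect_error(read_trc(path), "header")

  traj <- array(0, c(5, 2, 3), dimnames = list(NULL, c("A", "B"), NULL))
  write_trc(traj, 100, path)
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 2)], path) # silently truncated
  expect_error(read_trc(path), "truncated|frames")
})

test_that("GRF and muscle CSV readers validate their schemas", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(t = c(0, 5, 10), Fx = 0, Fy = 0, Fz = c(0, 10, 20)),
            path, row.names = FALSE)
  df <- read_grf_csv(path)
  expect_equal(df$Fz, c(0, 10, 20))

  write.csv(data.frame(t = c(0, 5, 10), Fx = 0, Fy = 0), path,
            row.names = FALSE)
  expect_error(read_grf_csv(path), "Fz")

  write.csv(data.frame(t = c(0, 5, 5), Fx = 0, Fy = 0, Fz = 0), path,
            row.names = FALSE)
  expect_error(read_grf_csv(path), "duplicate")

  write.csv(data.frame(t = c(0, 10, 5), Fx = 0, Fy = 0, Fz = 0), path,
            row.names = FALSE)
  expect_error(read_grf_csv(path), "monotone")

  prof <- default_muscle_profiles()
  write.csv(prof, path, row.names = FALSE)
  back <- read_muscle_csv(path)
  expect_equal(back$TS, prof$TS)
  expect_error(read_muscle_csv({
    write.csv(prof[c("pct", "TS", "TA", "EDL")], path, row.names = FALSE)
    path
  }), "EHL")
})

test_that("linear resampling hits midpoints of a two-row ramp", {
  expect_equal(resample_series(c(0, 10), c(0, 100), 5), 50)
  M <- cbind(a = c(0, 100), b = c(50, 70))
  out <- resample_series(c(0, 10), M, c(0, 5, 10))
  expect_equal(out[2, ], c(a = 50, b = 60))
})

test_that("the synthetic gait record is deterministic per seed with the
          canonical waveform structure", {
  g1 <- synthesize_gait()
  g2 <- synthesize_gait()
  expect_identical(g1$grf, g2$grf)
  expect_identical(g1$markers, g2$markers)

  gn1 <- synthesize_gait(synthetic_gait_params(seed = 9,
                                               marker_noise = 1))
  gn2 <- synthesize_gait(synthetic_gait_params(seed = 9,
                                               marker_noise = 1))
  gn3 <- synthesize_gait(synthetic_gait_params(seed = 10,
                                               marker_noise = 1))
  expect_identical(gn1$markers, gn2$markers)
  expect_false(identical(gn1$markers, gn3$markers))

  # AP net impulse is a tiny fraction of the total AP impulse magnitude
  fx <- g1$grf[, "Fx"]
  expect_lt(abs(sum(fx)) / sum(abs(fx)), 0.02)
  # braking first, propulsion second, crossing near mid-stance
  s <- g1$pct / 100
  expect_lt(min(fx[s < 0.5]), -0.1 * g1$body_weight)
  expect_gt(max(fx[s > 0.5]), 0.1 * g1$body_weight)

  # vertical: exactly two interior maxima and one interior minimum after
  # smoothing
  fz <- stats::filter(g1$grf[, "Fz"], rep(1 / 5, 5), sides = 2)
  fz <- fz[!is.na(fz)]
  d <- sign(diff(fz))
  flips <- which(diff(d) != 0 & d[-1] != 0)
  maxima <- flips[d[flips] > 0]
  minima <- flips[d[flips] < 0]
  expect_equal(length(maxima), 2)
  expect_equal(length(minima), 1)
  # peaks ~1.1 BW, valley ~0.75 BW
  expect_equal(max(g1$grf[, "Fz"]) / g1$body_weight, 1.1,
               tolerance = 0.02)
  # mean vertical load over stance in the physiologic band
  expect_gt(mean(g1$grf[, "Fz"]) / g1$body_weight, 0.7)
  expect_lt(mean(g1$grf[, "Fz"]) / g1$body_weight, 1.1)
})

test_that("the synthetic tibia is near-vertical at the 20 percent
          anchor", {
  g <- synthesize_gait()
  i20 <- which.min(abs(g$pct - 20))
  mm <- g$markers[i20, "medial_malleolus", ]
  lm <- g$markers[i20, "lateral_malleolus", ]
  tt <- g$markers[i20, "tibial_tuberosity", ]
  shank <- tt - (mm + lm) / 2
  tilt <- acos(shank[3] / norm3(shank)) * 180 / pi
  expect_lt(tilt, 10) # marker offsets add a few degrees to shank pitch
})

test_that("configs round-trip through YAML identically", {
  cfg <- list(dt = 0.0123456789012345, duration = 700L,
              label = "walk", nested = list(a = c(1.5, 2.5), b = "x"))
  txt <- write_config(cfg)
  expect_identical(read_config(text = txt), cfg)

  cfg2 <- standing_config()
  expect_identical(read_config(text = write_config(cfg2)), cfg2)
})
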