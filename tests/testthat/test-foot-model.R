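# Synthetic skeleton construction and validation.

model_default <- build_foot() # shared across blocks (pure data)

test_that("the default build has the full 23-bone enumeration and passes
          validation", {
  expect_length(model_default$bones, 23)
  expect_setequal(names(model_default$bones), BONE_NAMES)
  rep <- validate_model(model_default)
  expect_equal(nrow(rep), 0)
  expect_length(model_default$pa_slips, 10)
  expect_true(model_default$pa_slips[[1]]$via_sesamoid)
  expect_false(any(vapply(model_default$pa_slips[-1], `[[`, TRUE,
                          "via_sesamoid")))
})

test_that("builds are deterministic and scale as a similarity transform", {
  m2 <- build_foot()
  expect_identical(model_default$bones$calcaneus$surface$vertices,
                   m2$bones$calcaneus$surface$vertices)
  expect_identical(vapply(model_default$attachments, `[[`, numeric(3),
                          "local"),
                   vapply(m2$attachments, `[[`, numeric(3), "local"))

  big <- build_foot(foot_build_params(scale = 255))
  small <- build_foot(foot_build_params(scale = 127.5))
  lms <- c("heel_plantar", "met1_head", "met5_head", "toe_tip",
           "ankle_center", "medial_malleolus")
  pb <- t(vapply(lms, function(l) landmark_position(big, l), numeric(3)))
  ps <- t(vapply(lms, function(l) landmark_position(small, l),
                 numeric(3)))
  db <- as.matrix(stats::dist(pb))
  ds <- as.matrix(stats::dist(ps))
  expect_equal(db, 2 * ds, tolerance = 1e-9)
})

test_that("mirroring the build flips landmark y-coordinates exactly", {
  left <- build_foot(foot_build_params(side = "left"))
  for (lm in c("heel_plantar", "met1_head", "toe_tip", "ankle_center")) {
    pr <- landmark_position(model_default, lm)
    pl <- landmark_position(left, lm)
    expect_equal(pl, pr * c(1, -1, 1), tolerance = 1e-12)
  }
})

test_that("validation reports penetration and detached attachments", {
  broken <- model_default
  # push the cuboid into the calcaneus
  broken$bones$cuboid$centroid <- broken$bones$calcaneus$centroid +
    c(5, 0, 0)
  rep <- validate_model(broken)
  expect_true(any(rep$component == "penetration" &
                  grepl("cuboid", rep$where)))

  broken2 <- model_default
  att <- names(broken2$attachments)[1]
  broken2$attachments[[att]]$local <-
    broken2$attachments[[att]]$local + c(0, 10, 0) # off the bone side
  rep2 <- validate_model(broken2)
  expect_true(any(rep2$component == "attachment" & rep2$where == att))
})

test_that("surfaces are watertight with positive volume and masses and
          inertia are physical", {
  for (b in model_default$bones) {
    expect_gt(b$mass, 0)
    ev <- eigen(b$inertia, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    ws <- pedsim:::.mesh_watertight(b$surface)
    expect_true(ws$watertight)
    expect_gt(ws$volume, 0)
  }
  # total mass is the plain sum plus any attached extras
  expect_equal(model_mass(model_default, extra = 3300),
               sum(vapply(model_default$bones, `[[`, 0, "mass")) + 3300,
               tolerance = 1e-12)
})

test_that("invalid build parameters are rejected by name", {
  expect_error(foot_build_params(scale = -1), "scale")
  expect_error(foot_build_params(arch_ratio = 1.2), "arch_ratio")
  expect_error(foot_build_params(jitter = -1), "jitter")
})

test_that("slack lengths follow the category rules from the build
          posture", {
  for (lg in model_default$ligaments) {
    o <- pedsim:::attachment_position(model_default, lg$origin_attachment)
    i <- pedsim:::attachment_position(model_default,
                                      lg$insertion_attachment)
    ref <- norm3(i - o)
    factor <- if (lg$category == "default") 1.1 else 1.0
    expect_equal(lg$slack_length, factor * ref, tolerance = 1e-9)
  }
  # PA slack is the build-posture path length (no 1.1 factor): every
  # slip starts exactly at slack, i.e. zero tension at build
  sim <- compile_model(model_default)
  st <- simulation_state(sim)
  st2 <- sim_step(sim, st, sim_loads(), 0.01)
  expect_true(all(st2$audit$pa_tension < 1e-9))
})
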