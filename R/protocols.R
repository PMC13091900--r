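#' Loading protocols
#'
#' Three reproducible scenario drivers: cadaveric-style axial loading
#' through an instrumented shaft, two-stage quiet standing, and
#' marker-driven stance with muscle forces. Static protocols apply the
#' staged loads without skeletal self-weight (the loads already represent
#' the full share above the plate); the dynamic stance protocol keeps
#' gravity on the free bones.
#'
#' @name protocols
NULL

#' Axial-loading protocol configuration
#'
#' @param shaft_mass kg (default 3.3)
#' @param max_load N total axial load at the last ramp level (default
#'   588, i.e. 60 kg)
#' @param n_levels number of ramp levels above the zero-load reference
#' @param rubber list: block dimensions mm (x, y, z), `E` MPa, `nu`,
#'   `density` g/mm^3
#' @param forefoot_lift N of upward force per metatarsal head during the
#'   heel-first initial placement (decayed to zero before the reference
#'   settle)
#' @return an `axial_loading_config` list
#' @export
axial_loading_config <- function(shaft_mass = 3.3, max_load = 588,
                                 n_levels = 6,
                                 rubber = list(dims = c(70, 50, 20),
                                               E = 4.0, nu = 0.475,
                                               density = 0.0012),
                                 forefoot_lift = 12) {
  if (shaft_mass <= 0 || max_load <= 0) {
    stop("axial_loading_config: masses and loads must be > 0")
  }
  shaft_weight <- shaft_mass * 1000 * GRAVITY_INTERNAL # N
  levels <- seq(shaft_weight, max_load, length.out = n_levels + 1)
  if (any(diff(levels) <= 0)) {
    stop("axial_loading_config: load ramp must be increasing")
  }
  list(shaft_mass = shaft_mass, max_load = max_load,
       shaft_weight = shaft_weight, levels = levels, rubber = rubber,
       forefoot_lift = forefoot_lift)
}

#' Quiet-standing protocol configuration
#'
#' The per-foot ground-reaction target is half body weight; the Achilles
#' (triceps surae) load is a fraction of it, applied upward at the
#' calcaneal tuberosity, and the tibial load is their sum. Internal
#' consistency is asserted at construction.
#'
#' @param body_mass kg (default 72)
#' @param achilles_fraction fraction of the GRF target carried by the
#'   Achilles tendon (default 0.5)
#' @param grf_target,achilles_load,tibia_load N; defaults derived from
#'   `body_mass` and `achilles_fraction` and rounded to integers
#' @return a `standing_config` list
#' @export
standing_config <- function(body_mass = 72, achilles_fraction = 0.5,
                            grf_target = round(body_mass * GRAVITY_MS2 / 2),
                            achilles_load = floor(achilles_fraction *
                                                    grf_target + 0.5),
                            tibia_load = grf_target + achilles_load) {
  if (abs(achilles_load - achilles_fraction * grf_target) > 0.5) {
    stop("standing_config: achilles_load inconsistent with fraction")
  }
  if (abs(tibia_load - grf_target - achilles_load) > 0.5) {
    stop("standing_config: tibia_load must equal grf_target + achilles")
  }
  list(body_mass = body_mass, achilles_fraction = achilles_fraction,
       grf_target = grf_target, achilles_load = achilles_load,
       tibia_load = tibia_load)
}

# Attach the loading shaft (rigid body + rubber-block bushing) to a model.
.augment_with_shaft <- function(model, config) {
  tib <- model$bones$tibia
  fib <- model$bones$fibula
  top <- c((tib$centroid[1] + fib$centroid[1]) / 2,
           (tib$centroid[2] + fib$centroid[2]) / 2,
           max(tib$centroid[3] + tib$semi[3],
               fib$centroid[3] + fib$semi[3]))
  mass <- config$shaft_mass * 1000 # g
  semi <- c(15, 15, 150)
  shaft <- list(name = "shaft", mass = mass,
                centroid = top + c(0, 0, semi[3] + 25),
                inertia = mass / 5 * diag(c(semi[2]^2 + semi[3]^2,
                                            semi[1]^2 + semi[3]^2,
                                            semi[1]^2 + semi[2]^2)),
                orientation = quat_identity(),
                semi = semi, R_ell = diag(3), surface = NULL,
                landmarks = list())
  model$bones$shaft <- shaft
  rb <- config$rubber
  A <- rb$dims[1] * rb$dims[2]
  t_blk <- rb$dims[3]
  G <- rb$E / (2 * (1 + rb$nu))
  kz <- rb$E * A / t_blk
  ks <- G * A / t_blk
  kr_x <- rb$E * (rb$dims[1] * rb$dims[2]^3 / 12) / t_blk
  kr_y <- rb$E * (rb$dims[2] * rb$dims[1]^3 / 12) / t_blk
  kr_z <- G * (A * (rb$dims[1]^2 + rb$dims[2]^2) / 12) / t_blk
  model$bushings <- c(model$bushings, list(list(
    parent = "shaft", child = "tibia", point = top + c(0, 0, 10),
    kt = c(ks, ks, kz), kr = c(kr_x, kr_y, kr_z))))
  model
}

# translations / y-x-z rotations of a body relative to a reference state
.pose_change <- function(sim, state, ref_state, body) {
  b <- sim$idx[[body]]
  dx <- state$x[b, ] - ref_state$x[b, ]
  R <- quat_to_matrix(state$q[b, ])
  R0 <- quat_to_matrix(ref_state$q[b, ])
  eu <- euler_yxz(t(R0) %*% R)
  data.frame(bone = body, dx = dx[1], dy = dx[2], dz = dx[3],
             rot_y = eu$about_y, rot_x = eu$about_x, rot_z = eu$about_z,
             stringsAsFactors = FALSE)
}

#' Run the cadaveric-style axial-loading protocol
#'
#' The proximal tibia/fibula are coupled to a vertical shaft through a
#' rubber-block bushing; the shaft translates and rotates only about the
#' vertical axis. The foot is placed heel-first (transient upward forces
#' at the metatarsal heads), the zero-load reference is settled under the
#' shaft weight alone, and the axial load is then ramped with a static
#' settle per level. Reports translations and y-x-z rotations of the
#' calcaneus, talus, cuboid, navicular and first metatarsal relative to
#' the zero-load state.
#'
#' @param model a validated `foot_model`
#' @param config an [axial_loading_config()]
#' @param bones bones to report
#' @param settle_tol,max_settle_steps forwarded to [settle_static()]
#' @param verbose print per-level progress
#' @param ... forwarded to [compile_model()] (e.g. heavier mass scaling
#'   for very stiff variants: only the equilibrium matters in statics)
#' @return an `axial_loading_result`: `displacements` (data frame per
#'   level x bone), `levels` (N), `states`, `converged` flags
#' @export
run_axial_loading <- function(model, config = axial_loading_config(),
                              bones = c("calcaneus", "talus", "cuboid",
                                        "navicular", "metatarsal_1"),
                              settle_tol = 3e-4,
                              max_settle_steps = 15000,
                              verbose = FALSE, ...) {
  model <- .augment_with_shaft(model, config)
  sim <- compile_model(model, ...)
  state <- simulation_state(sim)
  cons <- list(shaft = list(trans = c(FALSE, FALSE, TRUE),
                            rot = c(FALSE, FALSE, TRUE)))

  lift_pf <- lapply(paste0("met", 1:5, "_head"), function(lm) {
    lk <- sim$landmark_lookup[[lm]]
    list(body = sim$body_names[lk$body], local = lk$local,
         force = c(0, 0, config$forefoot_lift))
  })
  shaft_pf <- function(total) {
    list(list(body = "shaft", local = NULL, force = c(0, 0, -total)))
  }

  # heel-first placement: settle with forefoot lift, then without
  loads_lift <- sim_loads(point_forces = c(shaft_pf(config$shaft_weight),
                                           lift_pf),
                          constraints = cons)
  state <- settle_static(sim, state, loads_lift, tol = 10 * settle_tol,
                         max_steps = max_settle_steps %/% 2,
                         ramp_steps = 2000)
  loads0 <- sim_loads(point_forces = shaft_pf(config$shaft_weight),
                      constraints = cons)
  state <- settle_static(sim, state, loads0, tol = settle_tol,
                         max_steps = max_settle_steps, ramp_steps = 0)
  ref_state <- state

  levels <- config$levels
  states <- vector("list", length(levels))
  converged <- logical(length(levels))
  states[[1]] <- state
  converged[1] <- isTRUE(attr(state, "converged"))
  disp <- list()
  for (b in bones) {
    d <- .pose_change(sim, state, ref_state, b)
    d$load <- levels[1]
    disp[[length(disp) + 1]] <- d
  }
  for (li in seq_along(levels)[-1]) {
    loads <- sim_loads(point_forces = shaft_pf(levels[li]),
                       constraints = cons)
    state <- settle_static(sim, state, loads, tol = settle_tol,
                           max_steps = max_settle_steps, ramp_steps = 500)
    states[[li]] <- state
    converged[li] <- isTRUE(attr(state, "converged"))
    if (verbose) {
      message(sprintf("axial level %.0f N: converged=%s grf=%.1f N",
                      levels[li], converged[li], state$audit$grf[3]))
    }
    for (b in bones) {
      d <- .pose_change(sim, state, ref_state, b)
      d$load <- levels[li]
      disp[[length(disp) + 1]] <- d
    }
  }
  structure(list(displacements = do.call(rbind, disp), levels = levels,
                 states = states, converged = converged, sim = sim),
            class = "axial_loading_result")
}

#' Run the two-stage quiet-standing protocol
#'
#' Stage 1 applies the per-foot axial force (353 N by default) to the
#' tibia without tendon traction and settles; stage 2 adds the Achilles
#' load (tibial force raised to 530 N, 177 N upward at the calcaneal
#' tuberosity) and settles again. The tibia is load-controlled in
#' translation and held upright in rotation. Reports the converged
#' states, the per-stage force-balance audit, the plantar pressure map
#' and the center of pressure.
#'
#' @param model a validated `foot_model`
#' @param config a [standing_config()]
#' @param cell pressure-map cell size, mm
#' @param settle_tol,max_settle_steps forwarded to [settle_static()]
#' @return a `quiet_standing_result`
#' @export
run_quiet_standing <- function(model, config = standing_config(),
                               cell = 10, settle_tol = 2e-4,
                               max_settle_steps = 20000) {
  sim <- compile_model(model)
  state <- simulation_state(sim)
  cons <- list(tibia = list(trans = c(TRUE, TRUE, TRUE),
                            rot = c(FALSE, FALSE, FALSE)))

  loads1 <- sim_loads(
    point_forces = list(list(body = "tibia", local = NULL,
                             force = c(0, 0, -config$grf_target))),
    constraints = cons)
  st1 <- settle_static(sim, state, loads1, tol = settle_tol,
                       max_steps = max_settle_steps, ramp_steps = 3000)

  ach <- sim$landmark_lookup[["calcaneal_tuberosity"]]
  loads2 <- sim_loads(
    point_forces = list(
      list(body = "tibia", local = NULL,
           force = c(0, 0, -config$tibia_load)),
      list(body = sim$body_names[ach$body], local = ach$local,
           force = c(0, 0, config$achilles_load))),
    constraints = cons)
  st2 <- settle_static(sim, st1, loads2, tol = settle_tol,
                       max_steps = max_settle_steps, ramp_steps = 1500)

  audit <- function(st) {
    c(grf = st$audit$grf, applied = st$audit$applied,
      residual = attr(st, "residual"))
  }
  ct <- st2$audit$contacts
  pm <- pressure_map(ct[, c("x", "y"), drop = FALSE], ct[, "fn"],
                     cell = cell)
  structure(list(
    stage1 = st1, stage2 = st2,
    audit1 = audit(st1), audit2 = audit(st2),
    converged = c(stage1 = isTRUE(attr(st1, "converged")),
                  stage2 = isTRUE(attr(st2, "converged"))),
    pressure = pm, cop = pm$cop, config = config, sim = sim
  ), class = "quiet_standing_result")
}

#' @export
print.quiet_standing_result <- function(x, ...) {
  cat("<quiet_standing_result>\n")
  cat(sprintf("  stage 1: vertical GRF %.1f N (target %g), converged %s\n",
              x$audit1[["grf3"]], x$config$grf_target,
              x$converged["stage1"]))
  cat(sprintf("  stage 2: vertical GRF %.1f N, COP (%.1f, %.1f) mm, converged %s\n",
              x$audit2[["grf3"]], x$cop[1], x$cop[2],
              x$converged["stage2"]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# marker-driven stance
# ---------------------------------------------------------------------------

# Closed-form 3-point Procrustes: rigid transform (R, t) minimizing
# ||R p_i + t - q_i||^2 (Kabsch).
.rigid_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(P - matrix(cp, nrow(P), 3, byrow = TRUE)) %*%
    (Q - matrix(cq, nrow(Q), 3, byrow = TRUE))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

# Tibia pose trajectory from the three tibial markers: filtered markers,
# per-frame Procrustes fit against the build-posture marker positions.
.tibia_trajectory <- function(model, gait, cutoff = 20) {
  fs <- gait$params$sampling_rate
  nfr <- dim(gait$markers)[1]
  filtered <- gait$markers
  if (!is.null(cutoff) && cutoff > 0) {
    for (k in 1:3) {
      filtered[, k, ] <- lowpass_markers(gait$markers[, k, ], fs, cutoff)
    }
  }
  P <- rbind(landmark_position(model, "medial_malleolus"),
             landmark_position(model, "lateral_malleolus"),
             landmark_position(model, "tibial_tuberosity"))
  x0 <- model$bones$tibia$centroid
  poses_x <- matrix(NA_real_, nfr, 3)
  poses_q <- matrix(NA_real_, nfr, 4)
  for (i in seq_len(nfr)) {
    ft <- .rigid_fit(P, filtered[i, , ])
    poses_x[i, ] <- as.numeric(ft$R %*% x0) + ft$t
    poses_q[i, ] <- matrix_to_quat(ft$R)
  }
  times <- gait$time
  function(t) {
    t <- min(max(t, times[1]), times[length(times)])
    i <- findInterval(t, times, rightmost.closed = TRUE)
    i <- min(max(i, 1), nfr - 1)
    a <- (t - times[i]) / (times[i + 1] - times[i])
    q1 <- poses_q[i, ]; q2 <- poses_q[i + 1, ]
    if (sum(q1 * q2) < 0) q2 <- -q2
    q <- quat_normalize((1 - a) * q1 + a * q2) # nlerp (frames are dense)
    list(x = (1 - a) * poses_x[i, ] + a * poses_x[i + 1, ], q = q)
  }
}

#' Initialize the stance simulation at heel contact
#'
#' Reproduces the foot posture at the anchor instant (default 20 %
#' stance, where the tibia is nearly vertical) by settling under the
#' anchor-time loads with the tibia prescribed; then integrates the
#' driven model backward in time to heel contact and reverses the
#' velocities to obtain the forward initial condition.
#'
#' @param model a validated `foot_model`
#' @param gait a `gait_record`
#' @param anchor_pct stance percentage of the anchor (default 20)
#' @param dissipation damping (1/ms) used during the backward pass
#' @param dt time step (default [stable_dt()])
#' @return list with `state` (heel-contact state, time 0), `anchor_state`,
#'   `tibia_traj` (pose function of time, ms), `sim`
#' @export
initialize_stance <- function(model, gait, anchor_pct = 20,
                              dissipation = 0.05, dt = NULL) {
  if (anchor_pct <= 0 || anchor_pct >= 100) {
    stop("initialize_stance: anchor_pct must be inside the stance window")
  }
  model <- set_muscle_profiles(model, gait$muscles)
  sim <- compile_model(model)
  if (is.null(dt)) dt <- stable_dt(sim, 0.3)
  traj <- .tibia_trajectory(model, gait)
  dur <- diff(gait$stance_window)
  t_anchor <- gait$stance_window[1] + dur * anchor_pct / 100

  pose_anchor <- traj(t_anchor)
  state <- simulation_state(sim)
  # carry the whole skeleton to the anchor pose as a rigid set
  R0 <- quat_to_matrix(pose_anchor$q)
  x_t0 <- model$bones$tibia$centroid
  for (b in seq_len(sim$nb)) {
    state$x[b, ] <- as.numeric(R0 %*% (sim$x0[b, ] - x_t0)) +
      pose_anchor$x
    state$q[b, ] <- matrix_to_quat(R0)
  }
  loads_anchor <- sim_loads(
    gravity = TRUE, muscle_pct = anchor_pct,
    prescribed = list(tibia = list(x = pose_anchor$x, q = pose_anchor$q,
                                   v = c(0, 0, 0), w = c(0, 0, 0))))
  anchor_state <- settle_static(sim, state, loads_anchor, tol = 5e-4,
                                dt = dt, max_steps = 12000,
                                ramp_steps = 0)
  if (!isTRUE(attr(anchor_state, "converged")) &&
      attr(anchor_state, "residual") > 2e-2) {
    warning("initialize_stance: anchor settle did not fully converge ",
            sprintf("(residual %.2g)", attr(anchor_state, "residual")))
  }

  # backward pass: reversed tibial trajectory from the anchor to contact
  back_traj <- function(t) traj(t_anchor - t)
  st <- anchor_state
  st$time <- 0
  back <- simulate_run(
    sim, st, duration = t_anchor,
    loads_fn = function(t, s) {
      sim_loads(gravity = TRUE,
                muscle_pct = 100 * (t_anchor - t) / dur,
                prescribed = list(tibia = back_traj),
                damping = dissipation)
    },
    dt = dt, record_every = t_anchor)
  init <- back$state
  init$v <- -init$v
  init$w <- -init$w
  init$time <- 0
  # friction anchors and viscous history do not carry over
  init$anchors[] <- NA_real_
  init$col_state[] <- 0
  list(state = init, anchor_state = anchor_state, tibia_traj = traj,
       sim = sim, dt = dt, t_anchor = t_anchor)
}

#' Run the marker-driven stance simulation
#'
#' The tibia (with the welded fibula) follows the filtered, registered
#' marker trajectory; muscle forces follow their stance-percentage
#' profiles; gravity acts on the free bones. Records GRF, COP, plantar
#' contact tables, tissue tensions and joint angles over stance.
#'
#' @param model a validated `foot_model`
#' @param gait a `gait_record`
#' @param init result of [initialize_stance()] (built if omitted)
#' @param damping mass-proportional damping for the dynamic run, 1/ms
#' @param record_every ms between recorded frames
#' @return a `stance_result`: `frames`, `summary` (per-frame data frame:
#'   time, pct, GRF, COP, PA tension, residual), `joint_angles`, `sim`
#' @export
run_stance <- function(model, gait, init = NULL, damping = 0.05,
                       record_every = 5) {
  if (is.null(init)) init <- initialize_stance(model, gait)
  sim <- init$sim
  traj <- init$tibia_traj
  dur <- diff(gait$stance_window)
  run <- simulate_run(
    sim, init$state, duration = dur,
    loads_fn = function(t, s) {
      sim_loads(gravity = TRUE, muscle_pct = 100 * t / dur,
                prescribed = list(tibia = traj), damping = damping)
    },
    dt = init$dt, record_every = record_every)

  frames <- run$frames
  summ <- do.call(rbind, lapply(frames, function(fr) {
    data.frame(time = fr$time, pct = 100 * fr$time / dur,
               grf_x = fr$grf[1], grf_y = fr$grf[2], grf_z = fr$grf[3],
               cop_x = fr$cop[1], cop_y = fr$cop[2],
               pa_tension = sum(fr$pa_tension),
               min_tension = min(c(fr$tensions, fr$pa_tension)),
               residual = fr$residual)
  }))

  joints <- list(TC = c("tibia", "talus"), TN = c("talus", "navicular"),
                 CC = c("calcaneus", "cuboid"),
                 N1MT = c("navicular", "metatarsal_1"))
  ja <- do.call(rbind, lapply(frames, function(fr) {
    rows <- lapply(names(joints), function(jn) {
      pr <- sim$idx[[joints[[jn]][1]]]
      di <- sim$idx[[joints[[jn]][2]]]
      eu <- joint_angles(quat_to_matrix(fr$q[pr, ]),
                         quat_to_matrix(fr$q[di, ]))
      data.frame(time = fr$time, joint = jn, about_y = eu$about_y,
                 about_x = eu$about_x, about_z = eu$about_z,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))

  structure(list(frames = frames, summary = summ, joint_angles = ja,
                 state = run$state, sim = sim, gait = gait),
            class = "stance_result")
}

#' @export
print.stance_result <- function(x, ...) {
  s <- x$summary
  cat("<stance_result>\n")
  cat(sprintf("  %d frames over %.0f ms\n", nrow(s), max(s$time)))
  cat(sprintf("  peak vertical GRF %.1f N; AP GRF range [%.1f, %.1f] N\n",
              max(s$grf_z), min(s$grf_x), max(s$grf_x)))
  cat(sprintf("  peak PA tension %.1f N\n", max(s$pa_tension)))
  invisible(x)
}

#' Write the per-frame contact log of a protocol run to CSV
#' @param frames list of snapshots (from `simulate_run` or a result)
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_contact_log <- function(frames, path) {
  rows <- list()
  for (fr in frames) {
    ct <- fr$contacts
    if (is.null(ct) || !nrow(ct)) next
    df <- as.data.frame(ct)
    df$point <- rownames(ct)
    df$time <- fr$time
    rows[[length(rows) + 1]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(x = numeric(), y = numeric(), fn = numeric(),
               ftx = numeric(), fty = numeric(), mode = numeric(),
               point = character(), time = numeric())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Bone-to-bone joint rotations of an axial-loading result
#'
#' Relative y-x-z joint rotations at the final load level against the
#' zero-load reference, for the hindfoot/midfoot articulations the
#' axial experiment reports.
#'
#' @param result an `axial_loading_result`
#' @param joints named list of `c(proximal, distal)` bone pairs
#' @return data frame: joint, about_y, about_x, about_z (deg)
#' @export
axial_joint_angles <- function(result,
                               joints = list(
                                 subtalar = c("talus", "calcaneus"),
                                 talonavicular = c("talus", "navicular"),
                                 calcaneocuboid = c("calcaneus",
                                                    "cuboid"))) {
  sim <- result$sim
  st <- result$states[[length(result$states)]]
  ref <- result$states[[1]]
  rows <- lapply(names(joints), function(jn) {
    pr <- sim$idx[[joints[[jn]][1]]]
    di <- sim$idx[[joints[[jn]][2]]]
    eu <- joint_angles(quat_to_matrix(st$q[pr, ]),
                       quat_to_matrix(st$q[di, ]),
                       quat_to_matrix(ref$q[pr, ]),
                       quat_to_matrix(ref$q[di, ]))
    data.frame(joint = jn, about_y = eu$about_y, about_x = eu$about_x,
               about_z = eu$about_z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
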