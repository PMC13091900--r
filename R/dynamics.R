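#' Explicit rigid-body dynamics
#'
#' Semi-implicit (symplectic) Euler integration of all rigid bodies under
#' tissue, contact, muscle, gravity, and prescribed-displacement loads.
#' The model is first compiled into flat arrays ([compile_model()]); the
#' integrator then advances a [simulation_state()] with [sim_step()],
#' relaxes to statics with [settle_static()], or runs a recorded
#' trajectory with [simulate_run()].
#'
#' Articulations are assembled as congruent ball-in-socket penalties: a
#' frictionless congruent joint resists any relative translation of the
#' shared joint-center point while leaving rotation free, which is what a
#' penalty spring on the joint-center offset implements. (The convex
#' sphere-proxy law is available separately as
#' [cartilage_contact_force()].)
#'
#' @name dynamics
NULL

#' Compile a foot model for simulation
#'
#' Flattens the model into indexed arrays, applies the explicit-dynamics
#' mass floor (classic mass scaling: bodies lighter than `mass_floor` are
#' inflated so gram-scale sesamoids do not dictate the stable time step),
#' and attaches contact parameters.
#'
#' @param model a `foot_model` (or compatible hand-built structure)
#' @param friction a [friction_params()] list
#' @param cartilage_penalty N/mm for the articulation penalties
#' @param mass_floor g; dynamic mass floor per body
#' @param gyration_floor mm; minimum radius of gyration (the rotational
#'   counterpart of the mass floor)
#' @return a `sim_model` list of flat arrays
#' @export
compile_model <- function(model, friction = friction_params(),
                          cartilage_penalty = 400, mass_floor = 5,
                          gyration_floor = 5) {
  bn <- names(model$bones)
  nb <- length(bn)
  idx <- stats::setNames(seq_len(nb), bn)
  mass_true <- vapply(model$bones, `[[`, 0, "mass")
  mass <- pmax(mass_true, mass_floor)
  x0 <- t(vapply(model$bones, `[[`, numeric(3), "centroid"))
  dimnames(x0) <- NULL
  I_local <- lapply(seq_len(nb), function(i) {
    b <- model$bones[[i]]
    b$inertia * max(1, mass_floor / b$mass) +
      diag(3) * mass[i] * gyration_floor^2
  })
  names(I_local) <- bn
  I_local_inv <- lapply(I_local, solve)
  I_mean <- vapply(I_local, function(I) mean(diag(I)), 0)

  att_names <- names(model$attachments)
  if (length(att_names)) {
    att_body <- vapply(model$attachments, function(a) idx[[a$bone]],
                       integer(1))
    att_local <- t(vapply(model$attachments, function(a) a$local,
                          numeric(3)))
  } else {
    att_body <- integer(0)
    att_local <- matrix(0, 0, 3)
  }
  att_index <- stats::setNames(seq_along(att_names), att_names)

  # chains: straight (vectorized) vs sphere-threaded (per-chain loop)
  chain_names <- vapply(model$ligaments, `[[`, "", "name")
  straight <- vapply(model$ligaments, function(lg) {
    lg$n_spheres == 0L || length(lg$hosts) == 0
  }, TRUE)
  sc <- model$ligaments[straight]
  sc_spec <- list(
    names = vapply(sc, `[[`, "", "name"),
    o_att = vapply(sc, function(l) att_index[[l$origin_attachment]], 1L),
    i_att = vapply(sc, function(l) att_index[[l$insertion_attachment]], 1L),
    o_body = vapply(sc, function(l) idx[[l$origin_bone]], 1L),
    i_body = vapply(sc, function(l) idx[[l$insertion_bone]], 1L),
    k = vapply(sc, function(l) l$E * l$area / l$slack_length, 0),
    slack = vapply(sc, function(l) l$slack_length, 0))
  sphere_chains <- lapply(model$ligaments[!straight], function(lg) {
    list(name = lg$name,
         o_att = att_index[[lg$origin_attachment]],
         i_att = att_index[[lg$insertion_attachment]],
         o_body = idx[[lg$origin_bone]], i_body = idx[[lg$insertion_bone]],
         k = lg$E * lg$area / lg$slack_length, slack = lg$slack_length,
         n_spheres = lg$n_spheres, radius = lg$sphere_radius,
         hosts = unname(vapply(lg$hosts, function(h) idx[[h]], 1L)))
  })

  pa <- lapply(model$pa_slips, function(sp) {
    wrap <- sp$wrap_cylinder
    list(index = sp$index,
         o_att = att_index[[sp$origin_attachment]],
         i_att = att_index[[sp$insertion_attachment]],
         o_body = idx[[sp$origin_bone]], i_body = idx[[sp$insertion_bone]],
         via_att = if (!is.null(sp$via_attachment)) {
           att_index[[sp$via_attachment]]
         } else NA_integer_,
         via_body = if (!is.null(sp$via_bone)) idx[[sp$via_bone]]
                    else NA_integer_,
         wrap_body = if (!is.null(wrap)) idx[[wrap$bone]] else NA_integer_,
         wrap_point = if (!is.null(wrap)) wrap$point else NULL,
         wrap_axis = if (!is.null(wrap)) wrap$axis else NULL,
         wrap_radius = if (!is.null(wrap)) wrap$radius else NA_real_,
         k = sp$E * sp$area / sp$slack_length, slack = sp$slack_length)
  })

  muscles <- lapply(model$muscles, function(mu) {
    list(name = mu$name,
         atts = unname(vapply(mu$attachments, function(a) att_index[[a]],
                              1L)),
         bodies = unname(vapply(mu$bones, function(b) idx[[b]], 1L)),
         profile = mu$force_profile)
  })

  nc <- length(model$columns)
  col_spec <- list(
    n = nc,
    names = if (nc) vapply(model$columns, `[[`, "", "name") else character(),
    body = if (nc) vapply(model$columns, function(cc) idx[[cc$bone]], 1L)
           else integer(0),
    anchor = if (nc) t(vapply(model$columns, `[[`, numeric(3), "anchor"))
             else matrix(0, 0, 3),
    ref = if (nc) vapply(model$columns, `[[`, 0, "reference_thickness")
          else numeric(0),
    area = if (nc) vapply(model$columns, `[[`, 0, "area") else numeric(0),
    C = if (nc) vapply(model$columns, function(cc) cc$ogden$C, 0)
        else numeric(0),
    alpha = if (nc) vapply(model$columns, function(cc) cc$ogden$alpha, 0)
            else numeric(0),
    g1 = if (nc) vapply(model$columns, function(cc) cc$prony$g1, 0)
         else numeric(0),
    g2 = if (nc) vapply(model$columns, function(cc) cc$prony$g2, 0)
         else numeric(0),
    tau1 = if (nc) vapply(model$columns, function(cc) cc$prony$tau1, 0)
           else numeric(0),
    tau2 = if (nc) vapply(model$columns, function(cc) cc$prony$tau2, 0)
           else numeric(0))

  cart <- lapply(model$cartilage_pairs, function(cp) {
    a <- idx[[cp$bone_a]]; b <- idx[[cp$bone_b]]
    krot <- if (!is.null(cp$rot_stiffness)) cp$rot_stiffness else 0
    # rate damping capped at ~40 % of critical so very stiff variants do
    # not become viscosity-limited
    ct <- min(0.08 * cartilage_penalty,
              sqrt(cartilage_penalty * min(mass[a], mass[b])))
    cr <- if (krot > 0) {
      min(0.02 * krot, sqrt(krot * min(I_mean[a], I_mean[b])))
    } else 0
    list(a = a, b = b,
         ja = cp$contact_point - x0[a, ], # joint center,
         jb = cp$contact_point - x0[b, ], # body-local
         radius = cp$radius, penalty = cartilage_penalty,
         k_rot = krot, c_t = ct, c_r = cr,
         name = paste(cp$bone_a, cp$bone_b, sep = "/"))
  })

  welds <- lapply(model$welds, function(w) {
    p <- idx[[w$parent]]; ch <- idx[[w$child]]
    list(parent = p, child = ch,
         r_rel = model$bones[[w$child]]$centroid -
                 model$bones[[w$parent]]$centroid,
         q_rel = quat_identity())
  })

  ellipsoids <- lapply(model$bones, function(b) {
    list(semi = b$semi, R_ell = b$R_ell)
  })

  # internal pseudo-attachments (joint centers, column anchors, wrap axis
  # points): one vectorized transform then positions every anchor
  extra_body <- integer(0)
  extra_local <- list()
  push_att <- function(body, local) {
    extra_body[length(extra_body) + 1L] <<- body
    extra_local[[length(extra_local) + 1L]] <<- local
    length(att_names) + length(extra_body)
  }
  for (e in seq_along(cart)) {
    cart[[e]]$a_att <- push_att(cart[[e]]$a, cart[[e]]$ja)
    cart[[e]]$b_att <- push_att(cart[[e]]$b, cart[[e]]$jb)
  }
  if (nc) {
    col_spec$att <- vapply(seq_len(nc), function(e) {
      push_att(col_spec$body[e], col_spec$anchor[e, ])
    }, 1L)
  } else {
    col_spec$att <- integer(0)
  }
  for (e in seq_along(pa)) {
    pa[[e]]$wrap_att <- if (!is.na(pa[[e]]$wrap_body)) {
      push_att(pa[[e]]$wrap_body, pa[[e]]$wrap_point)
    } else NA_integer_
  }
  # generalized 6-DOF bushings (e.g. the rubber block of the axial rig):
  # anisotropic translational + rotational springs between two bodies
  bushings <- lapply(if (is.null(model$bushings)) list() else
                     model$bushings, function(bu) {
    a <- idx[[bu$parent]]; b <- idx[[bu$child]]
    list(a = a, b = b,
         a_att = push_att(a, bu$point - x0[a, ]),
         b_att = push_att(b, bu$point - x0[b, ]),
         kt = bu$kt, kr = bu$kr,
         c_t = pmin(0.05 * bu$kt,
                    sqrt(bu$kt * min(mass[a], mass[b]))),
         c_r = pmin(0.02 * bu$kr,
                    sqrt(bu$kr * min(I_mean[a], I_mean[b]))))
  })
  if (length(extra_body)) {
    att_body <- c(att_body, extra_body)
    att_local <- rbind(att_local, do.call(rbind, extra_local))
  }

  att_groups <- split(seq_along(att_body), att_body)

  cart_a_body <- vapply(cart, function(cp) cp$a, 1L)
  cart_b_body <- vapply(cart, function(cp) cp$b, 1L)
  cart_a_att <- vapply(cart, function(cp) cp$a_att, 1L)
  cart_b_att <- vapply(cart, function(cp) cp$b_att, 1L)
  cart_k <- vapply(cart, function(cp) cp$penalty, 0)
  cart_krot <- vapply(cart, function(cp) cp$k_rot, 0)
  cart_ct <- vapply(cart, function(cp) cp$c_t, 0)
  cart_cr <- vapply(cart, function(cp) cp$c_r, 0)

  structure(list(
    cart_a_body = cart_a_body, cart_b_body = cart_b_body,
    cart_a_att = cart_a_att, cart_b_att = cart_b_att,
    cart_k = cart_k, cart_krot = cart_krot,
    cart_ct = cart_ct, cart_cr = cart_cr,
    body_names = bn, nb = nb, idx = idx,
    mass = mass, mass_true = mass_true, inv_mass = 1 / mass,
    I_local = I_local, I_local_inv = I_local_inv, x0 = x0,
    att_body = att_body, att_local = att_local, att_index = att_index,
    att_groups = att_groups,
    sc = sc_spec, sphere_chains = sphere_chains, chain_names = chain_names,
    pa = pa, muscles = muscles, col = col_spec,
    cart = cart, bushings = bushings, welds = welds,
    ellipsoids = ellipsoids,
    friction = friction, cartilage_penalty = cartilage_penalty,
    landmark_lookup = .landmark_table(model, idx)
  ), class = "sim_model")
}

.landmark_table <- function(model, idx) {
  out <- list()
  for (b in model$bones) {
    for (nm in names(b$landmarks)) {
      out[[nm]] <- list(body = idx[[b$name]], local = b$landmarks[[nm]])
    }
  }
  out
}

#' Initial simulation state for a compiled model
#'
#' @param sim a `sim_model`
#' @return a `simulation_state`: per-body pose and velocity, per-column
#'   viscoelastic internal variables (h1, h2, previous elastic stress),
#'   per-column friction stick anchors, and the clock (ms)
#' @export
simulation_state <- function(sim) {
  structure(list(
    x = sim$x0,
    q = matrix(rep(quat_identity(), sim$nb), ncol = 4, byrow = TRUE),
    v = matrix(0, sim$nb, 3),
    w = matrix(0, sim$nb, 3),
    col_state = matrix(0, sim$col$n, 3,
                       dimnames = list(NULL, c("h1", "h2", "sig_prev"))),
    anchors = matrix(NA_real_, sim$col$n, 2),
    time = 0
  ), class = "simulation_state")
}

.rot_all <- function(state, nb) {
  lapply(seq_len(nb), function(i) quat_to_matrix(state$q[i, ]))
}

.attachment_positions <- function(sim, state, rots) {
  P <- matrix(0, length(sim$att_body), 3)
  x <- state$x
  for (bs in names(sim$att_groups)) {
    b <- as.integer(bs)
    ii <- sim$att_groups[[bs]]
    M <- sim$att_local[ii, , drop = FALSE] %*% t(rots[[b]])
    M[, 1] <- M[, 1] + x[b, 1]
    M[, 2] <- M[, 2] + x[b, 2]
    M[, 3] <- M[, 3] + x[b, 3]
    P[ii, ] <- M
  }
  P
}

.point_velocity <- function(state, b, p) {
  state$v[b, ] + cross3(state$w[b, ], p - state$x[b, ])
}

#' Loads specification
#'
#' @param gravity logical: apply gravity to free bodies
#' @param point_forces list of `list(body, local, force)` entries (local
#'   point in the body frame, force in N, global axes); `local = NULL`
#'   applies at the centroid
#' @param muscle_pct stance percentage at which to evaluate muscle
#'   profiles (`NULL` disables muscles)
#' @param prescribed named list: body -> `function(t)` returning
#'   `list(x, q, v, w)` or a fixed `list(x, q)` pose
#' @param constraints named list: body -> `list(trans, rot)` logical
#'   masks of FREE components (global axes)
#' @param damping mass-proportional damping coefficient, 1/ms
#' @return a `sim_loads` list
#' @export
sim_loads <- function(gravity = FALSE, point_forces = list(),
                      muscle_pct = NULL, prescribed = list(),
                      constraints = list(), damping = 0) {
  list(gravity = gravity, point_forces = point_forces,
       muscle_pct = muscle_pct, prescribed = prescribed,
       constraints = constraints, damping = damping)
}

# vectorized Ogden with linear continuation below lambda_min
.ogden_stress_vec <- function(lambda, C, alpha, lambda_min = 0.25) {
  lam <- pmax(lambda, lambda_min)
  s <- -(2 * C / alpha) * (lam^(alpha - 1) - lam^(-alpha / 2 - 1))
  low <- lambda < lambda_min
  if (any(low)) {
    slope <- -(2 * C / alpha) *
      ((alpha - 1) * lambda_min^(alpha - 2) +
       (alpha / 2 + 1) * lambda_min^(-alpha / 2 - 2))
    s[low] <- s[low] + (slope * (lambda - lambda_min))[low]
  }
  s
}

# ---------------------------------------------------------------------------
# force assembly (vectorized where it counts)
# ---------------------------------------------------------------------------

.assemble_forces <- function(sim, state, loads, dt, rots = NULL) {
  nb <- sim$nb
  if (is.null(rots)) rots <- .rot_all(state, nb)
  x <- state$x
  Tq <- matrix(0, nb, 3)
  # force contributions collected as (body, point, force) rows and
  # aggregated in one rowsum pass at the end
  ab <- integer(0)
  ap <- list()
  af <- list()
  nrow_acc <- 0L
  add <- function(b, p, f) {
    nrow_acc <<- nrow_acc + 1L
    ab[nrow_acc] <<- b
    ap[[nrow_acc]] <<- p
    af[[nrow_acc]] <<- f
  }
  P <- .attachment_positions(sim, state, rots)

  applied <- c(0, 0, 0)
  Fg <- matrix(0, nb, 3)
  if (isTRUE(loads$gravity)) {
    Fg[, 3] <- -sim$mass * GRAVITY_INTERNAL
    applied[3] <- applied[3] - sum(sim$mass) * GRAVITY_INTERNAL
  }
  for (pf in loads$point_forces) {
    b <- sim$idx[[pf$body]]
    p <- if (is.null(pf$local)) x[b, ] else {
      x[b, ] + as.numeric(rots[[b]] %*% pf$local)
    }
    add(b, p, pf$force)
    applied <- applied + pf$force
  }

  # straight tension-only chains, vectorized
  tensions <- stats::setNames(numeric(length(sim$chain_names)),
                              sim$chain_names)
  ns <- length(sim$sc$k)
  if (ns) {
    Po <- P[sim$sc$o_att, , drop = FALSE]
    Pi <- P[sim$sc$i_att, , drop = FALSE]
    D <- Pi - Po
    L <- sqrt(rowSums(D * D))
    Tn <- pmax(0, sim$sc$k * (L - sim$sc$slack))
    tensions[sim$sc$names] <- Tn
    act <- which(Tn > 0)
    if (length(act)) {
      U <- D[act, , drop = FALSE] / L[act]
      Fo <- U * Tn[act]
      bo <- sim$sc$o_body[act]
      bi <- sim$sc$i_body[act]
      bodies_sc <- c(bo, bi)
      pts_sc <- rbind(Po[act, , drop = FALSE], Pi[act, , drop = FALSE])
      f_sc <- rbind(Fo, -Fo)
    } else {
      bodies_sc <- integer(0)
      pts_sc <- matrix(0, 0, 3)
      f_sc <- matrix(0, 0, 3)
    }
  } else {
    bodies_sc <- integer(0)
    pts_sc <- matrix(0, 0, 3)
    f_sc <- matrix(0, 0, 3)
  }

  for (ch in sim$sphere_chains) {
    o <- P[ch$o_att, ]; i <- P[ch$i_att, ]
    surfaces <- lapply(ch$hosts, function(h) {
      list(center = x[h, ], semi = sim$ellipsoids[[h]]$semi,
           R = rots[[h]] %*% sim$ellipsoids[[h]]$R_ell)
    })
    res <- resolve_sphere_contacts(o, i, ch$n_spheres, surfaces,
                                   sphere_radius = ch$radius)
    Tn <- max(0, ch$k * (res$length - ch$slack))
    tensions[ch$name] <- Tn
    if (Tn > 0) {
      path <- res$path
      np <- nrow(path)
      add(ch$o_body, o, Tn * unit3(path[2, ] - o))
      add(ch$i_body, i, Tn * unit3(path[np - 1, ] - i))
      if (is.data.frame(res$contacts) && nrow(res$contacts)) {
        for (r in seq_len(nrow(res$contacts))) {
          si <- res$contacts$sphere[r]
          a <- unit3(path[si, ] - path[si + 1, ])
          bb <- unit3(path[si + 2, ] - path[si + 1, ])
          add(ch$hosts[1], path[si + 1, ], Tn * (a + bb))
        }
      }
    }
  }

  pa_tension <- numeric(length(sim$pa))
  for (si in seq_along(sim$pa)) {
    sp <- sim$pa[[si]]
    o <- P[sp$o_att, ]; i <- P[sp$i_att, ]
    if (!is.na(sp$via_att)) {
      via <- P[sp$via_att, ]
      L <- norm3(via - o) + norm3(i - via)
      Tn <- max(0, sp$k * (L - sp$slack))
      if (Tn > 0) {
        add(sp$o_body, o, Tn * unit3(via - o))
        add(sp$i_body, i, Tn * unit3(via - i))
        add(sp$via_body, via, Tn * (unit3(o - via) + unit3(i - via)))
      }
    } else if (!is.na(sp$wrap_body)) {
      wb <- sp$wrap_body
      cyl_pt <- P[sp$wrap_att, ]
      cyl_ax <- as.numeric(rots[[wb]] %*% sp$wrap_axis)
      w <- wrap_cylinder_length(o, i, cyl_pt, cyl_ax, sp$wrap_radius,
                                clamp = TRUE)
      Tn <- max(0, sp$k * (w$length - sp$slack))
      if (Tn > 0) {
        add(sp$o_body, o, Tn * w$dir1)
        add(sp$i_body, i, Tn * w$dir2)
        if (w$wrapped) {
          add(wb, (w$tangent1 + w$tangent2) / 2, -Tn * (w$dir1 + w$dir2))
        }
      }
    } else {
      d <- i - o; L <- norm3(d)
      Tn <- max(0, sp$k * (L - sp$slack))
      if (Tn > 0) {
        u <- d / L
        add(sp$o_body, o, Tn * u)
        add(sp$i_body, i, -Tn * u)
      }
    }
    pa_tension[si] <- Tn
  }

  muscle_forces <- stats::setNames(numeric(length(sim$muscles)),
                                   names(sim$muscles))
  if (!is.null(loads$muscle_pct)) {
    for (mi in seq_along(sim$muscles)) {
      mu <- sim$muscles[[mi]]
      if (is.null(mu$profile)) next
      Fm <- interp_clamped(loads$muscle_pct, mu$profile$pct,
                           mu$profile$force)
      muscle_forces[mi] <- Fm
      if (Fm <= 0) next
      pts <- P[mu$atts, , drop = FALSE]
      m <- nrow(pts)
      add(mu$bodies[1], pts[1, ], Fm * unit3(pts[2, ] - pts[1, ]))
      add(mu$bodies[m], pts[m, ], Fm * unit3(pts[m - 1, ] - pts[m, ]))
      if (m > 2) {
        for (k in 2:(m - 1)) {
          add(mu$bodies[k], pts[k, ],
              Fm * (unit3(pts[k - 1, ] - pts[k, ]) +
                    unit3(pts[k + 1, ] - pts[k, ])))
        }
      }
    }
  }

  # soft-tissue columns (vectorized constitutive + friction update)
  grf <- c(0, 0, 0)
  col <- sim$col
  col_state <- state$col_state
  anchors <- state$anchors
  contacts <- NULL
  bodies_col <- integer(0)
  pts_col <- matrix(0, 0, 3)
  f_col <- matrix(0, 0, 3)
  if (col$n) {
    cb <- col$body
    Ap <- P[col$att, , drop = FALSE]
    lambda <- Ap[, 3] / col$ref
    sig_e <- ifelse(lambda < 1,
                    .ogden_stress_vec(lambda, col$C, col$alpha), 0)
    dsig <- sig_e - col_state[, 3]
    x1 <- dt / col$tau1; e1 <- exp(-x1)
    x2 <- dt / col$tau2; e2 <- exp(-x2)
    r1 <- e1 * col_state[, 1] + col$g1 * ((1 - e1) / x1) * dsig
    r2 <- e2 * col_state[, 2] + col$g2 * ((1 - e2) / x2) * dsig
    col_state <- cbind(r1, r2, sig_e)
    fn0 <- pmax(0, (1 - col$g1 - col$g2) * sig_e + r1 + r2) * col$area
    vel <- state$v[cb, , drop = FALSE] +
      cross3_rows(state$w[cb, , drop = FALSE],
                  Ap - x[cb, , drop = FALSE])
    fr <- sim$friction
    fn <- pmax(0, fn0 - fr$normal_damping * col$area * vel[, 3] *
                 (fn0 > 0))
    active <- fn > 0
    kt <- fr$tangential_penalty
    new_anchor <- anchors
    ftx <- numeric(col$n); fty <- numeric(col$n)
    mode <- integer(col$n) # 0 separated, 1 stick, 2 slip
    if (any(active)) {
      ai <- which(active)
      miss <- ai[is.na(anchors[ai, 1])]
      new_anchor[miss, ] <- Ap[miss, 1:2, drop = FALSE]
      ft <- -kt * (Ap[ai, 1:2, drop = FALSE] -
                   new_anchor[ai, , drop = FALSE]) -
        0.2 * kt * vel[ai, 1:2, drop = FALSE]
      ftn <- sqrt(rowSums(ft^2))
      cap_s <- fr$mu_static * fn[ai]
      slip <- ftn > cap_s
      if (any(slip)) {
        scl <- (fr$mu_dynamic * fn[ai] / ftn)[slip]
        ft[slip, ] <- ft[slip, , drop = FALSE] * scl
        new_anchor[ai[slip], ] <- Ap[ai[slip], 1:2, drop = FALSE] +
          ft[slip, , drop = FALSE] / kt +
          0.2 * vel[ai[slip], 1:2, drop = FALSE]
      }
      mode[ai] <- ifelse(slip, 2L, 1L)
      ftx[ai] <- ft[, 1]; fty[ai] <- ft[, 2]
      bodies_col <- cb[ai]
      pts_col <- cbind(Ap[ai, 1, drop = TRUE], Ap[ai, 2, drop = TRUE], 0)
      f_col <- cbind(ftx[ai], fty[ai], fn[ai])
      grf <- c(sum(ftx), sum(fty), sum(fn))
    }
    new_anchor[!active, ] <- NA_real_
    anchors <- new_anchor
    contacts <- cbind(x = Ap[, 1], y = Ap[, 2], fn = fn, ftx = ftx,
                      fty = fty, mode = mode)
    rownames(contacts) <- col$names
  }

  # articulations: congruent ball-socket penalty (+ rate damping) and a
  # torsional spring standing in for articular congruence
  ncart <- length(sim$cart)
  bodies_ct <- integer(0)
  pts_ct <- matrix(0, 0, 3)
  f_ct <- matrix(0, 0, 3)
  if (ncart) {
    a_att <- sim$cart_a_att
    b_att <- sim$cart_b_att
    abod <- sim$cart_a_body
    bbod <- sim$cart_b_body
    Pa <- P[a_att, , drop = FALSE]
    Pb <- P[b_att, , drop = FALSE]
    U <- Pb - Pa
    mid <- (Pa + Pb) / 2
    va <- state$v[abod, , drop = FALSE] +
      cross3_rows(state$w[abod, , drop = FALSE],
                  mid - x[abod, , drop = FALSE])
    vb <- state$v[bbod, , drop = FALSE] +
      cross3_rows(state$w[bbod, , drop = FALSE],
                  mid - x[bbod, , drop = FALSE])
    f_on_a <- sim$cart_k * U + sim$cart_ct * (vb - va)
    bodies_ct <- c(abod, bbod)
    pts_ct <- rbind(mid, mid)
    f_ct <- rbind(f_on_a, -f_on_a)
    # torsional part (small loop: per-pair quaternion algebra)
    for (e in which(sim$cart_krot > 0)) {
      cp_a <- abod[e]; cp_b <- bbod[e]
      qa <- state$q[cp_a, ]; qb <- state$q[cp_b, ]
      qrel <- quat_multiply(qb, c(qa[1], -qa[2], -qa[3], -qa[4]))
      vn <- sqrt(sum(qrel[2:4]^2))
      krot <- sim$cart_krot[e]
      tau <- -sim$cart_cr[e] * (state$w[cp_b, ] - state$w[cp_a, ])
      if (vn > 1e-12) {
        theta <- 2 * atan2(vn, abs(qrel[1]))
        axis <- qrel[2:4] / vn * sign(qrel[1])
        tau <- tau - krot * theta * axis
      }
      Tq[cp_b, ] <- Tq[cp_b, ] + tau
      Tq[cp_a, ] <- Tq[cp_a, ] - tau
    }
  }

  for (bu in sim$bushings) {
    pa_ <- P[bu$a_att, ]; pb_ <- P[bu$b_att, ]
    mid <- (pa_ + pb_) / 2
    va <- .point_velocity(state, bu$a, mid)
    vb <- .point_velocity(state, bu$b, mid)
    f_on_a <- bu$kt * (pb_ - pa_) + bu$c_t * (vb - va)
    add(bu$a, mid, f_on_a)
    add(bu$b, mid, -f_on_a)
    qa <- state$q[bu$a, ]; qb <- state$q[bu$b, ]
    qrel <- quat_multiply(qb, c(qa[1], -qa[2], -qa[3], -qa[4]))
    vn <- sqrt(sum(qrel[2:4]^2))
    tau <- -bu$c_r * (state$w[bu$b, ] - state$w[bu$a, ])
    if (vn > 1e-12) {
      theta <- 2 * atan2(vn, abs(qrel[1]))
      tau <- tau - bu$kr * (theta * qrel[2:4] / vn * sign(qrel[1]))
    }
    Tq[bu$b, ] <- Tq[bu$b, ] + tau
    Tq[bu$a, ] <- Tq[bu$a, ] - tau
  }

  # aggregate all (body, point, force) rows in one pass
  if (nrow_acc) {
    bodies_all <- c(ab[seq_len(nrow_acc)], bodies_sc, bodies_col,
                    bodies_ct)
    pts_all <- rbind(do.call(rbind, ap[seq_len(nrow_acc)]), pts_sc,
                     pts_col, pts_ct)
    f_all <- rbind(do.call(rbind, af[seq_len(nrow_acc)]), f_sc, f_col,
                   f_ct)
  } else {
    bodies_all <- c(bodies_sc, bodies_col, bodies_ct)
    pts_all <- rbind(pts_sc, pts_col, pts_ct)
    f_all <- rbind(f_sc, f_col, f_ct)
  }
  F <- Fg
  if (length(bodies_all)) {
    tq_all <- cross3_rows(pts_all - x[bodies_all, , drop = FALSE], f_all)
    Fagg <- rowsum(f_all, bodies_all)
    Tagg <- rowsum(tq_all, bodies_all)
    ii <- as.integer(rownames(Fagg))
    F[ii, ] <- F[ii, ] + Fagg
    Tq[ii, ] <- Tq[ii, ] + Tagg
  }

  # weld transfer: children contribute to their parents
  for (wd in sim$welds) {
    p <- wd$parent; ch <- wd$child
    F[p, ] <- F[p, ] + F[ch, ]
    Tq[p, ] <- Tq[p, ] + Tq[ch, ] +
      cross3(x[ch, ] - x[p, ], F[ch, ])
    F[ch, ] <- 0
    Tq[ch, ] <- 0
  }

  list(F = F, Tq = Tq, col_state = col_state, anchors = anchors,
       grf = grf, applied = applied, contacts = contacts,
       tensions = tensions, pa_tension = pa_tension,
       muscle_forces = muscle_forces)
}
# ---------------------------------------------------------------------------
# integrator
# ---------------------------------------------------------------------------

#' Advance the state by one explicit step
#'
#' Symplectic Euler: velocities first (from assembled forces, with the
#' gyroscopic torque in the rotational update), then positions;
#' quaternions advance by incremental rotation and are renormalized.
#' Prescribed bodies follow their trajectories exactly at sample times;
#' constrained bodies have non-free velocity components zeroed.
#'
#' @param sim a `sim_model`
#' @param state a `simulation_state`
#' @param loads a [sim_loads()] list
#' @param dt time step, ms (> 0)
#' @return the advanced `simulation_state` (with `audit` attached)
#' @export
sim_step <- function(sim, state, loads, dt) {
  if (dt <= 0) stop("sim_step: dt must be > 0")
  nb <- sim$nb
  rots <- .rot_all(state, nb)
  fa <- .assemble_forces(sim, state, loads, dt, rots)

  kinematic <- rep(FALSE, nb)
  for (nm in names(loads$prescribed)) kinematic[sim$idx[[nm]]] <- TRUE
  for (wd in sim$welds) kinematic[wd$child] <- TRUE
  free <- !kinematic

  damp <- loads$damping
  p_before <- colSums(state$v[free, , drop = FALSE] * sim$mass[free])

  vfac <- 1 - damp * dt
  for (b in which(free)) {
    state$v[b, ] <- state$v[b, ] * vfac + dt * fa$F[b, ] * sim$inv_mass[b]
    R <- rots[[b]]
    wb <- state$w[b, ]
    Iw_w <- R %*% (sim$I_local[[b]] %*% (t(R) %*% wb))
    gyro <- cross3(wb, as.numeric(Iw_w))
    a_ang <- R %*% (sim$I_local_inv[[b]] %*%
                    (t(R) %*% (fa$Tq[b, ] - gyro)))
    state$w[b, ] <- wb * vfac + dt * as.numeric(a_ang)
    cm <- loads$constraints[[sim$body_names[b]]]
    if (!is.null(cm)) {
      state$v[b, !cm$trans] <- 0
      state$w[b, !cm$rot] <- 0
    }
    state$x[b, ] <- state$x[b, ] + dt * state$v[b, ]
    state$q[b, ] <- quat_integrate(state$q[b, ], state$w[b, ], dt)
  }

  t_new <- state$time + dt
  for (nm in names(loads$prescribed)) {
    b <- sim$idx[[nm]]
    tr <- loads$prescribed[[nm]]
    pose <- if (is.function(tr)) tr(t_new) else tr
    if (!is.null(pose$v)) state$v[b, ] <- pose$v else {
      state$v[b, ] <- (pose$x - state$x[b, ]) / dt
    }
    state$w[b, ] <- if (!is.null(pose$w)) pose$w else c(0, 0, 0)
    state$x[b, ] <- pose$x
    state$q[b, ] <- quat_normalize(pose$q)
  }
  for (wd in sim$welds) {
    p <- wd$parent; ch <- wd$child
    Rp <- quat_to_matrix(state$q[p, ])
    r <- as.numeric(Rp %*% wd$r_rel)
    state$x[ch, ] <- state$x[p, ] + r
    state$q[ch, ] <- quat_multiply(state$q[p, ], wd$q_rel)
    state$v[ch, ] <- state$v[p, ] + cross3(state$w[p, ], r)
    state$w[ch, ] <- state$w[p, ]
  }

  if (any(!is.finite(state$x)) || any(!is.finite(state$v)) ||
      any(!is.finite(state$w))) {
    bad <- which(!is.finite(rowSums(state$x) + rowSums(state$v) +
                            rowSums(state$w)))[1]
    stop(sprintf("sim_step: divergence at t = %.3f ms (body %s)",
                 t_new, sim$body_names[bad]))
  }

  state$col_state <- fa$col_state
  state$anchors <- fa$anchors
  state$time <- t_new
  p_after <- colSums(state$v[free, , drop = FALSE] * sim$mass[free])
  state$audit <- list(
    grf = fa$grf, applied = fa$applied, contacts = fa$contacts,
    tensions = fa$tensions, pa_tension = fa$pa_tension,
    muscle_forces = fa$muscle_forces,
    impulse = dt * colSums(fa$F[free, , drop = FALSE]),
    dp = p_after - p_before,
    max_accel = {
      A <- abs(fa$F * sim$inv_mass)
      A[kinematic, ] <- 0
      for (nm in names(loads$constraints)) {
        A[sim$idx[[nm]], !loads$constraints[[nm]]$trans] <- 0
      }
      max(A, 0)
    })
  state
}

#' Stable explicit time step estimate
#'
#' For every elastic element (ligament chains, PA slips, soft-tissue
#' columns linearized at 30 % compression, articulation penalties, floor
#' penalty) the natural frequency is estimated from its stiffness and the
#' smaller attached dynamic mass; the step is `safety * 2 / omega_max`,
#' capped at 1 ms.
#'
#' @param sim a `sim_model`
#' @param safety fraction of the stability bound (default 0.2)
#' @return time step, ms
#' @export
stable_dt <- function(sim, safety = 0.2) {
  I_mean <- vapply(sim$I_local, function(I) mean(diag(I)), 0)
  # per-body accumulated stiffness-compliance products (Gershgorin-style:
  # stiffnesses of all elements loading one body add up), plus the
  # viscous rates of the rate-damping terms (which scale with the
  # stiffnesses and impose their own explicit limit dt < 2/rate)
  S <- numeric(sim$nb)
  V <- numeric(sim$nb)
  acc <- function(body, k, lever2) {
    S[body] <<- S[body] + k * (1 / sim$mass[body] + lever2 / I_mean[body])
  }
  lever2_att <- rowSums(sim$att_local^2)
  if (length(sim$sc$k)) {
    for (e in seq_along(sim$sc$k)) {
      acc(sim$sc$o_body[e], sim$sc$k[e], lever2_att[sim$sc$o_att[e]])
      acc(sim$sc$i_body[e], sim$sc$k[e], lever2_att[sim$sc$i_att[e]])
    }
  }
  for (ch in sim$sphere_chains) {
    acc(ch$o_body, ch$k, lever2_att[ch$o_att])
    acc(ch$i_body, ch$k, lever2_att[ch$i_att])
  }
  for (sp in sim$pa) {
    acc(sp$o_body, sp$k, lever2_att[sp$o_att])
    acc(sp$i_body, sp$k, lever2_att[sp$i_att])
  }
  if (sim$col$n) {
    # worst-case column stiffness: the guarded Ogden law is linear below
    # lambda = 0.25, so its slope there bounds the stiffness everywhere
    lam <- 0.25
    slope <- (2 * sim$col$C / sim$col$alpha) *
      ((sim$col$alpha - 1) * lam^(sim$col$alpha - 2) +
       (sim$col$alpha / 2 + 1) * lam^(-sim$col$alpha / 2 - 2))
    kcol <- sim$col$area * slope / sim$col$ref
    for (e in seq_len(sim$col$n)) {
      acc(sim$col$body[e], kcol[e] + sim$friction$tangential_penalty,
          sum(sim$col$anchor[e, ]^2))
    }
  }
  for (cp in sim$cart) {
    acc(cp$a, cp$penalty, sum(cp$ja^2))
    acc(cp$b, cp$penalty, sum(cp$jb^2))
    S[cp$a] <- S[cp$a] + cp$k_rot / I_mean[cp$a]
    S[cp$b] <- S[cp$b] + cp$k_rot / I_mean[cp$b]
    for (bb in c(cp$a, cp$b)) {
      V[bb] <- V[bb] + cp$c_t * (1 / sim$mass[bb]) +
        cp$c_r / I_mean[bb]
    }
  }
  for (bu in sim$bushings) {
    kmax <- max(bu$kt)
    acc(bu$a, kmax, lever2_att[bu$a_att])
    acc(bu$b, kmax, lever2_att[bu$b_att])
    S[bu$a] <- S[bu$a] + max(bu$kr) / I_mean[bu$a]
    S[bu$b] <- S[bu$b] + max(bu$kr) / I_mean[bu$b]
    for (bb in c(bu$a, bu$b)) {
      V[bb] <- V[bb] + max(bu$c_t) / sim$mass[bb] +
        max(bu$c_r) / I_mean[bb]
    }
  }
  if (sim$col$n) {
    fr <- sim$friction
    for (e in seq_len(sim$col$n)) {
      b <- sim$col$body[e]
      V[b] <- V[b] + (fr$normal_damping * sim$col$area[e] +
                        0.2 * fr$tangential_penalty) / sim$mass[b]
    }
  }
  w2max <- max(S)
  vmax <- max(V)
  if (w2max == 0 && vmax == 0) return(1)
  dt_el <- if (w2max > 0) safety * 2 / sqrt(w2max) else 1
  dt_vi <- if (vmax > 0) 1.6 / vmax else 1
  min(1, dt_el, dt_vi)
}

#' Relax to a static solution by damped dynamics
#'
#' Dynamic relaxation: explicit stepping with mass-proportional damping
#' and kinetic-energy resets (velocities are zeroed whenever kinetic
#' energy peaks). Converged when the peak residual acceleration over the
#' free bodies falls below `tol`.
#'
#' @param sim a `sim_model`
#' @param state starting `simulation_state`
#' @param loads a [sim_loads()] list (constant loads)
#' @param tol residual acceleration, mm/ms^2
#' @param dt time step (default from [stable_dt()])
#' @param max_steps step budget
#' @param ramp_steps applied point forces are scaled in linearly over this
#'   many steps (softens the loading transient)
#' @return the relaxed state with attributes `converged` and `residual`
#' @export
settle_static <- function(sim, state, loads, tol = 2e-4, dt = NULL,
                          max_steps = 20000, ramp_steps = 2000) {
  if (is.null(dt)) dt <- stable_dt(sim, 0.3)
  # damping rate capped so slow (e.g. attached-mass) modes are not
  # overdamped into creep when the stable step is very small
  loads$damping <- max(loads$damping, min(0.002 / dt, 0.3))
  full_forces <- loads$point_forces
  residual <- Inf
  converged <- FALSE
  ke_max <- 0
  since_reset <- 0L
  for (s in seq_len(max_steps)) {
    if (s <= ramp_steps && length(full_forces)) {
      scl <- s / ramp_steps
      loads$point_forces <- lapply(full_forces, function(pf) {
        pf$force <- pf$force * scl
        pf
      })
    } else {
      loads$point_forces <- full_forces
    }
    state <- sim_step(sim, state, loads, dt)
    ke <- sum(sim$mass * rowSums(state$v^2)) / 2
    since_reset <- since_reset + 1L
    ke_max <- max(ke_max, ke)
    # kinetic damping: zero velocities once kinetic energy has clearly
    # passed a peak (windowed, so fast modes do not mask slow ones)
    if (since_reset > 100L && ke < 0.5 * ke_max && ke_max > 0) {
      state$v[] <- 0
      state$w[] <- 0
      ke_max <- 0
      since_reset <- 0L
    }
    residual <- state$audit$max_accel
    if (s > max(20, ramp_steps) && residual < tol) {
      converged <- TRUE
      break
    }
  }
  attr(state, "converged") <- converged
  attr(state, "residual") <- residual
  state
}

#' Run a recorded simulation
#'
#' Integrates from `state` for `duration` ms, calling `loads_fn(t, state)`
#' for the (possibly time-varying) loads and recording an audit frame
#' every `record_every` ms.
#'
#' @param sim a `sim_model`
#' @param state starting state
#' @param duration ms
#' @param loads_fn `function(t, state) -> sim_loads`
#' @param dt step, ms (default [stable_dt()])
#' @param record_every ms between recorded frames
#' @return list with the final `state` and `frames` (list of snapshots:
#'   time, body poses, GRF, COP, contact table, tissue tensions)
#' @export
simulate_run <- function(sim, state, duration, loads_fn, dt = NULL,
                         record_every = 5) {
  if (is.null(dt)) dt <- stable_dt(sim, 0.3)
  n_steps <- ceiling(duration / dt)
  rec_stride <- max(1L, round(record_every / dt))
  frames <- list()
  for (s in seq_len(n_steps)) {
    loads <- loads_fn(state$time, state)
    state <- sim_step(sim, state, loads, dt)
    if (s %% rec_stride == 0 || s == n_steps) {
      frames[[length(frames) + 1]] <- .snapshot(sim, state)
    }
  }
  list(state = state, frames = frames)
}

.snapshot <- function(sim, state) {
  au <- state$audit
  cop <- c(NA_real_, NA_real_)
  if (!is.null(au$contacts) && nrow(au$contacts) &&
      sum(au$contacts[, "fn"]) > 1e-9) {
    wsum <- sum(au$contacts[, "fn"])
    cop <- c(sum(au$contacts[, "x"] * au$contacts[, "fn"]) / wsum,
             sum(au$contacts[, "y"] * au$contacts[, "fn"]) / wsum)
  }
  list(time = state$time, x = state$x, q = state$q,
       grf = au$grf, applied = au$applied, residual = au$max_accel,
       cop = cop,
       contacts = au$contacts, tensions = au$tensions,
       pa_tension = au$pa_tension, muscle_forces = au$muscle_forces)
}

#' Pose of a named landmark at the current state
#' @param sim a `sim_model`
#' @param state a `simulation_state`
#' @param name landmark name
#' @return global position, mm
#' @export
landmark_at <- function(sim, state, name) {
  lk <- sim$landmark_lookup[[name]]
  if (is.null(lk)) stop("unknown landmark: ", name)
  state$x[lk$body, ] +
    as.numeric(quat_to_matrix(state$q[lk$body, ]) %*% lk$local)
}

#' Minimal point-mass model for integrator verification
#'
#' Builds a `foot_model`-compatible structure of free point masses joined
#' by tension-only chains, without contact or tissue inventories. Useful
#' for validating the integrator against closed-form mechanics.
#'
#' @param masses vector of masses, g
#' @param positions n x 3 matrix, mm
#' @param springs data frame with columns `i`, `j`, `k` (N/mm) and
#'   `slack` (mm)
#' @return a `foot_model`-like list accepted by [compile_model()]
#' @export
point_mass_model <- function(masses, positions, springs = NULL) {
  n <- length(masses)
  positions <- matrix(positions, n, 3)
  bones <- lapply(seq_len(n), function(i) {
    r <- max(1, (masses[i] / (4 / 3 * pi * 1.5e-3))^(1 / 3))
    list(name = paste0("p", i), mass = masses[i],
         centroid = positions[i, ],
         inertia = diag(rep(2 / 5 * masses[i] * r^2, 3)),
         orientation = quat_identity(),
         semi = rep(r, 3), R_ell = diag(3),
         surface = NULL, landmarks = list())
  })
  names(bones) <- paste0("p", seq_len(n))
  attachments <- list()
  ligaments <- list()
  if (!is.null(springs)) {
    for (r in seq_len(nrow(springs))) {
      i <- springs$i[r]; j <- springs$j[r]
      ao <- paste0("s", r, "_o"); ai <- paste0("s", r, "_i")
      attachments[[ao]] <- list(bone = paste0("p", i), local = c(0, 0, 0))
      attachments[[ai]] <- list(bone = paste0("p", j), local = c(0, 0, 0))
      slack <- springs$slack[r]
      ligaments[[r]] <- list(
        name = paste0("s", r), category = "plantar", bundle_count = 1L,
        origin_bone = paste0("p", i), origin_attachment = ao,
        insertion_bone = paste0("p", j), insertion_attachment = ai,
        E = springs$k[r] * slack, area = 1, sphere_radius = 0.5,
        n_spheres = 0L, hosts = character(), slack_length = slack)
    }
    names(ligaments) <- vapply(ligaments, `[[`, "", "name")
  }
  structure(list(bones = bones, attachments = attachments,
                 ligaments = ligaments, pa_slips = list(),
                 muscles = list(), columns = list(),
                 cartilage_pairs = list(), welds = list(),
                 materials = NULL,
                 build_params = list(scale = NA, arch_ratio = NA,
                                     seed = 0L, side = "right")),
            class = "foot_model")
}
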