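#' Tension-only tissue elements
#'
#' Ligaments are chains of tension-only springs threaded through small
#' non-penetrating spheres that may slide frictionlessly over bone
#' surfaces; the plantar aponeurosis is ten tension-only slips that wrap
#' the metatarsal-head cylinders (slip 1 routes through the sesamoids);
#' muscles are piecewise-straight force paths; the plantar soft tissue is
#' a bed of uniaxial Ogden/Prony columns that push but never pull.
#'
#' @name tissues
NULL

#' Slack length rule
#'
#' The slack (zero-force) length of a tension-only element from its length
#' in the build reference posture: 1.1 x the reference length by default;
#' the lateral hindfoot and plantar groups (already taut, respectively not
#' shortened, in the reference posture) keep the reference length itself.
#' The plantar aponeurosis uses the `"plantar"` rule.
#'
#' @param reference_length element length in the reference posture, mm
#' @param category `"default"`, `"lateral_hindfoot"` or `"plantar"`
#' @return slack length, mm
#' @export
assign_slack_length <- function(reference_length,
                                category = c("default", "lateral_hindfoot",
                                             "plantar")) {
  if (any(reference_length <= 0)) {
    stop("assign_slack_length: reference_length must be > 0")
  }
  category <- match.arg(category)
  factor <- switch(category, default = 1.1, lateral_hindfoot = 1.0,
                   plantar = 1.0)
  factor * reference_length
}

#' Tension of a ligament chain at a given path length
#'
#' Linear in engineering strain above slack: `EA/slack * (L - slack)`,
#' zero at or below slack. A bundle of `n` sub-chains with total area A
#' along the same path carries the same total tension as one chain of
#' area A.
#'
#' @param path_length current origin-to-insertion path length, mm
#' @param chain a ligament chain entry (fields `E`, `area`, `slack_length`)
#' @return tension, N (>= 0)
#' @export
chain_tension <- function(path_length, chain) {
  if (any(path_length <= 0)) stop("chain_tension: path_length must be > 0")
  k <- chain$E * chain$area / chain$slack_length
  pmax(0, k * (path_length - chain$slack_length))
}

# ---------------------------------------------------------------------------
# sphere-chain contact resolution
# ---------------------------------------------------------------------------

#' Resolve ligament-chain sphere contacts against bone surfaces
#'
#' Spheres are placed evenly along the straight origin-insertion segment
#' and projected out of any host surface they penetrate, along the local
#' outward normal (frictionless contact: the push has no tangential
#' component). Surfaces may be triangle meshes
#' (`list(vertices, faces)`) or analytic ellipsoids
#' (`list(center, semi, R)`).
#'
#' @param origin,insertion chain endpoints, mm (global)
#' @param n_spheres number of interior spheres
#' @param surfaces list of host surfaces
#' @param sphere_radius sphere radius, mm
#' @param tension chain tension used to report contact force magnitudes, N
#' @return list with `positions` (n x 3), `path` ((n+2) x 3 polyline),
#'   `length` (polyline length, mm), and `contacts` (per-sphere force
#'   vector and normal; zero rows when no sphere touches)
#' @export
resolve_sphere_contacts <- function(origin, insertion, n_spheres, surfaces,
                                    sphere_radius = 0.5, tension = 0) {
  if (n_spheres < 1) {
    path <- rbind(origin, insertion)
    return(list(positions = matrix(0, 0, 3), path = path,
                length = norm3(insertion - origin),
                contacts = data.frame()))
  }
  tt <- seq_len(n_spheres) / (n_spheres + 1)
  pos <- outer(tt, insertion - origin) + matrix(origin, n_spheres, 3,
                                                byrow = TRUE)
  normals <- matrix(0, n_spheres, 3)
  touched <- logical(n_spheres)
  for (i in seq_len(n_spheres)) {
    p <- pos[i, ]
    for (s in surfaces) {
      proj <- .surface_project(p, s, sphere_radius)
      if (proj$penetrating) {
        if (proj$deep) {
          stop("resolve_sphere_contacts: sphere fully inside a host surface")
        }
        p <- proj$point
        normals[i, ] <- proj$normal
        touched[i] <- TRUE
      }
    }
    pos[i, ] <- p
  }
  path <- rbind(origin, pos, insertion)
  seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                          path[-nrow(path), , drop = FALSE])^2))
  contacts <- if (any(touched)) {
    # contact force balances the turn of the taut chain at the sphere
    idx <- which(touched)
    force <- t(vapply(idx, function(i) {
      a <- unit3(path[i, ] - path[i + 1, ])      # toward previous node
      b <- unit3(path[i + 2, ] - path[i + 1, ])  # toward next node
      -tension * (a + b) # reaction pushing the chain off the surface
    }, numeric(3)))
    data.frame(sphere = idx, fx = force[, 1], fy = force[, 2],
               fz = force[, 3], nx = normals[idx, 1], ny = normals[idx, 2],
               nz = normals[idx, 3])
  } else {
    data.frame()
  }
  list(positions = pos, path = path, length = sum(seglen),
       contacts = contacts)
}

# project a sphere center out of a surface if it penetrates; `deep` marks a
# center far inside a closed surface (initialization error)
.surface_project <- function(p, surface, radius) {
  if (!is.null(surface$vertices)) {
    cp <- mesh_closest_point(p, surface$vertices, surface$faces)
    inside <- mesh_contains(p, surface$vertices, surface$faces)
    dist <- if (inside) -cp$distance else cp$distance
    if (dist >= radius) {
      return(list(penetrating = FALSE))
    }
    n <- cp$normal
    if (inside && sum((p - cp$point) * n) > 0) n <- -n
    if (!inside && sum((p - cp$point) * n) < 0) n <- -n
    list(penetrating = TRUE, deep = inside && cp$distance > 4 * radius,
         point = cp$point + radius * n, normal = n)
  } else {
    lv <- ellipsoid_level(matrix(p, 1, 3), surface$center,
                          surface$semi + radius, surface$R)
    if (lv >= 1) return(list(penetrating = FALSE))
    pr <- ellipsoid_project(p, surface$center, surface$semi + radius,
                            surface$R)
    deep <- lv < 0.25
    list(penetrating = TRUE, deep = deep, point = pr$point,
         normal = pr$normal)
  }
}

# ---------------------------------------------------------------------------
# plantar aponeurosis cylinder wrapping
# ---------------------------------------------------------------------------

#' Path length of a line wrapping a cylinder
#'
#' Shortest path from `p1` to `p2` around an infinite cylinder (axis point
#' `c0`, unit axis `axis`, radius `r`): the straight distance if the
#' segment clears the cylinder, otherwise the tangent-arc-tangent geodesic
#' (obstacle-set method). Also returns the unit pull directions at the two
#' endpoints.
#'
#' @param p1,p2 endpoints, mm
#' @param c0 point on the cylinder axis, mm
#' @param axis unit axis direction
#' @param r cylinder radius, mm (> 0)
#' @return list with `length`, `wrapped`, `dir1`, `dir2` (unit vectors
#'   pointing from each endpoint into the path)
#' @export
wrap_cylinder_length <- function(p1, p2, c0, axis, r, clamp = FALSE) {
  if (r <= 0) stop("wrap_cylinder_length: radius must be > 0")
  Rf <- frame_from_axis(axis) # columns: axis, e1, e2
  to_local <- function(p) as.numeric(t(Rf) %*% (p - c0)) # (axial, u, v)
  l1 <- to_local(p1); l2 <- to_local(p2)
  q1 <- l1[2:3]; q2 <- l2[2:3] # in-plane coordinates
  r1 <- sqrt(sum(q1^2)); r2 <- sqrt(sum(q2^2))
  if (r1 < r - 1e-9 || r2 < r - 1e-9) {
    if (!clamp) stop("wrap_cylinder_length: endpoint inside the cylinder")
    # transient grazing during dynamics: shrink the obstacle instead
    r <- 0.98 * min(r1, r2)
    if (r <= 1e-9) {
      return(list(length = norm3(p2 - p1), wrapped = FALSE,
                  dir1 = unit3(p2 - p1), dir2 = unit3(p1 - p2)))
    }
  }
  # distance from the in-plane segment to the origin
  d <- q2 - q1
  tseg <- if (sum(d^2) > 0) -sum(q1 * d) / sum(d^2) else 0
  tseg <- min(max(tseg, 0), 1)
  closest <- q1 + tseg * d
  if (sqrt(sum(closest^2)) >= r - 1e-12) {
    return(list(length = norm3(p2 - p1), wrapped = FALSE,
                dir1 = unit3(p2 - p1), dir2 = unit3(p1 - p2)))
  }
  # tangent points in 2D (wrap side chosen to shorten the arc)
  tangent_pts <- function(q) {
    rq <- sqrt(sum(q^2))
    a <- r^2 / rq^2
    b <- r * sqrt(rq^2 - r^2) / rq^2
    list(t_pos = a * q + b * c(-q[2], q[1]),
         t_neg = a * q - b * c(-q[2], q[1]))
  }
  tp1 <- tangent_pts(q1); tp2 <- tangent_pts(q2)
  arc_len <- function(a, b) {
    ang <- acos(min(1, max(-1, sum(a * b) / r^2)))
    r * ang
  }
  best <- NULL
  for (ta in tp1) for (tb in tp2) {
    L2d <- sqrt(sum((q1 - ta)^2)) + arc_len(ta, tb) + sqrt(sum((q2 - tb)^2))
    if (is.null(best) || L2d < best$L2d) best <- list(ta = ta, tb = tb,
                                                      L2d = L2d)
  }
  # lift: distribute the axial travel along the unrolled 2D path
  dz <- l2[1] - l1[1]
  s1 <- sqrt(sum((q1 - best$ta)^2))
  sarc <- arc_len(best$ta, best$tb)
  total2d <- best$L2d
  z_ta <- l1[1] + dz * s1 / total2d
  z_tb <- l1[1] + dz * (s1 + sarc) / total2d
  seg1 <- sqrt(s1^2 + (z_ta - l1[1])^2)
  helix <- sqrt(sarc^2 + (z_tb - z_ta)^2)
  seg2 <- sqrt(sum((q2 - best$tb)^2) + (l2[1] - z_tb)^2)
  from_local <- function(ax, q) as.numeric(c0 + Rf %*% c(ax, q))
  T1 <- from_local(z_ta, best$ta)
  T2 <- from_local(z_tb, best$tb)
  list(length = seg1 + helix + seg2, wrapped = TRUE,
       dir1 = unit3(T1 - p1), dir2 = unit3(T2 - p2),
       tangent1 = T1, tangent2 = T2)
}

#' Path length and endpoint pull directions of a PA slip
#'
#' Straight origin-to-insertion distance unless the slip's metatarsal-head
#' cylinder interferes, in which case the tangent-arc-tangent wrap is
#' used. Slip 1 instead routes through its sesamoid via point.
#'
#' @param slip a PA slip entry from a `foot_model`
#' @param origin,insertion,via global endpoint (and optional via) points mm
#' @param cylinder global cylinder `list(point, axis, radius)` or `NULL`
#' @return list with `length`, `dir_origin`, `dir_insertion`, `wrapped`
#' @export
slip_path_length <- function(slip, origin, insertion, via = NULL,
                             cylinder = NULL) {
  if (!is.null(via)) {
    L <- norm3(via - origin) + norm3(insertion - via)
    return(list(length = L, dir_origin = unit3(via - origin),
                dir_insertion = unit3(via - insertion), wrapped = FALSE))
  }
  if (is.null(cylinder)) {
    return(list(length = norm3(insertion - origin),
                dir_origin = unit3(insertion - origin),
                dir_insertion = unit3(origin - insertion), wrapped = FALSE))
  }
  w <- wrap_cylinder_length(origin, insertion, cylinder$point,
                            cylinder$axis, cylinder$radius)
  list(length = w$length, dir_origin = w$dir1, dir_insertion = w$dir2,
       wrapped = w$wrapped,
       tangent_origin = if (w$wrapped) w$tangent1 else NULL,
       tangent_insertion = if (w$wrapped) w$tangent2 else NULL)
}

# ---------------------------------------------------------------------------
# muscles
# ---------------------------------------------------------------------------

#' Muscle force magnitude at a stance fraction
#'
#' Piecewise-linear interpolation of the sampled force profile. Times
#' outside `[0, 100]` are clamped with a warning.
#'
#' @param t_pct stance percentage
#' @param path a muscle path with `force_profile` (`data.frame(pct, force)`)
#' @return force, N
#' @export
muscle_force_at <- function(t_pct, path) {
  prof <- path$force_profile
  if (is.null(prof) || nrow(prof) == 0) return(rep(0, length(t_pct)))
  if (any(t_pct < 0 | t_pct > 100)) {
    warning("muscle_force_at: stance percentage clamped to [0, 100]")
  }
  interp_clamped(t_pct, prof$pct, prof$force)
}

#' Attach muscle force profiles to a model
#'
#' @param model a `foot_model`
#' @param profiles data frame with columns `pct` and one column per muscle
#'   (TS, TA, EDL, EHL), forces in N
#' @return the model with profiles attached
#' @export
set_muscle_profiles <- function(model, profiles) {
  if (!"pct" %in% names(profiles)) {
    stop("set_muscle_profiles: profiles need a 'pct' column")
  }
  if (any(diff(profiles$pct) <= 0)) {
    stop("set_muscle_profiles: 'pct' must be strictly increasing")
  }
  for (mn in names(model$muscles)) {
    if (!mn %in% names(profiles)) {
      stop("set_muscle_profiles: missing profile column ", mn)
    }
    if (any(profiles[[mn]] < 0)) {
      stop("set_muscle_profiles: forces must be >= 0 (", mn, ")")
    }
    model$muscles[[mn]]$force_profile <- data.frame(pct = profiles$pct,
                                                    force = profiles[[mn]])
  }
  model
}

#' Default synthetic muscle force profiles
#'
#' Physiologic shapes for a ~72 kg adult: triceps surae rising to a late
#' stance peak, tibialis anterior peaking just after heel contact, small
#' long-toe-extensor forces. These are synthetic stand-ins, not subject
#' measurements.
#'
#' @return data frame with columns pct, TS, TA, EDL, EHL (N)
#' @export
default_muscle_profiles <- function() {
  data.frame(
    pct = seq(0, 100, by = 10),
    TS = c(0, 40, 120, 250, 400, 600, 850, 1050, 900, 300, 0),
    TA = c(250, 180, 80, 30, 10, 5, 5, 10, 30, 60, 120),
    EDL = c(150, 100, 60, 30, 20, 15, 15, 20, 30, 50, 80),
    EHL = c(80, 60, 40, 25, 15, 10, 10, 15, 25, 40, 60))
}

# ---------------------------------------------------------------------------
# soft-tissue columns
# ---------------------------------------------------------------------------

#' Compressive force of a plantar soft-tissue column
#'
#' Uniaxial Ogden stress at stretch `current/reference`, filtered through
#' the Prony hereditary update, times the column area; contact-like (zero
#' in tension / separation).
#'
#' @param column a column entry (fields `reference_thickness`, `area`,
#'   `ogden`, `prony`)
#' @param current_thickness mm (> 0)
#' @param state a `prony_state`
#' @param dt time step, ms
#' @return list with `force` (N, >= 0) and the updated `state`
#' @export
column_force <- function(column, current_thickness, state, dt) {
  if (current_thickness <= 0) {
    stop("column_force: current_thickness must be > 0")
  }
  lambda <- current_thickness / column$reference_thickness
  sigma_e <- if (lambda < 1) {
    ogden_uniaxial_stress(lambda, column$ogden)
  } else 0
  upd <- viscoelastic_stress_update(sigma_e, state, column$prony, dt)
  list(force = max(0, upd$stress) * column$area, state = upd$state)
}

# ---------------------------------------------------------------------------
# model-level slack assignment (build posture = reference posture)
# ---------------------------------------------------------------------------

assign_model_slack <- function(model) {
  for (nm in names(model$ligaments)) {
    lg <- model$ligaments[[nm]]
    o <- attachment_position(model, lg$origin_attachment)
    i <- attachment_position(model, lg$insertion_attachment)
    ref <- norm3(i - o)
    model$ligaments[[nm]]$slack_length <-
      assign_slack_length(ref, lg$category)
  }
  for (k in seq_along(model$pa_slips)) {
    sp <- model$pa_slips[[k]]
    o <- attachment_position(model, sp$origin_attachment)
    i <- attachment_position(model, sp$insertion_attachment)
    via <- if (!is.null(sp$via_attachment)) {
      attachment_position(model, sp$via_attachment)
    } else NULL
    cyl <- if (!is.null(sp$wrap_cylinder)) {
      b <- model$bones[[sp$wrap_cylinder$bone]]
      list(point = b$centroid + sp$wrap_cylinder$point,
           axis = sp$wrap_cylinder$axis, radius = sp$wrap_cylinder$radius)
    } else NULL
    ref <- slip_path_length(sp, o, i, via = via, cylinder = cyl)$length
    # PA slack: reference-posture length (no 1.1 factor)
    model$pa_slips[[k]]$slack_length <- assign_slack_length(ref, "plantar")
  }
  model
}
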