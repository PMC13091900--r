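#' Penalty contact with Coulomb friction
#'
#' The floor is the rigid plane z = 0. Normal contact is penalty-based;
#' tangential friction uses a stick anchor spring capped at the Coulomb
#' cone (stick) and a kinetic force opposing the slip velocity (slip),
#' with a small regularization velocity at the transition. Cartilage
#' (bone-bone) contact is a frictionless penalty on proxy sphere overlap.
#'
#' @name contact
NULL

#' Friction and penalty parameters for floor contact
#'
#' @param mu_static,mu_dynamic Coulomb coefficients (default 0.6)
#' @param normal_penalty N/mm
#' @param tangential_penalty N/mm
#' @param regularization_velocity mm/ms below which slip is treated as
#'   stick for mode classification
#' @param normal_damping N per mm/ms of closing velocity
#' @return a `friction_params` list
#' @export
friction_params <- function(mu_static = 0.6, mu_dynamic = 0.6,
                            normal_penalty = 150, tangential_penalty = 80,
                            regularization_velocity = 1e-3,
                            normal_damping = 0.05) {
  if (mu_static < 0 || mu_dynamic < 0) {
    stop("friction_params: friction coefficients must be >= 0")
  }
  if (normal_penalty <= 0 || tangential_penalty <= 0) {
    stop("friction_params: penalties must be > 0")
  }
  list(mu_static = mu_static, mu_dynamic = mu_dynamic,
       normal_penalty = normal_penalty,
       tangential_penalty = tangential_penalty,
       regularization_velocity = regularization_velocity,
       normal_damping = normal_damping)
}

#' Floor contact force at a single point
#'
#' Separated points carry no force. In contact, the normal force is
#' `penalty x penetration` plus a small closing-velocity damping term
#' (never negative), and the tangential force is an anchor-spring force
#' capped at the friction cone: inside the cone the point sticks, on the
#' cone it slips with `|Ft| = mu_d Fn` opposing the slip velocity.
#'
#' @param point list with `position` (mm, global), `anchor` (stick anchor,
#'   xy mm, may be `NULL` to initialize at the contact point)
#' @param velocity point velocity, mm/ms
#' @param params a [friction_params()] list
#' @param normal_force optional externally supplied normal force (N); when
#'   given (e.g. from a soft-tissue column) it replaces the penalty term
#' @return list with `force` (3-vector N), `mode`
#'   (`"separated" | "stick" | "slip"`) and the updated `anchor`
#' @export
floor_contact_force <- function(point, velocity, params,
                                normal_force = NULL) {
  p <- point$position
  penetration <- -p[3]
  if (is.null(normal_force)) {
    if (penetration <= 0) {
      return(list(force = c(0, 0, 0), mode = "separated", anchor = NULL))
    }
    fn <- params$normal_penalty * penetration -
      params$normal_damping * params$normal_penalty * velocity[3]
    fn <- max(0, fn)
  } else {
    fn <- normal_force
    if (fn <= 0) {
      return(list(force = c(0, 0, 0), mode = "separated", anchor = NULL))
    }
  }
  anchor <- point$anchor
  if (is.null(anchor)) anchor <- p[1:2]
  ft <- -params$tangential_penalty * (p[1:2] - anchor) -
    0.2 * params$tangential_penalty * velocity[1:2]
  ftn <- sqrt(sum(ft^2))
  cap_static <- params$mu_static * fn
  if (ftn <= cap_static) {
    mode <- "stick"
  } else {
    cap <- params$mu_dynamic * fn
    ft <- ft * (cap / ftn)
    # drag the anchor so the spring sits exactly on the cone
    anchor <- p[1:2] + ft / params$tangential_penalty +
      0.2 * velocity[1:2]
    mode <- "slip"
  }
  list(force = c(ft[1], ft[2], fn), mode = mode, anchor = anchor)
}

#' Frictionless cartilage contact between proxy spheres
#'
#' Equal-and-opposite forces along the center line when the spheres
#' overlap; zero otherwise. Overlap beyond `max_overlap` signals a broken
#' configuration and raises an error naming the pair.
#'
#' @param center_a,center_b sphere centers, mm (global)
#' @param radius_a,radius_b sphere radii, mm
#' @param penalty N/mm
#' @param pair_name used in error messages
#' @param max_overlap mm
#' @return list with `force_on_a`, `force_on_b` (3-vectors, N),
#'   `overlap` (mm), `point` (contact point, mm)
#' @export
cartilage_contact_force <- function(center_a, center_b, radius_a, radius_b,
                                    penalty, pair_name = "pair",
                                    max_overlap = Inf) {
  d <- center_b - center_a
  dist <- norm3(d)
  overlap <- (radius_a + radius_b) - dist
  if (overlap <= 0 || dist < 1e-9) {
    return(list(force_on_a = c(0, 0, 0), force_on_b = c(0, 0, 0),
                overlap = max(0, overlap),
                point = (center_a + center_b) / 2))
  }
  if (overlap > max_overlap) {
    stop("cartilage_contact_force: deep penetration at ", pair_name,
         sprintf(" (%.2f mm)", overlap))
  }
  n <- d / dist
  f <- penalty * overlap
  list(force_on_a = -f * n, force_on_b = f * n, overlap = overlap,
       point = center_a + n * (radius_a - overlap / 2))
}
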