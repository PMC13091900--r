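#' Constitutive laws and material registry
#'
#' The model works in a consistent (mm, g, ms) unit system, in which forces
#' come out in N and stresses in MPa, so the constitutive constants can be
#' used exactly as tabulated. Gravitational acceleration is 9.81 m/s^2
#' (9.81e-3 mm/ms^2).
#'
#' @name materials
NULL

#' Standard gravity in m/s^2
#' @keywords internal
GRAVITY_MS2 <- 9.81

# mm/ms^2
GRAVITY_INTERNAL <- GRAVITY_MS2 * 1e-3

#' Ogden hyperelastic parameters (one-term)
#'
#' @param C shear-like coefficient, MPa (> 0)
#' @param alpha dimensionless exponent (non-zero)
#' @param nu Poisson ratio in `[0, 0.5)`
#' @param density g/mm^3
#' @return an `ogden_params` object
#' @export
ogden_params <- function(C, alpha, nu = 0.475, density = 0.937e-3) {
  if (!is.numeric(C) || C <= 0) stop("ogden_params: C must be > 0")
  if (alpha == 0) stop("ogden_params: alpha must be non-zero")
  if (nu < 0 || nu >= 0.5) stop("ogden_params: nu must be in [0, 0.5)")
  structure(list(C = C, alpha = alpha, nu = nu, density = density),
            class = "ogden_params")
}

#' Two-term Prony relaxation parameters
#'
#' Relaxation weights are dimensionless; time constants are stored in ms
#' (inputs in seconds are converted by the caller or via `tau_unit`).
#'
#' @param g1,g2 relaxation weights, `g1 + g2 < 1`
#' @param tau1,tau2 time constants
#' @param tau_unit `"s"` or `"ms"`; values are stored in ms
#' @return a `prony_params` object
#' @export
prony_params <- function(g1, g2, tau1, tau2, tau_unit = c("s", "ms")) {
  tau_unit <- match.arg(tau_unit)
  if (g1 < 0 || g2 < 0) stop("prony_params: weights must be >= 0")
  if (g1 + g2 >= 1) stop("prony_params: g1 + g2 must be < 1")
  if (tau1 <= 0 || tau2 <= 0) stop("prony_params: time constants must be > 0")
  scale <- if (tau_unit == "s") 1000 else 1
  structure(list(g1 = g1, g2 = g2,
                 tau1 = tau1 * scale, tau2 = tau2 * scale),
            class = "prony_params")
}

#' Linear elastic parameters
#'
#' @param E Young's modulus, MPa
#' @param nu Poisson ratio in `[0, 0.5)`
#' @param density g/mm^3
#' @return a `linear_elastic_params` object
#' @export
linear_elastic_params <- function(E, nu, density) {
  if (E <= 0) stop("linear_elastic_params: E must be > 0")
  if (nu < 0 || nu >= 0.5) stop("linear_elastic_params: nu must be in [0, 0.5)")
  structure(list(E = E, nu = nu, density = density),
            class = "linear_elastic_params")
}

#' Uniaxial nominal stress of the one-term Ogden law
#'
#' Nominal (first Piola-Kirchhoff) stress as a function of deviatoric
#' principal stretch,
#' `sigma = -(2C/alpha) * (lambda^(alpha-1) - lambda^(-alpha/2-1))`.
#' Under this sign convention compression (`lambda < 1`) gives a positive
#' stress; set `tension_positive = TRUE` to flip the sign.
#'
#' @param stretch principal stretch lambda (> 0), vectorized
#' @param params an [ogden_params()] object
#' @param tension_positive flip to the tension-positive convention
#' @return nominal stress, MPa
#' @export
ogden_uniaxial_stress <- function(stretch, params, tension_positive = FALSE) {
  if (any(stretch <= 0)) stop("ogden_uniaxial_stress: stretch must be > 0")
  a <- params$alpha
  s <- -(2 * params$C / a) * (stretch^(a - 1) - stretch^(-a / 2 - 1))
  if (tension_positive) -s else s
}

#' Prony relaxation function
#'
#' `g(t) = 1 - g1 (1 - exp(-t/tau1)) - g2 (1 - exp(-t/tau2))`, the scale
#' applied to the instantaneous elastic stress after holding a deformation
#' for time `t`.
#'
#' @param t time, ms (>= 0), vectorized
#' @param params a [prony_params()] object
#' @return dimensionless relaxation factor in `(1 - g1 - g2, 1]`
#' @export
prony_relaxation <- function(t, params) {
  if (any(t < 0)) stop("prony_relaxation: t must be >= 0")
  1 - params$g1 * (1 - exp(-t / params$tau1)) -
    params$g2 * (1 - exp(-t / params$tau2))
}

#' Initialize the internal state of a viscoelastic element
#' @param params a [prony_params()] object (unused fields tolerated)
#' @return a `prony_state` list with one hereditary variable per term
#' @export
prony_state_init <- function(params) {
  structure(list(h1 = 0, h2 = 0, sigma_elastic_prev = 0), class = "prony_state")
}

#' One step of the recursive hereditary-integral stress update
#'
#' Quasi-linear viscoelasticity via the standard recursive convolution:
#' the hereditary integral `sigma(t) = int g(t - s) dsigma_e(s)` is split
#' into the long-time part `(1 - g1 - g2) sigma_e` plus exponentially
#' fading terms `r_i` updated by
#' `r_i <- exp(-dt/tau_i) r_i + g_i (1-exp(-dt/tau_i))/(dt/tau_i) dsigma_e`,
#' which is exact when the elastic stress varies linearly over the step.
#' A suddenly applied and held deformation starts at the full elastic
#' stress and relaxes to `(1 - g1 - g2)` times it.
#'
#' @param sigma_elastic instantaneous elastic stress at the end of the step,
#'   MPa (history starts from a stress-free state)
#' @param state a `prony_state` from [prony_state_init()] or a previous call
#' @param params a [prony_params()] object
#' @param dt time step, ms (> 0)
#' @return list with `stress` (MPa) and the updated `state`
#' @export
viscoelastic_stress_update <- function(sigma_elastic, state, params, dt) {
  if (dt <= 0) stop("viscoelastic_stress_update: dt must be > 0")
  dsig <- sigma_elastic - state$sigma_elastic_prev
  upd <- function(r, g, tau) {
    x <- dt / tau
    exp(-x) * r + g * ((1 - exp(-x)) / x) * dsig
  }
  r1 <- upd(state$h1, params$g1, params$tau1)
  r2 <- upd(state$h2, params$g2, params$tau2)
  state$h1 <- r1
  state$h2 <- r2
  state$sigma_elastic_prev <- sigma_elastic
  list(stress = (1 - params$g1 - params$g2) * sigma_elastic + r1 + r2,
       state = state)
}

#' Elastic modulus of the plantar aponeurosis from a force-strain datum
#'
#' Converts a tensile force stated as a multiple of body weight at a given
#' engineering strain, over a cross-sectional area, into a Young's modulus:
#' `E = (bw_multiple * body_mass * g / area) / strain` with g = 9.81 m/s^2.
#'
#' @param bw_multiple tensile force as a multiple of body weight
#' @param body_mass kg
#' @param strain engineering strain (> 0)
#' @param area cross-sectional area, mm^2 (> 0)
#' @return Young's modulus, MPa
#' @examples
#' pa_elastic_modulus(1.5, 70, 0.05, 50) # 412.02
#' @export
pa_elastic_modulus <- function(bw_multiple, body_mass, strain, area) {
  vals <- c(bw_multiple, body_mass, strain, area)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("pa_elastic_modulus: all arguments must be finite and > 0")
  }
  (bw_multiple * body_mass * GRAVITY_MS2 / area) / strain
}

#' Default material registry
#'
#' One entry per model component: bone, encapsulated soft tissue, skin,
#' articular cartilage, ligament, plantar aponeurosis, and floor friction.
#' All values are overridable via `...` (named entries replace defaults).
#'
#' @param ... named overrides, e.g. `ligament = linear_elastic_params(...)`
#' @param prony_scope apply Prony scaling to the `"full"` or `"deviatoric"`
#'   response (the uniaxial columns make these equivalent up to bookkeeping)
#' @return a `material_set` object
#' @export
material_set <- function(..., prony_scope = c("full", "deviatoric")) {
  prony_scope <- match.arg(prony_scope)
  defaults <- list(
    bone = linear_elastic_params(E = 7300, nu = 0.30, density = 1.5e-3),
    soft_tissue = ogden_params(C = 0.0102, alpha = 8.04, nu = 0.475,
                               density = 0.937e-3),
    soft_tissue_prony = prony_params(g1 = 0.18, g2 = 0.12,
                                     tau1 = 0.57, tau2 = 6.03,
                                     tau_unit = "s"),
    skin = ogden_params(C = 0.122, alpha = 18, nu = 0.475,
                        density = 0.937e-3),
    cartilage = linear_elastic_params(E = 10, nu = 0.40, density = 2.0e-3),
    ligament = linear_elastic_params(E = 260, nu = 0.40, density = 1.0e-3),
    plantar_aponeurosis = linear_elastic_params(
      E = pa_elastic_modulus(1.5, 70, 0.05, 50), nu = 0.40, density = 1.0e-3),
    floor_friction = list(mu_static = 0.6, mu_dynamic = 0.6)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("material_set: unknown component(s): ", paste(bad, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  defaults$prony_scope <- prony_scope
  structure(defaults, class = "material_set")
}

#' @export
print.material_set <- function(x, ...) {
  cat("<material_set>\n")
  cat(sprintf("  bone:       E = %g MPa, nu = %g\n", x$bone$E, x$bone$nu))
  cat(sprintf("  soft tissue: Ogden C = %g MPa, alpha = %g; Prony g = (%g, %g), tau = (%g, %g) ms\n",
              x$soft_tissue$C, x$soft_tissue$alpha,
              x$soft_tissue_prony$g1, x$soft_tissue_prony$g2,
              x$soft_tissue_prony$tau1, x$soft_tissue_prony$tau2))
  cat(sprintf("  skin:       Ogden C = %g MPa, alpha = %g\n",
              x$skin$C, x$skin$alpha))
  cat(sprintf("  cartilage:  E = %g MPa\n", x$cartilage$E))
  cat(sprintf("  ligament:   E = %g MPa\n", x$ligament$E))
  cat(sprintf("  plantar aponeurosis: E = %g MPa\n",
              x$plantar_aponeurosis$E))
  cat(sprintf("  floor friction: mu_s = %g, mu_d = %g\n",
              x$floor_friction$mu_static, x$floor_friction$mu_dynamic))
  invisible(x)
}

#' Serialize / restore a material set (YAML)
#'
#' Round-trips bit-exactly: numbers are emitted with 17 significant digits.
#'
#' @param materials a [material_set()] object
#' @param path file path; if `NULL`, the YAML string is returned
#' @return `write_material_set`: the path (or YAML string) invisibly;
#'   `read_material_set`: a `material_set`
#' @export
write_material_set <- function(materials, path = NULL) {
  plain <- lapply(unclass(materials), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  txt <- yaml::as.yaml(plain, precision = 17)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_material_set
#' @param text YAML string (alternative to `path`)
#' @export
read_material_set <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  ms <- material_set(
    bone = do.call(linear_elastic_params, raw$bone),
    soft_tissue = do.call(ogden_params, raw$soft_tissue),
    soft_tissue_prony = prony_params(raw$soft_tissue_prony$g1,
                                     raw$soft_tissue_prony$g2,
                                     raw$soft_tissue_prony$tau1,
                                     raw$soft_tissue_prony$tau2,
                                     tau_unit = "ms"),
    skin = do.call(ogden_params, raw$skin),
    cartilage = do.call(linear_elastic_params, raw$cartilage),
    ligament = do.call(linear_elastic_params, raw$ligament),
    plantar_aponeurosis = do.call(linear_elastic_params,
                                  raw$plantar_aponeurosis),
    floor_friction = raw$floor_friction,
    prony_scope = raw$prony_scope
  )
  ms
}
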