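#' Ground-reaction-force tracking refinement
#'
#' Iteratively corrects a prescribed tibial displacement trajectory so
#' that the simulated ground reaction forces track measured ones: the
#' per-component GRF error over normalized stance time is fitted with an
#' 8th-order least-squares polynomial, scaled by per-component gains into
#' displacement corrections (diagonal coupling: vertical error moves the
#' vertical trajectory, anteroposterior moves anteroposterior,
#' mediolateral moves mediolateral), added to the trajectory, and the
#' simulation is rerun until the error converges or the iteration budget
#' is exhausted. The returned trajectory is always the best iterate seen.
#'
#' @name refinement
NULL

#' Refinement configuration
#'
#' @param poly_order polynomial order (default 8)
#' @param gains per-component gains, mm of displacement per N of GRF
#'   error; `NULL` auto-estimates by a one-shot secant probe
#' @param max_iterations iteration budget
#' @param tol convergence threshold on the GRF mean absolute error, %BW
#' @return a `refinement_config` list
#' @export
refinement_config <- function(poly_order = 8, gains = NULL,
                              max_iterations = 6, tol = 1) {
  if (poly_order < 0) stop("refinement_config: poly_order must be >= 0")
  if (tol <= 0) stop("refinement_config: tol must be > 0")
  if (!is.null(gains) && any(!is.finite(gains))) {
    stop("refinement_config: gains must be finite")
  }
  list(poly_order = as.integer(poly_order), gains = gains,
       max_iterations = as.integer(max_iterations), tol = tol)
}

#' Per-component GRF error over normalized stance time
#'
#' @param simulated,measured matrices (frames x components) on a common
#'   grid, or vectors
#' @param body_weight N, for the %BW summary
#' @return list with `error` (simulated - measured), `s` (normalized time
#'   in `[0, 1]`), and `mae_pct_bw` / `sd_pct_bw` per component
#' @export
grf_error <- function(simulated, measured, body_weight = NA_real_) {
  simulated <- as.matrix(simulated)
  measured <- as.matrix(measured)
  if (!all(dim(simulated) == dim(measured))) {
    stop("grf_error: series have different lengths")
  }
  err <- simulated - measured
  n <- nrow(err)
  s <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  mae <- apply(abs(err), 2, mean)
  sdv <- apply(abs(err), 2, stats::sd)
  list(error = err, s = s,
       mae_pct_bw = 100 * mae / body_weight,
       sd_pct_bw = 100 * sdv / body_weight)
}

#' Least-squares polynomial fit on normalized time
#'
#' Plain monomial basis on `[0, 1]` solved by QR orthogonal
#' decomposition.
#'
#' @param s normalized time in `[0, 1]`
#' @param y values
#' @param order polynomial order (default 8); needs `order + 1` samples
#' @return coefficient vector `c0..c_order` (constant first)
#' @export
fit_polynomial <- function(s, y, order = 8) {
  if (length(s) < order + 1) {
    stop("fit_polynomial: need at least order + 1 samples")
  }
  X <- outer(s, 0:order, `^`)
  qr.solve(X, y)
}

#' Evaluate a polynomial coefficient vector on normalized time
#' @param coef coefficients, constant first
#' @param s normalized time
#' @return values
#' @export
eval_polynomial <- function(coef, s) {
  drop(outer(s, seq_along(coef) - 1, `^`) %*% coef)
}

#' Convert fitted GRF-error polynomials into displacement corrections
#'
#' `correction(s) = -gain * poly(s)` per component. The sign of the gain
#' encodes the force convention of the plant: with a positive gain, a
#' positive (excess) force error moves the trajectory negatively. For an
#' upward-positive vertical GRF the physical gain is negative (a force
#' deficit must lower the tibia); [refine()]'s secant auto-gain
#' estimates the correct signed value from the plant response.
#'
#' @param coefs list (or matrix columns) of per-component coefficient
#'   vectors
#' @param gains per-component gains, mm/N
#' @param s normalized time grid
#' @return matrix (length(s) x components) of offsets, mm
#' @export
displacement_correction <- function(coefs, gains, s) {
  if (is.null(gains)) stop("displacement_correction: gains required")
  if (!is.list(coefs)) coefs <- list(coefs)
  if (length(gains) == 1) gains <- rep(gains, length(coefs))
  out <- vapply(seq_along(coefs), function(k) {
    -gains[k] * eval_polynomial(coefs[[k]], s)
  }, numeric(length(s)))
  matrix(out, nrow = length(s))
}

#' Iterative GRF-tracking refinement
#'
#' `plant` maps a displacement-offset matrix (frames x components, mm,
#' added to the nominal trajectory) to a simulated GRF matrix on the same
#' grid. Iterates error -> polynomial fit -> correction -> rerun.
#'
#' @param plant deterministic function `offsets -> GRF matrix`
#' @param measured target GRF matrix (frames x components)
#' @param config a [refinement_config()]
#' @param body_weight N (for the %BW history)
#' @return a `refinement_result`: `offsets` (best-seen trajectory
#'   correction), `history` (per-iteration MAE per component, %BW),
#'   `iterations`, `converged`, `failed`
#' @export
refine <- function(plant, measured, config = refinement_config(),
                   body_weight = 700) {
  measured <- as.matrix(measured)
  n <- nrow(measured)
  ncomp <- ncol(measured)
  s <- (seq_len(n) - 1) / (n - 1)
  offsets <- matrix(0, n, ncomp)

  run_plant <- function(off) {
    out <- tryCatch(plant(off), error = function(e) e)
    if (inherits(out, "error")) return(out)
    as.matrix(out)
  }

  gains <- config$gains
  sim0 <- run_plant(offsets)
  if (inherits(sim0, "error")) {
    stop("refine: plant failed on the unperturbed trajectory: ",
         conditionMessage(sim0))
  }
  mae0 <- 100 * apply(abs(sim0 - measured), 2, mean) / body_weight
  history <- list(mae0)
  if (is.null(gains)) {
    # one-shot secant probe: constant offset, measured GRF response,
    # gain = 0.5 * step / response (50 % stability margin)
    gains <- numeric(ncomp)
    delta <- 1 # mm
    for (k in seq_len(ncomp)) {
      probe <- offsets
      probe[, k] <- probe[, k] + delta
      simk <- run_plant(probe)
      if (inherits(simk, "error")) {
        gains[k] <- 0
        next
      }
      response <- mean(simk[, k] - sim0[, k])
      gains[k] <- if (abs(response) > 1e-9) 0.5 * delta / response else 0
    }
  }

  best_offsets <- offsets
  best_mae <- sum(mae0)
  sim_cur <- sim0
  converged <- sum(mae0) / ncomp < config$tol
  failed <- FALSE
  it <- 0L
  while (!converged && it < config$max_iterations) {
    it <- it + 1L
    err <- sim_cur - measured
    coefs <- lapply(seq_len(ncomp), function(k) {
      fit_polynomial(s, err[, k], config$poly_order)
    })
    corr <- displacement_correction(coefs, gains, s)
    offsets <- offsets + corr
    sim_new <- run_plant(offsets)
    if (inherits(sim_new, "error")) {
      failed <- TRUE
      break
    }
    sim_cur <- sim_new
    mae <- 100 * apply(abs(sim_cur - measured), 2, mean) / body_weight
    history[[length(history) + 1]] <- mae
    if (sum(mae) < best_mae) {
      best_mae <- sum(mae)
      best_offsets <- offsets
    }
    converged <- sum(mae) / ncomp < config$tol
  }
  hist_mat <- do.call(rbind, history)
  colnames(hist_mat) <- paste0("mae_", seq_len(ncomp))
  structure(list(offsets = best_offsets, history = hist_mat, gains = gains,
                 iterations = it, converged = converged, failed = failed),
            class = "refinement_result")
}

#' Write the refinement iteration history to CSV
#' @param result a `refinement_result`
#' @param path output path
#' @return the path, invisibly
#' @export
write_refinement_report <- function(result, path) {
  df <- as.data.frame(result$history)
  df <- cbind(iteration = seq_len(nrow(df)) - 1, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
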