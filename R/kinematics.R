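#' Joint kinematics and plantar-pressure post-processing
#'
#' Bone-fixed frames are aligned with the global axes in the build
#' posture (x anterior, y medial, z superior). Joint rotations are
#' reported as y-x-z Euler angles: plantarflexion-dorsiflexion about y,
#' inversion-eversion about x, internal-external rotation (synonymously
#' adduction-abduction) about z.
#'
#' @name kinematics
NULL

#' Decompose a rotation into y-x-z Euler angles
#'
#' Factorizes `R = Ry(about_y) Rx(about_x) Rz(about_z)`. Angles are in
#' degrees. Proximity to gimbal lock (`|about_x| > 89` deg) is flagged.
#'
#' @param R a 3x3 proper rotation matrix
#' @return an `euler_yxz` list with `about_y`, `about_x`, `about_z` (deg)
#'   and `gimbal` flag
#' @export
euler_yxz <- function(R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
    stop("euler_yxz: input is not a proper rotation")
  }
  # R = Ry(a) Rx(b) Rz(c):
  #   R[2,3] = -sin b
  #   R[1,3] = sin a cos b ; R[3,3] = cos a cos b
  #   R[2,1] = cos b sin c ; R[2,2] = cos b cos c
  b <- asin(min(1, max(-1, -R[2, 3])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[1, 3], R[3, 3])
    cc <- atan2(R[2, 1], R[2, 2])
  } else {
    # gimbal: split arbitrarily, all rotation into a
    a <- atan2(-R[3, 1], R[1, 1])
    cc <- 0
  }
  structure(list(about_y = a * 180 / pi, about_x = b * 180 / pi,
                 about_z = cc * 180 / pi,
                 gimbal = abs(b) > 89 * pi / 180),
            class = "euler_yxz")
}

#' Compose y-x-z Euler angles into a rotation matrix
#' @param about_y,about_x,about_z angles in degrees
#' @return 3x3 rotation matrix
#' @export
compose_yxz <- function(about_y, about_x, about_z) {
  d <- pi / 180
  rot_y(about_y * d) %*% rot_x(about_x * d) %*% rot_z(about_z * d)
}

#' Joint angles of a distal bone relative to a proximal bone
#'
#' The relative rotation `R_prox^T R_dist` is expressed against the
#' reference (zero-angle) relative rotation and decomposed with
#' [euler_yxz()].
#'
#' @param R_prox,R_dist current bone rotations (local -> global)
#' @param R_prox_ref,R_dist_ref reference rotations (default identity:
#'   the build posture is the zero-angle posture)
#' @return an `euler_yxz` list
#' @export
joint_angles <- function(R_prox, R_dist, R_prox_ref = diag(3),
                         R_dist_ref = diag(3)) {
  if (is.null(R_prox_ref) || is.null(R_dist_ref)) {
    stop("joint_angles: reference poses are required")
  }
  rel <- t(R_prox) %*% R_dist
  rel_ref <- t(R_prox_ref) %*% R_dist_ref
  euler_yxz(t(rel_ref) %*% rel)
}

#' Rasterize contact forces into a plantar pressure map
#'
#' Per-cell pressure is the sum of vertical contact forces in the cell
#' divided by the cell area; total force is conserved exactly. An
#' optional block-average downsampling emulates coarse sensor elements.
#'
#' @param points n x 2 matrix of contact locations (x, y), mm
#' @param forces n vector of vertical forces, N
#' @param areas optional n vector of contact areas (only used to report
#'   element pressure, not the map)
#' @param cell mm cell edge length
#' @param origin grid origin (xmin, ymin); default from the data
#' @param dims grid dimensions (nx, ny); default from the data
#' @param downsample integer block size for sensor-style averaging
#' @return a `pressure_map`: `grid` (nx x ny MPa), `origin`, `cell`,
#'   `cop` (mm, `NA` when unloaded), `total_force` (N)
#' @export
pressure_map <- function(points, forces, areas = NULL, cell = 10,
                         origin = NULL, dims = NULL, downsample = 1L) {
  points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (length(forces) != n) stop("pressure_map: length mismatch")
  if (is.null(origin)) {
    origin <- if (n) c(floor(min(points[, 1]) / cell) * cell - cell,
                       floor(min(points[, 2]) / cell) * cell - cell)
              else c(0, 0)
  }
  if (is.null(dims)) {
    dims <- if (n) c(ceiling((max(points[, 1]) - origin[1]) / cell) + 1,
                     ceiling((max(points[, 2]) - origin[2]) / cell) + 1)
            else c(1, 1)
  }
  grid <- matrix(0, dims[1], dims[2])
  if (n) {
    ix <- floor((points[, 1] - origin[1]) / cell) + 1
    iy <- floor((points[, 2] - origin[2]) / cell) + 1
    if (any(ix < 1 | ix > dims[1] | iy < 1 | iy > dims[2])) {
      stop("pressure_map: grid does not cover a loaded point")
    }
    for (i in seq_len(n)) {
      grid[ix[i], iy[i]] <- grid[ix[i], iy[i]] + forces[i]
    }
    grid <- grid / cell^2
  }
  if (downsample > 1L) {
    ds <- as.integer(downsample)
    nx <- ceiling(dims[1] / ds) * ds
    ny <- ceiling(dims[2] / ds) * ds
    padded <- matrix(0, nx, ny)
    padded[seq_len(dims[1]), seq_len(dims[2])] <- grid
    grid <- apply(array(padded, c(ds, nx / ds, ds, ny / ds)),
                  c(2, 4), mean)
    cell <- cell * ds
  }
  cop <- if (n && sum(forces) > 0) {
    c(sum(points[, 1] * forces), sum(points[, 2] * forces)) / sum(forces)
  } else c(NA_real_, NA_real_)
  structure(list(grid = grid, origin = origin, cell = cell, cop = cop,
                 total_force = sum(forces)),
            class = "pressure_map")
}

#' Center of pressure of a set of contact forces
#'
#' Vertical-force-weighted mean of the contact locations.
#'
#' @param points n x 2 (or n x 3) matrix of contact positions, mm
#' @param forces n vector of vertical forces, N
#' @return length-2 numeric (x, y), mm
#' @export
center_of_pressure <- function(points, forces) {
  points <- as.matrix(points)
  if (sum(forces) <= 0) {
    stop("center_of_pressure: total vertical force must be > 0")
  }
  c(sum(points[, 1] * forces), sum(points[, 2] * forces)) / sum(forces)
}

#' Mean absolute difference between two series
#'
#' @param a,b numeric vectors on a common grid
#' @return named vector: `mae` (mean of `|a - b|`) and `sd` (sample
#'   standard deviation of `|a - b|`)
#' @export
mae_sd <- function(a, b) {
  if (length(a) != length(b)) stop("mae_sd: length mismatch")
  d <- abs(a - b)
  c(mae = mean(d), sd = stats::sd(d))
}

#' Zero-phase low-pass filter for marker trajectories
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`):
#' unit DC gain, no phase delay.
#'
#' @param x numeric vector or matrix (columns filtered independently)
#' @param fs sampling rate, Hz
#' @param cutoff cutoff frequency, Hz (default 20)
#' @param order filter order (default 4)
#' @return filtered data, same shape
#' @export
lowpass_markers <- function(x, fs, cutoff = 20, order = 4) {
  if (fs <= 2 * cutoff) {
    stop("lowpass_markers: sampling rate must exceed twice the cutoff")
  }
  bf <- signal::butter(order, cutoff / (fs / 2))
  filt1 <- function(v) {
    # pad by reflection to suppress end transients
    npad <- min(length(v) - 1, ceiling(10 * fs / cutoff))
    vv <- c(2 * v[1] - rev(v[2:(npad + 1)]), v,
            2 * v[length(v)] - rev(v[(length(v) - npad):(length(v) - 1)]))
    out <- signal::filtfilt(bf, vv)
    out[(npad + 1):(npad + length(v))]
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}
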