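# Quaternion / rotation / mesh primitives shared by the model and the
# integrator. Quaternions are length-4 numeric (w, x, y, z), unit norm;
# rotation matrices map body-local to global coordinates.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @noRd
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

# Incremental rotation by angular velocity w (rad, world frame) over dt.
quat_integrate <- function(q, w_world, dt) {
  angle <- sqrt(sum(w_world^2)) * dt
  # non-finite spin: leave q; the integrator's divergence check reports it
  if (!is.finite(angle) || angle < 1e-14) return(q)
  axis <- w_world / sqrt(sum(w_world^2))
  dq <- c(cos(angle / 2), sin(angle / 2) * axis)
  quat_normalize(quat_multiply(dq, q))
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rotation matrix whose first column is the unit vector along `axis`;
# the remaining columns complete a right-handed orthonormal frame.
frame_from_axis <- function(axis) {
  u <- unit3(axis)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- unit3(cross3(ref, u))
  w <- cross3(u, v)
  cbind(u, v, w, deparse.level = 0)
}

## --- triangulated icosphere (unit radius) -------------------------------

icosphere <- function(subdivisions = 1L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    midpoint <- new.env(parent = emptyenv())
    verts <- v
    get_mid <- function(i, j) {
      key <- edge_key(i, j)
      if (!is.null(midpoint[[key]])) return(midpoint[[key]])
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    k <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      nf[k + 1L, ] <- c(a, ab, ca)
      nf[k + 2L, ] <- c(b, bc, ab)
      nf[k + 3L, ] <- c(cc, ca, bc)
      nf[k + 4L, ] <- c(ab, bc, ca)
      k <- k + 4L
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

# Signed "inside" test for an oriented ellipsoid: value < 1 means inside the
# surface. center/semi in mm, R local->global.
ellipsoid_level <- function(points, center, semi, R) {
  p <- sweep(as.matrix(points), 2, center)
  local <- p %*% R # = t(R) applied row-wise
  rowSums(sweep(local, 2, semi, "/")^2)
}

# Closest surface point (approximate, via scaled-space projection) and
# outward normal of an oriented ellipsoid. Adequate for contact projection
# of points near the surface.
ellipsoid_project <- function(point, center, semi, R) {
  local <- as.numeric(t(R) %*% (point - center))
  u <- local / semi
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) u <- c(1, 0, 0) / semi * semi # degenerate: pick +x
  us <- u / max(nu, 1e-12)
  surf_local <- us * semi
  # gradient of level function gives the outward normal
  n_local <- surf_local / semi^2
  list(point = as.numeric(center + R %*% surf_local),
       normal = as.numeric(R %*% (n_local / sqrt(sum(n_local^2)))),
       inside = nu < 1)
}

## --- closest point on a triangle / mesh ---------------------------------

closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  }
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

# Closest point on a triangle mesh (vertices n x 3, faces m x 3 indices).
mesh_closest_point <- function(p, vertices, faces) {
  best <- NULL
  best_d2 <- Inf
  for (i in seq_len(nrow(faces))) {
    q <- closest_point_triangle(p, vertices[faces[i, 1], ],
                                vertices[faces[i, 2], ],
                                vertices[faces[i, 3], ])
    d2 <- sum((p - q)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      best <- list(point = q, face = i)
    }
  }
  f <- faces[best$face, ]
  n <- cross3(vertices[f[2], ] - vertices[f[1], ],
              vertices[f[3], ] - vertices[f[1], ])
  best$normal <- n / sqrt(sum(n^2))
  best$distance <- sqrt(best_d2)
  best
}

# Ray-crossing point-in-mesh test for a closed mesh (odd crossings = inside).
mesh_contains <- function(p, vertices, faces) {
  dir <- c(0.577350269189626, 0.577350269189626, 0.577350269189626)
  crossings <- 0L
  for (i in seq_len(nrow(faces))) {
    a <- vertices[faces[i, 1], ]; b <- vertices[faces[i, 2], ]
    cc <- vertices[faces[i, 3], ]
    e1 <- b - a; e2 <- cc - a
    h <- cross3(dir, e2)
    det <- sum(e1 * h)
    if (abs(det) < 1e-12) next
    inv <- 1 / det
    s <- p - a
    u <- sum(s * h) * inv
    if (u < 0 || u > 1) next
    q <- cross3(s, e1)
    v <- sum(dir * q) * inv
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) * inv
    if (t > 1e-12) crossings <- crossings + 1L
  }
  (crossings %% 2L) == 1L
}

# Piecewise-linear interpolation with clamping at the ends.
interp_clamped <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = pmin(pmax(x, min(xs)), max(xs)),
                rule = 2, ties = "ordered")$y
}
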