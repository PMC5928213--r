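# Unit-quaternion helpers for rigid-body orientations. Quaternions are
# length-4 numeric vectors (w, x, y, z); particle orientations rotate the
# species' reference patch frame into the world frame.

#' Normalize a quaternion to unit length
#'
#' @param q Numeric vector of length 4, `(w, x, y, z)`.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion product
#'
#' Composition `a %*% b`: rotating by `b` first, then by `a`.
#'
#' @param a,b Quaternions `(w, x, y, z)`.
#' @return The product quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Rotate vectors by a quaternion
#'
#' @param q Unit quaternion.
#' @param v A 3-vector or an n x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

#' Quaternion from an axis and angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), axis * sin(angle / 2))
}

#' Uniform random unit quaternions
#'
#' Shoemake's subgroup algorithm; draws from R's RNG stream.
#'
#' @param n Number of quaternions.
#' @return n x 4 matrix, one unit quaternion per row.
#' @export
random_quaternion <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  cbind(b * cos(2 * pi * u3),
        a * sin(2 * pi * u2),
        a * cos(2 * pi * u2),
        b * sin(2 * pi * u3))
}

#' Quaternion rotating one unit vector onto another
#'
#' Shortest-arc rotation taking `a` to `b`.
#'
#' @param a,b Unit 3-vectors.
#' @return Unit quaternion.
#' @export
quat_from_vectors <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    return(quat_from_axis_angle(ax, pi))
  }
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  quat_normalize(c(1 + d, cr))
}

# Rotation mapping the ordered pair of unit vectors (a1, a2) onto (b1, b2),
# assuming the angle between a1,a2 equals that between b1,b2. Built from the
# orthonormal frames spanned by each pair.
quat_from_pair_alignment <- function(a1, a2, b1, b2) {
  frame <- function(u, v) {
    e1 <- u / sqrt(sum(u^2))
    w <- v - sum(v * e1) * e1
    e2 <- w / sqrt(sum(w^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    cbind(e1, e2, e3)
  }
  R <- frame(b1, b2) %*% t(frame(a1, a2))
  matrix_to_quat(R)
}

# Standard rotation-matrix -> quaternion conversion (Shepperd's method).
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
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
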