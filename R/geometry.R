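# Vector, rotation and quaternion primitives used by the frame construction
# and the orientation term of the contact function. Quaternions are stored
# (w, x, y, z) with |q| = 1; q and -q denote the same rotation.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Row-wise versions operating on n x 3 matrices
rows_norm <- function(m) sqrt(rowSums(m * m))

rows_unit <- function(m) m / rows_norm(m)

rows_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Convert rotation matrices to unit quaternions
#'
#' Vectorized Shepperd-style conversion: for each rotation the largest of the
#' four squared quaternion components is used as pivot for numerical
#' stability. Input is a 3 x 3 x n array (or a single 3 x 3 matrix); output an
#' n x 4 matrix of (w, x, y, z) rows with non-negative w.
#'
#' @param R a 3x3 rotation matrix or a 3x3xn array of rotation matrices.
#' @return an n x 4 numeric matrix of unit quaternions.
#' @keywords internal
rot_to_quat <- function(R) {
  if (is.matrix(R)) R <- array(R, dim = c(3L, 3L, 1L))
  n <- dim(R)[3L]
  r11 <- R[1L, 1L, ]; r12 <- R[1L, 2L, ]; r13 <- R[1L, 3L, ]
  r21 <- R[2L, 1L, ]; r22 <- R[2L, 2L, ]; r23 <- R[2L, 3L, ]
  r31 <- R[3L, 1L, ]; r32 <- R[3L, 2L, ]; r33 <- R[3L, 3L, ]
  # 4 * squared components (may be numerically negative near zero)
  qw2 <- 1 + r11 + r22 + r33
  qx2 <- 1 + r11 - r22 - r33
  qy2 <- 1 - r11 + r22 - r33
  qz2 <- 1 - r11 - r22 + r33
  piv <- max.col(cbind(qw2, qx2, qy2, qz2), ties.method = "first")
  q <- matrix(0, n, 4L)
  iw <- piv == 1L
  if (any(iw)) {
    s <- 2 * sqrt(qw2[iw])
    q[iw, ] <- cbind(s / 4, (r32[iw] - r23[iw]) / s,
                     (r13[iw] - r31[iw]) / s, (r21[iw] - r12[iw]) / s)
  }
  ix <- piv == 2L
  if (any(ix)) {
    s <- 2 * sqrt(qx2[ix])
    q[ix, ] <- cbind((r32[ix] - r23[ix]) / s, s / 4,
                     (r12[ix] + r21[ix]) / s, (r13[ix] + r31[ix]) / s)
  }
  iy <- piv == 3L
  if (any(iy)) {
    s <- 2 * sqrt(qy2[iy])
    q[iy, ] <- cbind((r13[iy] - r31[iy]) / s, (r12[iy] + r21[iy]) / s,
                     s / 4, (r23[iy] + r32[iy]) / s)
  }
  iz <- piv == 4L
  if (any(iz)) {
    s <- 2 * sqrt(qz2[iz])
    q[iz, ] <- cbind((r21[iz] - r12[iz]) / s, (r13[iz] + r31[iz]) / s,
                     (r23[iz] + r32[iz]) / s, s / 4)
  }
  q <- q / rows_norm(q)
  flip <- q[, 1L] < 0
  q[flip, ] <- -q[flip, ]
  q
}

#' @keywords internal
quat_to_rot <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

## Hamilton product, row-wise on n x 4 matrices
quat_mult <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  cbind(a[, 1L] * b[, 1L] - a[, 2L] * b[, 2L] - a[, 3L] * b[, 3L] - a[, 4L] * b[, 4L],
        a[, 1L] * b[, 2L] + a[, 2L] * b[, 1L] + a[, 3L] * b[, 4L] - a[, 4L] * b[, 3L],
        a[, 1L] * b[, 3L] - a[, 2L] * b[, 4L] + a[, 3L] * b[, 1L] + a[, 4L] * b[, 2L],
        a[, 1L] * b[, 4L] + a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L] + a[, 4L] * b[, 1L])
}

quat_conj <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, 1L)
  q * rep(c(1, -1, -1, -1), each = nrow(q))
}

## Geodesic angle (rad, in [0, pi]) between rotations given as quaternions.
## Row-wise; b may be a single quaternion recycled against rows of a.
quat_angle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  dt <- pmin(1, abs(rowSums(a * b)))
  2 * acos(dt)
}

#' Chordal mean of unit quaternions
#'
#' The rotation average minimizing summed chordal distance: the principal
#' eigenvector of the 4x4 outer-product accumulator. Sign ambiguity of the
#' input quaternions is irrelevant because q q^T = (-q)(-q)^T.
#'
#' @param q an n x 4 matrix of unit quaternions.
#' @return a unit quaternion (length-4 vector, w >= 0).
#' @keywords internal
quat_mean <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, 1L)
  M <- crossprod(q) / nrow(q)
  ev <- eigen(M, symmetric = TRUE)
  m <- ev$vectors[, 1L]
  m <- m / vnorm(m)
  if (m[1L] < 0) m <- -m
  m
}

## Uniform random rotation (quaternion) and small random rotation with
## axis uniform on the sphere and angle ~ N(0, sigma), used by fixtures.
runif_quat <- function(n) {
  u <- matrix(stats::rnorm(4L * n), n, 4L)
  u <- u / rows_norm(u)
  flip <- u[, 1L] < 0
  u[flip, ] <- -u[flip, ]
  u
}

rnoise_quat <- function(n, sigma) {
  ax <- matrix(stats::rnorm(3L * n), n, 3L)
  ax <- ax / rows_norm(ax)
  ang <- stats::rnorm(n, 0, sigma)
  cbind(cos(ang / 2), sin(ang / 2) * ax)
}
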