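#' Rigid-body pose (rotation + translation)
#'
#' A pose represents the placement of a rigid body: a 3x3 orthonormal rotation
#' matrix with determinant +1 and a 3-vector translation in millimetres. Poses
#' map body-frame coordinates to world (or parent-frame) coordinates as
#' \code{x_world = R x_body + t}.
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1).
#' @param translation numeric 3-vector, mm.
#' @param check validate orthonormality to 1e-9 (default \code{TRUE}).
#' @return An object of class \code{"pose"}: a list with elements \code{R} and
#'   \code{t}.
#' @examples
#' p <- pose(diag(3), c(1, 0, 0))
#' pose_apply(p, c(0, 0, 0))
#' @export
pose <- function(rotation, translation = c(0, 0, 0), check = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    stop("translation must be a 3-vector")
  if (check) {
    err <- max(abs(crossprod(rotation) - diag(3)))
    if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9)
      stop("rotation must be orthonormal with determinant +1 (tolerance 1e-9)")
  }
  structure(list(R = rotation, t = translation), class = "pose")
}

#' @rdname pose
#' @export
pose_identity <- function() pose(diag(3), c(0, 0, 0), check = FALSE)

#' Compose two poses
#'
#' \code{pose_compose(a, b)} returns the pose equivalent to applying \code{b}
#' first, then \code{a} (matrix convention \code{a \%*\% b}).
#'
#' @param a,b poses.
#' @return A pose.
#' @export
pose_compose <- function(a, b) {
  pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, check = FALSE)
}

#' Invert a pose
#' @param p a pose.
#' @return The inverse pose.
#' @export
pose_inverse <- function(p) {
  Rt <- t(p$R)
  pose(Rt, as.numeric(-Rt %*% p$t), check = FALSE)
}

#' Apply a pose to points
#'
#' @param p a pose.
#' @param x numeric 3-vector or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as \code{x}.
#' @export
pose_apply <- function(p, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(p$R), 2L, p$t, "+")
  } else {
    as.numeric(p$R %*% x) + p$t
  }
}

#' @export
print.pose <- function(x, ...) {
  cat("Rigid-body pose\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t(mm)"))
  print(round(m, 6))
  invisible(x)
}

## --- rotation helpers (internal) -------------------------------------------

# Rodrigues rotation about unit axis by angle (rad)
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) * ca + sa * K + (1 - ca) * tcrossprod(a)
}

# so(3) logarithm: rotation matrix -> axis*angle 3-vector
rot_log <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- max(-1, min(1, ca))
  theta <- acos(ca)
  if (theta < 1e-12) {
    # first-order: skew part
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (theta > pi - 1e-6) {
    # near pi: use symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (i == 1L) axis <- axis * c(1, sign(B[1, 2] + .Machine$double.eps), sign(B[1, 3] + .Machine$double.eps))
    if (i == 2L) axis <- axis * c(sign(B[1, 2] + .Machine$double.eps), 1, sign(B[2, 3] + .Machine$double.eps))
    if (i == 3L) axis <- axis * c(sign(B[1, 3] + .Machine$double.eps), sign(B[2, 3] + .Machine$double.eps), 1)
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(theta))
  w * theta
}

# random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# complete an orthonormal frame given one unit vector (returns 3x3 with v as col 1)
orthonormal_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- ref - sum(ref * v) * v
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(v[2] * u2[3] - v[3] * u2[2],
          v[3] * u2[1] - v[1] * u2[3],
          v[1] * u2[2] - v[2] * u2[1])
  cbind(v, u2, u3, deparse.level = 0)
}
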