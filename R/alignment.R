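#' Least-squares rigid alignment of paired point sets
#'
#' Finds the rigid transform (rotation + translation, no scaling) that maps
#' \code{points_a} onto \code{points_b} with minimum sum of squared distances
#' (Kabsch/Procrustes solution via SVD of the cross-covariance).
#'
#' @param points_a,points_b n x 3 matrices of paired points (mm), n >= 3,
#'   non-collinear.
#' @return A list with elements \code{pose} (the optimal rigid transform,
#'   applied as \code{pose_apply(pose, points_a)}) and \code{rms}, the RMS
#'   residual distance (mm) after alignment.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' fit <- solve_rigid_alignment(a, a)
#' fit$rms  # 0
#' @export
solve_rigid_alignment <- function(points_a, points_b) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (!identical(dim(a), dim(b)))
    stop("point sets must have identical dimensions")
  if (nrow(a) < 3L)
    stop("degenerate configuration: need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  # collinearity check: second singular value of the centred set
  sv <- svd(a0, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: points are collinear")
  H <- crossprod(a0, b0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.numeric(R %*% ca)
  p <- pose(R, tr, check = FALSE)
  res <- pose_apply(p, a) - b
  list(pose = p, rms = sqrt(mean(rowSums(res^2))))
}

#' RMS point error between two configurations
#'
#' Root mean square Euclidean distance over paired points; the error metric
#' used to score model-animated against observed fit points.
#'
#' @param config_a,config_b n x 3 matrices (mm).
#' @return RMS distance (mm).
#' @export
rms_point_error <- function(config_a, config_b) {
  a <- as.matrix(config_a); b <- as.matrix(config_b)
  if (!identical(dim(a), dim(b))) stop("configuration shapes differ")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Recover per-frame body poses from marker trajectories
#'
#' For each body and frame, rigidly aligns that body's reference marker
#' configuration to the observed marker positions. Frames where a body has
#' fewer than 3 visible markers yield a masked (NA) pose.
#'
#' @param markers a \code{\link{marker_trajectories}} object.
#' @param reference named list of reference marker configurations per body
#'   (rows = markers, in the same order as in \code{markers}); defaults to the
#'   per-body mean observed configuration aligned to the first usable frame.
#' @return A list per body, each containing \code{poses} (list of poses or NA)
#'   and \code{rms} (per-frame alignment residual, mm).
#' @export
poses_from_markers <- function(markers, reference = NULL) {
  stopifnot(inherits(markers, "marker_trajectories"))
  bodies <- unique(markers$body)
  out <- list()
  for (bd in bodies) {
    sel <- which(markers$body == bd)
    if (length(sel) < 3L) {
      warning("body '", bd, "' has fewer than 3 markers; poses not recovered")
      next
    }
    ref <- if (!is.null(reference) && !is.null(reference[[bd]])) {
      as.matrix(reference[[bd]])
    } else {
      # first frame with all markers visible
      vis <- rowSums(!markers$missing[, sel, drop = FALSE]) == length(sel)
      f0 <- which(vis)[1]
      if (is.na(f0)) stop("body '", bd, "' has no frame with all markers visible")
      t(markers$xyz[f0, , sel])
    }
    n_frames <- dim(markers$xyz)[1]
    poses <- vector("list", n_frames)
    rms <- rep(NA_real_, n_frames)
    for (f in seq_len(n_frames)) {
      vis <- !markers$missing[f, sel]
      if (sum(vis) < 3L) next
      obs <- t(markers$xyz[f, , sel[vis]])
      fit <- try(solve_rigid_alignment(ref[vis, , drop = FALSE], obs), silent = TRUE)
      if (inherits(fit, "try-error")) next
      poses[[f]] <- fit$pose
      rms[f] <- fit$rms
    }
    out[[bd]] <- list(poses = poses, rms = rms, reference = ref)
  }
  out
}
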