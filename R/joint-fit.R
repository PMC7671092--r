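## Fitting joint models to the relative motion of an articulated body pair.
##
## The observed data are per-frame relative poses (child relative to parent).
## A candidate joint model is scored by the RMS distance between fit points
## animated by the joint model and the same points animated by the observed
## poses; center, axes and per-frame coordinates are optimized jointly by
## Levenberg-Marquardt least squares with seeded random restarts.

# Moore-Penrose pseudoinverse solve (minimum-norm least squares)
pinv_solve <- function(A, b, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  as.numeric(s$v[, keep, drop = FALSE] %*%
               ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep]))
}

# unit vector from spherical angles
axis_from_angles <- function(th, ph) {
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}
angles_from_axis <- function(a) {
  a <- a / sqrt(sum(a^2))
  c(acos(max(-1, min(1, a[3]))), atan2(a[2], a[1]))
}

# intrinsic z-y'-x'' Euler decomposition of a rotation matrix
euler_zyx <- function(R) {
  b <- -asin(max(-1, min(1, R[3, 1])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(R[2, 1], R[1, 1])
    g <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock
    a <- atan2(-R[1, 2], R[2, 2])
    g <- 0
  }
  c(a, b, g)
}

#' Fit a joint model to observed relative motion
#'
#' Estimates the center, axes, and per-frame coordinates of a joint of the
#' requested type from a sequence of relative rigid-body poses, by minimizing
#' the RMS error between fit points animated by the joint model and the same
#' points animated by the observed poses. Spherical joints are solved in
#' closed form (linear least-squares center, exact Euler coordinates); the
#' other types use bounded Levenberg-Marquardt with multi-start.
#'
#' @param rel_poses list of \code{\link{pose}} objects: per-frame pose of the
#'   child relative to the parent. Needs at least \code{2 * dof} frames.
#' @param type joint type to fit.
#' @param fit_points a \code{\link{fit_point_set}} (or 3 x 3 matrix): three
#'   non-collinear landmarks on the child, parent-frame coordinates at the
#'   reference (identity) pose.
#' @param n_restarts random restarts for the nonlinear types (default 5).
#' @param seed seed for the restarts.
#' @return A \code{\link{joint_model}} with fitted \code{coordinates} and
#'   \code{fit_rms} (mm); attribute \code{converged} reports optimizer status.
#' @export
fit_joint_model <- function(rel_poses, type, fit_points, n_restarts = 5, seed = 1) {
  pts <- if (inherits(fit_points, "fit_point_set")) fit_points$points else as.matrix(fit_points)
  dof <- joint_dof(type)
  n <- length(rel_poses)
  if (n < 2L * dof) stop("need at least ", 2L * dof, " frames to fit a ", type, " joint")
  target <- lapply(rel_poses, function(p) pose_apply(p, pts))  # observed fit points
  W <- t(vapply(rel_poses, function(p) rot_log(p$R), numeric(3)))  # n x 3 logs

  if (type == "spherical") {
    # center: (I - R_i) c = t_i in least squares
    A <- do.call(rbind, lapply(rel_poses, function(p) diag(3) - p$R))
    b <- unlist(lapply(rel_poses, function(p) p$t))
    ctr <- pinv_solve(A, b)
    axes <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
    co <- t(vapply(rel_poses, function(p) euler_zyx(p$R), numeric(3)))
    jm <- joint_model("spherical", ctr, axes, co)
    jm$fit_rms <- joint_fit_rms(jm, target, pts)
    attr(jm, "converged") <- TRUE
    return(jm)
  }

  resid_fn <- function(par) {
    jm <- par_to_joint(par, type, n)
    unlist(lapply(seq_len(n), function(i) {
      pred <- pose_apply(joint_transform(jm, jm$coordinates[i, ]), pts)
      as.numeric(pred - target[[i]])
    }))
  }

  starts <- joint_fit_starts(type, rel_poses, W, n_restarts, seed)
  best <- NULL
  for (par0 in starts) {
    fit <- try(minpack.lm::nls.lm(par0, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("joint fit failed for all starts")
  jm <- par_to_joint(best$par, type, n)
  jm$fit_rms <- joint_fit_rms(jm, target, pts)
  attr(jm, "converged") <- best$info %in% 1:4
  if (!attr(jm, "converged"))
    warning("joint fit did not fully converge; returning best candidate")
  jm
}

# pack/unpack: [axis angles | center(3, rot only) | per-frame coords]
par_to_joint <- function(par, type, n) {
  if (type == "revolute") {
    ax <- axis_from_angles(par[1], par[2])
    joint_model("revolute", par[3:5], ax, matrix(par[5 + seq_len(n)], ncol = 1))
  } else if (type == "universal") {
    a1 <- axis_from_angles(par[1], par[2])
    a2 <- axis_from_angles(par[3], par[4])
    if (abs(sum(a1 * a2)) > 0.999) a2 <- orthonormal_frame(a1)[, 2]
    joint_model("universal", par[5:7], rbind(a1, a2),
                matrix(par[7 + seq_len(2 * n)], ncol = 2, byrow = TRUE))
  } else {  # prismatic
    ax <- axis_from_angles(par[1], par[2])
    joint_model("prismatic", c(0, 0, 0), ax, matrix(par[2 + seq_len(n)], ncol = 1))
  }
}

joint_fit_starts <- function(type, rel_poses, W, n_restarts, seed) {
  n <- length(rel_poses)
  tmat <- t(vapply(rel_poses, function(p) p$t, numeric(3)))
  sv <- svd(W)
  ctr0 <- tryCatch({
    A <- do.call(rbind, lapply(rel_poses, function(p) diag(3) - p$R))
    pinv_solve(A, unlist(lapply(rel_poses, function(p) p$t)))
  }, error = function(e) c(0, 0, 0))
  mk <- function(a1, a2, ctr) {
    if (type == "revolute") {
      q <- as.numeric(W %*% a1)
      c(angles_from_axis(a1), ctr, q)
    } else if (type == "universal") {
      q <- cbind(as.numeric(W %*% a1), as.numeric(W %*% a2))
      c(angles_from_axis(a1), angles_from_axis(a2), ctr, as.numeric(t(q)))
    } else {
      a <- svd(tmat)$v[, 1]
      c(angles_from_axis(a), as.numeric(tmat %*% a))
    }
  }
  a1 <- sv$v[, 1]; a2 <- sv$v[, 2]
  starts <- list(mk(a1, a2, ctr0))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (r in seq_len(max(0L, n_restarts - 1L))) {
    ra1 <- a1 + stats::rnorm(3, sd = 0.3); ra1 <- ra1 / sqrt(sum(ra1^2))
    ra2 <- a2 + stats::rnorm(3, sd = 0.3); ra2 <- ra2 / sqrt(sum(ra2^2))
    rc <- ctr0 + stats::rnorm(3, sd = max(1, sqrt(mean(tmat^2))))
    starts[[r + 1L]] <- mk(ra1, ra2, rc)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  starts
}

joint_fit_rms <- function(jm, target, pts) {
  errs <- vapply(seq_along(target), function(i) {
    pred <- pose_apply(joint_transform(jm, jm$coordinates[i, ]), pts)
    mean(rowSums((pred - target[[i]])^2))
  }, 0)
  sqrt(mean(errs))
}

#' Select the lowest-DoF joint model that fits adequately
#'
#' Given fitted revolute, universal and spherical models of one articulation,
#' returns the lowest-DoF model whose fit RMS is within an absolute
#' (precision-anchored) or relative (spherical-anchored) tolerance:
#' \code{fit_rms <= max(precision * k_precision, (1 + rel_tol) * rms_spherical)}.
#'
#' @param fits named list with elements \code{revolute}, \code{universal},
#'   \code{spherical} (each a fitted \code{\link{joint_model}}).
#' @param precision tracking precision (mm), e.g. from
#'   \code{\link{precision_metric}}.
#' @param k_precision multiplier on precision (default 1.5).
#' @param rel_tol relative slack versus the spherical fit (default 0.10).
#' @return The selected \code{\link{joint_model}}; attribute
#'   \code{"selection"} records the threshold and rule applied.
#' @export
select_joint_model <- function(fits, precision, k_precision = 1.5, rel_tol = 0.10) {
  stopifnot(all(c("revolute", "universal", "spherical") %in% names(fits)))
  thr <- max(precision * k_precision, (1 + rel_tol) * fits$spherical$fit_rms)
  for (ty in c("revolute", "universal", "spherical")) {
    if (fits[[ty]]$fit_rms <= thr) {
      sel <- fits[[ty]]
      attr(sel, "selection") <- list(threshold_mm = thr, rule = sprintf(
        "lowest-DoF model with fit_rms <= max(%.3g * precision, %.3g * spherical rms)",
        k_precision, 1 + rel_tol))
      return(sel)
    }
  }
  sel <- fits$spherical
  attr(sel, "selection") <- list(threshold_mm = thr, rule = "fallback: spherical")
  sel
}
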