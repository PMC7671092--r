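## Constrained forward kinematics: pose propagation over the spanning tree and
## Gauss-Newton solution of the loop-closure equations for the dependent joint
## coordinates. Residuals per chord joint are 6-vectors (axis-angle rotation
## mismatch, translation mismatch in mm); tolerance applies to their max norm.

# joint transform as list(R, t) without validation (hot path)
joint_mat <- function(ji, q) {
  if (ji$type == "prismatic")
    return(list(R = diag(3), t = q[1] * ji$axes[1, ]))
  R <- rot_axis_angle(ji$axes[1, ], q[1])
  if (ji$f >= 2L) R <- R %*% rot_axis_angle(ji$axes[2, ], q[2])
  if (ji$f >= 3L) R <- R %*% rot_axis_angle(ji$axes[3, ], q[3])
  list(R = R, t = ji$center - as.numeric(R %*% ji$center))
}

# all link poses from the full coordinate vector (list of R, t per link)
fk_link_poses <- function(cm, q) {
  Rs <- vector("list", cm$n_links)
  ts <- vector("list", cm$n_links)
  Rs[[cm$fixed_id]] <- diag(3)
  ts[[cm$fixed_id]] <- c(0, 0, 0)
  for (st in cm$tree) {
    ji <- cm$jinfo[[st$joint]]
    Tj <- joint_mat(ji, q[cm$qidx[[st$joint]]])
    fr <- cm$link_id[[st$from]]; to <- cm$link_id[[st$to]]
    if (st$forward) {
      Rs[[to]] <- Rs[[fr]] %*% Tj$R
      ts[[to]] <- as.numeric(Rs[[fr]] %*% Tj$t) + ts[[fr]]
    } else {
      Rti <- t(Tj$R)
      Rs[[to]] <- Rs[[fr]] %*% Rti
      ts[[to]] <- as.numeric(-(Rs[[to]] %*% Tj$t)) + ts[[fr]]
    }
  }
  list(R = Rs, t = ts)
}

# stacked 6-per-chord loop residuals
fk_residual <- function(cm, q, poses = NULL) {
  if (is.null(poses)) poses <- fk_link_poses(cm, q)
  out <- numeric(6L * length(cm$chords))
  k <- 0L
  for (ci in cm$chords) {
    ji <- cm$jinfo[[ci]]
    Tj <- joint_mat(ji, q[cm$qidx[[ci]]])
    Rp <- poses$R[[ji$parent]]; tp <- poses$t[[ji$parent]]
    Ra <- Rp %*% Tj$R
    ta <- as.numeric(Rp %*% Tj$t) + tp
    Rb <- poses$R[[ji$child]]; tb <- poses$t[[ji$child]]
    out[k + 1:3] <- rot_log(crossprod(Ra, Rb))
    out[k + 4:6] <- tb - ta
    k <- k + 6L
  }
  out
}

# FD Jacobian of the residual w.r.t. a subset of coordinates (independent
# oracle; the solver uses the analytic geometric Jacobian below)
fk_jacobian <- function(cm, q, idx, h = 1e-7) {
  r0 <- fk_residual(cm, q)
  J <- matrix(0, length(r0), length(idx))
  for (k in seq_along(idx)) {
    qp <- q; qp[idx[k]] <- qp[idx[k]] + h
    J[, k] <- (fk_residual(cm, qp) - r0) / h
  }
  J
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# World-frame screws of every joint coordinate at the current configuration:
# axis direction (omega), a point on the axis, rotational flag, tree-step
# sign/index, chord membership.
fk_screws <- function(cm, q, poses) {
  nq <- cm$nq
  omega <- matrix(0, 3, nq); pnt <- matrix(0, 3, nq)
  isrot <- logical(nq); sgn <- numeric(nq)
  stepof <- integer(nq); chordof <- integer(nq)
  screws_for <- function(j, si, sg) {
    ji <- cm$jinfo[[j]]
    Rp <- poses$R[[ji$parent]]; tp <- poses$t[[ji$parent]]
    qj <- q[cm$qidx[[j]]]
    cw <- as.numeric(Rp %*% ji$center) + tp
    pref <- diag(3)
    for (m in seq_len(ji$f)) {
      k <- cm$qidx[[j]][m]
      if (ji$type == "prismatic") {
        omega[, k] <<- as.numeric(Rp %*% ji$axes[1, ]); isrot[k] <<- FALSE
      } else {
        omega[, k] <<- as.numeric(Rp %*% (pref %*% ji$axes[m, ]))
        pnt[, k] <<- cw; isrot[k] <<- TRUE
        pref <- pref %*% rot_axis_angle(ji$axes[m, ], qj[m])
      }
      sgn[k] <<- sg; stepof[k] <<- si
    }
  }
  for (si in seq_along(cm$tree)) {
    st <- cm$tree[[si]]
    screws_for(st$joint, si, if (st$forward) 1 else -1)
  }
  for (ci in cm$chords) screws_for(ci, 0L, 1)
  for (ci in cm$chords) for (k in cm$qidx[[ci]]) chordof[k] <- ci
  list(omega = omega, pnt = pnt, isrot = isrot, sgn = sgn,
       stepof = stepof, chordof = chordof)
}

# Analytic geometric Jacobian of the loop residuals: each joint coordinate is
# a screw about its current world axis; exact at loop closure (the log-map
# correction vanishes there), which is all Newton needs.
fk_jacobian_analytic <- function(cm, q, idx, poses = NULL, screws = NULL) {
  if (is.null(poses)) poses <- fk_link_poses(cm, q)
  if (is.null(screws)) screws <- fk_screws(cm, q, poses)
  omega <- screws$omega; pnt <- screws$pnt; isrot <- screws$isrot
  sgn <- screws$sgn; stepof <- screws$stepof; chordof <- screws$chordof

  J <- matrix(0, 6L * length(cm$chords), length(idx))
  for (cp in seq_along(cm$chords)) {
    ci <- cm$chords[cp]; ji <- cm$jinfo[[ci]]
    rows <- (cp - 1L) * 6L
    Rp <- poses$R[[ji$parent]]; tp <- poses$t[[ji$parent]]
    Tj <- joint_mat(ji, q[cm$qidx[[ci]]])
    Ra <- Rp %*% Tj$R
    ta <- as.numeric(Rp %*% Tj$t) + tp
    tb <- poses$t[[ji$child]]
    for (col in seq_along(idx)) {
      k <- idx[col]
      si <- stepof[k]
      if (si > 0L) {
        e <- (cm$subtree[si, ji$child] - cm$subtree[si, ji$parent]) * sgn[k]
        if (e == 0) next
        if (isrot[k]) {
          w <- omega[, k]
          J[rows + 1:3, col] <- e * as.numeric(crossprod(Ra, w))
          J[rows + 4:6, col] <- e * cross3(w, tb - pnt[, k])
        } else {
          J[rows + 4:6, col] <- e * omega[, k]
        }
      } else if (chordof[k] == ci) {
        if (isrot[k]) {
          w <- omega[, k]
          J[rows + 1:3, col] <- -as.numeric(crossprod(Ra, w))
          J[rows + 4:6, col] <- -cross3(w, ta - pnt[, k])
        } else {
          J[rows + 4:6, col] <- -omega[, k]
        }
      }
    }
  }
  J
}

# Analytic Jacobian of world-frame fit-point coordinates with respect to a
# subset of joint coordinates. Points are given per body (world frame at the
# current configuration); rows are stacked x,y,z per point. Chord-joint
# coordinates do not move any body and get zero columns.
fk_point_jacobian <- function(cm, q, idx, body_ids, points_world,
                              poses = NULL, screws = NULL) {
  if (is.null(poses)) poses <- fk_link_poses(cm, q)
  if (is.null(screws)) screws <- fk_screws(cm, q, poses)
  npts <- sum(vapply(points_world, nrow, 0L))
  J <- matrix(0, 3L * npts, length(idx))
  for (col in seq_along(idx)) {
    k <- idx[col]
    si <- screws$stepof[k]
    if (si == 0L) next
    row <- 0L
    for (b in seq_along(body_ids)) {
      pts <- points_world[[b]]
      n <- nrow(pts)
      if (cm$subtree[si, body_ids[b]]) {
        e <- screws$sgn[k]
        if (screws$isrot[k]) {
          w <- screws$omega[, k]; p0 <- screws$pnt[, k]
          for (i in seq_len(n))
            J[row + (i - 1L) * 3L + 1:3, col] <- e * cross3(w, pts[i, ] - p0)
        } else {
          for (i in seq_len(n))
            J[row + (i - 1L) * 3L + 1:3, col] <- e * screws$omega[, k]
        }
      }
      row <- row + 3L * n
    }
  }
  J
}

# Levenberg-Marquardt solve of the dependent coordinates using the analytic
# geometric Jacobian. Adaptive damping handles ill-conditioned charts and
# rank-deficient (redundant-constraint) systems such as a planar four-bar.
fk_solve_dependent <- function(mech, q, dep_idx, tol = 1e-8, max_iter = 100,
                               cache = NULL) {
  cm <- mech$compiled
  if (length(cm$chords) == 0L || length(dep_idx) == 0L)
    return(list(q = q, converged = TRUE,
                residual = if (length(cm$chords)) max(abs(fk_residual(cm, q))) else 0))
  poses <- fk_link_poses(cm, q)
  r <- fk_residual(cm, q, poses)
  cost <- sum(r^2)
  mu <- 1e-6
  it <- 0L
  while (max(abs(r)) > tol && it < max_iter) {
    it <- it + 1L
    J <- fk_jacobian_analytic(cm, q, dep_idx, poses)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    dscale <- diag(JtJ); dscale[dscale < 1e-12] <- 1e-12
    accepted <- FALSE
    for (try_k in 1:12) {
      delta <- tryCatch(
        solve(JtJ + mu * diag(dscale, nrow(JtJ)), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        qn <- q; qn[dep_idx] <- qn[dep_idx] + as.numeric(delta)
        pn <- fk_link_poses(cm, qn)
        rn <- fk_residual(cm, qn, pn)
        if (sum(rn^2) < cost) {
          q <- qn; r <- rn; poses <- pn; cost <- sum(rn^2)
          mu <- max(mu / 3, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 5
    }
    if (!accepted) break
  }
  list(q = q, converged = max(abs(r)) <= tol, residual = max(abs(r)))
}

worst_chord <- function(mech, q) {
  cm <- mech$compiled
  r <- matrix(fk_residual(cm, q), nrow = 6L)
  nm <- vapply(mech$joints[cm$chords], `[[`, "", "name")
  nm[which.max(colSums(abs(r)))]
}

#' Degree-of-freedom parameterization of a mechanism
#'
#' Maps labelled scalar input parameters (A, B, C, ...) onto joint coordinate
#' indices, with a freeze mask and per-parameter freeze values (defaulting to
#' zero; after fitting, freeze values are the per-parameter means). The number
#' of parameters must equal the mechanism's mobility.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param inputs named integer vector: label -> coordinate index (into the
#'   mechanism's stacked coordinate vector).
#' @param groups optional named character vector mapping labels to anatomical
#'   groups (for reporting).
#' @return Object of class \code{"dof_parameterization"}.
#' @export
dof_parameterization <- function(mech, inputs, groups = NULL) {
  if (anyDuplicated(names(inputs))) stop("parameter labels must be unique")
  if (anyDuplicated(inputs)) stop("parameters must map to distinct coordinates")
  m <- gruebler_mobility(mech)
  if (length(inputs) != m) {
    mn <- numeric_mobility(mech)
    if (length(inputs) == mn)
      warning("parameter count matches numeric mobility (", mn,
              "); the CGK formula gives ", m,
              " (overconstrained special geometry)")
    else
      stop("parameter count (", length(inputs), ") must equal mechanism ",
           "mobility (CGK ", m, ", numeric ", mn, ")")
  }
  structure(list(labels = names(inputs), qidx = as.integer(inputs),
                 groups = groups,
                 frozen = stats::setNames(rep(FALSE, length(inputs)), names(inputs)),
                 freeze_values = stats::setNames(rep(0, length(inputs)), names(inputs))),
            class = "dof_parameterization")
}

#' @export
print.dof_parameterization <- function(x, ...) {
  cat(sprintf("DoF parameterization: %d parameters (%s)\n",
              length(x$labels), paste(range(x$labels), collapse = "-")))
  if (any(x$frozen))
    cat("  frozen:", paste(x$labels[x$frozen], collapse = ", "), "\n")
  invisible(x)
}

#' Constrained forward kinematics
#'
#' Poses the whole mechanism from its input parameters: sets the labelled
#' input coordinates, solves the loop-closure constraints for all dependent
#' coordinates by damped Gauss-Newton (warm-started from \code{init}), and
#' returns the resulting conformation. Assembly-branch selection is by
#' continuation: the solver stays on the branch of the initial guess.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param param a \code{\link{dof_parameterization}}.
#' @param values numeric vector of input parameter values (length = number of
#'   parameters, in label order), or named.
#' @param init optional conformation (or full coordinate vector) to warm-start
#'   the dependent solve; defaults to the reference (all-zero) conformation.
#' @param tol closure tolerance on the max loop residual (rotation rad /
#'   translation mm), default 1e-9.
#' @param cache optional environment for Jacobian reuse across repeated calls.
#' @param continuation on failure, retry with ramped continuation from the
#'   init conformation's parameter values (default \code{TRUE}; optimizers
#'   probing infeasible parameters should disable this and treat failure as
#'   a rejected step).
#' @return Object of class \code{"conformation"}: list with the full
#'   coordinate vector \code{q}, per-link \code{poses}, input \code{values}
#'   and the final closure \code{residual}.
#' @export
forward_kinematics <- function(mech, param, values, init = NULL, tol = 1e-8,
                               cache = NULL, continuation = TRUE) {
  cm <- mech$compiled
  if (!is.null(names(values))) values <- values[param$labels]
  if (length(values) != length(param$labels))
    stop("expected ", length(param$labels), " parameter values")
  q0 <- if (is.null(init)) numeric(cm$nq)
        else if (inherits(init, "conformation")) init$q
        else as.numeric(init)
  dep <- setdiff(seq_len(cm$nq), param$qidx)
  q <- q0; q[param$qidx] <- values
  sol <- fk_solve_dependent(mech, q, dep, tol = tol, cache = cache)
  if (!sol$converged && continuation) {
    # ramped continuation from the init conformation's parameter values
    v0 <- q0[param$qidx]
    lam <- 0; step <- 0.25; qcur <- q0
    while (lam < 1) {
      nxt <- min(1, lam + step)
      qtry <- qcur; qtry[param$qidx] <- v0 + (values - v0) * nxt
      s2 <- fk_solve_dependent(mech, qtry, dep, tol = tol, cache = cache)
      if (s2$converged) {
        lam <- nxt; qcur <- s2$q
        step <- min(step * 2, 0.25)
      } else {
        step <- step / 2
        if (step < 1 / 128) break
      }
    }
    sol <- if (lam >= 1) list(q = qcur, converged = TRUE, residual = 0)
           else s2
  }
  if (!sol$converged)
    stop("forward kinematics failed to close loop '", worst_chord(mech, sol$q),
         "' (residual ", signif(sol$residual, 3), "); near-singular conformation?")
  poses <- fk_link_poses(cm, sol$q)
  structure(list(q = sol$q, poses = poses, values = stats::setNames(values, param$labels),
                 residual = sol$residual, links = mech$links),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Mechanism conformation: %d links, closure residual %.2e\n",
              length(x$links), x$residual))
  print(round(x$values, 5))
  invisible(x)
}

#' Pose of one link in a conformation
#' @param conf a conformation from \code{\link{forward_kinematics}}.
#' @param link link name.
#' @return A \code{\link{pose}}.
#' @export
link_pose <- function(conf, link) {
  i <- match(link, conf$links)
  if (is.na(i)) stop("unknown link: ", link)
  pose(conf$poses$R[[i]], conf$poses$t[[i]], check = FALSE)
}

#' Numeric mobility from the constraint Jacobian
#'
#' The dimension of the null space of the loop-closure constraint Jacobian
#' with respect to all joint coordinates, evaluated at a closed conformation
#' (rank from singular values, relative threshold 1e-8). This is the
#' independent numeric oracle for \code{\link{gruebler_mobility}}; the two
#' disagree for overconstrained mechanisms with special geometry and at
#' kinematically singular conformations.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param conf optional closed conformation (default: reference, all-zero).
#' @param tol relative singular-value threshold (default 1e-8).
#' @return Integer DoF count.
#' @export
numeric_mobility <- function(mech, conf = NULL, tol = 1e-8) {
  cm <- mech$compiled
  q <- if (is.null(conf)) numeric(cm$nq)
       else if (inherits(conf, "conformation")) conf$q else as.numeric(conf)
  if (length(cm$chords) == 0L) return(as.integer(cm$nq))
  if (max(abs(fk_residual(cm, q))) > 1e-6)
    stop("conformation does not satisfy loop closure")
  J <- fk_jacobian(cm, q, seq_len(cm$nq), h = 1e-6)
  d <- svd(J, nu = 0, nv = 0)$d
  rank <- sum(d > tol * max(d, 1e-300))
  as.integer(cm$nq - rank)
}
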