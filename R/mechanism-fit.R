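#' Freeze or thaw parameters of a DoF parameterization
#'
#' Returns a copy of the parameterization with the given labels frozen at the
#' supplied values (or thawed). Frozen parameters are held fixed during
#' mechanism fitting; their values default to zero and, after a trajectory
#' fit, are set to per-parameter means.
#'
#' @param param a \code{\link{dof_parameterization}}.
#' @param labels character vector of parameter labels.
#' @param values freeze values (recycled); default keeps current values.
#' @param frozen logical, freeze (default) or thaw.
#' @return Updated \code{dof_parameterization}.
#' @export
freeze_parameters <- function(param, labels, values = NULL, frozen = TRUE) {
  i <- match(labels, param$labels)
  if (anyNA(i)) stop("unknown labels: ", paste(labels[is.na(i)], collapse = ", "))
  param$frozen[i] <- frozen
  if (!is.null(values)) param$freeze_values[i] <- rep_len(values, length(i))
  param
}

#' Fit mechanism input parameters to one frame of observed fit points
#'
#' Optimizes the free (unfrozen) input parameters so that the mechanism's
#' model-animated fit points match the observed fit points with minimum RMS
#' error, by Levenberg-Marquardt over the forward kinematics. Frozen
#' parameters are held at their freeze values.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param param a \code{\link{dof_parameterization}} (freeze mask respected).
#' @param targets named list: observed 3 x 3 fit-point matrices (mm, world
#'   frame) per marked body.
#' @param fit_points named list: reference fit-point matrices per body (body
#'   frame = world frame at the reference conformation).
#' @param init optional initial parameter vector (full length, label order);
#'   defaults to freeze values with zeros for free parameters.
#' @param init_conf optional conformation to warm-start the kinematics.
#' @param control list: \code{maxiter} (default 60), \code{ftol}, \code{ptol},
#'   and \code{ridge} (default 1e-4): weight of a tiny quadratic penalty that
#'   tethers the parameters to their warm-start values. It is orders of
#'   magnitude below the fit-point sensitivities, so identified parameters
#'   are unaffected, but it pins parameters that the fit points barely
#'   constrain (e.g. strut lengths with no markers on the strut), which
#'   would otherwise random-walk along near-null directions of the fit.
#' @return List of class \code{"mechanism_frame_fit"}: \code{values} (full
#'   parameter vector), \code{errors} (per-fit-point distances, mm; named
#'   body.point), \code{rms} (mm), \code{conformation}, \code{converged}.
#' @export
fit_mechanism_frame <- function(mech, param, targets, fit_points,
                                init = NULL, init_conf = NULL,
                                control = list()) {
  ctrl <- utils::modifyList(list(maxiter = 60, ftol = 1e-12, ptol = 1e-12,
                                 ridge = 1e-4), control)
  bodies <- names(targets)
  if (!length(bodies)) stop("need targets for at least one marked body")
  if (!all(bodies %in% names(fit_points)))
    stop("missing reference fit points for: ",
         paste(setdiff(bodies, names(fit_points)), collapse = ", "))
  free <- !param$frozen
  v0 <- param$freeze_values
  if (!is.null(init)) v0[free] <- init[free]
  state <- new.env(parent = emptyenv())
  state$conf <- init_conf
  predict_pts <- function(conf) {
    out <- numeric(0)
    for (bd in bodies) {
      p <- link_pose(conf, bd)
      out <- c(out, as.numeric(t(pose_apply(p, fit_points[[bd]]))))
    }
    out
  }
  obs <- unlist(lapply(bodies, function(bd) as.numeric(t(targets[[bd]]))))
  fk_at <- function(pfree) {
    v <- v0; v[free] <- pfree
    cf <- tryCatch(forward_kinematics(mech, param, v, init = state$conf,
                                      continuation = FALSE),
                   error = function(e) NULL)
    if (!is.null(cf)) { state$conf <- cf; state$par <- pfree }
    cf
  }
  pinit <- v0[free]
  resid_fn <- function(pfree) {
    cf <- fk_at(pfree)
    # infeasible trial parameters read as a large constant residual, which
    # Levenberg-Marquardt rejects and backs away from
    if (is.null(cf)) return(rep(1e3, length(obs) + length(pinit)))
    c(predict_pts(cf) - obs, ctrl$ridge * (pfree - pinit))
  }
  # analytic Jacobian via the implicit function theorem on loop closure:
  # dq_dep/dp = -A^{-1} B with A, B the closure Jacobians w.r.t. dependent
  # and free coordinates; then chain through the fit-point screws
  cm <- mech$compiled
  body_ids <- vapply(bodies, function(b) cm$link_id[[b]], 0L)
  dep_idx <- setdiff(seq_len(cm$nq), param$qidx)
  free_q <- param$qidx[free]
  ridgeJ <- diag(ctrl$ridge, sum(free))
  jac_fn <- function(pfree) {
    cf <- if (!is.null(state$par) && identical(state$par, pfree)) state$conf
          else fk_at(pfree)
    if (is.null(cf)) return(matrix(0, length(obs) + sum(free), sum(free)))
    poses <- cf$poses
    screws <- fk_screws(cm, cf$q, poses)
    pts_world <- lapply(bodies, function(bd)
      pose_apply(link_pose(cf, bd), fit_points[[bd]]))
    A <- fk_jacobian_analytic(cm, cf$q, dep_idx, poses, screws)
    B <- fk_jacobian_analytic(cm, cf$q, free_q, poses, screws)
    X <- tryCatch(solve(qr(A, LAPACK = TRUE), -B), error = function(e) NULL)
    if (is.null(X)) return(matrix(0, length(obs) + sum(free), sum(free)))
    Pfree <- fk_point_jacobian(cm, cf$q, free_q, body_ids, pts_world, poses, screws)
    Pdep <- fk_point_jacobian(cm, cf$q, dep_idx, body_ids, pts_world, poses, screws)
    # rows of P are x,y,z per point in body order; residual rows match
    rbind(Pfree + Pdep %*% X, ridgeJ)
  }
  if (any(free)) {
    r0 <- resid_fn(v0[free])
    if (sqrt(mean(r0^2)) < 1e-8) {
      # already at the optimum to numerical precision: a finite-difference
      # refit would only add differentiation noise
      v <- v0
      converged <- TRUE
    } else {
      ctl <- minpack.lm::nls.lm.control(maxiter = ctrl$maxiter,
                                        ftol = ctrl$ftol, ptol = ctrl$ptol)
      # nls.lm warns when it stops on maxiter; convergence is tracked through
      # the info code and the keep-best comparison below instead
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(v0[free], fn = resid_fn, jac = jac_fn, control = ctl)),
        error = function(e) NULL)
      if (is.null(fit))
        fit <- suppressWarnings(
          minpack.lm::nls.lm(v0[free], fn = resid_fn, control = ctl))
      if (fit$deviance <= sum(r0^2)) {
        v <- v0; v[free] <- fit$par
      } else v <- v0  # keep the better of init and fit
      converged <- fit$info %in% 1:4
    }
  } else {
    v <- v0
    converged <- TRUE
  }
  cf <- tryCatch(forward_kinematics(mech, param, v, init = state$conf,
                                    continuation = FALSE),
                 error = function(e) NULL)
  if (is.null(cf))
    cf <- forward_kinematics(mech, param, v, init = init_conf)
  pred <- predict_pts(cf)
  d2 <- rowSums(matrix((pred - obs)^2, ncol = 3L, byrow = TRUE))
  errs <- sqrt(d2)
  names(errs) <- unlist(lapply(bodies, function(bd) paste0(bd, ".", 1:3)))
  structure(list(values = stats::setNames(v, param$labels), errors = errs,
                 rms = sqrt(mean(d2)), conformation = cf,
                 converged = converged),
            class = "mechanism_frame_fit")
}

#' @export
print.mechanism_frame_fit <- function(x, ...) {
  cat(sprintf("Mechanism frame fit: RMS %.4g mm over %d fit points%s\n",
              x$rms, length(x$errors),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.mechanism_frame_fit <- function(object, ...) object$values

#' Fit mechanism parameters to a whole trajectory of observed fit points
#'
#' Fits each frame with \code{\link{fit_mechanism_frame}}, warm-starting every
#' frame from the previous frame's solution (the first from the reference
#' conformation).
#'
#' @inheritParams fit_mechanism_frame
#' @param targets_by_frame list over frames; each element a named list of
#'   observed 3 x 3 fit-point matrices per body.
#' @param progress print a dot every 25 frames.
#' @return List: \code{values} (frames x parameters matrix), \code{rms}
#'   (per-frame, mm), \code{errors} (frames x fit-points matrix).
#' @export
fit_mechanism_trajectory <- function(mech, param, targets_by_frame, fit_points,
                                     control = list(), progress = FALSE) {
  n <- length(targets_by_frame)
  vals <- matrix(NA_real_, n, length(param$labels),
                 dimnames = list(NULL, param$labels))
  rms <- numeric(n)
  errs <- NULL
  init <- NULL; conf <- NULL
  for (f in seq_len(n)) {
    ft <- fit_mechanism_frame(mech, param, targets_by_frame[[f]], fit_points,
                              init = init, init_conf = conf, control = control)
    vals[f, ] <- ft$values
    rms[f] <- ft$rms
    if (is.null(errs)) errs <- matrix(NA_real_, n, length(ft$errors),
                                      dimnames = list(NULL, names(ft$errors)))
    errs[f, ] <- ft$errors
    init <- ft$values; conf <- ft$conformation
    if (progress && f %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(values = vals, rms = rms, errors = errs)
}

#' Sequential degree-of-freedom freezing scan
#'
#' Ranks the mechanism's free DoFs by their contribution to observed motion.
#' Starting from the parameterization's a-priori freeze mask, the scan fits
#' the model to a set of maximally disparate sample frames, then repeatedly
#' freezes the single remaining free DoF (at its mean over the full fitted
#' trajectory) whose freezing increases the error statistic the least,
#' refitting after each freeze, down to the zero-DoF (akinesis) model. Ties
#' break by label order, making runs reproducible.
#'
#' @inheritParams fit_mechanism_frame
#' @param targets_by_frame list over frames of named target fit-point lists.
#' @param n_sample number of disparate frames used for the scan fits
#'   (default 15).
#' @param head_length optional head length (mm) to report errors as \%HL.
#' @param cost error statistic driving the greedy choice: \code{"median"}
#'   (default, matching box-plot presentation) or \code{"mean"}.
#' @param error_bodies bodies whose fit points enter the reported error
#'   distributions (default: all target bodies). All targets are always used
#'   in the fits themselves.
#' @param progress print progress.
#' @return Object of class \code{"freeze_curve"}: per-step free-DoF count,
#'   newly frozen label, error distribution (one entry per fit point, marked
#'   body and sampled frame), medians/means, the freeze order, freeze values,
#'   sampled frame indices, and the full-model fitted trajectory.
#' @export
sequential_freeze <- function(mech, param, targets_by_frame, fit_points,
                              n_sample = 15, head_length = NULL,
                              cost = c("median", "mean"), control = list(),
                              error_bodies = NULL, progress = FALSE) {
  cost <- match.arg(cost)
  cost_fn <- if (cost == "median") stats::median else mean
  n_frames <- length(targets_by_frame)
  if (n_sample > n_frames) stop("n_sample exceeds available frames")
  labels <- param$labels
  apriori <- labels[param$frozen]

  # full-model fit over the whole trajectory -> freeze values (means)
  if (progress) cat("fitting full trajectory (", n_frames, "frames )\n")
  full <- fit_mechanism_trajectory(mech, param, targets_by_frame, fit_points,
                                   control = control, progress = progress)
  means <- colMeans(full$values)

  # sample the most disparate target conformations
  X <- t(vapply(targets_by_frame, function(tg)
    unlist(lapply(tg, as.numeric)), numeric(9L * length(targets_by_frame[[1]]))))
  sel <- select_disparate_frames(X, n_sample)

  # refits start from the full-model solution for each frame (frozen values
  # are enforced by the freeze mask), keeping every fit on the global branch
  keep <- if (is.null(error_bodies)) NULL else
    unlist(lapply(error_bodies, function(b) paste0(b, ".", 1:3)))
  fit_sel <- function(par) {
    errs <- numeric(0)
    conf <- NULL
    for (f in sel) {
      ft <- fit_mechanism_frame(mech, par, targets_by_frame[[f]], fit_points,
                                init = full$values[f, ], init_conf = conf,
                                control = control)
      e <- if (is.null(keep)) ft$errors else ft$errors[keep]
      errs <- c(errs, e)
      conf <- ft$conformation
    }
    errs
  }

  cur <- param
  cur$freeze_values <- means  # frozen parameters sit at their trajectory means
  steps <- list()
  e0 <- fit_sel(cur)
  steps[[1]] <- list(n_free = sum(!cur$frozen), frozen_label = NA_character_,
                     errors = e0, median = stats::median(e0), mean = mean(e0))
  freeze_order <- character()
  while (sum(!cur$frozen) > 0L) {
    cand <- labels[!cur$frozen]
    stat <- rep(NA_real_, length(cand))
    errl <- vector("list", length(cand))
    for (k in seq_along(cand)) {
      trial <- freeze_parameters(cur, cand[k])
      errl[[k]] <- fit_sel(trial)
      stat[k] <- cost_fn(errl[[k]])
    }
    best <- which(stat == min(stat))[1]  # ties: first in label order
    cur <- freeze_parameters(cur, cand[best])
    freeze_order <- c(freeze_order, cand[best])
    e <- errl[[best]]
    steps[[length(steps) + 1L]] <- list(n_free = sum(!cur$frozen),
                                        frozen_label = cand[best], errors = e,
                                        median = stats::median(e), mean = mean(e))
    if (progress) cat("froze", cand[best], "->", sum(!cur$frozen), "free;",
                      cost, "error", signif(cost_fn(e), 3), "mm\n")
  }
  structure(list(steps = steps, freeze_order = freeze_order,
                 freeze_values = means, apriori_frozen = apriori,
                 labels = labels, sample_frames = sel,
                 head_length = head_length, cost = cost,
                 trajectory = full),
            class = "freeze_curve")
}

#' @export
print.freeze_curve <- function(x, ...) {
  cat("Sequential DoF-freezing scan\n")
  cat("  a-priori frozen:", if (length(x$apriori_frozen))
    paste(x$apriori_frozen, collapse = ", ") else "none", "\n")
  cat("  freeze order:", paste(x$freeze_order, collapse = " > "), "\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.freeze_curve <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- unique(df[, c("n_free", "frozen_label", "median_mm", "mean_mm",
                       "percent_scale_median", "percent_scale_mean",
                       if (!is.null(object$head_length)) c("median_pcthl"))])
  rownames(agg) <- NULL
  agg
}

#' @export
as.data.frame.freeze_curve <- function(x, ...) {
  ps_med <- tryCatch(percent_scale(x, "median"), error = function(e) rep(NA_real_, length(x$steps)))
  ps_mean <- tryCatch(percent_scale(x, "mean"), error = function(e) rep(NA_real_, length(x$steps)))
  do.call(rbind, lapply(seq_along(x$steps), function(i) {
    s <- x$steps[[i]]
    d <- data.frame(step = i - 1L, n_free = s$n_free,
                    frozen_label = if (is.na(s$frozen_label)) "" else s$frozen_label,
                    median_mm = s$median, mean_mm = s$mean,
                    percent_scale_median = ps_med[i],
                    percent_scale_mean = ps_mean[i])
    if (!is.null(x$head_length)) {
      d$median_pcthl <- scale_by_head_length(s$median, x$head_length)
      d$mean_pcthl <- scale_by_head_length(s$mean, x$head_length)
    }
    d
  }))
}

#' @export
plot.freeze_curve <- function(x, ...) {
  ers <- lapply(x$steps, `[[`, "errors")
  nf <- vapply(x$steps, `[[`, 0L, "n_free")
  lab <- vapply(x$steps, function(s)
    if (is.na(s$frozen_label)) as.character(s$n_free)
    else sprintf("%d (%s)", s$n_free, s$frozen_label), "")
  graphics::boxplot(rev(ers), names = rev(lab), las = 2,
                    xlab = "free DoFs (newly frozen)", ylab = "fit error (mm)",
                    main = "Model fit error vs. degrees of freedom", ...)
  invisible(x)
}

#' Percent-of-error-range scale for a freeze curve
#'
#' Expresses each step's error statistic as a percentage of the range spanned
#' by the highest-parameter (best) and lowest-parameter (akinesis, worst)
#' models: \code{100 * (e_step - e_best) / (e_worst - e_best)}. The best model
#' scores 0\%, akinesis 100\%.
#'
#' @param curve a \code{\link{sequential_freeze}} result.
#' @param stat \code{"median"} (default) or \code{"mean"}.
#' @return Numeric vector, one value per step.
#' @export
percent_scale <- function(curve, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (length(curve$steps) < 2L) stop("curve needs at least 2 steps")
  e <- vapply(curve$steps, `[[`, 0, stat)
  best <- e[1]; worst <- e[length(e)]
  if (worst <= best) stop("undefined percent scale: worst error <= best error")
  100 * (e - best) / (worst - best)
}

#' Benchmarks for judging mechanism-model sufficiency
#'
#' Bundles the three error benchmarks: motion-capture tracking precision
#' (mm), inter-individual variation from a Procrustes consensus (mm), and the
#' percent-of-error-range scale anchors implied by a freeze curve.
#'
#' @param precision_mm tracking precision, mm (e.g. mean of
#'   \code{\link{precision_metric}}).
#' @param interindividual_mm RMS deviation of individuals from the Procrustes
#'   consensus, mm (e.g. mean of \code{\link{procrustes_consensus}} rms).
#' @param head_length optional head length (mm) for \%HL reporting.
#' @return Object of class \code{"skull_benchmarks"}.
#' @export
benchmarks <- function(precision_mm, interindividual_mm, head_length = NULL) {
  structure(list(precision_mm = precision_mm,
                 interindividual_mm = interindividual_mm,
                 head_length = head_length),
            class = "skull_benchmarks")
}

#' @export
print.skull_benchmarks <- function(x, ...) {
  cat(sprintf("Benchmarks: precision %.3g mm; inter-individual %.3g mm",
              x$precision_mm, x$interindividual_mm))
  if (!is.null(x$head_length))
    cat(sprintf(" (%.2g%% HL)", 100 * x$interindividual_mm / x$head_length))
  cat("\n")
  invisible(x)
}

#' How many DoFs are sufficient to explain the motion?
#'
#' Finds the smallest free-DoF count along a freeze curve whose error
#' satisfies the chosen criterion: error below the inter-individual benchmark
#' (\code{"benchmark"}), and/or percent-of-error-range at or below
#' \code{percent_max} (\code{"percent"}). Reports both the unilateral count
#' and the bilateral-equivalent count obtained by adding the a-priori-frozen
#' contralateral twins of retained DoFs (e.g. a 5-DoF unilateral model with
#' unmeasured right-opercular twins is bilaterally a 7-DoF model).
#'
#' @param curve a \code{\link{sequential_freeze}} result.
#' @param bench a \code{\link{benchmarks}} object (needed for
#'   \code{criterion = "benchmark"}).
#' @param criterion \code{"benchmark"} or \code{"percent"}.
#' @param percent_max percent-scale threshold for \code{criterion = "percent"}.
#' @param stat error statistic, \code{"mean"} (default, as sufficiency is
#'   judged on mean error) or \code{"median"}.
#' @param twins named character vector mapping retained labels to their
#'   contralateral twins (default \code{c(G = "M", H = "N")}).
#' @return List: \code{n_free}, \code{n_bilateral}, \code{step}, the rule
#'   applied and the error at the chosen step. If no step satisfies the
#'   criterion, returns the full model with \code{satisfied = FALSE}.
#' @export
sufficient_dofs <- function(curve, bench = NULL,
                            criterion = c("benchmark", "percent"),
                            percent_max = NULL, stat = c("mean", "median"),
                            twins = c(G = "M", H = "N")) {
  criterion <- match.arg(criterion)
  stat <- match.arg(stat)
  e <- vapply(curve$steps, `[[`, 0, stat)
  nf <- vapply(curve$steps, function(s) as.integer(s$n_free), 0L)
  ok <- if (criterion == "benchmark") {
    if (is.null(bench)) stop("criterion 'benchmark' needs a benchmarks object")
    e < bench$interindividual_mm
  } else {
    if (is.null(percent_max)) stop("criterion 'percent' needs percent_max")
    percent_scale(curve, stat) <= percent_max
  }
  if (!any(ok)) {
    i <- 1L
    satisfied <- FALSE
  } else {
    i <- which(ok)[which.min(nf[ok])]
    satisfied <- TRUE
  }
  # retained free labels at that step: those never frozen up to step i
  frozen_by_i <- curve$freeze_order[seq_len(i - 1L)]
  retained <- setdiff(setdiff(curve$labels, curve$apriori_frozen), frozen_by_i)
  extra <- sum(!is.na(twins[retained]) & twins[retained] %in% curve$apriori_frozen)
  list(n_free = nf[i], n_bilateral = nf[i] + extra, step = i - 1L,
       satisfied = satisfied, retained = retained,
       criterion = criterion, stat = stat,
       threshold = if (criterion == "benchmark") bench$interindividual_mm else percent_max,
       error_mm = e[i])
}

#' Scale errors by head length
#'
#' @param errors numeric errors (mm).
#' @param head_length head length (mm), > 0.
#' @return Errors as percent of head length.
#' @export
scale_by_head_length <- function(errors, head_length) {
  if (head_length <= 0) stop("head length must be positive")
  100 * errors / head_length
}
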