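#' Marker trajectory container
#'
#' Holds per-frame 3D positions (mm) for a set of markers, each attached to a
#' named body, at a fixed frame rate. Missing observations are carried as an
#' explicit mask (and NA coordinates).
#'
#' @param xyz numeric array \code{n_frames x 3 x n_markers} (mm), or a list of
#'   \code{n_frames x 3} matrices.
#' @param marker character vector of marker ids.
#' @param body character vector, body id per marker.
#' @param fps frame rate, Hz (> 0).
#' @param missing optional logical \code{n_frames x n_markers} mask; defaults
#'   to frames with any NA coordinate.
#' @return An object of class \code{"marker_trajectories"}.
#' @export
marker_trajectories <- function(xyz, marker, body, fps, missing = NULL) {
  if (is.list(xyz)) {
    n <- nrow(xyz[[1]])
    arr <- array(NA_real_, c(n, 3L, length(xyz)))
    for (i in seq_along(xyz)) arr[, , i] <- as.matrix(xyz[[i]])
    xyz <- arr
  }
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (fps <= 0) stop("frame rate must be > 0")
  n_markers <- dim(xyz)[3]
  if (length(marker) != n_markers || length(body) != n_markers)
    stop("marker and body must have one entry per marker")
  if (is.null(missing))
    missing <- apply(xyz, c(1, 3), function(v) anyNA(v))
  structure(list(xyz = xyz, marker = as.character(marker),
                 body = as.character(body), fps = fps,
                 missing = missing),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("Marker trajectories: %d markers on %d bodies, %d frames @ %g Hz\n",
              length(x$marker), length(unique(x$body)), dim(x$xyz)[1], x$fps))
  miss <- mean(x$missing)
  if (miss > 0) cat(sprintf("  %.1f%% of marker-frames missing\n", 100 * miss))
  invisible(x)
}

#' Three-landmark fit point set for one body
#'
#' Fit points are the landmarks, rigidly attached to a skeletal element, whose
#' model-versus-observed distances score a joint or mechanism fit.
#'
#' @param body body id.
#' @param points 3 x 3 matrix: exactly three non-collinear landmark positions
#'   (rows), body frame, mm.
#' @return Object of class \code{"fit_point_set"}.
#' @export
fit_point_set <- function(body, points) {
  points <- as.matrix(points)
  if (!all(dim(points) == c(3L, 3L)))
    stop("fit point set must contain exactly three 3D points")
  c0 <- sweep(points, 2L, colMeans(points))
  if (svd(c0, nu = 0, nv = 0)$d[2] <= 1e-9)
    stop("fit points are collinear")
  structure(list(body = body, points = points), class = "fit_point_set")
}

#' Zero-phase low-pass smoothing of marker trajectories
#'
#' Filters each marker coordinate with a zero-phase (forward-backward)
#' 4th-order Butterworth low-pass filter. Missing frames are linearly
#' interpolated before filtering and re-masked afterwards, so the mask is
#' preserved.
#'
#' @param markers a \code{\link{marker_trajectories}} object.
#' @param cutoff low-pass cutoff frequency, Hz; must be below the Nyquist
#'   frequency. Default 25 Hz, appropriate for 300 Hz skeletal kinematics.
#' @param order filter order (default 4).
#' @return A smoothed \code{marker_trajectories} object.
#' @export
smooth_trajectories <- function(markers, cutoff = 25, order = 4) {
  stopifnot(inherits(markers, "marker_trajectories"))
  nyq <- markers$fps / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency (", nyq, " Hz)")
  bf <- signal::butter(order %/% 2, cutoff / nyq, type = "low")
  out <- markers
  n <- dim(markers$xyz)[1]
  # odd-reflection padding suppresses the zero-state edge transients of
  # forward-backward filtering
  npad <- min(n - 1L, ceiling(3 * markers$fps / cutoff))
  for (m in seq_along(markers$marker)) {
    for (ax in 1:3) {
      y <- markers$xyz[, ax, m]
      if (all(is.na(y))) next
      if (anyNA(y)) {
        ok <- which(!is.na(y))
        y <- stats::approx(ok, y[ok], xout = seq_len(n), rule = 2)$y
      }
      ypad <- c(2 * y[1] - y[(npad + 1):2], y, 2 * y[n] - y[(n - 1):(n - npad)])
      ys <- signal::filtfilt(bf, ypad)
      out$xyz[, ax, m] <- ys[npad + seq_len(n)]
    }
    out$xyz[markers$missing[, m], , m] <- NA_real_
  }
  out
}

#' Tracking-precision benchmark from intra-body marker configurations
#'
#' For each body, samples motion frames, rigidly aligns the body's marker
#' configuration in each sampled frame to the mean (consensus) configuration,
#' and reports the RMS deviation. This captures calibration error, tracking
#' error, and non-rigidity of the element, and anchors the error thresholds of
#' joint-model selection.
#'
#' @param markers a \code{\link{marker_trajectories}} object.
#' @param n_frames number of random frames to sample per body (default 50);
#'   sampling is without replacement, and when \code{n_frames} equals the
#'   number of usable frames all frames are used (seed-independent).
#' @param seed integer seed for frame sampling.
#' @return Named numeric vector: RMS precision (mm) per body.
#' @export
precision_metric <- function(markers, n_frames = 50, seed = 1) {
  stopifnot(inherits(markers, "marker_trajectories"))
  bodies <- unique(markers$body)
  out <- stats::setNames(numeric(length(bodies)), bodies)
  for (bd in bodies) {
    sel <- which(markers$body == bd)
    if (length(sel) < 3L)
      warning("body '", bd, "' has fewer than 3 markers; precision computed on available markers")
    usable <- which(rowSums(!markers$missing[, sel, drop = FALSE]) == length(sel))
    if (length(usable) < 1L) { out[bd] <- NA_real_; next }
    k <- min(n_frames, length(usable))
    frames <- if (k == length(usable)) usable else {
      set.seed(seed)
      sort(sample(usable, k))
    }
    shapes <- lapply(frames, function(f) t(markers$xyz[f, , sel, drop = FALSE][1, , ]))
    if (length(sel) >= 3L && length(shapes) >= 2L) {
      gpa <- procrustes_consensus(shapes)
      # RMS over all landmarks and frames of deviation from consensus
      out[bd] <- sqrt(mean(unlist(lapply(gpa$aligned, function(s)
        rowSums((s - gpa$consensus)^2)))))
    } else if (length(shapes) == 1L) {
      out[bd] <- 0
    } else {
      # < 3 markers: fall back to per-marker deviation about the mean position
      xs <- simplify2array(shapes)
      mu <- apply(xs, c(1, 2), mean)
      out[bd] <- sqrt(mean(apply(xs, 3, function(s) rowSums((s - mu)^2))))
    }
  }
  out
}

#' Generalized Procrustes consensus of landmark configurations
#'
#' Iterative generalized least-squares superimposition using rotation and
#' translation (scaling optional, off by default so deviations stay in mm).
#' The consensus is the mean of the aligned shapes.
#'
#' @param shapes list of k x 3 landmark matrices (equal k).
#' @param scale logical; also remove isotropic scale (default \code{FALSE}).
#' @param max_iter,tol GPA iteration controls.
#' @return List with \code{consensus} (k x 3), \code{aligned} (list of k x 3),
#'   and \code{rms} (per-shape RMS deviation from the consensus, mm).
#' @export
procrustes_consensus <- function(shapes, scale = FALSE, max_iter = 50, tol = 1e-10) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  k <- nrow(shapes[[1]])
  if (any(vapply(shapes, nrow, 0L) != k)) stop("inconsistent landmark counts")
  centred <- lapply(shapes, function(s) {
    s <- as.matrix(s)
    s <- sweep(s, 2L, colMeans(s))
    if (scale) s <- s / sqrt(sum(s^2))
    s
  })
  consensus <- centred[[1]]
  prev <- Inf
  for (it in seq_len(max_iter)) {
    aligned <- lapply(centred, function(s) {
      f <- solve_rigid_alignment(s, consensus)
      pose_apply(f$pose, s)
    })
    consensus_new <- Reduce(`+`, aligned) / length(aligned)
    consensus_new <- sweep(consensus_new, 2L, colMeans(consensus_new))
    change <- sqrt(mean((consensus_new - consensus)^2))
    consensus <- consensus_new
    if (change < tol) break
  }
  aligned <- lapply(centred, function(s) {
    f <- solve_rigid_alignment(s, consensus)
    pose_apply(f$pose, s)
  })
  rms <- vapply(aligned, function(s) sqrt(mean(rowSums((s - consensus)^2))), 0)
  list(consensus = consensus, aligned = aligned, rms = rms)
}
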