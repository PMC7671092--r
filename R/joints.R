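#' Joint model: type, center, axes and per-frame coordinates
#'
#' The four joint primitives used to articulate skeletal elements: revolute
#' (hinge, 1 DoF), universal (saddle, 2 DoF), spherical (ball-in-socket,
#' 3 DoF) and prismatic (slider, 1 DoF). Rotational coordinates are radians;
#' prismatic slide is mm.
#'
#' @param type one of \code{"revolute"}, \code{"universal"}, \code{"spherical"},
#'   \code{"prismatic"}.
#' @param center 3-vector (mm), joint center in the parent frame (ignored for
#'   prismatic).
#' @param axes matrix with one unit axis per row: 1 row (revolute, prismatic),
#'   2 rows (universal) or 3 rows (spherical). Universal/spherical axes must be
#'   linearly independent.
#' @param coordinates optional per-frame coordinate matrix (frames x dof).
#' @param fit_rms optional RMS fit error (mm) from \code{\link{fit_joint_model}}.
#' @return Object of class \code{"joint_model"}.
#' @export
joint_model <- function(type = c("revolute", "universal", "spherical", "prismatic"),
                        center = c(0, 0, 0), axes, coordinates = NULL,
                        fit_rms = NA_real_) {
  type <- match.arg(type)
  dof <- joint_dof(type)
  axes <- matrix(as.numeric(axes), ncol = 3L)
  n_axes <- if (type == "spherical") 3L else if (type == "universal") 2L else 1L
  if (nrow(axes) != n_axes)
    stop(sprintf("%s joint requires %d axis row(s)", type, n_axes))
  nrm <- sqrt(rowSums(axes^2))
  if (any(abs(nrm - 1) > 1e-8)) axes <- axes / nrm
  if (n_axes > 1L && abs(det(rbind(axes, if (n_axes == 2L) pracma_cross(axes[1, ], axes[2, ])))) < 1e-8)
    stop("joint axes must be linearly independent")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (ncol(coordinates) != dof)
      stop("coordinate count per frame must equal joint dof")
  }
  structure(list(type = type, dof = dof, center = as.numeric(center),
                 axes = axes, coordinates = coordinates, fit_rms = fit_rms),
            class = "joint_model")
}

# cross product (avoids a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Degrees of freedom of a joint type
#' @param type joint type string.
#' @return Integer DoF count: revolute 1, universal 2, spherical 3, prismatic 1.
#' @export
joint_dof <- function(type) {
  switch(type, revolute = 1L, universal = 2L, spherical = 3L, prismatic = 1L,
         stop("unknown joint type: ", type))
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("%s joint (%d DoF)\n", x$type, x$dof))
  cat("  center (mm):", paste(round(x$center, 3), collapse = ", "), "\n")
  for (i in seq_len(nrow(x$axes)))
    cat(sprintf("  axis %d: %s\n", i, paste(round(x$axes[i, ], 4), collapse = ", ")))
  if (!is.na(x$fit_rms)) cat(sprintf("  fit RMS: %.4g mm\n", x$fit_rms))
  if (!is.null(x$coordinates))
    cat(sprintf("  coordinates: %d frames\n", nrow(x$coordinates)))
  invisible(x)
}

#' @export
coef.joint_model <- function(object, ...) object$coordinates

#' Forward transform of one joint
#'
#' Returns the child-relative-to-parent pose produced by a joint at the given
#' coordinates. Zero coordinates give the identity. Rotational joints rotate
#' about their axes through the joint center (axes applied in order, each
#' fixed in the parent frame); prismatic joints translate along their axis.
#'
#' @param model a \code{\link{joint_model}}.
#' @param coords numeric vector of length \code{model$dof}.
#' @return A \code{\link{pose}}.
#' @examples
#' j <- joint_model("revolute", c(0, 0, 0), c(0, 0, 1))
#' joint_transform(j, pi / 2)$R
#' @export
joint_transform <- function(model, coords) {
  if (length(coords) != model$dof)
    stop("expected ", model$dof, " coordinate(s), got ", length(coords))
  if (model$type == "prismatic")
    return(pose(diag(3), coords[1] * model$axes[1, ], check = FALSE))
  R <- rot_axis_angle(model$axes[1, ], coords[1])
  if (model$dof >= 2L) R <- R %*% rot_axis_angle(model$axes[2, ], coords[2])
  if (model$dof >= 3L) R <- R %*% rot_axis_angle(model$axes[3, ], coords[3])
  pose(R, model$center - as.numeric(R %*% model$center), check = FALSE)
}

#' Select maximally disparate frames by greedy maximin
#'
#' Deterministic greedy selection of the \code{k} most mutually disparate
#' frames under the RMS row-distance metric: the first selected frame is the
#' one farthest from the column mean; each subsequent frame maximizes its
#' minimum distance to the already-selected set. Ties break toward the lowest
#' frame index. Used to subsample long recordings for joint and mechanism
#' fitting.
#'
#' @param x frames x features numeric matrix (e.g., stacked fit-point
#'   coordinates or joint coordinates, one row per frame).
#' @param k number of frames to select (\code{k <=} frame count).
#' @return Sorted integer vector of frame indices.
#' @export
select_disparate_frames <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of frames")
  if (k == n) return(seq_len(n))
  mu <- colMeans(x)
  d0 <- sqrt(rowMeans(sweep(x, 2L, mu)^2))
  sel <- which.max(d0)  # which.max takes the first (lowest index) on ties
  mind <- sqrt(rowMeans((x - matrix(x[sel, ], n, ncol(x), byrow = TRUE))^2))
  while (length(sel) < k) {
    nxt <- which.max(replace(mind, sel, -Inf))
    sel <- c(sel, nxt)
    d <- sqrt(rowMeans((x - matrix(x[nxt, ], n, ncol(x), byrow = TRUE))^2))
    mind <- pmin(mind, d)
  }
  sort(sel)
}
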