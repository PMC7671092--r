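#' Default geometry of the catfish-like skull fixture
#'
#' Joint centers and strut attachment sites (mm) for a bilaterally symmetric,
#' catfish-like skull linkage with a head length of 76 mm, in the anatomical
#' frame: +x rostral to caudal, +y left to right, +z ventral to dorsal, origin
#' at the rostral tip of the neurocranium. Left-side structures have y < 0;
#' right-side geometry is the mirror image. The numbers are order-of-magnitude
#' anatomical placements for a ~30 cm fish, not measured coordinates.
#'
#' @param head_length head length, mm (default 76); all positions scale
#'   linearly with \code{head_length / 76}.
#' @return Named list of 3-vectors (left side and midline) plus
#'   \code{head_length}.
#' @export
catfish_geometry <- function(head_length = 76) {
  s <- head_length / 76
  g <- list(
    quadrate_L       = c(16, -9, -6),    # suspensorium-mandible jaw joint
    symphysis        = c(4, 0, -10),     # mandibular symphysis (midline)
    susp_cranial_L   = c(26, -10, 8),    # neurocranium-suspensorium
    operc_joint_L    = c(38, -12, 2),    # suspensorium-operculum
    hyoid_prox_L     = c(24, -8, -8),    # suspensorium-hyoid
    hyoid_dist_L     = c(32, -3, -16),   # hyoid-urohyal (near midline)
    girdle_joint     = c(58, 0, 5),      # neurocranium-pectoral girdle
    iom_mand_L       = c(18.9, -17.8, -3.5), # IOM ligament, mandible attachment
                                         # (retroarticular corner; placed so mandibular
                                         # depression swings rather than stretches the
                                         # ligament, while mandible spin about its
                                         # jaw-symphysis axis retains a length lever)
    iom_operc_L      = c(32.5, -12.2, 7.65), # IOM ligament, operculum attachment
                                         # (tangential to the ligament line for both
                                         # opercular rotations)
    sh_urohyal       = c(38, 0, -21),    # sternohyoideus, urohyal attachment
    sh_girdle        = c(63, 0, -9),     # sternohyoideus, girdle attachment
    head_length = head_length
  )
  lapply(g, function(v) if (length(v) == 3L) v * s else v)
}

mirror_y <- function(v) v * c(1, -1, 1)

# frame with given unit vector as third row plus two orthonormal complements
strut_axes <- function(from, to) {
  u <- to - from
  fr <- orthonormal_frame(u)
  rbind(fr[, 2], fr[, 3], fr[, 1])  # rows: two transverse axes, then long axis
}

#' Build the catfish-like five-loop skull mechanism fixture
#'
#' Constructs a bilaterally symmetric skull linkage with 11 bones
#' (neurocranium fixed; left/right suspensorium, mandible, operculum and
#' hyoid; urohyal; pectoral girdle) and three soft-tissue struts (left and
#' right interoperculomandibular ligaments, sternohyoideus), each strut
#' modelled as two half-links joined by a prismatic slide with a spherical
#' joint at each end. The census is 17 links, 21 joints, summed joint DoFs 49,
#' 5 independent loops, and Chebychev-Gruebler-Kutzbach mobility 19. The
#' fixture refuses to build if any of these counts is violated.
#'
#' The accompanying parameterization labels the 19 DoFs A-S:
#' three strut length changes (A, B, L), four midline-asymmetric motions
#' (C-F), four opercular rotations (G, H, M, N), mandibular depression (I),
#' suspensorial abduction (J), hyoid depression (K), and five long-axis
#' rotations of links with spherical joints at both ends (O-S: the three
#' struts and the two hyoid bars).
#'
#' @param geometry geometry list from \code{\link{catfish_geometry}}.
#' @param check verify the census and mobility invariants (default TRUE).
#' @return List with elements \code{mechanism}, \code{param} (a
#'   \code{\link{dof_parameterization}}), \code{fit_points} (named list of
#'   3 x 3 landmark matrices for the marked bodies), \code{marked_bodies},
#'   and \code{head_length} (mm).
#' @examples
#' fx <- build_catfish_fixture()
#' mechanism_census(fx$mechanism)
#' @export
build_catfish_fixture <- function(geometry = catfish_geometry(), check = TRUE) {
  g <- geometry
  xhat <- c(1, 0, 0); yhat <- c(0, 1, 0); zhat <- c(0, 0, 1)
  unit <- function(v) v / sqrt(sum(v^2))
  # joint axes are tilted off the anatomical axes, as in real skulls; pure
  # axis-aligned axes put the symmetric reference close to a kinematic
  # singularity of the input chart
  ax_susp1 <- unit(c(1, -0.2, 0.3))   # suspensorial abduction (rostrocaudal-ish)
  ax_susp2 <- unit(c(-0.2, 0.3, 1))
  ax_susp3 <- unit(c(0.2, 1, 0.15))
  ax_jaw1 <- unit(c(0.25, 1, 0.2))    # mandibular depression (mediolateral-ish)
  ax_jaw2 <- unit(c(0.15, -0.3, 1))
  ax_jaw3 <- unit(c(1, 0.2, 0.25))
  ax_operc1 <- unit(c(0.2, 0.25, 1))  # opercular abduction (dorsoventral-ish)
  ax_operc2 <- unit(c(1, 0.2, -0.25)) # opercular flaring out
  ax_hyo1 <- unit(c(0.2, 1, -0.15))   # hyoid depression
  ax_hyo2 <- unit(c(-0.15, 0.25, 1))
  ax_uro1 <- unit(c(0.15, 1, 0.2))    # urohyal pitch
  ax_uro2 <- unit(c(0.25, -0.15, 1))  # urohyal yaw
  ax_uro3 <- unit(c(1, 0.15, 0.2))
  ax_symph <- unit(c(1, 0, 0.3))      # symphyseal splay hinge (midline, xz-plane)

  links <- c("neurocranium",
             "suspensorium_L", "suspensorium_R", "mandible_L", "mandible_R",
             "operculum_L", "operculum_R", "hyoid_L", "hyoid_R",
             "urohyal", "girdle",
             "iom_L_a", "iom_L_b", "iom_R_a", "iom_R_b", "sh_a", "sh_b")
  struts <- c("iom_L_a", "iom_L_b", "iom_R_a", "iom_R_b", "sh_a", "sh_b")

  # spherical axes: rows applied in order; row 1 is the labelled input axis,
  # row 3 the long (twist) axis where one is needed
  hyoid_axis_L <- unit(g$hyoid_dist_L - g$hyoid_prox_L)
  sph_hyoid_L <- rbind(ax_hyo1, ax_hyo2, hyoid_axis_L)
  sph_hyoid_R <- rbind(mirror_y(ax_hyo1), mirror_y(ax_hyo2), mirror_y(hyoid_axis_L))

  J <- function(name, parent, child, type, center, axes)
    list(name = name, parent = parent, child = child, type = type,
         center = center, axes = axes)

  joints <- list(
    J("cranio_susp_L", "neurocranium", "suspensorium_L", "revolute",
      g$susp_cranial_L, rbind(ax_susp1)),
    J("cranio_susp_R", "neurocranium", "suspensorium_R", "revolute",
      mirror_y(g$susp_cranial_L), rbind(mirror_y(ax_susp1))),
    J("jaw_L", "suspensorium_L", "mandible_L", "spherical",
      g$quadrate_L, rbind(ax_jaw1, ax_jaw2, ax_jaw3)),
    J("jaw_R", "suspensorium_R", "mandible_R", "spherical",
      mirror_y(g$quadrate_L),
      rbind(mirror_y(ax_jaw1), mirror_y(ax_jaw2), mirror_y(ax_jaw3))),
    J("symphysis", "mandible_L", "mandible_R", "spherical",
      g$symphysis, rbind(ax_symph, unit(c(-0.3, 0, 1)), yhat)),
    J("operc_L", "suspensorium_L", "operculum_L", "universal",
      g$operc_joint_L, rbind(ax_operc1, ax_operc2)),
    J("operc_R", "suspensorium_R", "operculum_R", "universal",
      mirror_y(g$operc_joint_L), rbind(mirror_y(ax_operc1), mirror_y(ax_operc2))),
    J("susp_hyoid_L", "suspensorium_L", "hyoid_L", "spherical",
      g$hyoid_prox_L, sph_hyoid_L),
    J("susp_hyoid_R", "suspensorium_R", "hyoid_R", "spherical",
      mirror_y(g$hyoid_prox_L), sph_hyoid_R),
    J("hyoid_urohyal_L", "hyoid_L", "urohyal", "spherical",
      g$hyoid_dist_L, rbind(ax_uro1, ax_uro2, ax_uro3)),
    J("hyoid_urohyal_R", "hyoid_R", "urohyal", "spherical",
      mirror_y(g$hyoid_dist_L),
      rbind(mirror_y(ax_uro1), mirror_y(ax_uro2), mirror_y(ax_uro3))),
    J("cranio_girdle", "neurocranium", "girdle", "revolute",
      g$girdle_joint, rbind(yhat)),
    # interoperculomandibular ligament, left: S - P - S
    J("iom_L_mand", "mandible_L", "iom_L_a", "spherical",
      g$iom_mand_L, strut_axes(g$iom_mand_L, g$iom_operc_L)),
    J("iom_L_slide", "iom_L_a", "iom_L_b", "prismatic",
      g$iom_mand_L, rbind(strut_axes(g$iom_mand_L, g$iom_operc_L)[3, ])),
    J("iom_L_operc", "iom_L_b", "operculum_L", "spherical",
      g$iom_operc_L, strut_axes(g$iom_mand_L, g$iom_operc_L)),
    # interoperculomandibular ligament, right
    J("iom_R_mand", "mandible_R", "iom_R_a", "spherical",
      mirror_y(g$iom_mand_L), strut_axes(mirror_y(g$iom_mand_L), mirror_y(g$iom_operc_L))),
    J("iom_R_slide", "iom_R_a", "iom_R_b", "prismatic",
      mirror_y(g$iom_mand_L),
      rbind(strut_axes(mirror_y(g$iom_mand_L), mirror_y(g$iom_operc_L))[3, ])),
    J("iom_R_operc", "iom_R_b", "operculum_R", "spherical",
      mirror_y(g$iom_operc_L), strut_axes(mirror_y(g$iom_mand_L), mirror_y(g$iom_operc_L))),
    # sternohyoideus: urohyal to girdle
    J("sh_urohyal", "urohyal", "sh_a", "spherical",
      g$sh_urohyal, strut_axes(g$sh_urohyal, g$sh_girdle)),
    J("sh_slide", "sh_a", "sh_b", "prismatic",
      g$sh_urohyal, rbind(strut_axes(g$sh_urohyal, g$sh_girdle)[3, ])),
    J("sh_girdle", "sh_b", "girdle", "spherical",
      g$sh_girdle, strut_axes(g$sh_urohyal, g$sh_girdle))
  )

  mech <- mechanism(links, joints, fixed = "neurocranium", struts = struts)

  qof <- function(joint, k) {
    i <- which(vapply(mech$joints, `[[`, "", "name") == joint)
    mech$compiled$qidx[[i]][k]
  }
  inputs <- c(
    A = qof("iom_L_slide", 1),      # IOM ligament length change, left (mm)
    B = qof("sh_slide", 1),         # sternohyoideus length change (mm)
    C = qof("sh_urohyal", 1),       # urohyal pitch re sternohyoideus line (midline)
    D = qof("sh_urohyal", 2),       # urohyal yaw re sternohyoideus line (midline)
    E = qof("cranio_girdle", 1),    # girdle rotation (midline)
    F = qof("hyoid_urohyal_R", 1),  # urohyal pitch re right hyoid (midline asymmetry)
    G = qof("operc_L", 1),          # left opercular abduction
    H = qof("operc_L", 2),          # left opercular flaring out
    I = qof("jaw_L", 1),            # left mandibular depression (gape)
    J = qof("cranio_susp_L", 1),    # left suspensorial abduction
    K = qof("susp_hyoid_L", 1),     # left hyoid depression
    L = qof("iom_R_slide", 1),      # IOM ligament length change, right (mm)
    M = qof("operc_R", 1),          # right opercular abduction
    N = qof("operc_R", 2),          # right opercular flaring out
    O = qof("iom_L_mand", 3),       # IOM L long-axis twist
    P = qof("iom_R_mand", 3),       # IOM R long-axis twist
    Q = qof("sh_urohyal", 3),       # sternohyoideus long-axis twist
    R = qof("susp_hyoid_L", 3),     # left hyoid bar long-axis twist
    S = qof("susp_hyoid_R", 3)      # right hyoid bar long-axis twist
  )
  groups <- c(A = "strut_length", B = "strut_length", L = "strut_length",
              C = "midline_asymmetry", D = "midline_asymmetry",
              E = "midline_asymmetry", F = "midline_asymmetry",
              G = "opercular", H = "opercular", M = "opercular", N = "opercular",
              I = "mandibular_depression", J = "suspensorial_abduction",
              K = "hyoid_depression",
              O = "twist", P = "twist", Q = "twist", R = "twist", S = "twist")
  param <- dof_parameterization(mech, inputs, groups = groups)

  # three non-collinear landmarks per marked (left/midline) skeletal element
  fp <- function(a, b, c) rbind(a, b, c, deparse.level = 0)
  fit_points <- list(
    mandible_L = fp(g$quadrate_L, g$symphysis + c(0, -1, 0), g$iom_mand_L + c(-2, 0, 3)),
    suspensorium_L = fp(g$susp_cranial_L, g$quadrate_L + c(2, 0, 2), g$operc_joint_L + c(-3, 1, 3)),
    operculum_L = fp(g$operc_joint_L, g$operc_joint_L + c(12, -4, -8), g$operc_joint_L + c(8, -1, 5)),
    hyoid_L = fp(g$hyoid_prox_L, g$hyoid_dist_L + c(0, -1, 1), (g$hyoid_prox_L + g$hyoid_dist_L) / 2 + c(0, -3, -2)),
    urohyal = fp(g$hyoid_dist_L + c(1, 1, 0), g$sh_urohyal, g$sh_urohyal + c(5, 0, 2)),
    girdle = fp(g$girdle_joint + c(2, -3, -1), g$sh_girdle, g$sh_girdle + c(3, -4, 6))
  )
  marked <- names(fit_points)

  # model-vs-observed error distributions are reported over the five mobile
  # left/midline elements; the girdle is marked (and used in fitting) but
  # moves little
  fx <- list(mechanism = mech, param = param, fit_points = fit_points,
             marked_bodies = marked,
             error_bodies = setdiff(marked, "girdle"),
             head_length = g$head_length)
  class(fx) <- "catfish_fixture"

  if (check) {
    cz <- mechanism_census(mech)
    want <- list(links = 17L, joints = 21L, sum_joint_dof = 49L, loops = 5L,
                 mobility = 19L)
    for (nm in names(want))
      if (cz[[nm]] != want[[nm]])
        stop("fixture census violated: ", nm, " = ", cz[[nm]],
             " (expected ", want[[nm]], ")")
    grp <- table(groups)
    stopifnot(grp[["twist"]] == 5L, grp[["strut_length"]] == 3L,
              grp[["midline_asymmetry"]] == 4L, grp[["opercular"]] == 4L)
  }
  fx
}

#' @export
print.catfish_fixture <- function(x, ...) {
  cat("Catfish-like five-loop skull fixture\n")
  print(x$mechanism)
  cat(sprintf("  head length: %g mm; marked bodies: %s\n", x$head_length,
              paste(x$marked_bodies, collapse = ", ")))
  invisible(x)
}

#' The five primary degrees of freedom tracked during feeding
#'
#' Named mapping from the five motion-pattern trace names to the fixture's
#' parameter labels: mandibular depression (I), suspensorial abduction (J),
#' hyoid depression (K), opercular abduction (G) and opercular flaring out
#' (H), all on the left side.
#'
#' @return Named character vector.
#' @export
primary_dof_labels <- function() {
  c(mandibular_depression = "I", suspensorial_abduction = "J",
    hyoid_depression = "K", opercular_abduction = "G",
    opercular_flaring_out = "H")
}
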