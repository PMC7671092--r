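## Seeded synthetic-data generation: wave-patterned DoF trajectories for a
## catfish-like skull fixture, simulated marker observations, and prey tracks.
## These emulate the statistical structure of an XROMM suction-feeding
## recording (unilateral marking, ~0.080 mm marker noise, 300 Hz) so the full
## analysis pipeline can be exercised and validated without in vivo data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Wave specification for one cranial motion-pattern class
#'
#' Defines per-DoF peak amplitudes, peak-time offsets and bump widths for a
#' synthetic expansion-wave event, plus the class-matched prey velocity
#' template. Rostrocaudal waves peak in rostral-to-caudal order (mandible,
#' suspensorium, hyoid, operculum) with a sharp caudally-directed prey pulse
#' at peak gape; caudorostral waves reverse the order with flaring leading,
#' larger flaring amplitude, and a slower rostrally-directed prey pulse after
#' peak flaring; compressive waves start with hyoid elevation followed by
#' flaring, minimal gape, and an order-of-magnitude slower positive prey
#' pulse; slow-open waves are a slow, gape-dominated opening. Amplitudes are
#' order-of-magnitude choices within the fixture's feasible motion range (the
#' source traces are not available numerically).
#'
#' @param class one of \code{"rostrocaudal"}, \code{"caudorostral"},
#'   \code{"compressive"}, \code{"slow_open"}.
#' @param stage_lag_s lag between successive wave stages (default 0.02 s).
#' @param width_s Gaussian bump width (sd) for the primary DoFs (default
#'   0.08 s; 0.13 s for slow-open gape).
#' @param measurable_only zero the amplitudes of the eight DoFs that a
#'   unilateral marker set cannot measure (right-side L, M, N and the five
#'   long-axis twists O-S), so the motion lies exactly in the span of the
#'   11-DoF reduced model (default \code{FALSE}).
#' @param active optional character vector: restrict nonzero amplitudes to
#'   exactly these labels.
#' @return Object of class \code{"wave_spec"}: amplitude/offset/width per
#'   parameter label plus a \code{prey} template list.
#' @export
wave_spec <- function(class = c("rostrocaudal", "caudorostral", "compressive",
                                "slow_open"),
                      stage_lag_s = 0.02, width_s = 0.08,
                      measurable_only = FALSE, active = NULL) {
  class <- match.arg(class)
  labs <- c("A","B","C","D","E","F","G","H","I","J","K","L","M","N",
            "O","P","Q","R","S")
  amp <- stats::setNames(rep(0.005, 19), labs)  # small residual activity
  amp[c("A", "L")] <- 0.2; amp["B"] <- -0.5     # strut length changes (mm)
  off <- stats::setNames(rep(0, 19), labs)
  wid <- stats::setNames(rep(width_s, 19), labs)
  lag <- stage_lag_s
  if (class == "rostrocaudal") {
    amp[c("I", "J", "K", "G", "H")] <- c(0.30, 0.04, 0.12, 0.12, 0.15)
    off[c("I", "J", "K", "G", "H")] <- c(0, 1, 2, 3, 3) * lag
    prey <- list(peak_mm_s = 250, offset_s = 0, width_s = 0.03, ref = "I")
  } else if (class == "caudorostral") {
    amp[c("I", "J", "K", "G", "H")] <- c(0.10, 0.03, 0.08, 0.14, 0.20)
    off[c("H", "G", "K", "J", "I")] <- c(0, 0.5, 2, 3, 3.5) * lag
    prey <- list(peak_mm_s = -80, offset_s = 0.10, width_s = 0.06, ref = "H")
  } else if (class == "compressive") {
    # hyoid elevation (negative depression) precedes opercular flaring;
    # gape below 10% of the other amplitudes
    amp[c("I", "J", "K", "G", "H")] <- c(0.008, 0.01, -0.10, 0.10, 0.15)
    off[c("K", "G", "H")] <- c(0, 2, 2.5) * lag
    off[c("I", "J")] <- 2 * lag
    prey <- list(peak_mm_s = 20, offset_s = 0.08, width_s = 0.08, ref = "H")
  } else {  # slow_open
    amp[c("I", "J", "K", "G", "H")] <- c(0.20, 0.02, 0.06, 0.05, 0.05)
    off[c("I", "J", "K", "G", "H")] <- c(0, 1, 2, 3, 3) * lag
    wid["I"] <- max(0.13, width_s)
    prey <- list(peak_mm_s = 0, offset_s = 0, width_s = 0.05, ref = "I")
  }
  if (measurable_only)
    amp[c("L", "M", "N", "O", "P", "Q", "R", "S")] <- 0
  if (!is.null(active)) amp[setdiff(labs, active)] <- 0
  structure(list(class = class, amp = amp, offset = off, width = wid,
                 prey = prey),
            class = "wave_spec")
}

#' @export
print.wave_spec <- function(x, ...) {
  cat(sprintf("Wave spec '%s': gape %.3g rad, flare %.3g rad, prey peak %g mm/s\n",
              x$class, x$amp[["I"]], x$amp[["H"]], x$prey$peak_mm_s))
  invisible(x)
}

#' Generate wave-patterned DoF parameter trajectories
#'
#' Produces smooth bump-train trajectories for all 19 input parameters: a
#' train of \code{n_events} events of the given class, with per-event
#' amplitude and timing jitter, at the stated frame rate. Also returns the
#' per-event ground truth (event centers, class, per-DoF peak times) and the
#' class-matched prey rostrocaudal velocity series.
#'
#' @param spec a \code{\link{wave_spec}} (or list of specs, cycled over
#'   events).
#' @param n_events number of events.
#' @param fs frame rate, Hz (default 300).
#' @param seed integer seed; fully determines the output.
#' @param spacing_s time between event centers (default 1.2 s).
#' @param amp_jitter,time_jitter_s per-event relative amplitude jitter
#'   (default 5\%) and peak-time jitter sd (default 3 ms).
#' @return List: \code{values} (frames x 19 matrix, label columns),
#'   \code{time} (s), \code{fs}, \code{events} (data.frame: center time and
#'   class per event), \code{prey_velocity} (mm/s, positive = caudally
#'   directed), \code{prey_x} (rostrocaudal prey coordinate, mm).
#' @export
generate_wave_trajectories <- function(spec, n_events = 3, fs = 300, seed = 1,
                                       spacing_s = 1.2, amp_jitter = 0.05,
                                       time_jitter_s = 0.003) {
  if (fs <= 0) stop("frame rate must be positive")
  specs <- if (inherits(spec, "wave_spec")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, TRUE, "wave_spec")))
  dur <- n_events * spacing_s + spacing_s / 2
  tt <- seq(0, dur, by = 1 / fs)
  labs <- names(specs[[1]]$amp)
  vals <- matrix(0, length(tt), 19L, dimnames = list(NULL, labs))
  prey_v <- numeric(length(tt))
  centers <- (seq_len(n_events) - 0.5) * spacing_s + spacing_s / 4
  cls <- character(n_events)
  with_seed(seed, {
    for (e in seq_len(n_events)) {
      sp <- specs[[(e - 1L) %% length(specs) + 1L]]
      cls[e] <- sp$class
      aj <- 1 + stats::rnorm(19, sd = amp_jitter)
      tj <- stats::rnorm(19, sd = time_jitter_s)
      for (k in seq_len(19L)) {
        a <- sp$amp[k] * aj[k]
        if (a == 0) next
        pk <- centers[e] + sp$offset[k] + tj[k]
        vals[, k] <- vals[, k] + a * exp(-0.5 * ((tt - pk) / sp$width[k])^2)
      }
      if (sp$prey$peak_mm_s != 0) {
        ref_pk <- centers[e] + sp$offset[[sp$prey$ref]] + tj[match(sp$prey$ref, labs)]
        pk <- ref_pk + sp$prey$offset_s
        prey_v <- prey_v + sp$prey$peak_mm_s *
          exp(-0.5 * ((tt - pk) / sp$prey$width_s)^2)
      }
    }
  })
  list(values = vals, time = tt, fs = fs,
       events = data.frame(center_s = centers, class = cls),
       prey_velocity = prey_v,
       prey_x = cumsum(prey_v) / fs)
}

#' Simulate a marker-based recording of the skull fixture
#'
#' Runs constrained forward kinematics over a parameter trajectory, rigidly
#' attaches markers to the marked bodies, and observes them with isotropic
#' Gaussian noise and random missingness, emulating an XROMM-style recording
#' with unilateral (left-side and midline) marking. Noise-free marker
#' positions are exactly consistent with the link pose trajectories; the seed
#' fully determines the output.
#'
#' @param fixture a fixture from \code{\link{build_catfish_fixture}}.
#' @param trajectories output of \code{\link{generate_wave_trajectories}} (or
#'   any list with a \code{values} matrix and \code{fs}).
#' @param markers_per_body markers per marked body (>= 3, default 4).
#' @param sigma isotropic marker noise sd, mm (default 0; the study-like
#'   value is 0.08 mm).
#' @param missing_rate per-marker-frame missingness probability (default 0).
#' @param bodies marked bodies (default the fixture's left/midline set).
#' @param seed integer seed.
#' @return Object of class \code{"synthetic_recording"}: \code{markers}
#'   (a \code{\link{marker_trajectories}}), \code{poses} (per-body pose
#'   lists), \code{truth} (the input parameter matrix), \code{targets_by_frame}
#'   (noise-free fit-point positions per frame, for fitting), \code{prey}
#'   (positions in the neurocranium frame), and the generation settings.
#' @export
simulate_recording <- function(fixture, trajectories, markers_per_body = 4,
                               sigma = 0, missing_rate = 0, bodies = NULL,
                               seed = 1) {
  mech <- fixture$mechanism; param <- fixture$param
  if (is.null(bodies)) bodies <- fixture$marked_bodies
  if (markers_per_body < 3L) stop("need at least 3 markers per marked body")
  vals <- trajectories$values
  n <- nrow(vals)
  # marker reference positions: the fit points plus extra offset markers
  mref <- list()
  for (bd in bodies) {
    fp <- fixture$fit_points[[bd]]
    ctr <- colMeans(fp)
    nrm <- pracma_cross(fp[2, ] - fp[1, ], fp[3, ] - fp[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    extra <- max(0L, markers_per_body - 3L)
    pts <- fp
    if (extra > 0)
      for (k in seq_len(extra))
        pts <- rbind(pts, ctr + nrm * 3 * k + (fp[1 + (k %% 3), ] - ctr) * 0.3)
    mref[[bd]] <- pts
  }
  conf <- NULL
  poses <- lapply(bodies, function(b) vector("list", n))
  names(poses) <- bodies
  targets <- vector("list", n)
  xyz <- array(NA_real_, c(n, 3L, markers_per_body * length(bodies)))
  marker_ids <- unlist(lapply(bodies, function(b) paste0(b, ".m", seq_len(markers_per_body))))
  marker_body <- rep(bodies, each = markers_per_body)
  for (f in seq_len(n)) {
    conf <- tryCatch(
      forward_kinematics(mech, param, vals[f, ], init = conf),
      error = function(e) stop("kinematic failure at frame ", f, ": ",
                               conditionMessage(e)))
    tg <- list()
    col <- 0L
    for (bd in bodies) {
      p <- link_pose(conf, bd)
      poses[[bd]][[f]] <- p
      tg[[bd]] <- pose_apply(p, fixture$fit_points[[bd]])
      xyz[f, , col + seq_len(markers_per_body)] <- t(pose_apply(p, mref[[bd]]))
      col <- col + markers_per_body
    }
    targets[[f]] <- tg
  }
  with_seed(seed, {
    if (sigma > 0) xyz <- xyz + array(stats::rnorm(length(xyz), sd = sigma), dim(xyz))
    miss <- matrix(stats::runif(n * dim(xyz)[3]) < missing_rate, n, dim(xyz)[3])
  })
  for (m in which(colSums(miss) > 0)) xyz[miss[, m], , m] <- NA_real_
  markers <- marker_trajectories(xyz, marker_ids, marker_body,
                                 fps = trajectories$fs, missing = miss)
  prey <- if (!is.null(trajectories$prey_x)) {
    cbind(x_mm = 40 + trajectories$prey_x, y_mm = 0, z_mm = -10)
  } else NULL
  structure(list(markers = markers, poses = poses, truth = vals,
                 targets_by_frame = targets, marker_reference = mref,
                 prey = prey, fs = trajectories$fs,
                 events = trajectories$events,
                 sigma = sigma, missing_rate = missing_rate, seed = seed,
                 bodies = bodies, head_length = fixture$head_length),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "Synthetic recording: %d frames @ %g Hz, %d bodies, sigma %g mm, seed %d\n",
    nrow(x$truth), x$fs, length(x$bodies), x$sigma, x$seed))
  invisible(x)
}

#' Generate an individual-specific fixture geometry
#'
#' Isotropically scales the default fixture geometry and adds small,
#' bilaterally symmetric jitter to the joint centers and attachment sites,
#' emulating inter-individual shape variation. Head length scales linearly;
#' the census invariants are unaffected.
#'
#' @param scale_factor isotropic scale (> 0); 1 gives the default geometry.
#' @param seed integer seed for the jitter.
#' @param jitter_sd landmark jitter sd, mm (default 0; the inter-individual
#'   tests use ~0.5 mm).
#' @return A fixture list as from \code{\link{build_catfish_fixture}}.
#' @export
make_individual <- function(scale_factor = 1, seed = 1, jitter_sd = 0) {
  if (scale_factor <= 0) stop("scale factor must be positive")
  g <- catfish_geometry(head_length = 76 * scale_factor)
  if (jitter_sd > 0) {
    with_seed(seed, {
      for (nm in setdiff(names(g), "head_length")) {
        j <- stats::rnorm(3, sd = jitter_sd)
        if (nm %in% c("symphysis", "girdle_joint", "sh_urohyal", "sh_girdle"))
          j[2] <- 0  # midline structures stay on the midline
        g[[nm]] <- g[[nm]] + j
      }
    })
  }
  build_catfish_fixture(geometry = g)
}
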