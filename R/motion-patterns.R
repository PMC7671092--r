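#' Container for the five primary DoF traces
#'
#' Holds the named time series of the five cranial DoFs tracked during
#' feeding: mandibular depression (gape), suspensorial abduction, hyoid
#' depression, opercular abduction, and opercular flaring out (radians), at a
#' fixed frame rate.
#'
#' @param values matrix or data.frame with exactly the five named columns (or
#'   a full 19-parameter matrix with label columns, from which the five are
#'   extracted via \code{\link{primary_dof_labels}}).
#' @param fs frame rate, Hz.
#' @param prey_velocity optional rostrocaudal prey velocity series (mm/s,
#'   positive = caudally directed), same length.
#' @return Object of class \code{"dof_traces"}.
#' @export
dof_traces <- function(values, fs, prey_velocity = NULL) {
  nm <- names(primary_dof_labels())
  values <- as.matrix(values)
  if (!all(nm %in% colnames(values))) {
    lab <- primary_dof_labels()
    if (all(lab %in% colnames(values))) {
      values <- values[, lab, drop = FALSE]
      colnames(values) <- nm
    } else stop("values must contain the five primary DoF columns")
  }
  values <- values[, nm, drop = FALSE]
  if (!is.null(prey_velocity) && length(prey_velocity) != nrow(values))
    stop("prey velocity length must match the traces")
  structure(list(values = values, fs = fs,
                 time = (seq_len(nrow(values)) - 1L) / fs,
                 prey_velocity = prey_velocity),
            class = "dof_traces")
}

#' @export
print.dof_traces <- function(x, ...) {
  cat(sprintf("DoF traces: %d frames @ %g Hz (%.2f s)%s\n", nrow(x$values),
              x$fs, nrow(x$values) / x$fs,
              if (!is.null(x$prey_velocity)) ", with prey velocity" else ""))
  invisible(x)
}

#' @export
plot.dof_traces <- function(x, ...) {
  graphics::matplot(x$time, x$values, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "angle (rad)", ...)
  graphics::legend("topright", colnames(x$values), col = 1:5, lty = 1, cex = 0.7)
  invisible(x)
}

# local maxima with prominence (height above the higher of the two
# enclosing valleys toward equal-or-higher peaks)
find_peaks <- function(y, prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer())
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    left <- y[seq_len(p - 1L)]
    higher_l <- which(left >= y[p])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(p - 1L)]) else min(left)
    right <- y[(p + 1L):n]
    higher_r <- which(right >= y[p])
    base_r <- if (length(higher_r)) min(y[p + seq_len(min(higher_r) - 1L)]) else min(right)
    keep[i] <- (y[p] - max(base_l, base_r)) >= prominence
  }
  cand[keep]
}

#' Detect feeding-event windows in the DoF traces
#'
#' Finds windows of fixed duration surrounding peaks of mandibular depression
#' (gape), opercular flaring out, or both. Gape and flaring peaks closer than
#' half a window are merged into a single event.
#'
#' @param traces a \code{\link{dof_traces}} object.
#' @param window_s event window duration, s (default 0.5).
#' @param prominence minimum peak prominence, rad (default 0.05).
#' @return data.frame with one row per event: \code{t_center_s},
#'   \code{t_start_s}, \code{t_end_s}, \code{source} (gape/flaring/both).
#' @export
detect_events <- function(traces, window_s = 0.5, prominence = 0.05) {
  stopifnot(inherits(traces, "dof_traces"))
  if (nrow(traces$values) < 3L) stop("traces too short")
  tt <- traces$time
  pg <- find_peaks(traces$values[, "mandibular_depression"], prominence)
  pf <- find_peaks(traces$values[, "opercular_flaring_out"], prominence)
  cand <- data.frame(t = c(tt[pg], tt[pf]),
                     src = c(rep("gape", length(pg)), rep("flaring", length(pf))))
  if (!nrow(cand)) return(data.frame(t_center_s = numeric(), t_start_s = numeric(),
                                     t_end_s = numeric(), source = character()))
  cand <- cand[order(cand$t), ]
  # merge peaks closer than window/2
  grp <- cumsum(c(TRUE, diff(cand$t) > window_s / 2))
  out <- do.call(rbind, lapply(split(cand, grp), function(d) {
    data.frame(t_center_s = mean(d$t),
               source = if (length(unique(d$src)) > 1L) "both" else d$src[1])
  }))
  out$t_start_s <- out$t_center_s - window_s / 2
  out$t_end_s <- out$t_center_s + window_s / 2
  rownames(out) <- NULL
  out[, c("t_center_s", "t_start_s", "t_end_s", "source")]
}

#' Classification thresholds for expansion-wave patterns
#'
#' The quantitative surrogate for the expert labelling of cranial motion
#' patterns. \code{dominance_ratio}: gape counts as minimal when its
#' amplitude is below this fraction of the largest other amplitude.
#' \code{order_margin_s}: two peaks are considered ordered only if separated
#' by at least this margin. \code{slow_rise_s}: gape rise times above this
#' are classified slow-open.
#'
#' @param dominance_ratio default 0.1.
#' @param order_margin_s default 0.005 s.
#' @param order_slack_s tolerance for the intermediate (suspensorium, hyoid)
#'   peaks when judging rostral-to-caudal ordering, default 0.02 s.
#' @param slow_rise_s default 0.25 s.
#' @param smooth_cutoff_hz zero-phase low-pass applied to the traces before
#'   peak extraction (default 10 Hz), making peak order and amplitude robust
#'   to in-band noise.
#' @return Named list of thresholds.
#' @export
classify_thresholds <- function(dominance_ratio = 0.1, order_margin_s = 0.005,
                                order_slack_s = 0.02, slow_rise_s = 0.25,
                                smooth_cutoff_hz = 10) {
  list(dominance_ratio = dominance_ratio, order_margin_s = order_margin_s,
       order_slack_s = order_slack_s, slow_rise_s = slow_rise_s,
       smooth_cutoff_hz = smooth_cutoff_hz)
}

# zero-phase low-pass with odd-reflection padding (internal)
lp_filter <- function(y, fs, cutoff) {
  n <- length(y)
  if (cutoff >= fs / 2 || n < 13) return(y)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  npad <- min(n - 1L, ceiling(3 * fs / cutoff))
  y0 <- y[1]
  yc <- y - y0
  ypad <- c(2 * yc[1] - yc[(npad + 1):2], yc, 2 * yc[n] - yc[(n - 1):(n - npad)])
  signal::filtfilt(bf, ypad)[npad + seq_len(n)] + y0
}

# centroid of the lobe above half-maximum around the global peak: a noise-
# robust peak-time estimate for bump-shaped traces
centroid_peak_time <- function(tt, y) {
  i <- which.max(y)
  half <- y[i] - 0.5 * (y[i] - min(y))
  lo <- i; while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
  hi <- i; while (hi < length(y) && y[hi + 1] >= half) hi <- hi + 1
  w <- y[lo:hi] - half
  sum(tt[lo:hi] * w) / sum(w)
}

#' Classify the motion pattern within one event window
#'
#' Rule-based classification of an event into one of five classes from the
#' relative amplitudes and peak timing of the five DoF traces:
#' \itemize{
#'   \item \code{compressive}: minimal gape, hyoid elevation preceding
#'     opercular flaring.
#'   \item \code{slow_open}: substantial gape with rise time above the
#'     slow-open threshold.
#'   \item \code{rostrocaudal}: peaks ordered rostral to caudal (mandible,
#'     then suspensorium/hyoid, then operculum) with substantial gape.
#'   \item \code{caudorostral}: reversed order with flaring leading.
#'   \item \code{unknown}: fallback.
#' }
#' The alignment reference is peak gape for rostrocaudal and slow-open
#' events, and peak flaring out for caudorostral and compressive events.
#'
#' @param traces a \code{\link{dof_traces}} object.
#' @param window numeric length-2: window start and end, s (e.g. one row of
#'   \code{\link{detect_events}}).
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @return Object of class \code{"motion_event"}: window, class, alignment
#'   reference time, and the per-DoF peak table.
#' @export
classify_event <- function(traces, window, thresholds = classify_thresholds()) {
  stopifnot(inherits(traces, "dof_traces"))
  th <- thresholds
  sel <- traces$time >= window[1] & traces$time <= window[2]
  if (sum(sel) < 5L) stop("window contains too few frames")
  Vs <- apply(traces$values, 2, lp_filter, fs = traces$fs,
              cutoff = th$smooth_cutoff_hz)
  tt <- traces$time[sel]
  Y <- Vs[sel, , drop = FALSE]
  base <- apply(Y, 2, stats::quantile, 0.1)
  amp <- apply(Y, 2, max) - base
  pk_t <- vapply(colnames(Y), function(nm) centroid_peak_time(tt, Y[, nm]), 0)
  # hyoid elevation: negative excursion of hyoid depression
  hy <- Y[, "hyoid_depression"]
  elev_amp <- stats::quantile(hy, 0.9) - min(hy)
  elev_t <- centroid_peak_time(tt, -hy)
  a_mand <- amp[["mandibular_depression"]]
  a_others <- max(amp[["opercular_flaring_out"]], amp[["opercular_abduction"]],
                  abs(amp[["hyoid_depression"]]), elev_amp)
  gape_minimal <- a_mand < th$dominance_ratio * a_others
  # gape rise time: walk back from the window peak through the full
  # (smoothed) trace to the 10% crossing above the whole-trace baseline;
  # slow openings start before the event window
  gall <- Vs[, "mandibular_depression"]
  gfull <- gall - stats::quantile(gall, 0.1)
  ipk_full <- which(sel)[which.max(Y[, "mandibular_depression"])]
  pkval <- gfull[ipk_full]
  below <- which(gfull[seq_len(ipk_full)] < 0.1 * pkval)
  rise <- if (length(below)) traces$time[ipk_full] - traces$time[max(below)]
          else traces$time[ipk_full] - traces$time[1]

  m <- th$order_margin_s
  sl <- th$order_slack_s
  t_mand <- pk_t[["mandibular_depression"]]
  t_susp <- pk_t[["suspensorial_abduction"]]
  t_hyo <- pk_t[["hyoid_depression"]]
  t_operc <- min(pk_t[["opercular_abduction"]], pk_t[["opercular_flaring_out"]])
  t_flare <- pk_t[["opercular_flaring_out"]]

  cls <- "unknown"
  if (gape_minimal && elev_amp > th$dominance_ratio * a_others &&
      elev_t + m < t_flare) {
    cls <- "compressive"
  } else if (!gape_minimal && !is.na(rise) && rise > th$slow_rise_s) {
    cls <- "slow_open"
  } else if (!gape_minimal &&
             t_mand + m < t_operc &&
             t_mand <= min(t_susp, t_hyo) + sl &&
             max(t_susp, t_hyo) <= t_operc + sl) {
    cls <- "rostrocaudal"
  } else if (t_flare + m < t_mand &&
             t_flare <= min(t_susp, t_hyo) + sl &&
             max(t_susp, t_hyo) <= t_mand + sl) {
    cls <- "caudorostral"
  }
  t_ref <- if (cls %in% c("caudorostral", "compressive")) t_flare else t_mand
  structure(list(window = c(start = window[1], end = window[2]),
                 class = cls, t_ref = t_ref,
                 peaks = data.frame(dof = colnames(Y), peak_time_s = pk_t,
                                    amplitude = amp, row.names = NULL),
                 rise_s = rise, elev_amp = elev_amp, elev_t = elev_t),
            class = "motion_event")
}

#' @export
print.motion_event <- function(x, ...) {
  cat(sprintf("Motion event [%.3f, %.3f] s: %s (aligned at %.3f s)\n",
              x$window[1], x$window[2], x$class, x$t_ref))
  invisible(x)
}

#' Detect and classify all events in a recording
#'
#' @inheritParams detect_events
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @return data.frame: one row per event with window, class, alignment
#'   reference and per-DoF peak times/amplitudes (columns
#'   \code{peak_time_<dof>}, \code{peak_amp_<dof>}).
#' @export
classify_events <- function(traces, window_s = 0.5, prominence = 0.05,
                            thresholds = classify_thresholds()) {
  ev <- detect_events(traces, window_s, prominence)
  if (!nrow(ev)) return(cbind(ev, class = character(), t_ref_s = numeric()))
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    me <- classify_event(traces, c(ev$t_start_s[i], ev$t_end_s[i]), thresholds)
    pk <- stats::setNames(me$peaks$peak_time_s, paste0("peak_time_", me$peaks$dof))
    am <- stats::setNames(me$peaks$amplitude, paste0("peak_amp_", me$peaks$dof))
    cbind(data.frame(event_id = i, class = me$class, t_ref_s = me$t_ref,
                     t_start_s = ev$t_start_s[i], t_end_s = ev$t_end_s[i]),
          as.data.frame(as.list(c(pk, am))))
  })
  do.call(rbind, rows)
}

#' Align events of one class and aggregate their traces
#'
#' Resamples each event's five DoF traces (and prey velocity, if present)
#' onto a common time grid relative to its alignment reference, then returns
#' the pointwise mean and standard error across events.
#'
#' @param traces a \code{\link{dof_traces}} object.
#' @param events data.frame from \code{\link{classify_events}}.
#' @param class the class to aggregate (events of other classes are an
#'   error if passed explicitly via \code{events} filtering; the function
#'   subsets by this class).
#' @param window_s aggregate window duration, s (default 0.5).
#' @param n_grid grid points (default 151).
#' @return List of class \code{"wave_aggregate"}: \code{t_rel_s}, per-DoF
#'   \code{mean} and \code{se} matrices, \code{n} events, and (if available)
#'   \code{mean_preyvel}/\code{se_preyvel}.
#' @export
align_and_aggregate <- function(traces, events, class, window_s = 0.5,
                                n_grid = 151) {
  stopifnot(inherits(traces, "dof_traces"))
  ev <- events[events$class == class, , drop = FALSE]
  if (!nrow(ev)) stop("no events of class '", class, "'")
  grid <- seq(-window_s / 2, window_s / 2, length.out = n_grid)
  nm <- colnames(traces$values)
  acc <- array(NA_real_, c(n_grid, length(nm), nrow(ev)),
               dimnames = list(NULL, nm, NULL))
  pv <- if (!is.null(traces$prey_velocity))
    matrix(NA_real_, n_grid, nrow(ev)) else NULL
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$t_ref_s[i]
    for (k in seq_along(nm))
      acc[, k, i] <- stats::approx(traces$time - t0, traces$values[, k],
                                   xout = grid, rule = 2)$y
    if (!is.null(pv))
      pv[, i] <- stats::approx(traces$time - t0, traces$prey_velocity,
                               xout = grid, rule = 2)$y
  }
  mu <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), function(v)
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v)))
  out <- list(t_rel_s = grid, mean = mu, se = se, n = nrow(ev), class = class)
  if (!is.null(pv)) {
    out$mean_preyvel <- rowMeans(pv)
    out$se_preyvel <- apply(pv, 1, function(v)
      if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v)))
  }
  structure(out, class = "wave_aggregate")
}

#' @export
print.wave_aggregate <- function(x, ...) {
  cat(sprintf("Aggregate of %d '%s' events over [%.2f, %.2f] s\n", x$n,
              x$class, min(x$t_rel_s), max(x$t_rel_s)))
  invisible(x)
}

#' @export
plot.wave_aggregate <- function(x, ...) {
  graphics::matplot(x$t_rel_s, x$mean, type = "l", lty = 1,
                    xlab = "time relative to alignment (s)",
                    ylab = "angle (rad)", main = paste0(x$class, " wave"), ...)
  graphics::legend("topright", colnames(x$mean), col = 1:5, lty = 1, cex = 0.6)
  invisible(x)
}

#' Rostrocaudal prey velocity from a prey track
#'
#' Differentiates the rostrocaudal (x) coordinate of prey positions in the
#' neurocranium anatomical frame: zero-phase low-pass smoothing followed by
#' central differences. Positive velocity is caudally directed. Frames
#' flagged excluded (prey on the tank bottom or past the esophagus) are set
#' to NA.
#'
#' @param prey_positions n x 3 matrix of prey positions (mm, neurocranium
#'   frame; column 1 = rostrocaudal).
#' @param fs frame rate, Hz.
#' @param cutoff smoothing cutoff, Hz (default 25).
#' @param exclude optional logical vector of frames to exclude.
#' @return Numeric velocity series (mm/s).
#' @export
prey_velocity_rc <- function(prey_positions, fs, cutoff = 25, exclude = NULL) {
  x <- as.matrix(prey_positions)[, 1]
  n <- length(x)
  if (cutoff < fs / 2 && n > 12) {
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    npad <- min(n - 1L, ceiling(3 * fs / cutoff))
    x0 <- x[1]
    xc <- x - x0
    xpad <- c(2 * xc[1] - xc[(npad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - npad)])
    x <- signal::filtfilt(bf, xpad)[npad + seq_len(n)] + x0
  }
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  if (!is.null(exclude)) v[exclude] <- NA_real_
  v
}
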