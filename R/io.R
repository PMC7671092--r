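## File formats: marker and transform CSV dialects, mechanism YAML, and run
## configuration. All units are mm, seconds, Hz; angles are degrees at the
## YAML boundary and radians internally.

#' Write / read marker trajectories as CSV
#'
#' Dialect: columns \code{frame,time_s,marker,body,x_mm,y_mm,z_mm}, one row
#' per marker-frame; blank coordinate cells mark missing observations.
#'
#' @param markers a \code{\link{marker_trajectories}} object.
#' @param path file path.
#' @return \code{read_marker_csv} returns a \code{marker_trajectories};
#'   \code{write_marker_csv} returns \code{path} invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  n <- dim(markers$xyz)[1]
  rows <- vector("list", length(markers$marker))
  for (m in seq_along(markers$marker)) {
    rows[[m]] <- data.frame(frame = seq_len(n),
                            time_s = (seq_len(n) - 1) / markers$fps,
                            marker = markers$marker[m],
                            body = markers$body[m],
                            x_mm = markers$xyz[, 1, m],
                            y_mm = markers$xyz[, 2, m],
                            z_mm = markers$xyz[, 3, m])
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$frame, match(df$marker, markers$marker)), ]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_marker_csv
#' @param fps frame rate override; by default inferred from the
#'   \code{time_s} column.
#' @export
read_marker_csv <- function(path, fps = NULL) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed marker CSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("frame", "time_s", "marker", "body", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("marker CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(is.na(df$frame) | df$marker == "")
  if (length(bad))
    stop("malformed marker CSV row(s): line ", paste(bad[1] + 1, collapse = ","))
  markers <- unique(df$marker)
  frames <- sort(unique(df$frame))
  n <- length(frames)
  if (is.null(fps)) {
    dt <- diff(sort(unique(df$time_s)))
    fps <- if (length(dt)) 1 / stats::median(dt) else 1
  }
  xyz <- array(NA_real_, c(n, 3L, length(markers)))
  body <- character(length(markers))
  for (m in seq_along(markers)) {
    d <- df[df$marker == markers[m], ]
    body[m] <- d$body[1]
    i <- match(d$frame, frames)
    xyz[i, 1, m] <- d$x_mm; xyz[i, 2, m] <- d$y_mm; xyz[i, 3, m] <- d$z_mm
  }
  marker_trajectories(xyz, markers, body, fps = fps)
}

#' Write / read per-body rigid transform trajectories as CSV
#'
#' Dialect: columns \code{frame,body,r11..r33,t1,t2,t3} (row-major rotation,
#' translation in mm), one row per body-frame.
#'
#' @param poses named list (per body) of lists of \code{\link{pose}} objects
#'   (NULL entries allowed for masked frames).
#' @param path file path.
#' @return \code{read_transform_csv} returns the poses list;
#'   \code{write_transform_csv} returns \code{path} invisibly.
#' @export
write_transform_csv <- function(poses, path) {
  rows <- list()
  for (bd in names(poses)) {
    pl <- poses[[bd]]
    for (f in seq_along(pl)) {
      p <- pl[[f]]
      if (is.null(p) || (length(p) == 1 && is.na(p))) next
      R <- t(p$R)  # row-major
      rows[[length(rows) + 1L]] <- c(frame = f, body = bd,
                                     stats::setNames(as.numeric(R),
                                                     paste0("r", rep(1:3, each = 3), rep(1:3, 3))),
                                     t1 = p$t[1], t2 = p$t[2], t3 = p$t[3])
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  num <- setdiff(names(df), "body")
  df[num] <- lapply(df[num], as.numeric)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transform_csv
#' @export
read_transform_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "body", paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
            "t1", "t2", "t3")
  if (!all(need %in% names(df)))
    stop("transform CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (bd in unique(df$body)) {
    d <- df[df$body == bd, ]
    n <- max(d$frame)
    pl <- vector("list", n)
    for (i in seq_len(nrow(d))) {
      R <- matrix(as.numeric(d[i, paste0("r", rep(1:3, each = 3), rep(1:3, 3))]),
                  3, 3, byrow = TRUE)
      pl[[d$frame[i]]] <- pose(R, as.numeric(d[i, c("t1", "t2", "t3")]))
    }
    out[[bd]] <- pl
  }
  out
}

#' Write / read a mechanism (and optional parameterization) as YAML
#'
#' Links carry a \code{fixed} flag on the fixed link and a \code{strut} flag
#' on strut half-links; joints carry parent, child, type, center (mm) and
#' axes. A parameterization block maps labels to coordinate indices with
#' groups, freeze mask and freeze values.
#'
#' @param mech a \code{\link{mechanism}}.
#' @param path file path.
#' @param param optional \code{\link{dof_parameterization}}.
#' @return \code{read_mechanism_yaml} returns a list with \code{mechanism}
#'   and (if stored) \code{param}; the writer returns \code{path} invisibly.
#' @export
write_mechanism_yaml <- function(mech, path, param = NULL) {
  obj <- list(
    links = lapply(mech$links, function(l) {
      x <- list(name = l)
      if (l == mech$fixed) x$fixed <- TRUE
      if (l %in% mech$struts) x$strut <- TRUE
      x
    }),
    joints = lapply(mech$joints, function(j)
      list(name = j$name, parent = j$parent, child = j$child, type = j$type,
           center_mm = as.numeric(j$center),
           axes = lapply(seq_len(nrow(matrix(j$axes, ncol = 3))), function(i)
             as.numeric(matrix(j$axes, ncol = 3)[i, ]))))
  )
  if (!is.null(param))
    obj$parameterization <- list(
      labels = param$labels, qidx = as.integer(param$qidx),
      groups = as.list(param$groups),
      frozen = as.logical(param$frozen),
      freeze_values = as.numeric(param$freeze_values))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_mechanism_yaml
#' @export
read_mechanism_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  links <- vapply(obj$links, `[[`, "", "name")
  fixed <- links[vapply(obj$links, function(l) isTRUE(l$fixed), TRUE)]
  struts <- links[vapply(obj$links, function(l) isTRUE(l$strut), TRUE)]
  joints <- lapply(obj$joints, function(j)
    list(name = j$name, parent = j$parent, child = j$child, type = j$type,
         center = as.numeric(j$center_mm),
         axes = do.call(rbind, lapply(j$axes, as.numeric))))
  mech <- mechanism(links, joints, fixed = fixed, struts = struts)
  out <- list(mechanism = mech)
  if (!is.null(obj$parameterization)) {
    p <- obj$parameterization
    param <- dof_parameterization(
      mech, stats::setNames(as.integer(p$qidx), unlist(p$labels)),
      groups = unlist(p$groups))
    param$frozen[] <- as.logical(p$frozen)
    param$freeze_values[] <- as.numeric(p$freeze_values)
    out$param <- param
  }
  out
}

#' Run configuration for the analysis pipeline
#'
#' All tunable settings of \code{\link{run_pipeline}} with their defaults.
#' Thresholds that stand in for choices the source methodology left
#' unspecified live under \code{artifact_decisions}.
#'
#' @param seed master seed (all randomness derives from it).
#' @param out_dir output directory.
#' @param fs frame rate (Hz).
#' @param n_events simulated feeding events.
#' @param classes wave classes cycled over events.
#' @param sigma_mm marker noise sd (mm).
#' @param missing_rate marker missingness probability.
#' @param smoothing_cutoff_hz low-pass cutoff (Hz).
#' @param n_sample_frames disparate frames per freeze-scan step.
#' @param freeze_scan run the (slow) freeze scan stage.
#' @param artifact_decisions list of surrogate thresholds (joint-model
#'   selection factors, classifier thresholds).
#' @return Object of class \code{"run_config"} (a validated list).
#' @export
run_config <- function(seed = 1, out_dir = "skullkin-out", fs = 300,
                       n_events = 3,
                       classes = c("rostrocaudal", "caudorostral", "compressive"),
                       sigma_mm = 0.08, missing_rate = 0,
                       smoothing_cutoff_hz = 25, n_sample_frames = 15,
                       freeze_scan = FALSE,
                       artifact_decisions = list(
                         k_precision = 1.5, rel_tol = 0.10,
                         dominance_ratio = 0.1, order_margin_s = 0.005,
                         slow_rise_s = 0.25)) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, fs = fs,
              n_events = n_events, classes = classes, sigma_mm = sigma_mm,
              missing_rate = missing_rate,
              smoothing_cutoff_hz = smoothing_cutoff_hz,
              n_sample_frames = n_sample_frames, freeze_scan = freeze_scan,
              artifact_decisions = artifact_decisions)
  stopifnot(cfg$fs > 0, cfg$smoothing_cutoff_hz < cfg$fs / 2,
            cfg$sigma_mm >= 0, cfg$missing_rate >= 0, cfg$missing_rate < 1)
  class(cfg) <- "run_config"
  cfg
}

#' Stable hash of a run configuration
#'
#' Hashes the scientific settings of a config (the output directory does not
#' affect the hash, so runs into different directories compare equal).
#'
#' @param config a \code{\link{run_config}}.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}
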