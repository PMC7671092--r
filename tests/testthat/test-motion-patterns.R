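# Event detection, wave classification, alignment/aggregation, prey velocity.

traces_from_class <- function(classes, seed = 1, n_per = 1, noise_frac = 0) {
  specs <- lapply(classes, wave_spec)
  traj <- generate_wave_trajectories(specs, n_events = length(classes) * n_per,
                                     fs = 300, seed = seed)
  vals <- traj$values
  if (noise_frac > 0) {
    set.seed(seed + 1000)
    lab <- primary_dof_labels()
    for (k in lab) {
      amp <- max(abs(vals[, k]))
      if (amp == 0) next
      raw <- stats::rnorm(nrow(vals), sd = noise_frac * amp)
      bf <- signal::butter(2, 15 / 150, type = "low")
      vals[, k] <- vals[, k] + signal::filtfilt(bf, raw)
    }
  }
  list(traces = dof_traces(vals, fs = 300, prey_velocity = traj$prey_velocity),
       truth = traj$events)
}

test_that("flat traces contain no events; single bumps are localized", {
  flat <- dof_traces(matrix(0, 300, 5,
                            dimnames = list(NULL, names(primary_dof_labels()))),
                     fs = 300)
  expect_equal(nrow(detect_events(flat)), 0L)
  tw <- traces_from_class("rostrocaudal", seed = 2)
  ev <- detect_events(tw$traces)
  expect_equal(nrow(ev), 1L)
  # window centered on the gape/flare peak pair, within a frame or two of
  # the constructed event center plus its stage lags
  expect_lt(abs(ev$t_center_s - tw$truth$center_s[1]), 0.08)
})

test_that("close gape and flaring peaks merge; distant bumps stay separate", {
  tw2 <- traces_from_class(c("rostrocaudal", "rostrocaudal"), seed = 3)
  ev <- detect_events(tw2$traces)
  expect_equal(nrow(ev), 2L)   # spacing 1.2 s >> window
  expect_true(all(ev$source == "both"))  # gape+flare merged within events
})

test_that("generator-labeled events are classified correctly without noise", {
  classes <- c("rostrocaudal", "caudorostral", "compressive", "slow_open")
  for (cl in classes) {
    tw <- traces_from_class(cl, seed = 4)
    ev <- classify_events(tw$traces)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$class, cl)
  }
})

test_that("classification is invariant to amplitude scaling and time shifts", {
  tw <- traces_from_class("caudorostral", seed = 5)
  ev0 <- classify_events(tw$traces)
  scaled <- dof_traces(tw$traces$values * 3.7, fs = 300)
  ev1 <- classify_events(scaled)
  expect_equal(ev1$class, ev0$class)
  shifted <- dof_traces(rbind(matrix(0, 90, 5,
                                     dimnames = list(NULL, colnames(tw$traces$values))),
                              tw$traces$values), fs = 300)
  ev2 <- classify_events(shifted)
  expect_equal(ev2$class, ev0$class)
  expect_equal(ev2$t_ref_s, ev0$t_ref_s + 0.3, tolerance = 1e-6)
})

test_that("aggregation reproduces single events and removes absolute time", {
  tw <- traces_from_class("rostrocaudal", seed = 6)
  ev <- classify_events(tw$traces)
  ag <- align_and_aggregate(tw$traces, ev, "rostrocaudal")
  expect_equal(ag$n, 1L)
  expect_true(all(ag$se == 0))
  # mean equals the event's own trace at the grid (interpolation tolerance)
  gi <- which.min(abs(ag$t_rel_s))
  ti <- which.min(abs(tw$traces$time - ev$t_ref_s))
  expect_equal(ag$mean[gi, "mandibular_depression"],
               tw$traces$values[ti, "mandibular_depression"], tolerance = 1e-4)
  # two identical events shifted in time aggregate with zero SE
  two <- traces_from_class(c("rostrocaudal", "rostrocaudal"), seed = 6,
                           n_per = 1)
  # same seed jitter differs per event, so rebuild with no jitter instead
  spec <- wave_spec("rostrocaudal")
  tj <- generate_wave_trajectories(list(spec, spec), n_events = 2, fs = 300,
                                   seed = 7, amp_jitter = 0, time_jitter_s = 0)
  tr <- dof_traces(tj$values, fs = 300)
  ev2 <- classify_events(tr)
  ag2 <- align_and_aggregate(tr, ev2, "rostrocaudal")
  expect_equal(ag2$n, 2L)
  expect_lt(max(ag2$se), 1e-6)
})

test_that("aggregate standard errors scale as sigma over sqrt(n)", {
  spec <- wave_spec("rostrocaudal")
  n_ev <- 8; sigma <- 0.01
  tj <- generate_wave_trajectories(rep(list(spec), n_ev), n_events = n_ev,
                                   fs = 300, seed = 8, amp_jitter = 0,
                                   time_jitter_s = 0)
  set.seed(81)
  vals <- tj$values
  lab <- primary_dof_labels()
  vals[, lab] <- vals[, lab] + matrix(rnorm(nrow(vals) * 5, sd = sigma),
                                      ncol = 5)
  tr <- dof_traces(vals, fs = 300)
  ev <- data.frame(class = "rostrocaudal",
                   t_ref_s = tj$events$center_s)
  ag <- align_and_aggregate(tr, ev, "rostrocaudal")
  # pointwise SE of iid noise: sigma/sqrt(n) on average
  expect_equal(mean(ag$se), sigma / sqrt(n_ev), tolerance = 0.2)
})

test_that("prey velocity differentiates rostrocaudal position correctly", {
  n <- 300; fs <- 300
  still <- cbind(rep(40, n), 0, -10)
  v0 <- prey_velocity_rc(still, fs)
  expect_lt(max(abs(v0)), 1e-8)
  ramp <- cbind(40 + 100 * (seq_len(n) - 1) / fs, 0, -10)
  v1 <- prey_velocity_rc(ramp, fs)
  expect_equal(unname(v1[20:(n - 20)]), rep(100, n - 39), tolerance = 1e-3)
  # exclusion flags null out frames
  v2 <- prey_velocity_rc(ramp, fs, exclude = seq_len(n) <= 10)
  expect_true(all(is.na(v2[1:10])))
})

test_that("noisy events are still classified at ninety percent agreement", {
  # 40 seeded events at 20% amplitude noise (the acceptance suite runs the
  # full 200-event version)
  classes <- rep(c("rostrocaudal", "caudorostral", "compressive", "slow_open"),
                 each = 10)
  good <- 0L
  for (i in seq_along(classes)) {
    tw <- traces_from_class(classes[i], seed = 100 + i, noise_frac = 0.2)
    ev <- classify_events(tw$traces)
    if (nrow(ev) >= 1L) {
      # score the detected event nearest the true event center; extra
      # noise-triggered detections elsewhere are not the property under test
      j <- which.min(abs(ev$t_ref_s - tw$truth$center_s[1]))
      if (abs(ev$t_ref_s[j] - tw$truth$center_s[1]) < 0.3 &&
          ev$class[j] == classes[i]) good <- good + 1L
    }
  }
  expect_gte(good / length(classes), 0.9)
})
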