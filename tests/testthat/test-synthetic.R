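test_that("wave trajectories are seed-deterministic and respect zero amplitudes", {
  sp <- wave_spec("rostrocaudal")
  a <- generate_wave_trajectories(sp, n_events = 2, seed = 7)
  b <- generate_wave_trajectories(sp, n_events = 2, seed = 7)
  expect_identical(a$values, b$values)
  c2 <- generate_wave_trajectories(sp, n_events = 2, seed = 8)
  expect_false(identical(a$values, c2$values))
  # zero amplitudes give constant trajectories
  sp0 <- wave_spec("rostrocaudal", active = character())
  z <- generate_wave_trajectories(sp0, n_events = 2, seed = 7)
  expect_true(all(z$values == 0))
})

test_that("rostrocaudal waves peak in rostral-to-caudal order by construction", {
  sp <- wave_spec("rostrocaudal")
  tr <- generate_wave_trajectories(sp, n_events = 1, seed = 9,
                                   amp_jitter = 0, time_jitter_s = 0)
  pk <- vapply(c("I", "J", "K", "G"), function(k) which.max(tr$values[, k]), 0L)
  expect_true(pk[["I"]] < pk[["J"]], )
  expect_true(pk[["J"]] < pk[["K"]])
  expect_true(pk[["K"]] < pk[["G"]])
  # caudorostral reverses the order
  cr <- generate_wave_trajectories(wave_spec("caudorostral"), n_events = 1,
                                   seed = 9, amp_jitter = 0, time_jitter_s = 0)
  pk2 <- vapply(c("I", "K", "H"), function(k) which.max(cr$values[, k]), 0L)
  expect_true(pk2[["H"]] < pk2[["K"]])
  expect_true(pk2[["K"]] < pk2[["I"]])
  # compressive: hyoid elevation (negative K) precedes flaring
  cp <- generate_wave_trajectories(wave_spec("compressive"), n_events = 1,
                                   seed = 9, amp_jitter = 0, time_jitter_s = 0)
  expect_true(which.min(cp$values[, "K"]) < which.max(cp$values[, "H"]))
  expect_lt(max(cp$values[, "I"]), 0.1 * max(cp$values[, "H"]))
})

test_that("noise-free recordings are exactly consistent with the link poses", {
  fx <- get_fixture()
  traj <- generate_wave_trajectories(wave_spec("rostrocaudal"), n_events = 1,
                                     fs = 150, seed = 10, spacing_s = 0.8)
  rec <- simulate_recording(fx, traj, sigma = 0, seed = 10)
  # markers land exactly on the rigidly attached reference positions
  f <- which.max(traj$values[, "I"])
  for (bd in fx$marked_bodies[1:3]) {
    sel <- which(rec$markers$body == bd)
    got <- t(rec$markers$xyz[f, , sel])
    want <- pose_apply(rec$poses[[bd]][[f]], rec$marker_reference[[bd]])
    expect_lt(max(abs(got - want)), 1e-9)
  }
  # and the precision metric reads zero
  p <- precision_metric(rec$markers, n_frames = 40, seed = 1)
  expect_lt(max(p), 1e-8)
})

test_that("marker noise of 0.08 mm is recovered by the precision metric", {
  fx <- get_fixture()
  traj <- generate_wave_trajectories(wave_spec("rostrocaudal"), n_events = 1,
                                     fs = 150, seed = 11, spacing_s = 0.8)
  rec <- simulate_recording(fx, traj, sigma = 0.08, seed = 11)
  p <- precision_metric(rec$markers, n_frames = 50, seed = 3)
  expect_gt(mean(p), 0.04)
  expect_lt(mean(p), 0.12)
})

test_that("recordings are seed-deterministic including missingness", {
  fx <- get_fixture()
  traj <- generate_wave_trajectories(wave_spec("compressive"), n_events = 1,
                                     fs = 100, seed = 12, spacing_s = 0.6)
  r1 <- simulate_recording(fx, traj, sigma = 0.05, missing_rate = 0.1, seed = 5)
  r2 <- simulate_recording(fx, traj, sigma = 0.05, missing_rate = 0.1, seed = 5)
  expect_identical(r1$markers$xyz, r2$markers$xyz)
  expect_identical(r1$markers$missing, r2$markers$missing)
  expect_gt(mean(r1$markers$missing), 0.05)
})

test_that("scaled individuals preserve the census and scale distances linearly", {
  fx1 <- get_fixture()
  fx2 <- make_individual(scale_factor = 2)
  expect_equal(mechanism_census(fx2$mechanism),
               mechanism_census(fx1$mechanism))
  expect_equal(fx2$head_length, 2 * fx1$head_length)
  c1 <- vapply(fx1$mechanism$joints, function(j) j$center, numeric(3))
  c2 <- vapply(fx2$mechanism$joints, function(j) j$center, numeric(3))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_error(make_individual(scale_factor = -1), "positive")
})

test_that("jittered individuals deviate from the consensus by the jitter scale", {
  # three individuals built with ~0.5 mm landmark jitter: the Procrustes
  # deviations of their homologous joint centers recover that scale
  shapes <- lapply(1:3, function(i) {
    fxi <- make_individual(scale_factor = 1, seed = 20 + i, jitter_sd = 0.5)
    t(vapply(fxi$mechanism$joints, function(j) j$center, numeric(3)))
  })
  g <- procrustes_consensus(shapes)
  expect_gt(mean(g$rms), 0.15)
  expect_lt(mean(g$rms), 1.5)
})

test_that("generator randomness does not leak into the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_wave_trajectories(wave_spec("rostrocaudal"), seed = 3))
  expect_identical(.Random.seed, before)
})
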