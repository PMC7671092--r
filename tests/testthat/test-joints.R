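test_that("joint primitives carry the right DoFs and validate axes", {
  expect_equal(joint_dof("revolute"), 1L)
  expect_equal(joint_dof("universal"), 2L)
  expect_equal(joint_dof("spherical"), 3L)
  expect_equal(joint_dof("prismatic"), 1L)
  expect_error(joint_model("universal", axes = rbind(c(1, 0, 0))), "2 axis")
  expect_error(joint_model("universal", axes = rbind(c(1, 0, 0), c(1, 0, 0))),
               "independent")
})

test_that("joint_transform reproduces closed-form poses", {
  j <- joint_model("revolute", c(0, 0, 0), c(0, 0, 1))
  expect_equal(joint_transform(j, 0)$R, diag(3))
  p <- joint_transform(j, pi / 2)
  expect_equal(p$R, matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
               tolerance = 1e-12)
  expect_error(joint_transform(j, c(1, 2)), "coordinate")
  # rotation about an off-origin center leaves the center fixed
  j2 <- joint_model("revolute", c(5, -2, 3), c(0, 1, 0))
  expect_equal(pose_apply(joint_transform(j2, 1.1), c(5, -2, 3)), c(5, -2, 3),
               tolerance = 1e-12)
  # prismatic slides along its axis
  j3 <- joint_model("prismatic", axes = c(1, 0, 0))
  expect_equal(joint_transform(j3, 2.5)$t, c(2.5, 0, 0))
})

test_that("a spherical joint equals the sequential composition of its rotations", {
  set.seed(51)
  axes <- qr.Q(qr(matrix(rnorm(9), 3)))
  ctr <- c(2, -1, 4)
  js <- joint_model("spherical", ctr, t(axes))
  for (i in 1:10) {
    q <- rnorm(3, sd = 0.8)
    got <- joint_transform(js, q)
    # oracle: compose three single-axis rotations about the same center
    oracle <- pose_identity()
    for (k in 1:3) {
      jk <- joint_model("revolute", ctr, axes[, k])
      oracle <- pose_compose(oracle, joint_transform(jk, q[k]))
    }
    expect_lt(max(abs(got$R - oracle$R)), 1e-12)
    expect_lt(max(abs(got$t - oracle$t)), 1e-10)
  }
})

test_that("fitting recovers a revolute joint from noise-free motion", {
  ax <- c(0.3, 0.9, 0.2); ax <- ax / sqrt(sum(ax^2))
  jm <- joint_model("revolute", c(10, -5, 3), ax)
  poses <- lapply(seq(-0.4, 0.5, length.out = 20),
                  function(a) joint_transform(jm, a))
  fp <- fit_point_set("child", rbind(c(15, 0, 0), c(8, 4, -2), c(12, -3, 5)))
  fit <- fit_joint_model(poses, "revolute", fp, seed = 1)
  expect_lt(fit$fit_rms, 1e-6)
  axis_err <- acos(min(1, abs(sum(fit$axes[1, ] * ax)))) * 180 / pi
  expect_lt(axis_err, 0.1)
  expect_true(attr(fit, "converged"))
})

test_that("model mismatch is detectable and nesting holds", {
  set.seed(52)
  sph <- joint_model("spherical", c(10, -5, 3), diag(3))
  poses <- lapply(1:20, function(i) joint_transform(sph, rnorm(3, sd = 0.3)))
  fp <- rbind(c(15, 0, 0), c(8, 4, -2), c(12, -3, 5))
  f_rev <- fit_joint_model(poses, "revolute", fp, seed = 1)
  f_uni <- fit_joint_model(poses, "universal", fp, seed = 1)
  f_sph <- fit_joint_model(poses, "spherical", fp)
  # spherical data fitted as revolute leaves a residual far above precision
  expect_gt(f_rev$fit_rms, 0.5)
  expect_lt(f_sph$fit_rms, 1e-9)
  # nested models: error never increases with added DoFs
  expect_gte(f_rev$fit_rms + 1e-8, f_uni$fit_rms)
  expect_gte(f_uni$fit_rms + 1e-8, f_sph$fit_rms)
  # and the fitted model reproduces its own input poses at fit_rms
  pred_err <- vapply(seq_along(poses), function(i) {
    pr <- joint_transform(f_sph, f_sph$coordinates[i, ])
    rms_point_error(pose_apply(pr, fp), pose_apply(poses[[i]], fp))
  }, 0)
  expect_equal(sqrt(mean(pred_err^2)), f_sph$fit_rms, tolerance = 1e-6)
})

test_that("noisy revolute motion fits at the noise scale", {
  set.seed(53)
  ax <- c(0, 0.8, 0.6)
  jm <- joint_model("revolute", c(5, 0, -2), ax)
  fp <- rbind(c(10, 2, 0), c(4, 6, -3), c(7, -2, 4))
  sigma <- 0.08
  target_poses <- lapply(seq(-0.5, 0.5, length.out = 18), function(a) {
    p <- joint_transform(jm, a)
    # noise enters through perturbed fit-point observations; emulate by a
    # small random rigid wobble of comparable magnitude
    w <- skullkin:::rot_axis_angle(rnorm(3), rnorm(1, sd = sigma / 10))
    pose(p$R %*% w, p$t + rnorm(3, sd = sigma), check = FALSE)
  })
  fit <- fit_joint_model(target_poses, "revolute", fp, seed = 2)
  expect_gt(fit$fit_rms, sigma / 4)
  expect_lt(fit$fit_rms, sigma * 4)
})

test_that("the lowest adequate joint model is selected", {
  ax <- c(0.3, 0.9, 0.2); ax <- ax / sqrt(sum(ax^2))
  jm <- joint_model("revolute", c(10, -5, 3), ax)
  hinge_poses <- lapply(seq(-0.4, 0.5, length.out = 16),
                        function(a) joint_transform(jm, a))
  fp <- rbind(c(15, 0, 0), c(8, 4, -2), c(12, -3, 5))
  fits <- list(revolute = fit_joint_model(hinge_poses, "revolute", fp, seed = 1),
               universal = fit_joint_model(hinge_poses, "universal", fp, seed = 1),
               spherical = fit_joint_model(hinge_poses, "spherical", fp))
  expect_equal(select_joint_model(fits, precision = 0.08)$type, "revolute")

  set.seed(54)
  sph <- joint_model("spherical", c(10, -5, 3), diag(3))
  ball_poses <- lapply(1:16, function(i) joint_transform(sph, rnorm(3, sd = 0.3)))
  fits2 <- list(revolute = fit_joint_model(ball_poses, "revolute", fp, seed = 1),
                universal = fit_joint_model(ball_poses, "universal", fp, seed = 1),
                spherical = fit_joint_model(ball_poses, "spherical", fp))
  expect_equal(select_joint_model(fits2, precision = 0.08)$type, "spherical")

  # identical errors: the lowest-DoF model wins the tie
  tie <- fits
  tie$revolute$fit_rms <- 0.01
  tie$universal$fit_rms <- 0.01
  tie$spherical$fit_rms <- 0.01
  expect_equal(select_joint_model(tie, precision = 0.08)$type, "revolute")
})

test_that("disparate-frame selection is deterministic, maximin and complete", {
  # k = frame count returns everything in order
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(select_disparate_frames(x, 10), 1:10)
  expect_error(select_disparate_frames(x, 11), "exceeds")
  # 1D ramp: two frames -> the endpoints (brute-force over all pairs)
  ramp <- matrix(seq(0, 1, length.out = 11), ncol = 1)
  expect_equal(select_disparate_frames(ramp, 2), c(1, 11))
  # oracle: for k=2 the greedy pick matches the exhaustive max-distance pair
  set.seed(55)
  for (i in 1:5) {
    y <- matrix(rnorm(24), 8, 3)
    got <- select_disparate_frames(y, 2)
    d <- as.matrix(dist(y)) / sqrt(ncol(y))
    best <- which(d == max(d), arr.ind = TRUE)[1, ]
    # greedy's first pick is farthest-from-mean, so its pair attains at
    # least the max-min criterion; check the distance is the row maximum
    expect_equal(d[got[1], got[2]], max(d[got[1], ]), tolerance = 1e-12)
  }
  # duplicated frames are not both selected while distinct poses remain
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 2, 0),
               c(3, 1, 0))
  sel <- select_disparate_frames(dup, 4)
  expect_equal(length(unique(lapply(sel, function(i) dup[i, ]))), 4)
  # permutation invariance up to relabeling
  set.seed(56)
  z <- matrix(rnorm(36), 12, 3)
  perm <- sample(12)
  s1 <- select_disparate_frames(z, 5)
  s2 <- select_disparate_frames(z[perm, ], 5)
  expect_setequal(perm[s2], s1)
})
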