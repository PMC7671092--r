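test_that("the catfish fixture census matches the printed totals", {
  fx <- get_fixture()
  cz <- mechanism_census(fx$mechanism)
  expect_equal(cz$links, 17L)
  expect_equal(cz$joints, 21L)
  expect_equal(cz$sum_joint_dof, 49L)
  expect_equal(cz$loops, 5L)
  expect_equal(cz$mobility, 19L)
})

test_that("fixture geometry is bilaterally mirror-symmetric", {
  fx <- get_fixture()
  jt <- fx$mechanism$joints
  byname <- stats::setNames(jt, vapply(jt, `[[`, "", "name"))
  mirror <- function(v) v * c(1, -1, 1)
  for (nm in c("cranio_susp", "jaw", "operc", "susp_hyoid", "hyoid_urohyal")) {
    l <- byname[[paste0(nm, "_L")]]; r <- byname[[paste0(nm, "_R")]]
    expect_equal(r$center, mirror(l$center), tolerance = 1e-12)
    expect_equal(unname(as.matrix(r$axes)),
                 unname(t(apply(as.matrix(l$axes), 1, mirror))),
                 tolerance = 1e-12)
    expect_equal(l$type, r$type)
  }
})

test_that("parameter labels group as the anatomical decomposition", {
  fx <- get_fixture()
  g <- fx$param$groups
  expect_setequal(names(g)[g == "twist"], c("O", "P", "Q", "R", "S"))
  expect_setequal(names(g)[g == "strut_length"], c("A", "B", "L"))
  expect_setequal(names(g)[g == "midline_asymmetry"], c("C", "D", "E", "F"))
  expect_setequal(names(g)[g == "opercular"], c("G", "H", "M", "N"))
  expect_equal(unname(g[c("I", "J", "K")]),
               c("mandibular_depression", "suspensorial_abduction",
                 "hyoid_depression"))
})

test_that("loop count equals joints - links + 1 and matches a GF(2) cycle basis", {
  # open serial chain has no loops
  chain <- mechanism(c("a", "b", "c"), list(
    list(name = "j1", parent = "a", child = "b", type = "revolute",
         center = c(0, 0, 0), axes = rbind(c(0, 0, 1))),
    list(name = "j2", parent = "b", child = "c", type = "revolute",
         center = c(1, 0, 0), axes = rbind(c(0, 0, 1)))), fixed = "a")
  expect_equal(count_loops(chain), 0L)
  expect_equal(count_loops(get_fixture()$mechanism), 5L)
  # random connected multigraphs: explicit chord-cycle basis rank oracle
  set.seed(61)
  for (rep in 1:8) {
    nl <- sample(4:8, 1)
    links <- paste0("L", 1:nl)
    edges <- cbind(links[-nl], links[-1])  # spanning path
    extra <- sample(2:4, 1)
    for (e in seq_len(extra)) {
      pair <- sample(links, 2)
      edges <- rbind(edges, pair)
    }
    joints <- lapply(seq_len(nrow(edges)), function(i)
      list(name = paste0("j", i), parent = edges[i, 1], child = edges[i, 2],
           type = "spherical", center = rnorm(3), axes = diag(3)))
    m <- mechanism(links, joints, fixed = links[1])
    expect_equal(count_loops(m), cycle_basis_size(links, edges))
  }
})

test_that("CGK mobility matches hand counts and the numeric oracle", {
  # two links joined by one spherical joint: 6(2-1-1)+3 = 3
  ball <- mechanism(c("a", "b"), list(
    list(name = "s", parent = "a", child = "b", type = "spherical",
         center = c(0, 0, 0), axes = diag(3))), fixed = "a")
  expect_equal(gruebler_mobility(ball), 3L)
  expect_equal(numeric_mobility(ball), 3L)
  # spatial RSSR four-bar: 6(4-1-4)+8 = 2 (includes the coupler spin)
  rssr <- make_rssr()
  expect_equal(gruebler_mobility(rssr), 2L)
  expect_equal(numeric_mobility(rssr), 2L)
  # fixture: 6(17-1-21)+49 = 19
  expect_equal(gruebler_mobility(get_fixture()$mechanism), 19L)
})

test_that("numeric mobility flags overconstrained special geometry", {
  # planar four-bar in 3D: CGK says -2, the constraint rank says 1
  fb <- make_four_bar()$mech
  expect_equal(gruebler_mobility(fb), -2L)
  expect_equal(numeric_mobility(fb), 1L)
  # rigid triangle with skew revolute axes: immobile
  tri <- make_rigid_triangle()
  expect_equal(gruebler_mobility(tri), -3L)
  expect_equal(numeric_mobility(tri), 0L)
})

test_that("numeric and CGK mobility agree on the fixture away from reference", {
  fx <- get_fixture()
  expect_equal(numeric_mobility(fx$mechanism), 19L)
  set.seed(62)
  amps <- c(A = 0.2, B = -0.5, C = 0.005, D = 0.005, E = 0.005, F = 0.005,
            G = 0.12, H = 0.15, I = 0.3, J = 0.04, K = 0.12, L = 0.2,
            M = 0.005, N = 0.005, O = 0.005, P = 0.005, Q = 0.005,
            R = 0.005, S = 0.005)
  cf <- forward_kinematics(fx$mechanism, fx$param, rep(0, 19))
  for (i in 1:5) {
    v <- amps * runif(19)
    cf <- forward_kinematics(fx$mechanism, fx$param, v, init = cf)
    expect_equal(numeric_mobility(fx$mechanism, cf), 19L)
  }
})

test_that("census invariants are unaffected by link relabeling and fixed choice", {
  fx <- build_catfish_fixture()
  m <- fx$mechanism
  # choose a different fixed link: loop count and mobility are unchanged
  m2 <- mechanism(m$links, m$joints, fixed = "urohyal", struts = m$struts)
  expect_equal(count_loops(m2), count_loops(m))
  expect_equal(gruebler_mobility(m2), gruebler_mobility(m))
  # rename all links consistently
  ren <- function(x) paste0("link_", x)
  joints2 <- lapply(m$joints, function(j) {
    j$parent <- ren(j$parent); j$child <- ren(j$child); j
  })
  m3 <- mechanism(ren(m$links), joints2, fixed = ren(m$fixed))
  expect_equal(count_loops(m3), count_loops(m))
  expect_equal(gruebler_mobility(m3), gruebler_mobility(m))
})

test_that("mechanism construction validates its graph", {
  expect_error(mechanism(c("a", "b"), list(
    list(name = "j", parent = "a", child = "a", type = "revolute",
         center = c(0, 0, 0), axes = rbind(c(0, 0, 1)))), fixed = "a"),
    "distinct")
  expect_error(mechanism(c("a", "b", "c"), list(
    list(name = "j", parent = "a", child = "b", type = "revolute",
         center = c(0, 0, 0), axes = rbind(c(0, 0, 1)))), fixed = "a"),
    "disconnected")
})
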