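# Shared fixtures and independent oracles, built in code at test time.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_fixture <- function() cached("fixture", build_catfish_fixture())

# planar circle-circle intersection (closed-form four-bar oracle)
circle_intersect <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h <- sqrt(max(r1^2 - a^2, 0))
  m <- c1 + a * (c2 - c1) / d
  perp <- c(-(c2 - c1)[2], (c2 - c1)[1]) / d
  list(p1 = m + h * perp, p2 = m - h * perp)
}

# planar four-bar embedded in 3D (all revolute axes +z); crank-rocker
# geometry: ground 10, crank 3, coupler 9, rocker 8; reference closed at
# crank angle 90 degrees
make_four_bar <- function() {
  z <- c(0, 0, 1)
  B0 <- circle_intersect(c(0, 3), 9, c(10, 0), 8)$p1
  joints <- list(
    list(name = "crank_pin", parent = "ground", child = "crank",
         type = "revolute", center = c(0, 0, 0), axes = rbind(z)),
    list(name = "coupler_pin", parent = "crank", child = "coupler",
         type = "revolute", center = c(0, 3, 0), axes = rbind(z)),
    list(name = "rocker_pin", parent = "coupler", child = "rocker",
         type = "revolute", center = c(B0, 0), axes = rbind(z)),
    list(name = "ground_pin", parent = "ground", child = "rocker",
         type = "revolute", center = c(10, 0, 0), axes = rbind(z)))
  list(mech = mechanism(c("ground", "crank", "coupler", "rocker"), joints,
                        fixed = "ground"),
       B0 = B0)
}

# rigid triangle: three links in a loop joined by revolutes with skew axes
make_rigid_triangle <- function() {
  u <- function(v) v / sqrt(sum(v^2))
  joints <- list(
    list(name = "j1", parent = "a", child = "b", type = "revolute",
         center = c(0, 0, 0), axes = rbind(u(c(1, 0.3, 0.2)))),
    list(name = "j2", parent = "b", child = "c", type = "revolute",
         center = c(5, 0, 0), axes = rbind(u(c(0.1, 1, -0.4)))),
    list(name = "j3", parent = "c", child = "a", type = "revolute",
         center = c(2, 4, 1), axes = rbind(u(c(-0.3, 0.2, 1)))))
  mechanism(c("a", "b", "c"), joints, fixed = "a")
}

# spatial RSSR four-bar: revolute-spherical-spherical-revolute, generic axes
make_rssr <- function() {
  u <- function(v) v / sqrt(sum(v^2))
  I3 <- diag(3)
  joints <- list(
    list(name = "r1", parent = "ground", child = "input", type = "revolute",
         center = c(0, 0, 0), axes = rbind(u(c(0.2, 0.1, 1)))),
    list(name = "s1", parent = "input", child = "coupler", type = "spherical",
         center = c(3, 0, 1), axes = I3),
    list(name = "s2", parent = "coupler", child = "output", type = "spherical",
         center = c(7, 4, 2), axes = I3),
    list(name = "r2", parent = "ground", child = "output", type = "revolute",
         center = c(10, 1, 0), axes = rbind(u(c(1, 0.3, 0.4)))))
  mechanism(c("ground", "input", "coupler", "output"), joints, fixed = "ground")
}

# random single-loop mechanism: n links in a cycle, random joint types with
# generic centers and axes; closed at the all-zero reference by construction
make_random_loop <- function(seed) {
  set.seed(seed)
  n <- sample(4:6, 1)
  types <- sample(c("revolute", "universal", "spherical", "prismatic"), n,
                  replace = TRUE, prob = c(0.2, 0.25, 0.45, 0.1))
  # ensure enough freedom for a generically mobile loop
  while (sum(vapply(types, joint_dof, 0L)) < 7)
    types[sample(n, 1)] <- "spherical"
  links <- paste0("L", seq_len(n))
  centers <- matrix(rnorm(3 * n, sd = 5), n, 3)
  joints <- lapply(seq_len(n), function(i) {
    ax <- qr.Q(qr(matrix(rnorm(9), 3)))
    nax <- switch(types[i], revolute = 1, prismatic = 1, universal = 2, spherical = 3)
    list(name = paste0("j", i), parent = links[i],
         child = links[i %% n + 1], type = types[i],
         center = centers[i, ], axes = ax[seq_len(nax), , drop = FALSE])
  })
  mechanism(links, joints, fixed = links[1])
}

# GF(2) rank of a binary matrix (independent cycle-basis oracle)
gf2_rank <- function(M) {
  M <- M %% 2
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col] == 1 & seq_len(nrow(M)) > r)
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    for (i in which(M[, col] == 1)) if (i != r) M[i, ] <- (M[i, ] + M[r, ]) %% 2
  }
  r
}

# cycle basis size via explicit chord cycles + GF(2) independence
cycle_basis_size <- function(links, edges) {
  # edges: 2-column character matrix
  parent <- stats::setNames(rep(NA_character_, length(links)), links)
  seen <- stats::setNames(rep(FALSE, length(links)), links)
  seen[links[1]] <- TRUE
  tree <- integer(); chords <- integer()
  repeat {
    progressed <- FALSE
    for (e in seq_len(nrow(edges))) {
      if (e %in% c(tree, chords)) next
      a <- edges[e, 1]; b <- edges[e, 2]
      if (seen[a] && seen[b]) { chords <- c(chords, e); progressed <- TRUE }
      else if (seen[a] || seen[b]) {
        nw <- if (seen[a]) b else a
        seen[nw] <- TRUE; parent[nw] <- if (seen[a] && a != nw) a else b
        tree <- c(tree, e); progressed <- TRUE
      }
    }
    if (length(tree) + length(chords) == nrow(edges)) break
    if (!progressed) stop("disconnected")
  }
  if (!length(chords)) return(0L)
  # each chord + tree path forms a cycle; row = edge incidence over GF(2)
  path_to_root <- function(v) {
    out <- character()
    while (!is.na(parent[v])) { out <- c(out, v); v <- parent[v] }
    c(out, v)
  }
  M <- matrix(0L, length(chords), nrow(edges))
  for (i in seq_along(chords)) {
    e <- chords[i]
    M[i, e] <- 1L
    pa <- path_to_root(edges[e, 1]); pb <- path_to_root(edges[e, 2])
    sym <- c(setdiff(pa, pb), setdiff(pb, pa))
    # mark tree edges along the symmetric difference
    for (v in sym) {
      pe <- which((edges[, 1] == v & edges[, 2] == parent[v]) |
                  (edges[, 2] == v & edges[, 1] == parent[v]))
      pe <- intersect(pe, tree)
      if (length(pe)) M[i, pe[1]] <- (M[i, pe[1]] + 1L) %% 2L
    }
  }
  gf2_rank(M)
}

random_rotation_test <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
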