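#' Assemble a multi-loop linkage mechanism
#'
#' A mechanism is a connected graph of rigid links joined by joints, with one
#' link fixed (the reference frame; for skull linkages, the neurocranium).
#' Joint centers and axes are given in the common reference frame, in which
#' every link's reference pose is the identity, so the all-zero coordinate
#' vector always closes every loop.
#'
#' @param links character vector of link names.
#' @param joints list of joint definitions, each a list with elements
#'   \code{name}, \code{parent}, \code{child}, \code{type} (see
#'   \code{\link{joint_model}}), \code{center} (3-vector, mm) and \code{axes}
#'   (rows of unit axes). Parent and child must be distinct links. Multiple
#'   joints between one pair of links are allowed.
#' @param fixed name of the fixed link.
#' @param struts optional character vector naming links that are soft-tissue
#'   strut half-pairs (metadata used by the census).
#' @return Object of class \code{"mechanism"}.
#' @export
mechanism <- function(links, joints, fixed, struts = character()) {
  links <- as.character(links)
  if (anyDuplicated(links)) stop("duplicate link names")
  if (!fixed %in% links) stop("fixed link not among links")
  for (j in joints) {
    if (!all(c(j$parent, j$child) %in% links))
      stop("joint '", j$name, "' references unknown link")
    if (j$parent == j$child)
      stop("joint '", j$name, "' must join two distinct links")
  }
  m <- structure(list(links = links, joints = joints, fixed = fixed,
                      struts = struts), class = "mechanism")
  if (!is_connected(m)) stop("mechanism graph is disconnected")
  m$compiled <- compile_mechanism(m)
  m
}

is_connected <- function(mech) {
  adj <- lapply(stats::setNames(vector("list", length(mech$links)), mech$links), identity)
  for (j in mech$joints) {
    adj[[j$parent]] <- c(adj[[j$parent]], j$child)
    adj[[j$child]] <- c(adj[[j$child]], j$parent)
  }
  seen <- mech$fixed
  queue <- mech$fixed
  while (length(queue)) {
    nb <- setdiff(unlist(adj[queue]), seen)
    seen <- c(seen, nb)
    queue <- nb
  }
  length(seen) == length(mech$links)
}

# Compile: coordinate indexing, BFS spanning tree, chord list.
compile_mechanism <- function(mech) {
  nj <- length(mech$joints)
  f <- vapply(mech$joints, function(j) joint_dof(j$type), 0L)
  qend <- cumsum(f)
  qidx <- lapply(seq_len(nj), function(i) (qend[i] - f[i] + 1L):qend[i])
  link_id <- stats::setNames(seq_along(mech$links), mech$links)

  # BFS spanning tree from the fixed link, visiting joints in list order
  visited <- rep(FALSE, length(mech$links))
  visited[link_id[[mech$fixed]]] <- TRUE
  tree <- list(); chords <- integer()
  used <- rep(FALSE, nj)
  repeat {
    progressed <- FALSE
    for (i in seq_len(nj)) {
      if (used[i]) next
      j <- mech$joints[[i]]
      pv <- visited[link_id[[j$parent]]]; cv <- visited[link_id[[j$child]]]
      if (pv && cv) { chords <- c(chords, i); used[i] <- TRUE; progressed <- TRUE }
      else if (pv || cv) {
        fwd <- pv  # propagate parent -> child if parent visited
        to <- if (fwd) j$child else j$parent
        visited[link_id[[to]]] <- TRUE
        tree[[length(tree) + 1L]] <- list(joint = i, forward = fwd,
                                          from = if (fwd) j$parent else j$child,
                                          to = to)
        used[i] <- TRUE; progressed <- TRUE
      }
    }
    if (all(used)) break
    if (!progressed) stop("mechanism graph is disconnected")
  }
  # precompute numeric fields for speed
  jinfo <- lapply(mech$joints, function(j) {
    list(type = j$type, f = joint_dof(j$type),
         center = as.numeric(j$center),
         axes = matrix(as.numeric(j$axes), ncol = 3L),
         parent = link_id[[j$parent]], child = link_id[[j$child]])
  })
  # subtree membership: for each tree step, which links move when that step's
  # joint coordinates vary (links on the 'to' side of the cut tree edge)
  n_links <- length(mech$links)
  subtree <- matrix(FALSE, length(tree), n_links)
  if (length(tree)) {
    tree_adj <- lapply(seq_len(n_links), function(i) integer())
    for (si in seq_along(tree)) {
      a <- link_id[[tree[[si]]$from]]; b <- link_id[[tree[[si]]$to]]
      tree_adj[[a]] <- c(tree_adj[[a]], si)
      tree_adj[[b]] <- c(tree_adj[[b]], si)
    }
    for (si in seq_along(tree)) {
      start <- link_id[[tree[[si]]$to]]
      seen <- rep(FALSE, n_links); seen[start] <- TRUE
      queue <- start
      while (length(queue)) {
        nxt <- integer()
        for (v in queue) for (e in tree_adj[[v]]) {
          if (e == si) next
          w <- c(link_id[[tree[[e]]$from]], link_id[[tree[[e]]$to]])
          w <- w[!seen[w]]
          seen[w] <- TRUE; nxt <- c(nxt, w)
        }
        queue <- nxt
      }
      subtree[si, ] <- seen
    }
  }
  list(nq = qend[nj], qidx = qidx, f = f, link_id = link_id,
       fixed_id = link_id[[mech$fixed]],
       tree = tree, chords = chords, jinfo = jinfo,
       n_links = n_links, subtree = subtree)
}

#' Independent loop count of a mechanism
#'
#' The number of independent closed loops in the link/joint graph, computed as
#' \code{joints - links + 1} for a connected graph (the size of a cycle
#' basis).
#'
#' @param mech a \code{\link{mechanism}}.
#' @return Integer loop count.
#' @export
count_loops <- function(mech) {
  if (!is_connected(mech)) stop("mechanism graph is disconnected")
  length(mech$joints) - length(mech$links) + 1L
}

#' Chebychev-Gruebler-Kutzbach mobility
#'
#' Analytic mobility of a spatial mechanism:
#' \code{M = 6 (n_links - 1 - n_joints) + sum(joint DoFs)}. For
#' overconstrained mechanisms with special geometry (e.g. a planar four-bar
#' evaluated with the spatial formula) this undercounts; compare with
#' \code{\link{numeric_mobility}}.
#'
#' @param mech a \code{\link{mechanism}}.
#' @return Integer DoF count.
#' @export
gruebler_mobility <- function(mech) {
  n <- length(mech$links); j <- length(mech$joints)
  6L * (n - 1L - j) + sum(mech$compiled$f)
}

#' Mechanism census
#'
#' Summary counts of a mechanism: links, joints, summed joint DoFs,
#' independent loops, and Chebychev-Gruebler-Kutzbach mobility.
#'
#' @param mech a \code{\link{mechanism}}.
#' @return Named list of integers.
#' @export
mechanism_census <- function(mech) {
  list(links = length(mech$links),
       joints = length(mech$joints),
       sum_joint_dof = as.integer(sum(mech$compiled$f)),
       loops = count_loops(mech),
       mobility = gruebler_mobility(mech))
}

#' @export
print.mechanism <- function(x, ...) {
  cz <- mechanism_census(x)
  cat(sprintf("Mechanism: %d links (fixed: %s), %d joints, %d loops\n",
              cz$links, x$fixed, cz$joints, cz$loops))
  cat(sprintf("  summed joint DoFs: %d; CGK mobility: %d\n",
              cz$sum_joint_dof, cz$mobility))
  if (length(x$struts))
    cat("  strut half-links:", paste(x$struts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mechanism <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$joints, function(j)
    data.frame(joint = j$name, parent = j$parent, child = j$child,
               type = j$type, dof = joint_dof(j$type))))
  structure(list(census = mechanism_census(object), joints = tab),
            class = "summary.mechanism")
}

#' @export
print.summary.mechanism <- function(x, ...) {
  cz <- x$census
  cat(sprintf("links %d | joints %d | sum DoF %d | loops %d | CGK mobility %d\n",
              cz$links, cz$joints, cz$sum_joint_dof, cz$loops, cz$mobility))
  print(x$joints, row.names = FALSE)
  invisible(x)
}
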