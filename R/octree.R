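#' Orientation point cloud
#'
#' A set of positions, each carrying an orthonormal right-handed triad of
#' material axes (rows of the 3x3 matrix = axes 1, 2, 3). Such clouds stand
#' for CT-derived fields of local orthotropy directions.
#'
#' @param points N x 3 matrix of positions (mm).
#' @param triads N x 3 x 3 array of triads (`triads[i, , ]` has the three
#'   axis vectors as rows), each orthonormal within 1e-8 and with
#'   determinant +1.
#' @return An object of class `orientation_cloud`.
#' @export
orientation_cloud <- function(points, triads) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L || any(!is.finite(points))) {
    stop_bonevpd("'points' must be a non-empty N x 3 finite matrix",
                 "bonevpd_cloud_error")
  }
  if (length(dim(triads)) != 3L || any(dim(triads) != c(nrow(points), 3L, 3L))) {
    stop_bonevpd("'triads' must be an N x 3 x 3 array", "bonevpd_cloud_error")
  }
  for (i in seq_len(nrow(points))) {
    R <- triads[i, , ]
    if (max(abs(R %*% t(R) - diag(3))) > 1e-8 || det(R) < 0) {
      stop_bonevpd(sprintf("triad %d is not an orthonormal right-handed frame", i),
                   "bonevpd_cloud_error")
    }
  }
  cl <- list(points = points, triads = triads)
  class(cl) <- "orientation_cloud"
  cl
}

#' Build an octree over an orientation cloud
#'
#' The root is the tight bounding cube of the points (equal edges, centred
#' on the bounding box). Each node is split into eight congruent octants
#' until every leaf holds at most `capacity` points; points lying exactly
#' on a splitting plane go to the lower octant. Subdivision stops at depth
#' 21 regardless, so duplicate-point clouds terminate (such leaves may
#' exceed the capacity).
#'
#' @param cloud an [orientation_cloud()] (or any list with a `points`
#'   matrix).
#' @param capacity maximum points per leaf (>= 1); default 8.
#' @return An object of class `octree_index`.
#' @export
build_octree <- function(cloud, capacity = 8L) {
  pts <- cloud$points
  if (is.null(pts) || nrow(pts) < 1L) {
    stop_bonevpd("cannot build an octree over an empty cloud", "bonevpd_cloud_error")
  }
  capacity <- as.integer(check_scalar(capacity, "capacity", positive = TRUE))
  lo_box <- apply(pts, 2, min)
  hi_box <- apply(pts, 2, max)
  edge <- max(hi_box - lo_box)
  if (edge <= 0) edge <- 1
  lo <- (lo_box + hi_box) / 2 - edge / 2

  build <- function(idx, lo, edge, depth) {
    if (length(idx) <= capacity || depth >= 21L) {
      return(list(lo = lo, edge = edge, idx = idx, children = NULL))
    }
    mid <- lo + edge / 2
    oct <- 1L +
      (pts[idx, 1] > mid[1]) + 2L * (pts[idx, 2] > mid[2]) +
      4L * (pts[idx, 3] > mid[3])
    children <- vector("list", 8L)
    for (k in 1:8) {
      sub <- idx[oct == k]
      if (length(sub)) {
        off <- c(k - 1L, (k - 1L) %/% 2L, (k - 1L) %/% 4L) %% 2L
        children[[k]] <- build(sub, lo + off * edge / 2, edge / 2, depth + 1L)
      }
    }
    list(lo = lo, edge = edge, idx = NULL, children = children)
  }

  tree <- list(root = build(seq_len(nrow(pts)), lo, edge, 0L),
               points = pts, capacity = capacity)
  class(tree) <- "octree_index"
  tree
}

## Squared distance from q to an axis-aligned cube.
box_dist2 <- function(lo, edge, q) {
  d <- pmax(lo - q, q - (lo + edge), 0)
  sum(d^2)
}

#' Octree nearest-neighbour query
#'
#' Returns the index of the cloud point minimising the squared Euclidean
#' distance to `q`, descending nearest octants first and pruning subtrees
#' whose box distance exceeds the current best. Ties at exactly equal
#' distance are broken towards the smallest cloud index, matching
#' [brute_force_nearest()].
#'
#' @param tree a [build_octree()] index.
#' @param q query position (length-3).
#' @return Integer index, with attributes `distance` (Euclidean) and
#'   `n_eval` (number of point-distance evaluations performed).
#' @export
query_nearest <- function(tree, q) {
  stopifnot(inherits(tree, "octree_index"), length(q) == 3L)
  q <- as.numeric(q)
  pts <- tree$points
  env <- new.env(parent = emptyenv())
  env$best_d2 <- Inf; env$best_idx <- NA_integer_; env$n_eval <- 0L

  visit <- function(node) {
    if (is.null(node$children)) {
      idx <- node$idx
      if (!length(idx)) return(invisible())
      d2 <- (pts[idx, 1] - q[1])^2 + (pts[idx, 2] - q[2])^2 +
        (pts[idx, 3] - q[3])^2
      env$n_eval <- env$n_eval + length(idx)
      j <- which.min(d2)                 # first minimum = smallest index (idx ascending)
      if (d2[j] < env$best_d2 ||
          (d2[j] == env$best_d2 && idx[j] < env$best_idx)) {
        env$best_d2 <- d2[j]
        env$best_idx <- idx[j]
      }
      return(invisible())
    }
    keep <- !vapply(node$children, is.null, logical(1))
    kids <- node$children[keep]
    bd <- vapply(kids, function(ch) box_dist2(ch$lo, ch$edge, q), numeric(1))
    for (k in order(bd)) {
      if (bd[k] <= env$best_d2) visit(kids[[k]])
    }
    invisible()
  }
  visit(tree$root)
  structure(env$best_idx, distance = sqrt(env$best_d2), n_eval = env$n_eval)
}

#' Brute-force nearest neighbour (correctness oracle)
#'
#' Linear scan over all cloud points; the reference against which the
#' octree search is validated. Ties broken towards the smallest index.
#'
#' @param cloud an [orientation_cloud()] (or list with `points`).
#' @param q query position (length-3).
#' @return Integer index with attributes `distance` and `n_eval` (always
#'   the number of cloud points).
#' @export
brute_force_nearest <- function(cloud, q) {
  pts <- cloud$points
  if (is.null(pts) || nrow(pts) < 1L) {
    stop_bonevpd("empty cloud", "bonevpd_cloud_error")
  }
  q <- as.numeric(q)
  d2 <- (pts[, 1] - q[1])^2 + (pts[, 2] - q[2])^2 + (pts[, 3] - q[3])^2
  i <- which.min(d2)
  structure(i, distance = sqrt(d2[i]), n_eval = nrow(pts))
}

#' Project a matrix onto the nearest rotation
#'
#' Polar-factor orthonormalization: the closest orthonormal matrix in the
#' Frobenius sense, with the determinant forced to +1 by flipping the third
#' axis if needed (the first two axes are preserved up to
#' orthonormalization).
#'
#' @param raw non-singular 3x3 matrix (rows = axis vectors).
#' @return 3x3 rotation matrix.
#' @export
orthonormalize_triad <- function(raw) {
  raw <- as.matrix(raw)
  stopifnot(all(dim(raw) == c(3L, 3L)))
  sv <- svd(raw)
  if (min(sv$d) <= 1e-12 * max(sv$d)) {
    stop_bonevpd("cannot orthonormalize a (near-)singular triad",
                 "bonevpd_cloud_error")
  }
  P <- sv$u %*% t(sv$v)
  if (det(P) < 0) P[3, ] <- -P[3, ]
  P
}

#' Assign orthotropic axes to query points
#'
#' For every query position, finds the nearest cloud point through the
#' octree and attaches its (re-orthonormalized) triad. Pure nearest-point
#' assignment: no interpolation or averaging between neighbours.
#'
#' @param queries M x 3 matrix of integration-point positions.
#' @param cloud an [orientation_cloud()].
#' @param capacity octree leaf capacity; default 8.
#' @return An object of class `axis_assignment`: list with `source_index`
#'   (length M), `distance` (length M), `triads` (M x 3 x 3 array) and
#'   `n_eval` (total point-distance evaluations over all queries).
#' @export
assign_axes <- function(queries, cloud, capacity = 8L) {
  queries <- as.matrix(queries)
  if (ncol(queries) != 3L || any(!is.finite(queries))) {
    stop_bonevpd("'queries' must be an M x 3 finite matrix", "bonevpd_cloud_error")
  }
  tree <- build_octree(cloud, capacity)
  m <- nrow(queries)
  idx <- integer(m); dist <- numeric(m)
  triads <- array(NA_real_, c(m, 3L, 3L))
  n_eval <- 0L
  for (i in seq_len(m)) {
    hit <- query_nearest(tree, queries[i, ])
    idx[i] <- as.integer(hit)
    dist[i] <- attr(hit, "distance")
    n_eval <- n_eval + attr(hit, "n_eval")
    triads[i, , ] <- orthonormalize_triad(cloud$triads[idx[i], , ])
  }
  out <- list(source_index = idx, distance = dist, triads = triads,
              n_eval = n_eval)
  class(out) <- "axis_assignment"
  out
}
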