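#' Cutoff-bounded Voronoi tessellation: domains of danger
#'
#' Computes, for every agent, the area of its Voronoi cell intersected with
#' the disk of radius `delta` centred on the agent -- the domain of danger
#' (DOD) used as the geometric proxy for predation risk. An isolated agent
#' therefore has the maximum possible area `pi * delta^2`. Also returns the
#' Voronoi adjacency restricted to the cutoff (two agents are neighbours
#' only when their shared cell edge has positive length inside both cutoff
#' disks) and exact nearest-neighbour distances.
#'
#' Cells are built by direct half-plane intersection of the perpendicular
#' bisectors with a bounding box, then intersected exactly with the cutoff
#' disk (circular-segment arithmetic, no polygonal approximation of the
#' disk). This construction is robust for collinear and other degenerate
#' configurations where a generic Delaunay-based tessellation fails.
#'
#' @param points numeric matrix with two columns (x, y), one row per agent,
#'   in units of the body diameter sigma.
#' @param delta cutoff radius in sigma; default 10.
#' @return an object of class `dod_result`: a list with
#'   \describe{
#'     \item{areas}{numeric vector, per-agent DOD area in sigma^2;
#'       each in (0, pi*delta^2].}
#'     \item{adjacency}{symmetric, irreflexive logical matrix of
#'       within-cutoff Voronoi neighbourhood.}
#'     \item{nn_distance}{per-agent Euclidean distance to the nearest other
#'       agent (`Inf` for a single agent).}
#'     \item{delta}{the cutoff used.}
#'   }
#' @examples
#' compute_dod(rbind(c(0, 0), c(2, 0)), delta = 10)$areas
#' @export
compute_dod <- function(points, delta = 10) {
  points <- as_points(points)
  if (delta <= 0) stop("`delta` must be positive")
  n <- nrow(points)
  res <- .dod_cpp(points, delta)
  if (n >= 2 && min(res$nn_distance) <= 1e-9)
    stop("degenerate tessellation: coincident points (pairwise distance <= 1e-9)")
  structure(list(areas = res$areas, adjacency = res$adjacency,
                 nn_distance = res$nn_distance, delta = delta),
            class = "dod_result")
}

#' Exact nearest-neighbour distances
#'
#' @param points numeric matrix with columns (x, y), at least two rows.
#' @return numeric vector: for each agent, the minimum distance to any
#'   other agent.
#' @export
nearest_neighbor_distances <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 2) stop("need at least 2 points for neighbour distances")
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# validate and coerce a point set
as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("`points` must have two columns (x, y)")
  if (nrow(points) < 1) stop("empty input: need at least one point")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("non-finite coordinates in `points`")
  points
}
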