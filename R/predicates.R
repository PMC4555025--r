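#' Exact ellipsoid overlap predicate
#'
#' Tests whether two closed ellipsoids share at least one point, using
#' the algebraic separation condition for the matrix pencil of their two
#' quadratic forms: the quartic `det(lambda*A + B) = 0` has two distinct
#' positive real roots if and only if the ellipsoids are disjoint (a
#' positive double root corresponds to external tangency).  The predicate
#' is symmetric and exact up to floating point.
#'
#' A conservative safety `margin` (default 0.1 nm) treats configurations
#' whose surface gap is below the margin as overlapping: each ellipsoid's
#' radii are inflated by `margin/2` before the test.  This guards against
#' floating-point effects at the ~5 nm voxel resolution of the data.
#'
#' @param e1,e2 [ellipsoid()] objects.
#' @param margin near-tangency tolerance, nm; `0` gives the pure
#'   geometric predicate.
#' @return logical.
#' @examples
#' s1 <- ellipsoid(c(0, 0, 0), c(20, 20, 20))
#' s2 <- ellipsoid(c(41, 0, 0), c(20, 20, 20))
#' ellipsoids_overlap(s1, s2)  # FALSE (gap 1 nm)
#' @export
ellipsoids_overlap <- function(e1, e2, margin = 0.1) {
  stopifnot(inherits(e1, "ellipsoid"), inherits(e2, "ellipsoid"))
  cpp_ellipsoids_overlap(e1$center, e1$radii, e1$axes,
                         e2$center, e2$radii, e2$axes, margin)
}

#' Numerical separation gap between two ellipsoids
#'
#' Independent validation route for [ellipsoids_overlap()]: maps space so
#' that `e1` becomes the unit ball and computes the Euclidean distance in
#' mapped space from the origin to the (mapped, polygonized) surface of
#' `e2`, minus 1.  Negative values indicate overlap.  This is a sampling
#' approximation (surface polygonized at `n` points), intended for
#' cross-checks, not for the MCMC inner loop.
#'
#' @param e1,e2 [ellipsoid()] objects.
#' @param n surface sample count on `e2`.
#' @return approximate signed gap in the mapped metric (unitless;
#'   sign is what matters).
#' @export
ellipsoid_separation_gap <- function(e1, e2, n = 2000L) {
  S <- diag(1 / e1$radii) %*% t(e1$axes)
  pts <- fibonacci_sphere(n)
  surf <- t(e2$axes %*% (t(pts) * e2$radii) + e2$center)
  mapped <- t(S %*% (t(surf) - e1$center))
  min(sqrt(rowSums(mapped^2))) - 1
}

# internal: n roughly uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Ellipsoid / surface-mesh intersection
#'
#' True iff any mesh triangle meets the closed ellipsoid.  Exact: space
#' is mapped by the affine transform sending the ellipsoid to the unit
#' ball and each triangle's distance to the origin is compared to 1.
#' The same near-tangency `margin` convention as [ellipsoids_overlap()]
#' applies (radii inflated by the full margin, since the mesh cannot be
#' inflated).
#'
#' @param e an [ellipsoid()].
#' @param surface a [mesh3()].
#' @param margin near-tangency tolerance, nm.
#' @return logical.
#' @export
ellipsoid_intersects_surface <- function(e, surface, margin = 0.1) {
  stopifnot(inherits(e, "ellipsoid"), inherits(surface, "mesh3"))
  ma <- mesh_arrays(surface)
  cpp_ellipsoid_mesh_intersect(e$center, e$radii, e$axes, ma$V, ma$F,
                               margin)
}

#' Shortest straight path from a point to a surface
#'
#' Minimum point-to-triangle distance over the mesh, with the unit
#' direction from the point to the nearest surface point.  Ties are
#' broken by the lowest triangle index.  A point lying on the surface
#' (distance ~ 0) has no defined direction and is flagged degenerate;
#' downstream angle computations skip flagged records.
#'
#' @param p 3-vector, nm.
#' @param surface a [mesh3()].
#' @return list with `distance` (nm), `direction` (unit 3-vector, or
#'   `NA`s when degenerate), `degenerate` (logical) and `triangle`
#'   (1-based index of the nearest triangle).
#' @export
shortest_path_to_surface <- function(p, surface) {
  stopifnot(length(p) == 3L, inherits(surface, "mesh3"))
  ma <- mesh_arrays(surface)
  res <- cpp_mesh_closest(matrix(as.numeric(p), 1, 3), ma$V, ma$F)
  d <- res$distance[1]
  if (d < 1e-9) {
    return(list(distance = 0, direction = rep(NA_real_, 3),
                degenerate = TRUE, triangle = res$triangle[1] + 1L))
  }
  dir <- (res$nearest[1, ] - as.numeric(p)) / d
  list(distance = d, direction = dir, degenerate = FALSE,
       triangle = res$triangle[1] + 1L)
}

#' Distances from many points to a surface
#'
#' Vectorized distance-only variant of [shortest_path_to_surface()],
#' used for voxel grids and center binning.
#'
#' @param points n x 3 matrix, nm.
#' @param surface a [mesh3()].
#' @return numeric vector of distances, nm.
#' @export
surface_distances <- function(points, surface) {
  ma <- mesh_arrays(surface)
  as.numeric(cpp_mesh_dist(as.matrix(points), ma$V, ma$F))
}
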