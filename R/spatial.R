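#' Summary function container
#'
#' A statistic evaluated on a grid of inter-point distances: the
#' K-function, its L transform, or a mark variogram.
#'
#' @param t distance grid, nm.
#' @param value statistic values.
#' @param kind one of `"K"`, `"L"`, `"variogram_scalar"`,
#'   `"variogram_angle"`.
#' @param n_pairs pairs per bin (variograms only).
#' @return data.frame of class `"summary_function"` with attribute
#'   `kind`.
#' @export
summary_function <- function(t, value, kind, n_pairs = NULL) {
  out <- data.frame(t = t, value = value)
  if (!is.null(n_pairs)) out$n_pairs <- n_pairs
  attr(out, "kind") <- kind
  class(out) <- c("summary_function", "data.frame")
  out
}

#' Empirical K-function without edge correction
#'
#' `K(t) = (1/(N * lambda)) * sum_i N_i(t)` where `N_i(t)` counts the
#' other centers within closed distance `t` of center `i` and
#' `lambda = N / V` is the observed intensity.  No edge correction is
#' applied: the vesicle centers are confined to the synapse and the
#' pattern does not extend beyond it, so the uncorrected estimator is
#' the natural one (a small negative boundary bias relative to the
#' unconfined Poisson benchmark is expected and documented).
#'
#' @param config a [vesicle_configuration()].
#' @param grid distance grid, nm (default 5, 10, ..., 300).
#' @param volume which volume to use in `lambda = N/V`: `"free"`
#'   (interior excluding organelles, default, consistent with the
#'   density-profile convention) or `"total"` (interior including
#'   organelles).
#' @return a [summary_function()] of kind `"K"`.
#' @export
k_function <- function(config, grid = seq(5, 300, by = 5),
                       volume = c("free", "total")) {
  volume <- match.arg(volume)
  if (config$N < 2L) stop("at least 2 vesicles are required")
  V <- domain_volume(config$domain,
                     exclude_organelles = (volume == "free"))
  k_function_points(vesicle_centers(config), V, grid)
}

# internal: K from raw centers and volume (used for null samples too)
k_function_points <- function(centers, V, grid) {
  N <- nrow(centers)
  pd <- sort(as.numeric(dist(centers)))
  npairs <- findInterval(grid, pd)  # pairs with distance <= t (closed)
  value <- V / N^2 * 2 * npairs
  summary_function(grid, value, kind = "K")
}

#' L-function transform
#'
#' `L(t) = (3 K(t) / (4 pi))^(1/3)`, the cube-root normalization under
#' which a homogeneous Poisson process gives `L(t) = t`.
#'
#' @param k a [summary_function()] of kind `"K"`.
#' @return a [summary_function()] of kind `"L"`.
#' @export
l_function <- function(k) {
  stopifnot(inherits(k, "summary_function"))
  if (!identical(attr(k, "kind"), "K"))
    stop("l_function() expects a K-function")
  summary_function(k$t, (3 * k$value / (4 * pi))^(1 / 3), kind = "L")
}

#' Mark specification for variograms
#'
#' Defines the mark attached to each vesicle and its dissimilarity:
#' squared difference for scalar marks (`surface_area`, `E`), axial
#' angle `v(m, m') = acos(|m . m'|)` in degrees for axis marks
#' (`long_axis`, `mid_axis`, `short_axis`).
#'
#' @param mark_name one of `"surface_area"`, `"E"`, `"long_axis"`,
#'   `"mid_axis"`, `"short_axis"`.
#' @return object of class `"mark_spec"`.
#' @export
mark_spec <- function(mark_name = c("surface_area", "E", "long_axis",
                                    "mid_axis", "short_axis")) {
  mark_name <- match.arg(mark_name)
  axis <- mark_name %in% c("long_axis", "mid_axis", "short_axis")
  structure(list(mark_name = mark_name, axis = axis),
            class = "mark_spec")
}

# internal: extract marks; scalar vector or N x 3 axis matrix
extract_marks <- function(config, spec) {
  switch(spec$mark_name,
    surface_area = vapply(config$vesicles, surface_area, 0),
    E = vapply(config$vesicles,
               function(e) e$radii[1] / e$radii[3], 0),
    long_axis = t(vapply(config$vesicles,
                         function(e) e$axes[, 1], numeric(3))),
    mid_axis = t(vapply(config$vesicles,
                        function(e) e$axes[, 2], numeric(3))),
    short_axis = t(vapply(config$vesicles,
                          function(e) e$axes[, 3], numeric(3))))
}

#' Mark variogram
#'
#' For each grid distance `t`, averages the mark dissimilarity over all
#' unordered pairs of centers whose inter-center distance falls in
#' `[t - delta, t + delta]`:
#' `V(t) = (1/N_t) * sum (m - m')^2` for scalar marks (no 1/2 factor),
#' or the mean axial angle between the chosen axes for orientation
#' marks.  Bins with no pairs are reported as `NA`.
#'
#' @param config a [vesicle_configuration()].
#' @param spec a [mark_spec()] (or a mark name).
#' @param grid distance grid, nm.
#' @param delta half-width of the distance bin, nm (default 10).
#' @return a [summary_function()] with `n_pairs`.
#' @export
mark_variogram <- function(config, spec, grid = seq(5, 300, by = 5),
                           delta = 10) {
  if (is.character(spec)) spec <- mark_spec(spec)
  stopifnot(inherits(spec, "mark_spec"))
  if (length(grid) == 0L) stop("empty distance grid")
  if (config$N < 2L) stop("at least 2 vesicles are required")
  if (delta <= 0) stop("delta must be positive")
  marks <- extract_marks(config, spec)
  centers <- vesicle_centers(config)
  mark_variogram_points(centers, marks, spec$axis, grid, delta)
}

# internal: variogram from raw arrays
mark_variogram_points <- function(centers, marks, axis, grid, delta) {
  N <- nrow(centers)
  pd <- as.matrix(dist(centers))
  iu <- which(upper.tri(pd), arr.ind = TRUE)
  d <- pd[iu]
  if (axis) {
    dots <- abs(rowSums(marks[iu[, 1], , drop = FALSE] *
                        marks[iu[, 2], , drop = FALSE]))
    diss <- acos(pmin(dots, 1)) * 180 / pi
  } else {
    diss <- (marks[iu[, 1]] - marks[iu[, 2]])^2
  }
  value <- numeric(length(grid))
  np <- integer(length(grid))
  for (k in seq_along(grid)) {
    sel <- d >= grid[k] - delta & d <= grid[k] + delta
    np[k] <- sum(sel)
    value[k] <- if (np[k] > 0) mean(diss[sel]) else NA_real_
  }
  summary_function(grid, value,
                   kind = if (axis) "variogram_angle"
                          else "variogram_scalar",
                   n_pairs = np)
}
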