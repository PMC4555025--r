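#' Vesicle configuration
#'
#' A marked point pattern inside a synapse domain: the points are the
#' vesicle centers, the marks the associated ellipsoids (size, shape,
#' orientation).
#'
#' @param domain a [synapse_domain()].
#' @param vesicles list of [ellipsoid()] objects.
#' @return object of class `"vesicle_configuration"` with fields
#'   `domain`, `vesicles` and `N`.
#' @export
vesicle_configuration <- function(domain, vesicles) {
  stopifnot(inherits(domain, "synapse_domain"), is.list(vesicles))
  for (v in vesicles) stopifnot(inherits(v, "ellipsoid"))
  structure(list(domain = domain, vesicles = vesicles,
                 N = length(vesicles)),
            class = "vesicle_configuration")
}

#' @export
print.vesicle_configuration <- function(x, ...) {
  cat("vesicle_configuration:", x$N, "vesicles\n")
  print(x$domain)
  invisible(x)
}

#' Vesicle centers as a matrix
#' @param config a [vesicle_configuration()].
#' @return N x 3 matrix, nm.
#' @export
vesicle_centers <- function(config) {
  do.call(rbind, lapply(config$vesicles, `[[`, "center"))
}

# internal: arrays for C++ (centers N x 3, radii N x 3, axes 3 x 3 x N)
config_arrays <- function(config) {
  N <- config$N
  centers <- vesicle_centers(config)
  radii <- do.call(rbind, lapply(config$vesicles, `[[`, "radii"))
  axes <- array(0, dim = c(3, 3, N))
  for (i in seq_len(N)) axes[, , i] <- config$vesicles[[i]]$axes
  list(centers = centers, radii = radii, axes = axes)
}

# internal: rebuild configuration from chain state (row = center + 9 axes)
config_from_state <- function(domain, radii, state) {
  N <- nrow(radii)
  ves <- vector("list", N)
  for (i in seq_len(N)) {
    ves[[i]] <- ellipsoid(center = state$centers[i, ],
                          radii = radii[i, ],
                          axes = state$axes[, (3 * i - 2):(3 * i)])
  }
  vesicle_configuration(domain, ves)
}

#' Verify the hard-core constraints of a configuration
#'
#' Checks, with the exact predicates, that no two ellipsoids overlap and
#' that no ellipsoid intersects the membrane or any obstacle (and that
#' every center lies in the free interior).
#'
#' @param config a [vesicle_configuration()].
#' @param margin near-tangency tolerance, nm (see
#'   [ellipsoids_overlap()]).
#' @return list with `ok` (logical), `pair_violations` (k x 2 matrix of
#'   vesicle index pairs) and `domain_violations` (indices of vesicles
#'   meeting the membrane or an obstacle or lying outside).
#' @export
verify_configuration <- function(config, margin = 0.1) {
  arr <- config_arrays(config)
  pv <- cpp_pair_violations(arr$centers, arr$radii, arr$axes, margin)
  dviol <- integer(0)
  inside <- points_in_domain(arr$centers, config$domain)
  for (i in seq_len(config$N)) {
    e <- config$vesicles[[i]]
    bad <- !inside[i] ||
      ellipsoid_intersects_surface(e, config$domain$membrane, margin)
    if (!bad && length(config$domain$obstacles)) {
      for (ob in config$domain$obstacles) {
        if (ellipsoid_intersects_surface(e, ob, margin)) {
          bad <- TRUE
          break
        }
      }
    }
    if (bad) dviol <- c(dviol, i)
  }
  list(ok = nrow(pv) == 0L && length(dviol) == 0L,
       pair_violations = pv, domain_violations = dviol)
}

#' Convert a configuration to an ellipsoid table
#'
#' One row per vesicle with the columns of the on-disk CSV format:
#' `center_x, center_y, center_z, a, b, c, ax1_x ... ax3_z` (nm).
#'
#' @param x a [vesicle_configuration()] (or list of ellipsoids).
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.vesicle_configuration <- function(x, ...) {
  ellipsoid_table(x$vesicles)
}

ellipsoid_table <- function(vesicles) {
  rows <- lapply(vesicles, function(e) {
    ax <- e$axes
    data.frame(center_x = e$center[1], center_y = e$center[2],
               center_z = e$center[3], a = e$radii[1], b = e$radii[2],
               c = e$radii[3], ax1_x = ax[1, 1], ax1_y = ax[2, 1],
               ax1_z = ax[3, 1], ax2_x = ax[1, 2], ax2_y = ax[2, 2],
               ax2_z = ax[3, 2], ax3_x = ax[1, 3], ax3_y = ax[2, 3],
               ax3_z = ax[3, 3])
  })
  do.call(rbind, rows)
}
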