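#' Specification for the synthetic synapse generator
#'
#' Defines the study conditions emulated by the generator: an enclosed
#' pre-synaptic compartment with an active-zone patch, optional interior
#' organelles, and a population of non-overlapping ellipsoidal vesicles
#' with controllable size, shape, interaction and orientation structure.
#'
#' Defaults reflect typical hippocampal synapses reconstructed at ~5 nm
#' isotropic resolution: a 600 x 600 x 400 nm compartment, vesicle
#' equivalent diameters of 40 +/- 5 nm (truncated normal, sd 2.5 nm,
#' truncated at +/- 3 sd), and mean aspect ratios a/c of about 1.96
#' (oblate mode) or 2.60 (cigar mode) as reported for asymmetric and
#' symmetric synapses respectively.
#'
#' @param domain_dims interior box dimensions (x, y, z), nm.
#' @param az_fraction linear fraction of the `z = 0` face used as the
#'   (centered, square) active-zone patch.
#' @param n_organelles number of spherical organelle obstacles.
#' @param organelle_radius radius range (min, max) of organelles, nm.
#' @param n_vesicles target vesicle count.
#' @param diameter_mean,diameter_sd equivalent-diameter distribution, nm.
#' @param shape_mode `"sphere"`, `"oblate"` or `"cigar"`.
#' @param aspect_mean mean elongation `a/c` (ignored for spheres);
#'   defaults to 1.96 for oblate, 2.60 for cigar.
#' @param aspect_sdlog log-scale spread of the elongation (log-normal).
#' @param interaction `"hardcore"` (non-overlap only) or `"repulsive"`
#'   (extra surface gap of `repulsion_range` nm enforced).
#' @param repulsion_range extra hard-core gap, nm.
#' @param alignment `"random"` or `"field"` (long axes concentrated
#'   around a common reference direction).
#' @param alignment_strength von Mises-Fisher concentration of the
#'   alignment field.
#' @param alignment_direction unit 3-vector reference direction.
#' @param gradient_beta log-linear density trend per nm of distance to
#'   the active zone (0 = homogeneous).
#' @param relax_moves Metropolis relaxation proposals after sequential
#'   placement (default `50 * n_vesicles`).  Relaxation preserves the
#'   interaction constraint and equilibrates the pattern to the uniform
#'   (Gibbs hard-core) law, removing the insertion-order bias of
#'   sequential placement.
#' @param seed integer seed.
#' @return object of class `"generator_spec"`.
#' @export
generator_spec <- function(domain_dims = c(600, 600, 400),
                           az_fraction = 0.5, n_organelles = 0L,
                           organelle_radius = c(60, 100),
                           n_vesicles = 100L, diameter_mean = 40,
                           diameter_sd = 2.5,
                           shape_mode = c("oblate", "sphere", "cigar"),
                           aspect_mean = NULL, aspect_sdlog = 0.18,
                           interaction = c("hardcore", "repulsive"),
                           repulsion_range = 20,
                           alignment = c("random", "field"),
                           alignment_strength = 50,
                           alignment_direction = c(0, 0, 1),
                           gradient_beta = 0, relax_moves = NULL,
                           seed = NULL) {
  shape_mode <- match.arg(shape_mode)
  interaction <- match.arg(interaction)
  alignment <- match.arg(alignment)
  if (is.null(aspect_mean))
    aspect_mean <- switch(shape_mode, sphere = 1, oblate = 1.96,
                          cigar = 2.60)
  stopifnot(all(domain_dims > 0), diameter_mean - 3 * diameter_sd > 0,
            az_fraction > 0, az_fraction <= 1)
  structure(list(domain_dims = as.numeric(domain_dims),
                 az_fraction = az_fraction,
                 n_organelles = as.integer(n_organelles),
                 organelle_radius = organelle_radius,
                 n_vesicles = as.integer(n_vesicles),
                 diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd, shape_mode = shape_mode,
                 aspect_mean = aspect_mean, aspect_sdlog = aspect_sdlog,
                 interaction = interaction,
                 repulsion_range = repulsion_range,
                 alignment = alignment,
                 alignment_strength = alignment_strength,
                 alignment_direction = alignment_direction /
                   sqrt(sum(alignment_direction^2)),
                 gradient_beta = gradient_beta,
                 relax_moves = relax_moves, seed = seed),
            class = "generator_spec")
}

#' Sample vesicle sizes and shapes from a generator specification
#'
#' Draws equivalent diameters from the truncated normal size
#' distribution and converts them to ordered radii according to the
#' shape mode: elongation `a/c` is log-normal with the specified mean,
#' and its logarithm is split between `a/b` and `b/c` with a fixed
#' fraction (0.41 for oblate, giving `a/b < b/c` and negative mode of
#' anisotropy; 0.70 for cigar, giving positive MO).  The radii preserve
#' the drawn equivalent diameter exactly: `2 * (abc)^(1/3) = D`.
#'
#' @param spec a [generator_spec()].
#' @param n number of vesicles to draw.
#' @return n x 3 matrix of radii `(a, b, c)`, nm.
#' @export
sample_vesicle_shapes <- function(spec, n) {
  D <- rtruncnorm(n, spec$diameter_mean, spec$diameter_sd,
                  lower = spec$diameter_mean - 3 * spec$diameter_sd,
                  upper = spec$diameter_mean + 3 * spec$diameter_sd)
  if (spec$shape_mode == "sphere") {
    r <- D / 2
    return(cbind(a = r, b = r, c = r))
  }
  split <- if (spec$shape_mode == "oblate") 0.41 else 0.70
  # log-normal with arithmetic mean aspect_mean
  mlog <- log(spec$aspect_mean) - spec$aspect_sdlog^2 / 2
  E <- exp(rnorm(n, mlog, spec$aspect_sdlog))
  E <- pmax(E, 1)
  rab <- E^split
  rbc <- E^(1 - split)
  # c from the volume constraint abc = (D/2)^3, a = E*c, b = rbc*c
  cc <- (D / 2) / (E * rbc)^(1 / 3)
  b <- rbc * cc
  a <- E * cc
  cbind(a = a, b = b, c = cc)
}

# internal: truncated normal by inverse-cdf sampling
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# internal: uniform random rotation matrix (quaternion method)
random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),
           2 * (x * z - w * y), 2 * (x * y - w * z),
           1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x),
           1 - 2 * (x^2 + y^2)), 3, 3)
}

# internal: unit vector from a von Mises-Fisher distribution
rvmf_one <- function(mu, kappa) {
  if (kappa <= 0) {
    v <- rnorm(3)
    return(v / sqrt(sum(v^2)))
  }
  u <- runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- runif(1, 0, 2 * pi)
  # orthonormal basis around mu
  tmp <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- tmp - sum(tmp * mu) * mu
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(mu[2] * b1[3] - mu[3] * b1[2], mu[3] * b1[1] - mu[1] * b1[3],
          mu[1] * b1[2] - mu[2] * b1[1])
  s <- sqrt(max(0, 1 - w^2))
  w * mu + s * (cos(phi) * b1 + sin(phi) * b2)
}

# internal: orthonormal frame whose first column is v, the rest random
frame_around <- function(v) {
  phi <- runif(1, 0, 2 * pi)
  tmp <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- tmp - sum(tmp * v) * v
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(v[2] * b1[3] - v[3] * b1[2], v[3] * b1[1] - v[1] * b1[3],
          v[1] * b1[2] - v[2] * b1[1])
  cbind(v, cos(phi) * b1 + sin(phi) * b2,
        -sin(phi) * b1 + cos(phi) * b2)
}

#' Build the synapse domain described by a generator specification
#'
#' Box membrane with a centered square active-zone patch on the
#' `z = 0` face and optional spherical organelles placed in the
#' interior.
#'
#' @param spec a [generator_spec()].
#' @return a [synapse_domain()].
#' @export
build_domain <- function(spec) {
  dd <- spec$domain_dims
  membrane <- box_mesh(c(0, 0, 0), dd)
  half <- spec$az_fraction / 2
  az <- rect_patch_mesh(dd[1] * (0.5 - half), dd[1] * (0.5 + half),
                        dd[2] * (0.5 - half), dd[2] * (0.5 + half),
                        0, n = 4L)
  obstacles <- list()
  if (spec$n_organelles > 0) {
    for (k in seq_len(spec$n_organelles)) {
      r <- runif(1, spec$organelle_radius[1], spec$organelle_radius[2])
      ctr <- c(runif(1, r + 10, dd[1] - r - 10),
               runif(1, r + 10, dd[2] - r - 10),
               runif(1, max(r + 10, dd[3] / 2), dd[3] - r - 10))
      obstacles[[k]] <- icosphere_mesh(ctr, r, subdiv = 1L)
    }
  }
  synapse_domain(membrane, az, obstacles, check = FALSE)
}

#' Generate a synthetic vesicle configuration
#'
#' Places `n_vesicles` ellipsoids with sizes, shapes and orientations
#' drawn from the specification by sequential random insertion under the
#' chosen interaction (hard core, or hard core plus an extra repulsion
#' gap), followed by Metropolis relaxation sweeps under the same
#' constraint.  A density gradient, when requested, thins candidate
#' positions with probability `exp(gradient_beta * d)` (normalized), `d`
#' being the distance to the active zone.  Reproducible from `seed`.
#'
#' @param spec a [generator_spec()].
#' @param max_tries proposal budget per vesicle during insertion.
#' @return a [vesicle_configuration()] satisfying all constraints.
#' @export
generate_configuration <- function(spec, max_tries = 2000L) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  domain <- build_domain(spec)
  dd <- spec$domain_dims
  margin <- 0.1 + if (spec$interaction == "repulsive")
    spec$repulsion_range else 0

  radii <- sample_vesicle_shapes(spec, spec$n_vesicles)
  # feasibility of the requested packing (nominal vesicle incl. gap)
  vves <- 4 / 3 * pi * (spec$diameter_mean / 2 + margin / 2)^3
  vfree <- prod(dd)
  if (spec$n_vesicles * vves > 0.3 * vfree)
    stop("requested packing too dense: expected vesicle volume ",
         "exceeds 30% of the free domain volume")

  axes <- vector("list", spec$n_vesicles)
  for (i in seq_len(spec$n_vesicles)) {
    axes[[i]] <- if (spec$alignment == "field")
      frame_around(rvmf_one(spec$alignment_direction,
                            spec$alignment_strength))
    else random_rotation_matrix()
  }

  mem <- mesh_arrays(domain$membrane)
  obs <- meshes_concat(domain$obstacles)
  placed_c <- matrix(0, 0, 3)
  placed_r <- matrix(0, 0, 3)
  placed_a <- array(0, dim = c(3, 3, 0))
  for (i in seq_len(spec$n_vesicles)) {
    ri <- sort(radii[i, ], decreasing = TRUE)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- runif(3) * dd
      if (spec$gradient_beta != 0) {
        d <- surface_distances(matrix(cand, 1, 3),
                               domain$active_zone)
        keep_p <- exp(spec$gradient_beta * d)
        ref <- max(exp(spec$gradient_beta *
                       c(0, sqrt(sum(dd^2)))))
        if (runif(1) > keep_p / ref) next
      }
      if (cpp_candidate_feasible(cand, ri, axes[[i]], placed_c,
                                 placed_r, placed_a, mem$V, mem$F,
                                 obs$V, obs$F, margin)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("packing infeasible: placed ", i - 1L, " of ",
           spec$n_vesicles, " vesicles within the proposal budget")
    placed_c <- rbind(placed_c, cand)
    placed_r <- rbind(placed_r, ri)
    placed_a <- array(c(placed_a, axes[[i]]), dim = c(3, 3, i))
  }

  relax <- if (is.null(spec$relax_moves)) 50L * spec$n_vesicles
           else as.integer(spec$relax_moves)
  if (relax > 0 && spec$gradient_beta == 0) {
    res <- cpp_run_chain(placed_c, placed_r, placed_a, mem$V, mem$F,
                         obs$V, obs$F, c(0, 0, 0), dd, margin, 1L,
                         relax, 0L, FALSE, -1)
    placed_c <- matrix(res$centers[, , 1], ncol = 3)
  }

  ves <- vector("list", spec$n_vesicles)
  for (i in seq_len(spec$n_vesicles)) {
    ves[[i]] <- ellipsoid(placed_c[i, ], placed_r[i, ],
                          placed_a[, , i])
  }
  vesicle_configuration(domain, ves)
}
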