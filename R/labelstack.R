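#' Voxelize a configuration into a label stack
#'
#' Rasterizes a vesicle configuration and its domain into an integer
#' label volume at isotropic resolution, emulating the annotated
#' FIB-SEM volumes that the analysis normally starts from.  Labels (see
#' `default_label_map()`): exterior 0, cytosol 1, membrane shell 2,
#' active zone 3, organelles 4, vesicle interiors 10, and one boundary
#' label per vesicle starting at `vesicle_boundary_base` (100), so that
#' instances can be separated without connected-component analysis.
#' Priority where classes meet: organelles > vesicle boundary > vesicle
#' interior > membrane/active zone > cytosol.
#'
#' A vesicle's boundary voxels are those whose center lies within half a
#' voxel diagonal of the ellipsoid surface (estimated radially from the
#' quadratic form), which yields a closed one-voxel shell at the default
#' resolution.  Vesicles smaller than two voxels across are skipped with
#' a warning.
#'
#' @param config a [vesicle_configuration()].
#' @param voxel_size voxel edge, nm (default 5).
#' @return object of class `"label_stack"`: list with `labels` (integer
#'   array indexed `[x, y, z]`), `voxel_size`, `origin` and
#'   `label_map`.
#' @export
voxelize <- function(config, voxel_size = 5) {
  stopifnot(voxel_size > 0)
  domain <- config$domain
  bb <- mesh_bbox(domain$membrane)
  origin <- bb$lo
  n <- pmax(1L, as.integer(ceiling((bb$hi - bb$lo) / voxel_size)))
  centers <- voxel_center_grid(n, origin, voxel_size)
  lm <- default_label_map()

  mem <- mesh_arrays(domain$membrane)
  inside <- as.logical(cpp_inside_mesh(centers, mem$V, mem$F))
  lab <- ifelse(inside, lm$cytosol, lm$exterior)

  memd <- as.numeric(cpp_mesh_dist(centers, mem$V, mem$F))
  shell <- inside & memd < voxel_size
  lab[shell] <- lm$membrane
  azd <- surface_distances(centers[shell, , drop = FALSE],
                           domain$active_zone)
  shell_idx <- which(shell)
  lab[shell_idx[azd < voxel_size]] <- lm$active_zone

  half_diag <- voxel_size * sqrt(3) / 2
  gx <- origin[1] + (seq_len(n[1]) - 0.5) * voxel_size
  gy <- origin[2] + (seq_len(n[2]) - 0.5) * voxel_size
  gz <- origin[3] + (seq_len(n[3]) - 0.5) * voxel_size
  arr <- array(lab, dim = n)
  skipped <- 0L
  for (i in seq_len(config$N)) {
    e <- config$vesicles[[i]]
    if (2 * e$radii[3] < 2 * voxel_size) {
      skipped <- skipped + 1L
      next
    }
    rmax <- e$radii[1] + 2 * voxel_size
    ix <- which(gx >= e$center[1] - rmax & gx <= e$center[1] + rmax)
    iy <- which(gy >= e$center[2] - rmax & gy <= e$center[2] + rmax)
    iz <- which(gz >= e$center[3] - rmax & gz <= e$center[3] + rmax)
    if (!length(ix) || !length(iy) || !length(iz)) next
    sub <- as.matrix(expand.grid(x = gx[ix], y = gy[iy], z = gz[iz]))
    u <- t(t(e$axes) %*% (t(sub) - e$center))
    q <- sqrt((u[, 1] / e$radii[1])^2 + (u[, 2] / e$radii[2])^2 +
              (u[, 3] / e$radii[3])^2)
    rr <- sqrt(rowSums(u^2))
    dist_est <- abs(rr - rr / pmax(q, 1e-12))
    on_boundary <- dist_est <= half_diag
    in_interior <- q < 1 & !on_boundary
    sel <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    if (any(in_interior))
      arr[sel[in_interior, , drop = FALSE]] <- lm$vesicle_interior
    if (any(on_boundary))
      arr[sel[on_boundary, , drop = FALSE]] <-
        lm$vesicle_boundary_base + (i - 1L)
  }
  if (skipped > 0)
    warning(skipped, " vesicle(s) smaller than 2 voxels across skipped")

  if (length(domain$obstacles)) {
    ob <- meshes_concat(domain$obstacles)
    org <- as.logical(cpp_inside_mesh(centers, ob$V, ob$F))
    arr[array(org, dim = n)] <- lm$organelle
  }
  structure(list(labels = arr, voxel_size = voxel_size,
                 origin = origin, label_map = lm),
            class = "label_stack")
}

#' Default structure-to-label map
#' @return named list of integer labels; vesicle boundary labels are
#'   `vesicle_boundary_base + i - 1` for vesicle `i`.
#' @export
default_label_map <- function() {
  list(exterior = 0L, cytosol = 1L, membrane = 2L, active_zone = 3L,
       organelle = 4L, vesicle_interior = 10L,
       vesicle_boundary_base = 100L)
}

#' @export
print.label_stack <- function(x, ...) {
  cat("label_stack:", paste(dim(x$labels), collapse = " x "),
      "voxels @", x$voxel_size, "nm;",
      length(unique(as.vector(x$labels))), "distinct labels\n")
  invisible(x)
}

#' Fit ellipsoids to every vesicle in a label stack
#'
#' Groups boundary voxels by their per-instance label and fits an
#' ellipsoid to each group.  Instances whose fit fails (too few voxels,
#' or a degenerate quadric) are dropped with a warning.
#'
#' @param stack a [voxelize()] result (or any `label_stack`).
#' @param domain optional [synapse_domain()] for the returned
#'   configuration; defaults to a box spanning the stack.
#' @return a [vesicle_configuration()].
#' @export
fit_configuration_from_stack <- function(stack, domain = NULL) {
  lm <- stack$label_map
  labs <- sort(unique(as.vector(stack$labels)))
  blabs <- labs[labs >= lm$vesicle_boundary_base]
  if (is.null(domain)) {
    dd <- dim(stack$labels) * stack$voxel_size
    membrane <- box_mesh(stack$origin, stack$origin + dd)
    az <- rect_patch_mesh(stack$origin[1], stack$origin[1] + dd[1],
                          stack$origin[2], stack$origin[2] + dd[2],
                          stack$origin[3], n = 2L)
    domain <- synapse_domain(membrane, az, check = FALSE)
  }
  ves <- list()
  failed <- 0L
  for (bl in blabs) {
    pts <- voxel_boundary_to_points(stack$labels, bl,
                                    stack$voxel_size)
    pts <- sweep(pts, 2, stack$origin, "+")
    e <- tryCatch(fit_ellipsoid(pts),
                  vesicle3d_fit_failure = function(cond) NULL)
    if (is.null(e)) failed <- failed + 1L else ves <- c(ves, list(e))
  }
  if (failed > 0)
    warning(failed, " vesicle fit(s) failed and were dropped")
  vesicle_configuration(domain, ves)
}
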