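#' Synapse domain
#'
#' The state space for vesicle centers: a watertight pre-synaptic
#' membrane mesh, an active-zone surface patch, and optional interior
#' organelle obstacles (mitochondria, lysosome).  A voxelized interior
#' mask can be attached for volume computations.
#'
#' @param membrane closed (watertight) [mesh3()], nm.
#' @param active_zone open [mesh3()] patch lying on the membrane.
#' @param obstacles list of closed [mesh3()] obstacles inside the
#'   membrane.
#' @param check validate watertightness of membrane and obstacles.
#' @return object of class `"synapse_domain"`.
#' @export
synapse_domain <- function(membrane, active_zone, obstacles = list(),
                           check = TRUE) {
  stopifnot(inherits(membrane, "mesh3"), inherits(active_zone, "mesh3"))
  if (check) {
    if (!mesh_is_watertight(membrane))
      stop("membrane mesh is not watertight")
    for (ob in obstacles)
      if (!mesh_is_watertight(ob))
        stop("obstacle mesh is not watertight")
  }
  structure(list(membrane = membrane, active_zone = active_zone,
                 obstacles = obstacles, voxel_mask = NULL),
            class = "synapse_domain")
}

#' @export
print.synapse_domain <- function(x, ...) {
  bb <- mesh_bbox(x$membrane)
  cat("synapse_domain: bbox",
      paste(signif(bb$hi - bb$lo, 4), collapse = " x "), "nm,",
      length(x$obstacles), "obstacle(s),",
      if (is.null(x$voxel_mask)) "no voxel mask"
      else paste0("voxel mask ", paste(dim(x$voxel_mask$interior),
                                       collapse = "x"), " @ ",
                  x$voxel_mask$voxel_size, " nm"), "\n")
  invisible(x)
}

#' Voxelize the interior of a domain
#'
#' Builds a boolean interior mask on a regular grid of voxel centers
#' (array indexed `[x, y, z]`, world position of voxel center `(index -
#' 0.5) * voxel_size + origin` with 1-based indices), plus a mask of
#' voxels inside any organelle.  Attach the result to the domain to
#' enable volume computations ([domain_volume()], [compute_bands()]).
#'
#' @param domain a [synapse_domain()].
#' @param voxel_size voxel edge, nm (default 5, the typical FIB-SEM
#'   resolution).
#' @return the domain with a `voxel_mask` field: list of `interior`
#'   (logical array), `organelle` (logical array), `origin` (3-vector)
#'   and `voxel_size`.
#' @export
voxelize_domain <- function(domain, voxel_size = 5) {
  bb <- mesh_bbox(domain$membrane)
  origin <- bb$lo
  n <- pmax(1L, as.integer(ceiling((bb$hi - bb$lo) / voxel_size)))
  centers <- voxel_center_grid(n, origin, voxel_size)
  mem <- mesh_arrays(domain$membrane)
  inside <- cpp_inside_mesh(centers, mem$V, mem$F)
  org <- rep(FALSE, nrow(centers))
  if (length(domain$obstacles)) {
    ob <- meshes_concat(domain$obstacles)
    org <- as.logical(cpp_inside_mesh(centers, ob$V, ob$F))
  }
  domain$voxel_mask <- list(
    interior = array(inside, dim = n),
    organelle = array(org & inside, dim = n),
    origin = origin, voxel_size = voxel_size)
  domain
}

# internal: matrix of voxel-center world coordinates for dims n
voxel_center_grid <- function(n, origin, voxel_size) {
  gx <- origin[1] + (seq_len(n[1]) - 0.5) * voxel_size
  gy <- origin[2] + (seq_len(n[2]) - 0.5) * voxel_size
  gz <- origin[3] + (seq_len(n[3]) - 0.5) * voxel_size
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

#' Interior volume of a domain
#'
#' Volume by voxel counting when a mask is attached; for a plain box
#' membrane without obstacles the exact box volume is used.
#'
#' @param domain a [synapse_domain()].
#' @param exclude_organelles subtract organelle volume (the convention
#'   used for intensity and density denominators).
#' @return volume, nm^3.
#' @export
domain_volume <- function(domain, exclude_organelles = TRUE) {
  if (!is.null(domain$voxel_mask)) {
    vm <- domain$voxel_mask
    nvox <- sum(vm$interior) -
      if (exclude_organelles) sum(vm$organelle) else 0
    return(nvox * vm$voxel_size^3)
  }
  box <- attr(domain$membrane, "box")
  if (!is.null(box) && length(domain$obstacles) == 0L)
    return(prod(box$hi - box$lo))
  dv <- voxelize_domain(domain, voxel_size = 5)
  domain_volume(dv, exclude_organelles)
}

#' Test points for membership in the free domain interior
#'
#' @param points n x 3 matrix, nm.
#' @param domain a [synapse_domain()].
#' @return logical vector: inside the membrane and outside all
#'   organelles.
#' @export
points_in_domain <- function(points, domain) {
  P <- as.matrix(points)
  mem <- mesh_arrays(domain$membrane)
  ins <- as.logical(cpp_inside_mesh(P, mem$V, mem$F))
  if (length(domain$obstacles)) {
    ob <- meshes_concat(domain$obstacles)
    ins <- ins & !as.logical(cpp_inside_mesh(P, ob$V, ob$F))
  }
  ins
}
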