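#' Write / read ellipsoid tables as CSV
#'
#' On-disk format: one row per vesicle with columns
#' `center_x, center_y, center_z, a, b, c, ax1_x ... ax3_z` (nm).
#'
#' @param x a [vesicle_configuration()] or list of [ellipsoid()]s.
#' @param path file path.
#' @return `write_ellipsoid_csv()` returns `path` invisibly;
#'   `read_ellipsoid_csv()` returns a list of ellipsoids, or a
#'   [vesicle_configuration()] when `domain` is supplied.
#' @export
write_ellipsoid_csv <- function(x, path) {
  tab <- if (inherits(x, "vesicle_configuration")) as.data.frame(x)
         else ellipsoid_table(x)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ellipsoid_csv
#' @param domain optional [synapse_domain()].
#' @export
read_ellipsoid_csv <- function(path, domain = NULL) {
  tab <- read.csv(path)
  need <- c("center_x", "center_y", "center_z", "a", "b", "c",
            "ax1_x", "ax1_y", "ax1_z", "ax2_x", "ax2_y", "ax2_z",
            "ax3_x", "ax3_y", "ax3_z")
  if (!all(need %in% names(tab)))
    stop("missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  ves <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    axes <- cbind(c(r$ax1_x, r$ax1_y, r$ax1_z),
                  c(r$ax2_x, r$ax2_y, r$ax2_z),
                  c(r$ax3_x, r$ax3_y, r$ax3_z))
    ellipsoid(c(r$center_x, r$center_y, r$center_z),
              c(r$a, r$b, r$c), axes)
  })
  if (is.null(domain)) ves else vesicle_configuration(domain, ves)
}

#' Write / read label stacks as multipage TIFF
#'
#' One 16-bit page per z-slice; within a page, rows are y and columns x.
#' The in-memory convention is `(z, y, x)` for the raw pages and
#' `[x, y, z]` for the working array; [stack_pages_to_array()] is the
#' single conversion point.  Voxel size is not stored in the TIFF and
#' must be supplied on read (config wins over metadata by convention).
#'
#' @param stack a `label_stack` (see [voxelize()]).
#' @param path file path.
#' @return `write_label_stack()` returns `path` invisibly.
#' @export
write_label_stack <- function(stack, path) {
  n <- dim(stack$labels)
  if (max(stack$labels) > 65535L)
    stop("labels exceed the 16-bit range")
  pages <- lapply(seq_len(n[3]), function(z)
    t(stack$labels[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_stack
#' @param voxel_size voxel edge, nm.
#' @param label_map label map; defaults to [default_label_map()].
#' @param origin world coordinate of the corner of voxel (1,1,1), nm.
#' @export
read_label_stack <- function(path, voxel_size = 5,
                             label_map = default_label_map(),
                             origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L)
    stop("multi-channel (RGB) TIFF is not a label volume")
  if (!all(vapply(pages, function(p) all(p == round(p)), TRUE)))
    stop("non-integer pixel values: not a label volume")
  arr <- stack_pages_to_array(pages)
  known <- unlist(label_map[c("exterior", "cytosol", "membrane",
                              "active_zone", "organelle",
                              "vesicle_interior")])
  present <- unique(as.vector(arr))
  unknown <- setdiff(present,
                     c(known, present[present >=
                                      label_map$vesicle_boundary_base]))
  if (length(unknown))
    warning("labels absent from the map: ",
            paste(sort(unknown), collapse = ", "))
  structure(list(labels = arr, voxel_size = voxel_size,
                 origin = as.numeric(origin), label_map = label_map),
            class = "label_stack")
}

#' Convert TIFF pages to the working array
#'
#' Centralized axis conversion: a list of pages (page = z, rows = y,
#' columns = x) becomes the working integer array indexed `[x, y, z]`.
#'
#' @param pages list of matrices.
#' @return 3D integer array.
#' @export
stack_pages_to_array <- function(pages) {
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0L, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) arr[, , z] <- as.integer(t(pages[[z]]))
  arr
}

#' Write a summary function (or envelope) to CSV
#' @param x a [summary_function()] or [envelope()] result.
#' @param path file path.
#' @export
write_summary_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the pipeline
#'
#' Validates the inputs of [run_pipeline()]: exactly one input mode
#' (a label stack path XOR an ellipsoid CSV) and existing files.
#'
#' @param stack_path multipage TIFF of labels, or `NULL`.
#' @param csv_path ellipsoid CSV, or `NULL`.
#' @param domain a [synapse_domain()] (required with `csv_path`;
#'   optional with a stack from [voxelize()]).
#' @param voxel_size nm, for reading the stack.
#' @param band_thickness nm.
#' @param grid distance grid for spatial statistics, nm.
#' @param delta variogram bin half-width, nm.
#' @param n_sim null-model simulations for envelopes.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(stack_path = NULL, csv_path = NULL,
                       domain = NULL, voxel_size = 5,
                       band_thickness = 50,
                       grid = seq(5, 300, by = 5), delta = 10,
                       n_sim = 100, seed = 1, out_dir = tempfile()) {
  if (is.null(stack_path) == is.null(csv_path))
    stop("exactly one of stack_path or csv_path must be given")
  for (p in c(stack_path, csv_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if (!is.null(csv_path) && is.null(domain))
    stop("a domain is required with an ellipsoid CSV input")
  structure(list(stack_path = stack_path, csv_path = csv_path,
                 domain = domain, voxel_size = voxel_size,
                 band_thickness = band_thickness, grid = grid,
                 delta = delta, n_sim = n_sim, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one synapse: ellipsoid fitting (for stack
#' input), shape and orientation statistics with KS uniformity tests,
#' density bands with the quasi-Poisson distance model, K/L functions
#' and mark variograms, hard-core null simulation, and envelopes.
#' Writes per-vesicle CSV, summary JSON, envelope CSVs and plots under
#' `out_dir`, plus a manifest recording the package version, seed and
#' per-stage status.  Deterministic for a fixed config and seed.
#'
#' @param config a [run_config()], or a [vesicle_configuration()] (then
#'   the remaining arguments of [run_config()] may be passed via
#'   `...`).
#' @param ... passed to [run_config()] when `config` is a
#'   configuration.
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "vesicle_configuration")) {
    tmp <- tempfile(fileext = ".csv")
    write_ellipsoid_csv(config, tmp)
    cfg <- run_config(csv_path = tmp, domain = config$domain, ...)
  } else cfg <- config
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "vesicle3d",
                   version = as.character(
                     utils::packageVersion("vesicle3d")),
                   seed = cfg$seed, stages = list())
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "FAILED",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "OK",
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  vc <- stage("load", {
    if (!is.null(cfg$stack_path)) {
      stk <- read_label_stack(cfg$stack_path, cfg$voxel_size)
      fit_configuration_from_stack(stk, cfg$domain)
    } else {
      read_ellipsoid_csv(cfg$csv_path, cfg$domain)
    }
  })

  shp <- stage("shape", {
    s <- shape_summary_table(vc)
    o <- orientation_table(vc)
    per <- cbind(as.data.frame(vc), s, o)
    write.csv(per, file.path(cfg$out_dir, "vesicles.csv"),
              row.names = FALSE)
    ks <- lapply(c("angle_long", "angle_mid", "angle_short"),
                 function(a) ks_uniformity_test(o[[a]][!o$degenerate]))
    names(ks) <- c("long", "mid", "short")
    list(shape = s, orientation = o, ks = ks)
  })

  dens <- stage("density", {
    dom <- vc$domain
    if (is.null(dom$voxel_mask)) {
      dom <- voxelize_domain(dom, cfg$voxel_size)
      vc$domain <- dom
    }
    bands <- compute_bands(vc, cfg$band_thickness)
    write_summary_csv(bands, file.path(cfg$out_dir, "bands.csv"))
    gfit <- fit_density_glm(bands)
    list(bands = bands, glm = gfit)
  })

  spat <- stage("spatial", {
    K <- k_function(vc, cfg$grid)
    L <- l_function(K)
    vg_sa <- mark_variogram(vc, "surface_area", cfg$grid, cfg$delta)
    vg_ax <- mark_variogram(vc, "long_axis", cfg$grid, cfg$delta)
    list(K = K, L = L, vg_surface = vg_sa, vg_long = vg_ax)
  })

  nullm <- stage("null_model", {
    sample_null(vc, mcmc_settings(n_samples = cfg$n_sim,
                                  seed = cfg$seed))
  })

  envs <- stage("envelopes", {
    V <- domain_volume(vc$domain)
    envL <- envelope(spat$L, nullm, function(cf)
      l_function(k_function(cf, cfg$grid)))
    envV <- envelope(spat$vg_long, nullm, function(cf)
      mark_variogram(cf, "long_axis", cfg$grid, cfg$delta))
    write_summary_csv(envL, file.path(cfg$out_dir, "envelope_L.csv"))
    write_summary_csv(envV,
                      file.path(cfg$out_dir,
                                "envelope_vg_long.csv"))
    grDevices::png(file.path(cfg$out_dir, "envelope_L.png"), 700, 500)
    plot(envL, main = "L-function vs. hard-core null")
    grDevices::dev.off()
    grDevices::png(file.path(cfg$out_dir, "envelope_vg_long.png"),
                   700, 500)
    plot(envV, main = "Long-axis angle variogram vs. null")
    grDevices::dev.off()
    list(L = envL, vg_long = envV)
  })

  summary_json <- list(
    n_vesicles = vc$N,
    mean_surface_area = mean(shp$shape$A),
    mean_E = mean(shp$shape$E),
    mean_ratio_ab = mean(shp$shape$ratio_ab),
    mean_ratio_bc = mean(shp$shape$ratio_bc),
    mean_FA = mean(shp$shape$FA),
    mean_MO = mean(shp$shape$MO, na.rm = TRUE),
    ks = lapply(shp$ks, function(k) list(D = k$D, p = k$p)),
    density_glm = list(alpha = dens$glm$alpha, beta = dens$glm$beta,
                       se_beta = dens$glm$se_beta,
                       dispersion = dens$glm$dispersion,
                       p_beta = dens$glm$p_beta),
    null_acceptance_rate = nullm$acceptance_rate,
    seed = cfg$seed)
  jsonlite::write_json(summary_json,
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(cfg$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(configuration = vc, shape = shp, density = dens,
                 spatial = spat, null = nullm, envelopes = envs,
                 manifest = manifest))
}
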