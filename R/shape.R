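#' Size and shape summary of an ellipsoid
#'
#' Computes the size and size-independent shape characteristics of a
#' vesicle from its ordered radii `a >= b >= c`:
#' \itemize{
#'   \item approximate surface area `A` (see [surface_area()]);
#'   \item elongation `E = a/c` and the ratios `a/b`, `b/c`;
#'   \item fractional anisotropy
#'     `FA = sqrt(3*mu2 / (2*(mu1^2 + mu2)))`, zero for a sphere;
#'   \item mode of anisotropy `MO = sqrt(2) * mu3 * mu2^(-3/2)` in
#'     `[-1, 1]`: -1 planar (oblate), 0 orthotropic, +1 linear
#'     (prolate/cigar);
#' }
#' where `mu1`, `mu2`, `mu3` are the mean, variance and third central
#' moment of the three radii with population normalization (divide by
#' 3), matching the tensor-anisotropy conventions of the diffusion
#' literature.  For a sphere `mu2 = 0`, so `MO` is undefined and
#' returned as `NA` with a warning.
#'
#' @param e an [ellipsoid()] or numeric 3-vector of radii.
#' @return a one-row data.frame with columns `A`, `E`, `ratio_ab`,
#'   `ratio_bc`, `FA`, `MO`, `mu1`, `mu2`, `mu3`.
#' @examples
#' shape_summary(c(40, 10, 10))  # prolate: MO = 1, FA = sqrt(1/2)
#' @export
shape_summary <- function(e) {
  r <- if (inherits(e, "ellipsoid")) e$radii
       else sort(as.numeric(e), decreasing = TRUE)
  stopifnot(length(r) == 3L, all(r > 0))
  a <- r[1]; b <- r[2]; c <- r[3]
  mu1 <- mean(r)
  dev <- r - mu1
  mu2 <- mean(dev^2)
  mu3 <- mean(dev^3)
  fa <- sqrt(3 * mu2 / (2 * (mu1^2 + mu2)))
  if (mu2 < 1e-12 * mu1^2) {
    mo <- NA_real_
    warning("sphere (all radii equal): mode of anisotropy is undefined")
  } else {
    mo <- sqrt(2) * mu3 * mu2^(-3 / 2)
  }
  data.frame(A = surface_area(r), E = a / c, ratio_ab = a / b,
             ratio_bc = b / c, FA = fa, MO = mo, mu1 = mu1, mu2 = mu2,
             mu3 = mu3)
}

#' Shape summaries for every vesicle in a configuration
#' @param config a [vesicle_configuration()].
#' @return data.frame, one row per vesicle.
#' @export
shape_summary_table <- function(config) {
  out <- do.call(rbind, lapply(config$vesicles, shape_summary))
  rownames(out) <- NULL
  out
}

#' Orientation of a vesicle relative to the active zone
#'
#' For a vesicle, finds the shortest straight path from its center to
#' the active-zone surface and the smallest (axial, unsigned) angles
#' between the path direction and the three ellipsoid axes:
#' `angle = acos(|axis . direction|)` in degrees, each in `[0, 90]`.
#' Because the axes are orthonormal, the squared cosines of the three
#' angles sum to one.
#'
#' @param e an [ellipsoid()].
#' @param az the active-zone [mesh3()].
#' @return one-row data.frame with `angle_long`, `angle_mid`,
#'   `angle_short` (degrees), `path_distance` (nm) and `degenerate`
#'   (TRUE when the center lies on the surface, in which case the angles
#'   are `NA` and the record should be excluded from tests).
#' @export
orientation_record <- function(e, az) {
  stopifnot(inherits(e, "ellipsoid"))
  sp <- shortest_path_to_surface(e$center, az)
  if (sp$degenerate) {
    warning("vesicle center lies on the active zone; ",
            "orientation undefined")
    return(data.frame(angle_long = NA_real_, angle_mid = NA_real_,
                      angle_short = NA_real_, path_distance = 0,
                      degenerate = TRUE))
  }
  cosines <- abs(as.numeric(t(e$axes) %*% sp$direction))
  cosines <- pmin(cosines, 1)
  ang <- acos(cosines) * 180 / pi
  data.frame(angle_long = ang[1], angle_mid = ang[2],
             angle_short = ang[3], path_distance = sp$distance,
             degenerate = FALSE)
}

#' Orientation records for every vesicle in a configuration
#' @param config a [vesicle_configuration()].
#' @return data.frame, one row per vesicle.
#' @export
orientation_table <- function(config) {
  out <- do.call(rbind, lapply(config$vesicles, orientation_record,
                               az = config$domain$active_zone))
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov test of angle uniformity
#'
#' One-sample two-sided KS test of the hypothesis that orientation
#' angles are uniform on `[0, 90]` degrees -- the distribution expected
#' for each axis-path angle set if vesicle orientations carry no
#' information.  Uses the asymptotic Kolmogorov p-value.
#'
#' @param angles numeric vector of angles in degrees, each in `[0, 90]`;
#'   at least 5 are required for the test to be informative.
#' @return list with `D` (sup-norm statistic) and `p` (p-value).
#' @examples
#' ks_uniformity_test(seq(9, 81, by = 9))$D  # 0.1
#' @export
ks_uniformity_test <- function(angles) {
  angles <- as.numeric(angles)
  angles <- angles[!is.na(angles)]
  if (length(angles) < 5L)
    stop("at least 5 angles are required for the uniformity test")
  if (any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90] degrees")
  ht <- suppressWarnings(ks.test(angles, "punif", min = 0, max = 90))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}
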