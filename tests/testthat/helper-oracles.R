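# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's fast code paths: plain loops,
# dense sampling, direct formula evaluation.

# roughly uniform points on the unit sphere (Fibonacci lattice)
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# uniform random rotation matrix
rot_rand <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x),
           1 - 2 * (x^2 + y^2)), 3, 3)
}

rand_ellipsoid <- function(center_spread = 40, rmin = 10, rmax = 30) {
  ellipsoid(runif(3, -center_spread, center_spread),
            sort(runif(3, rmin, rmax), decreasing = TRUE), rot_rand())
}

# membership of points in a closed ellipsoid
in_ellipsoid <- function(P, e) {
  Q <- e$axes %*% diag(1 / e$radii^2) %*% t(e$axes)
  X <- sweep(as.matrix(P), 2, e$center)
  rowSums((X %*% Q) * X) <= 1
}

# dense-sampling overlap oracle: scaled surface shells of each ellipsoid
# tested for membership in the other, plus mutual center containment
oracle_overlap <- function(e1, e2, n = 1500) {
  dirs <- fib_sphere(n)
  for (pair in list(list(e1, e2), list(e2, e1))) {
    a <- pair[[1]]; b <- pair[[2]]
    if (in_ellipsoid(rbind(a$center), b)) return(TRUE)
    for (s in c(0.4, 0.7, 0.9, 1.0)) {
      pts <- t(a$axes %*% (t(dirs) * (s * a$radii)) + a$center)
      if (any(in_ellipsoid(pts, b))) return(TRUE)
    }
  }
  FALSE
}

# brute-force K-function: explicit loop over ordered pairs
oracle_k <- function(centers, V, grid) {
  N <- nrow(centers)
  total <- numeric(length(grid))
  for (i in seq_len(N)) {
    di <- sqrt(rowSums(sweep(centers, 2, centers[i, ])^2))
    di <- di[-i]
    for (k in seq_along(grid)) total[k] <- total[k] + sum(di <= grid[k])
  }
  V / N^2 * total
}

# brute-force mark variogram over unordered pairs
oracle_variogram <- function(centers, marks, axis, grid, delta) {
  N <- nrow(centers)
  acc <- numeric(length(grid))
  cnt <- integer(length(grid))
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    diss <- if (axis) {
      acos(min(1, abs(sum(marks[i, ] * marks[j, ])))) * 180 / pi
    } else (marks[i] - marks[j])^2
    hit <- abs(grid - d) <= delta
    acc[hit] <- acc[hit] + diss
    cnt[hit] <- cnt[hit] + 1L
  }
  list(value = ifelse(cnt > 0, acc / cnt, NA_real_), n_pairs = cnt)
}

# configuration with prescribed centers in a box domain (marks are
# small spheres unless ellipsoids are supplied)
box_config <- function(centers, dims, vesicles = NULL, az_n = 2L) {
  membrane <- box_mesh(c(0, 0, 0), dims)
  az <- rect_patch_mesh(0, dims[1], 0, dims[2], 0, n = az_n)
  dom <- synapse_domain(membrane, az, check = FALSE)
  if (is.null(vesicles))
    vesicles <- lapply(seq_len(nrow(centers)), function(i)
      ellipsoid(centers[i, ], c(1, 1, 1)))
  vesicle_configuration(dom, vesicles)
}
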