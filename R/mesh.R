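#' Triangle surface mesh
#'
#' Minimal triangle-mesh container used for the pre-synaptic membrane,
#' the active-zone patch and organelle surfaces.  Vertices are world
#' coordinates in nm; faces are 1-based vertex index triples.
#'
#' @param vertices n x 3 numeric matrix, nm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `"mesh3"`.
#' @export
mesh3 <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  cat("mesh3:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles\n")
  invisible(x)
}

#' Axis-aligned box mesh
#'
#' Closed (watertight) triangulated box between corners `lo` and `hi`.
#' @param lo,hi numeric 3-vectors, nm.
#' @return a [mesh3()] with 12 triangles and an attribute `box` holding
#'   `lo` and `hi` (used for exact interior volume when available).
#' @export
box_mesh <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex numbering from expand.grid: x fastest
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  m <- mesh3(v, f)
  attr(m, "box") <- list(lo = lo, hi = hi)
  m
}

#' Rectangular surface patch
#'
#' Open triangulated rectangle, used for planar active zones.  The patch
#' lies in the plane `z = z0` spanning `[x0, x1] x [y0, y1]`, subdivided
#' into a grid of triangles.
#'
#' @param x0,x1,y0,y1,z0 extents, nm.
#' @param n grid subdivisions per side.
#' @return a [mesh3()].
#' @export
rect_patch_mesh <- function(x0, x1, y0, y1, z0, n = 4L) {
  xs <- seq(x0, x1, length.out = n + 1L)
  ys <- seq(y0, y1, length.out = n + 1L)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(g, z0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  f <- NULL
  for (j in 1:n) for (i in 1:n) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
               c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  mesh3(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron approximating a sphere; watertight.  Used for
#' organelle obstacles and curved membrane tests.
#'
#' @param center 3-vector, nm.
#' @param radius nm.
#' @param subdiv number of subdivision rounds (0 gives the icosahedron).
#' @return a [mesh3()].
#' @export
icosphere_mesh <- function(center, radius, subdiv = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      nv <<- nv + 1L
      edge_mid[[key]] <- nv
      nv
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  mesh3(sweep(v * radius, 2, as.numeric(center), "+"), f)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two triangles.
#' @param mesh a [mesh3()].
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Bounding box of a mesh
#' @param mesh a [mesh3()].
#' @return list with `lo` and `hi` 3-vectors.
#' @export
mesh_bbox <- function(mesh) {
  list(lo = apply(mesh$vertices, 2, min),
       hi = apply(mesh$vertices, 2, max))
}

#' Read / write meshes in OFF format
#'
#' Plain-text Object File Format: counts line, vertex lines, face lines
#' (`3 i j k`, 0-based).
#' @param path file path.
#' @return `read_off()` returns a [mesh3()]; `write_off()` returns `path`
#'   invisibly.
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = paste(ln[3:(2 + nv)], collapse = "\n"),
                   quiet = TRUE), ncol = 3, byrow = TRUE)
  fraw <- matrix(scan(text = paste(ln[(3 + nv):(2 + nv + nf)],
                                   collapse = "\n"), quiet = TRUE),
                 ncol = 4, byrow = TRUE)
  if (any(fraw[, 1] != 3)) stop("only triangle faces are supported")
  mesh3(v, fraw[, 2:4] + 1L)
}

#' @rdname read_off
#' @param mesh a [mesh3()] to write.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)),
             con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 12), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

# internal: V matrix (0-based faces) pair for C++ calls
mesh_arrays <- function(mesh) {
  list(V = mesh$vertices, F = mesh$faces - 1L)
}

# internal: concatenate meshes (e.g. all obstacles) into one V/F pair
meshes_concat <- function(meshes) {
  if (length(meshes) == 0L)
    return(list(V = matrix(0, 0, 3), F = matrix(0L, 0, 3)))
  V <- NULL; F <- NULL; off <- 0L
  for (m in meshes) {
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces - 1L + off)
    off <- off + nrow(m$vertices)
  }
  list(V = V, F = matrix(as.integer(F), ncol = 3))
}
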