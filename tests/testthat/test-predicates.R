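test_that("overlap predicate handles sphere and axis-aligned cases", {
  s <- function(ctr) ellipsoid(ctr, c(20, 20, 20))
  expect_true(ellipsoids_overlap(s(c(0, 0, 0)), s(c(39, 0, 0))))
  expect_false(ellipsoids_overlap(s(c(0, 0, 0)), s(c(41, 0, 0))))
  e1 <- ellipsoid(c(0, 0, 0), c(25, 20, 10))
  e2 <- ellipsoid(c(0, 0, 21), c(25, 20, 10))
  expect_false(ellipsoids_overlap(e1, e2))   # gap along shortest axes
  e3 <- ellipsoid(c(0, 0, 19), c(25, 20, 10))
  expect_true(ellipsoids_overlap(e1, e3))
  # containment counts as overlap
  expect_true(ellipsoids_overlap(s(c(0, 0, 0)),
                                 ellipsoid(c(0, 0, 0), c(5, 5, 5))))
})

test_that("overlap predicate is symmetric and rigid-motion invariant", {
  set.seed(13)
  for (rep in 1:40) {
    e1 <- rand_ellipsoid(); e2 <- rand_ellipsoid()
    o12 <- ellipsoids_overlap(e1, e2)
    expect_identical(o12, ellipsoids_overlap(e2, e1))
    R <- rot_rand(); tr <- runif(3, -100, 100)
    move <- function(e) ellipsoid(as.numeric(R %*% e$center + tr),
                                  e$radii, R %*% e$axes)
    expect_identical(o12, ellipsoids_overlap(move(e1), move(e2)))
  }
})

test_that("overlap predicate agrees with the dense-sampling oracle", {
  set.seed(21)
  tested <- 0
  while (tested < 200) {
    e1 <- rand_ellipsoid(); e2 <- rand_ellipsoid()
    # exclude near-tangent pairs (0.1 nm band around the boundary)
    grow <- function(e, d) ellipsoid(e$center, e$radii + d, e$axes)
    near <- ellipsoids_overlap(grow(e1, 0.05), grow(e2, 0.05), 0) !=
      ellipsoids_overlap(grow(e1, -0.05), grow(e2, -0.05), 0)
    if (near) next
    expect_identical(ellipsoids_overlap(e1, e2, margin = 0),
                     oracle_overlap(e1, e2))
    tested <- tested + 1
  }
})

test_that("ellipsoid-surface intersection handles planar cases", {
  plane <- mesh3(rbind(c(-500, -500, 0), c(500, -500, 0), c(0, 500, 0)),
                 rbind(c(1, 2, 3)))
  expect_false(ellipsoid_intersects_surface(
    ellipsoid(c(0, 0, 25), c(20, 20, 20)), plane))
  expect_true(ellipsoid_intersects_surface(
    ellipsoid(c(0, 0, 15), c(20, 20, 20)), plane))
  # shortest axis normal to the plane: clearance 15 > c = 10
  expect_false(ellipsoid_intersects_surface(
    ellipsoid(c(0, 0, 15), c(30, 20, 10)), plane))
  expect_true(ellipsoid_intersects_surface(
    ellipsoid(c(0, 0, 9), c(30, 20, 10)), plane))
})

test_that("ellipsoid-surface intersection agrees with sampling oracle", {
  set.seed(33)
  sphere_mesh <- icosphere_mesh(c(0, 0, 0), 30, subdiv = 2L)
  for (rep in 1:30) {
    e <- ellipsoid(runif(3, -60, 60), sort(runif(3, 5, 25),
                                           decreasing = TRUE),
                   rot_rand())
    got <- ellipsoid_intersects_surface(e, sphere_mesh, margin = 0)
    # oracle: dense points on the mesh triangles tested against the
    # ellipsoid membership function
    V <- sphere_mesh$vertices; F <- sphere_mesh$faces
    hit <- FALSE
    bary <- expand.grid(u = seq(0, 1, by = 0.1),
                        v = seq(0, 1, by = 0.1))
    bary <- bary[bary$u + bary$v <= 1, ]
    for (j in seq_len(nrow(F))) {
      tri <- V[F[j, ], ]
      pts <- cbind(1 - bary$u - bary$v, bary$u, bary$v) %*% tri
      if (any(in_ellipsoid(pts, e))) { hit <- TRUE; break }
    }
    # skip marginal cases within the sampling resolution
    if (got != hit) {
      grow <- ellipsoid(e$center, e$radii + 1, e$axes)
      shrink <- ellipsoid(e$center, pmax(e$radii - 1, 0.5), e$axes)
      marginal <- ellipsoid_intersects_surface(grow, sphere_mesh, 0) !=
        ellipsoid_intersects_surface(shrink, sphere_mesh, 0)
      expect_true(marginal)
    } else expect_identical(got, hit)
  }
})

test_that("shortest path to a surface: distance, direction, ties", {
  patch <- rect_patch_mesh(-200, 200, -200, 200, 0, n = 4L)
  sp <- shortest_path_to_surface(c(10, -20, 50), patch)
  expect_equal(sp$distance, 50, tolerance = 1e-12)
  expect_equal(sp$direction, c(0, 0, -1), tolerance = 1e-12)
  # point on the surface is degenerate
  sp0 <- shortest_path_to_surface(c(10, 10, 0), patch)
  expect_true(sp0$degenerate)
  expect_equal(sp0$distance, 0)
  expect_true(all(is.na(sp0$direction)))
})

test_that("shortest path matches dense surface sampling", {
  set.seed(17)
  m <- icosphere_mesh(c(0, 0, 0), 50, subdiv = 2L)
  # dense point cloud on the mesh
  bary <- expand.grid(u = seq(0, 1, by = 0.05),
                      v = seq(0, 1, by = 0.05))
  bary <- bary[bary$u + bary$v <= 1, ]
  W <- cbind(1 - bary$u - bary$v, bary$u, bary$v)
  cloud <- do.call(rbind, lapply(seq_len(nrow(m$faces)), function(j)
    W %*% m$vertices[m$faces[j, ], ]))
  for (rep in 1:10) {
    p <- runif(3, -120, 120)
    sp <- shortest_path_to_surface(p, m)
    brute <- min(sqrt(rowSums(sweep(cloud, 2, p)^2)))
    expect_lt(abs(sp$distance - brute), 0.5)
  }
})

test_that("surface distance is 1-Lipschitz in the query point", {
  set.seed(19)
  m <- icosphere_mesh(c(0, 0, 0), 50, subdiv = 1L)
  for (rep in 1:40) {
    p1 <- runif(3, -100, 100); p2 <- runif(3, -100, 100)
    d1 <- shortest_path_to_surface(p1, m)$distance
    d2 <- shortest_path_to_surface(p2, m)$distance
    expect_lte(abs(d1 - d2), sqrt(sum((p1 - p2)^2)) + 1e-9)
  }
})
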