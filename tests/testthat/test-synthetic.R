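test_that("generator is deterministic and satisfies all constraints", {
  sp <- generator_spec(n_vesicles = 40, seed = 97)
  c1 <- generate_configuration(sp)
  c2 <- generate_configuration(sp)
  expect_equal(c1$N, 40)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(verify_configuration(c1)$ok)
})

test_that("sphere mode yields exactly spherical vesicles", {
  sp <- generator_spec(n_vesicles = 30, shape_mode = "sphere",
                       seed = 101)
  cfg <- generate_configuration(sp)
  fa <- suppressWarnings(shape_summary_table(cfg)$FA)
  expect_equal(fa, rep(0, 30))
})

test_that("oblate mode matches its target elongation and skewness", {
  set.seed(103)
  r <- sample_vesicle_shapes(generator_spec(shape_mode = "oblate"), 500)
  E <- r[, 1] / r[, 3]
  expect_lt(abs(mean(E) - 1.96) / 1.96, 0.05)
  mo <- apply(r, 1, function(x) shape_summary(x)$MO)
  expect_lt(mean(mo), 0)  # disc-like population
  # cigar mode has positive mode of anisotropy
  rc <- sample_vesicle_shapes(generator_spec(shape_mode = "cigar"), 500)
  expect_lt(abs(mean(rc[, 1] / rc[, 3]) - 2.60) / 2.60, 0.05)
  expect_gt(mean(apply(rc, 1, function(x) shape_summary(x)$MO)), 0)
})

test_that("equivalent diameters follow the 40 +/- 5 nm distribution", {
  set.seed(107)
  r <- sample_vesicle_shapes(generator_spec(), 5000)
  D <- 2 * apply(r, 1, function(x) prod(x)^(1 / 3))
  expect_lt(abs(mean(D) - 40), 3 * sd(D) / sqrt(length(D)))
  expect_true(all(D >= 40 - 7.5 & D <= 40 + 7.5))  # 3 sd truncation
})

test_that("planted repulsion enforces the requested gap", {
  sp <- generator_spec(n_vesicles = 40, interaction = "repulsive",
                       repulsion_range = 20, seed = 109)
  cfg <- generate_configuration(sp)
  # all pairs keep a surface gap around the repulsion range: re-check
  # with the overlap predicate at the inflated margin
  arr <- vesicle3d:::config_arrays(cfg)
  pv <- vesicle3d:::cpp_pair_violations(arr$centers, arr$radii,
                                        arr$axes, 20)
  expect_equal(nrow(pv), 0L)
})

test_that("alignment field concentrates long axes", {
  sp <- generator_spec(n_vesicles = 60, shape_mode = "cigar",
                       alignment = "field", alignment_strength = 50,
                       seed = 113)
  cfg <- generate_configuration(sp)
  ax <- t(vapply(cfg$vesicles, function(e) e$axes[, 1], numeric(3)))
  ang <- acos(pmin(1, abs(ax[, 3]))) * 180 / pi  # angle to +z
  expect_lt(mean(ang), 20)
  # random orientation baseline is much wider
  sp0 <- generator_spec(n_vesicles = 60, shape_mode = "cigar",
                        seed = 113)
  ax0 <- t(vapply(generate_configuration(sp0)$vesicles,
                  function(e) e$axes[, 1], numeric(3)))
  expect_gt(mean(acos(pmin(1, abs(ax0[, 3]))) * 180 / pi), 40)
})

test_that("density gradient thins vesicles away from the active zone", {
  sp <- generator_spec(n_vesicles = 80, gradient_beta = -0.008,
                       seed = 127)
  cfg <- generate_configuration(sp)
  d <- surface_distances(vesicle_centers(cfg),
                         cfg$domain$active_zone)
  # compare near vs far halves of the distance range
  mid <- (min(d) + max(d)) / 2
  expect_gt(sum(d < mid), sum(d > mid))
})

test_that("voxelization produces plausible slices and closed shells", {
  dom_cfg <- box_config(matrix(c(100, 100, 100), 1, 3),
                        c(200, 200, 200),
                        vesicles = list(
                          ellipsoid(c(100, 100, 100), c(20, 20, 20))))
  stk <- voxelize(dom_cfg, voxel_size = 5)
  lm <- stk$label_map
  bl <- lm$vesicle_boundary_base
  zs <- apply(stk$labels == bl | stk$labels == lm$vesicle_interior,
              3, any)
  expect_true(sum(zs) >= 8 && sum(zs) <= 10)  # ~40 nm across 5 nm slices
  # boundary shell is closed: 6-connected flood fill from outside the
  # vesicle cannot reach interior-labelled voxels
  sub <- stk$labels[11:30, 11:30, 11:30]
  reach <- array(FALSE, dim(sub))
  queue <- matrix(0L, prod(dim(sub)), 3)
  queue[1, ] <- c(1L, 1L, 1L)
  head <- 1L; tail <- 1L
  reach[1, 1, 1] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (head <= tail) {
    p <- queue[head, ]; head <- head + 1L
    for (s in 1:6) {
      q <- p + shifts[s, ]
      if (any(q < 1) || any(q > 20)) next
      if (reach[q[1], q[2], q[3]]) next
      if (sub[q[1], q[2], q[3]] >= bl) next  # cannot cross the shell
      reach[q[1], q[2], q[3]] <- TRUE
      tail <- tail + 1L
      queue[tail, ] <- q
    }
  }
  interior_voxels <- which(sub == lm$vesicle_interior, arr.ind = TRUE)
  expect_gt(nrow(interior_voxels), 0)
  expect_false(any(reach[interior_voxels]))
})

test_that("voxelize/fit round trip recovers each vesicle", {
  cfg <- generate_configuration(generator_spec(n_vesicles = 12,
                                               seed = 131))
  stk <- voxelize(cfg, voxel_size = 5)
  rec <- fit_configuration_from_stack(stk, cfg$domain)
  expect_equal(rec$N, 12)
  # boundary labels preserve the vesicle order
  for (i in seq_len(12)) {
    e0 <- cfg$vesicles[[i]]; e1 <- rec$vesicles[[i]]
    expect_lt(sqrt(sum((e0$center - e1$center)^2)), 2.5)
    expect_lt(max(abs(e0$radii - e1$radii)), 2.5)
  }
})

test_that("empty configurations voxelize to domain labels only", {
  cfg <- box_config(matrix(numeric(0), 0, 3), c(100, 100, 100),
                    vesicles = list())
  stk <- voxelize(cfg, voxel_size = 5)
  lm <- stk$label_map
  expect_true(all(stk$labels %in% c(lm$exterior, lm$cytosol,
                                    lm$membrane, lm$active_zone)))
})

test_that("infeasible packings fail with an informative error", {
  sp <- generator_spec(domain_dims = c(100, 100, 100),
                       n_vesicles = 50, seed = 137)
  expect_error(generate_configuration(sp), "too dense|infeasible")
})
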