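test_that("infeasible initial configurations are rejected with detail", {
  cfg <- box_config(rbind(c(100, 100, 100), c(110, 100, 100)),
                    c(200, 200, 200),
                    vesicles = list(
                      ellipsoid(c(100, 100, 100), c(20, 20, 20)),
                      ellipsoid(c(110, 100, 100), c(20, 20, 20))))
  expect_error(sample_null(cfg, mcmc_settings(n_samples = 5)),
               "infeasible.*1-2")
})

test_that("single-vesicle chain samples uniformly over the box", {
  set.seed(71)
  cfg <- box_config(matrix(c(200, 200, 200), 1, 3), c(400, 400, 400),
                    vesicles = list(
                      ellipsoid(c(200, 200, 200), c(20, 20, 20))))
  ns <- sample_null(cfg, mcmc_settings(n_samples = 10000,
                                       moves_per_sample = 10,
                                       burn_in = 100, seed = 71))
  cen <- t(vapply(ns$configurations, function(cc)
    cc$vesicles[[1]]$center, numeric(3)))
  # octant partition of the box; feasible region is symmetric, so all
  # eight cells have equal probability under the uniform law
  oct <- 1 + (cen[, 1] > 200) + 2 * (cen[, 2] > 200) +
    4 * (cen[, 3] > 200)
  ht <- suppressWarnings(chisq.test(tabulate(oct, 8)))
  expect_gt(ht$p.value, 0.01)
  # centers never leave the feasible region (clearance >= radius)
  expect_true(all(cen > 20 & cen < 380))
})

test_that("a vesicle filling a tight pocket never moves", {
  membrane <- icosphere_mesh(c(0, 0, 0), 30, subdiv = 2L)
  # inradius of the polyhedral membrane
  ri <- min(vesicle3d:::cpp_mesh_dist(matrix(0, 1, 3),
                                      membrane$vertices,
                                      membrane$faces - 1L))
  az <- mesh3(membrane$vertices[membrane$faces[1, ], ],
              matrix(1:3, 1))
  dom <- synapse_domain(membrane, az, check = FALSE)
  r <- ri - 0.12  # clearance barely above the 0.1 nm margin
  cfg <- vesicle_configuration(dom, list(
    ellipsoid(c(0, 0, 0), c(r, r, r))))
  expect_warning(
    ns <- sample_null(cfg, mcmc_settings(n_samples = 50,
                                         moves_per_sample = 20,
                                         burn_in = 0, seed = 73)),
    "acceptance rate")
  cen <- t(vapply(ns$configurations, function(cc)
    cc$vesicles[[1]]$center, numeric(3)))
  expect_true(all(cen == 0))
})

test_that("emitted samples keep N and violate no constraints", {
  cfg <- generate_configuration(generator_spec(n_vesicles = 30,
                                               seed = 79))
  ns <- sample_null(cfg, mcmc_settings(n_samples = 40, seed = 79))
  expect_length(ns$configurations, 40)
  for (cc in ns$configurations[c(1, 20, 40)]) {
    expect_equal(cc$N, 30)
    expect_true(verify_configuration(cc)$ok)
  }
  # radii are preserved throughout
  r0 <- sort(unlist(lapply(cfg$vesicles, `[[`, "radii")))
  r1 <- sort(unlist(lapply(ns$configurations[[40]]$vesicles, `[[`,
                           "radii")))
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("two-sphere chain matches direct rejection sampling", {
  set.seed(83)
  dims <- c(200, 200, 200)
  cfg <- box_config(rbind(c(60, 100, 100), c(140, 100, 100)), dims,
                    vesicles = list(
                      ellipsoid(c(60, 100, 100), c(20, 20, 20)),
                      ellipsoid(c(140, 100, 100), c(20, 20, 20))))
  n <- 10000
  ns <- sample_null(cfg, mcmc_settings(n_samples = n,
                                       moves_per_sample = 10,
                                       burn_in = 200, seed = 83))
  d_chain <- vapply(ns$configurations, function(cc)
    sqrt(sum((cc$vesicles[[1]]$center - cc$vesicles[[2]]$center)^2)),
    0)
  # independent rejection sampler: centers uniform in the shrunken box
  # (clearance radius + margin), kept when the gap exceeds the margin
  d_rej <- numeric(0)
  lo <- 20.1; hi <- 179.9
  while (length(d_rej) < n) {
    m <- n
    c1 <- matrix(runif(3 * m, lo, hi), ncol = 3)
    c2 <- matrix(runif(3 * m, lo, hi), ncol = 3)
    d <- sqrt(rowSums((c1 - c2)^2))
    d_rej <- c(d_rej, d[d > 40.1])
  }
  d_rej <- d_rej[seq_len(n)]
  ht <- suppressWarnings(ks.test(d_chain, d_rej))
  expect_gt(ht$p.value, 0.01)
})

test_that("envelope construction: quantiles, flags, degenerate cases", {
  set.seed(89)
  cfg <- generate_configuration(generator_spec(n_vesicles = 25,
                                               seed = 89))
  grid <- seq(20, 120, by = 20)
  ns <- sample_null(cfg, mcmc_settings(n_samples = 40, seed = 90))
  obs <- l_function(k_function(cfg, grid))
  expect_error(envelope(obs, ns$configurations[1:10], function(cc)
    l_function(k_function(cc, grid))), "at least 40")
  # constant statistic: degenerate band equal to the constant
  const_stat <- function(cc) summary_function(grid, rep(7, length(grid)),
                                              kind = "L")
  env_c <- envelope(summary_function(grid, rep(7, length(grid)), "L"),
                    ns, const_stat)
  expect_equal(env_c$lo, rep(7, length(grid)))
  expect_equal(env_c$hi, rep(7, length(grid)))
  expect_false(any(env_c$exceed_lo | env_c$exceed_hi))
  # self-consistency: a null draw mostly stays inside its own band
  env_s <- envelope(l_function(k_function(ns$configurations[[5]], grid)),
                    ns, function(cc) l_function(k_function(cc, grid)))
  expect_gte(mean(!(env_s$exceed_lo | env_s$exceed_hi)), 0.5)
  # grid mismatch is an error
  bad_stat <- function(cc) l_function(k_function(cc, grid + 1))
  expect_error(envelope(obs, ns, bad_stat), "grid")
})
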