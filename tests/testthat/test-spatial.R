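test_that("K-function of two points is a step of height V*2/N^2", {
  cfg <- box_config(rbind(c(35, 50, 50), c(65, 50, 50)),
                    c(100, 100, 100))
  K <- k_function(cfg, grid = c(10, 20, 29.9, 30, 40))
  expect_equal(attr(K, "kind"), "K")
  expect_equal(K$value, c(0, 0, 0, 5e5, 5e5))  # ties at t included
})

test_that("K-function equals the brute-force pair-count oracle", {
  set.seed(47)
  grid <- seq(5, 150, by = 5)
  for (rep in 1:5) {
    N <- sample(20:80, 1)
    centers <- cbind(runif(N, 0, 300), runif(N, 0, 300),
                     runif(N, 0, 200))
    cfg <- box_config(centers, c(300, 300, 200))
    K <- k_function(cfg, grid)
    expect_equal(K$value, oracle_k(centers, 300 * 300 * 200, grid),
                 tolerance = 1e-12)
  }
})

test_that("K is rigid-motion invariant and scales with volume", {
  set.seed(53)
  N <- 30
  centers <- cbind(runif(N, 50, 250), runif(N, 50, 250),
                   runif(N, 50, 150))
  grid <- seq(10, 100, by = 10)
  K1 <- k_function(box_config(centers, c(300, 300, 200)), grid)
  # translate the whole pattern (same box size elsewhere)
  K2 <- k_function(box_config(centers - 20, c(300, 300, 200)), grid)
  expect_equal(K1$value, K2$value, tolerance = 1e-12)
  # doubling the volume doubles K (explicit intensity dependence)
  K3 <- k_function(box_config(centers, c(600, 300, 200)), grid)
  expect_equal(K3$value, 2 * K1$value, tolerance = 1e-12)
})

test_that("L transform is exact and monotone", {
  t <- seq(10, 100, by = 10)
  Kp <- summary_function(t, 4 / 3 * pi * t^3, kind = "K")
  expect_equal(l_function(Kp)$value, t, tolerance = 1e-12)
  K0 <- summary_function(t, rep(0, length(t)), kind = "K")
  expect_equal(l_function(K0)$value, rep(0, length(t)))
  Ks <- summary_function(30, 5e5, kind = "K")
  expect_equal(l_function(Ks)$value, (3 * 5e5 / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  expect_error(l_function(summary_function(t, t, kind = "L")),
               "K-function")
})

test_that("uncorrected L is near t for a binomial (Poisson-like) pattern", {
  set.seed(59)
  grid <- c(25, 50, 75, 100)
  nsim <- 200
  acc <- matrix(0, nsim, length(grid))
  for (s in seq_len(nsim)) {
    centers <- matrix(runif(500 * 3, 0, 1000), ncol = 3)
    cfg <- box_config(centers, c(1000, 1000, 1000))
    acc[s, ] <- l_function(k_function(cfg, grid))$value
  }
  ml <- colMeans(acc)
  # small negative boundary bias expected (no edge correction)
  expect_true(all(abs(ml - grid) / grid < 0.05))
  expect_true(all(ml <= grid + 1))
})

test_that("mark variogram handles the elementary cases", {
  # identical marks give a zero variogram
  cfg <- box_config(rbind(c(30, 50, 50), c(60, 50, 50), c(90, 50, 50)),
                    c(120, 100, 100),
                    vesicles = list(
                      ellipsoid(c(30, 50, 50), c(10, 8, 6)),
                      ellipsoid(c(60, 50, 50), c(10, 8, 6)),
                      ellipsoid(c(90, 50, 50), c(10, 8, 6))))
  v <- mark_variogram(cfg, "surface_area", grid = c(30, 60), delta = 5)
  expect_equal(v$value, c(0, 0))
  # two centers 10 nm apart with scalar marks 1 and 3: V(10) = 4
  cfg2 <- box_config(rbind(c(45, 50, 50), c(55, 50, 50)),
                     c(100, 100, 100),
                     vesicles = list(
                       ellipsoid(c(45, 50, 50), c(5, 5, 5)),
                       ellipsoid(c(55, 50, 50), c(5, 5, 5))))
  marks <- c(1, 3)
  vv <- vesicle3d:::mark_variogram_points(rbind(c(45, 50, 50),
                                                c(55, 50, 50)),
                                          marks, FALSE, c(10), 5)
  expect_equal(vv$value, 4)
  expect_equal(vv$n_pairs, 1L)
  # axial marks at 30 degrees
  a1 <- c(1, 0, 0)
  a2 <- c(cos(pi / 6), sin(pi / 6), 0)
  va <- vesicle3d:::mark_variogram_points(rbind(c(45, 50, 50),
                                                c(55, 50, 50)),
                                          rbind(a1, a2), TRUE, c(10), 5)
  expect_equal(va$value, 30, tolerance = 1e-9)
  # empty bins are missing
  v3 <- mark_variogram(cfg2, "E", grid = c(10, 50), delta = 2)
  expect_true(is.na(v3$value[2]))
})

test_that("mark variograms equal the brute-force all-pairs oracle", {
  set.seed(61)
  grid <- seq(10, 150, by = 10)
  for (rep in 1:3) {
    N <- 40
    centers <- cbind(runif(N, 0, 300), runif(N, 0, 300),
                     runif(N, 0, 200))
    ves <- lapply(seq_len(N), function(i)
      ellipsoid(centers[i, ], sort(runif(3, 8, 25), decreasing = TRUE),
                rot_rand()))
    cfg <- box_config(centers, c(300, 300, 200), vesicles = ves)
    # scalar mark
    v <- mark_variogram(cfg, "surface_area", grid, delta = 10)
    marks <- vapply(ves, surface_area, 0)
    o <- oracle_variogram(centers, marks, FALSE, grid, 10)
    expect_equal(v$value, o$value, tolerance = 1e-12)
    expect_equal(v$n_pairs, o$n_pairs)
    # axis mark
    va <- mark_variogram(cfg, "long_axis", grid, delta = 10)
    am <- t(vapply(ves, function(e) e$axes[, 1], numeric(3)))
    oa <- oracle_variogram(centers, am, TRUE, grid, 10)
    expect_equal(va$value, oa$value, tolerance = 1e-9)
  }
})

test_that("shuffled marks give a flat variogram", {
  set.seed(67)
  N <- 80
  centers <- cbind(runif(N, 0, 400), runif(N, 0, 400),
                   runif(N, 0, 300))
  marks <- rnorm(N, 100, 15)
  grid <- seq(30, 200, by = 10)
  v <- vesicle3d:::mark_variogram_points(centers, marks, FALSE, grid, 15)
  pop <- !is.na(v$value) & v$n_pairs >= 5
  spread_obs <- max(v$value[pop]) - min(v$value[pop])
  # Monte-Carlo band from mark permutations
  spreads <- replicate(200, {
    vp <- vesicle3d:::mark_variogram_points(centers, sample(marks),
                                            FALSE, grid, 15)
    max(vp$value[pop]) - min(vp$value[pop])
  })
  expect_lt(spread_obs, mean(spreads) + 3 * sd(spreads))
})
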