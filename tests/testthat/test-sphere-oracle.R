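random_interior_points <- function(n, radius, rmin = 5, rmax = 0.9 * radius,
                                   seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * runif(n, rmin, rmax)
}

test_that("potential is antisymmetric under source/sink exchange", {
  pts <- random_interior_points(200, 50)
  cfg <- sphere_source_config(radius = 50, sigma = 0.1, n_terms = 150)
  swapped <- sphere_source_config(radius = 50, sigma = 0.1,
                                  source = cfg$sink, sink = cfg$source,
                                  n_terms = 150)
  v <- sphere_potential(cfg, pts)
  expect_equal(sphere_potential(swapped, pts), -v, tolerance = 1e-12)
})

test_that("potential vanishes on the symmetry plane of antipodal electrodes", {
  cfg <- sphere_source_config(radius = 50, sigma = 0.1, n_terms = 150)
  theta <- seq(0, 2 * pi, length.out = 37)
  eq <- cbind(cos(theta), sin(theta), 0) * 30 # equidistant from +-z sources
  expect_lt(max(abs(sphere_potential(cfg, eq))), 1e-12)
})

test_that("series truncation has converged by N = 50 at mid radius", {
  pts <- random_interior_points(100, 50, rmin = 24, rmax = 26)
  v50 <- sphere_potential(sphere_source_config(radius = 50, sigma = 0.1, n_terms = 50), pts)
  v200 <- sphere_potential(sphere_source_config(radius = 50, sigma = 0.1, n_terms = 200), pts)
  expect_lt(max(abs(v50 - v200) / abs(v200)), 1e-6)
  # monotone decrease of truncation error with N at an interior point
  p <- matrix(c(10, 15, 20), 1)
  ref <- sphere_potential(sphere_source_config(radius = 50, sigma = 0.1, n_terms = 400), p)
  errs <- sapply(c(5, 10, 20, 40), function(N) {
    abs(sphere_potential(sphere_source_config(radius = 50, sigma = 0.1, n_terms = N), p) - ref)
  })
  expect_true(all(diff(errs) <= 0))
})

test_that("series and closed-form evaluations agree", {
  pts <- random_interior_points(200, 50)
  cfg <- sphere_source_config(radius = 50, sigma = 0.1, n_terms = 300)
  expect_equal(sphere_potential(cfg, pts, "series"),
               sphere_potential(cfg, pts, "closed"), tolerance = 1e-8)
  fs <- sphere_field(cfg, pts, "series")
  fc <- sphere_field(cfg, pts, "closed")
  expect_equal(fs$E, fc$E, tolerance = 1e-7)
})

test_that("analytic field matches the finite-difference gradient", {
  pts <- random_interior_points(100, 50, seed = 7)
  cfg <- sphere_source_config(radius = 50, sigma = 0.1, n_terms = 200)
  f <- sphere_field(cfg, pts, "closed")
  eps <- 1e-5
  for (k in 1:3) {
    e <- matrix(0, nrow(pts), 3); e[, k] <- eps
    fd <- (sphere_potential(cfg, pts + e, "closed") -
             sphere_potential(cfg, pts - e, "closed")) / (2 * eps)
    expect_lt(max(abs(-1000 * fd - f$E[, k])) / max(f$magnitude), 1e-4)
  }
})

test_that("degenerate drives and positions behave as specified", {
  cfg0 <- sphere_source_config(radius = 50, sigma = 0.1, current = 0)
  pts <- random_interior_points(20, 50)
  expect_equal(max(sphere_field(cfg0, pts)$magnitude), 0)
  # field at the centre points along the source-sink axis
  cfg <- sphere_source_config(radius = 50, sigma = 0.1, current = 1)
  E0 <- sphere_field(cfg, matrix(0, 1, 3))$E
  expect_equal(E0[1, 1:2], c(0, 0))
  expect_lt(E0[1, 3], 0) # current flows +z -> -z, E points down the axis
  # evaluation at a source is a singularity error
  expect_error(sphere_potential(cfg, matrix(c(0, 0, 50), 1)), "singularity")
  expect_error(sphere_potential(cfg, matrix(c(0, 0, 60), 1)), "inside")
})
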