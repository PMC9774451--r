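test_that("spherical unwrap uses the documented conventions", {
  c0 <- c(25, 61, 0)
  # directly above the eye centre -> latitude +pi/2
  top <- to_spherical(c0 + c(0, 0, 5), c0, "right")
  expect_equal(top$latitude, pi / 2)
  # on the horizontal meridian -> latitude 0
  mer <- to_spherical(c0 + c(3, 4, 0), c0, "right")
  expect_equal(mer$latitude, 0)
  # temporal axis -> longitude 0; anterior -> +pi/2 for both eyes
  expect_equal(to_spherical(c0 + c(5, 0, 0), c0, "right")$longitude, 0)
  expect_equal(to_spherical(c0 + c(0, 5, 0), c0, "right")$longitude, pi / 2)
  l0 <- c(-25, 61, 0)
  expect_equal(to_spherical(l0 + c(-5, 0, 0), l0, "left")$longitude, 0)
  expect_equal(to_spherical(l0 + c(0, 5, 0), l0, "left")$longitude, pi / 2)
  expect_error(to_spherical(c0, c0, "right"), "zero-length")
})

test_that("unwrap and inverse map round-trip 1000 random directions", {
  set.seed(123)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  for (eye in c("right", "left")) {
    ll <- to_spherical(u, c(0, 0, 0), eye)
    back <- from_spherical(ll$longitude, ll$latitude, eye)
    # chord-based angle: well-conditioned near zero, unlike acos of a dot product
    ang <- 2 * asin(0.5 * sqrt(rowSums((u - back)^2)))
    expect_lt(max(ang), 1e-9)
  }
})

test_that("eye surface extraction is a bijection from surface triangles", {
  ph <- coarse_phantom()
  fix <- coarse_ac_solutions()
  s <- fix$solutions[[1]]
  samp <- extract_eye_surface(ph, s, "right")
  n_tri <- sum(ph$surface$label == "eyeball" & ph$surface$eye == "right",
               na.rm = TRUE)
  expect_equal(nrow(samp), n_tri)
  expect_true(all(samp$magnitude >= 0))
  expect_true(all(samp$longitude >= -pi & samp$longitude < pi))
  expect_true(all(abs(samp$latitude) <= pi / 2))
  # an analytically uniform field maps to constant samples
  unif <- s
  unif$magnitude <- rep(1, length(s$magnitude))
  samp1 <- extract_eye_surface(ph, unif, "right")
  expect_equal(samp1$magnitude, rep(1, nrow(samp1)))
  expect_error(extract_eye_surface(coarse_sphere(), s, "right"), "no eyes")
  other <- build_head_phantom(phantom_config(element_size = 12, seed = 8))
  expect_error(extract_eye_surface(other, s, "right"), "different phantom")
})

test_that("grid interpolation reproduces samples and masks the hull", {
  samp <- synthetic_eye_samples(function(lon, lat) 1 + sin(lon) * cos(lat), n = 400)
  g <- interpolate_grid(samp, resolution_deg = 2)
  # interpolating property, checked by brute-force lookup at sample sites
  z <- grid_lookup(g, samp$longitude, samp$latitude)
  expect_equal(z, samp$magnitude, tolerance = 1e-9)
  # constant samples -> constant grid
  cs <- samp; cs$magnitude <- rep(2.5, nrow(cs))
  gc <- interpolate_grid(cs, resolution_deg = 2)
  expect_equal(range(gc$magnitude, na.rm = TRUE), c(2.5, 2.5), tolerance = 1e-9)
  # degenerate inputs error
  expect_error(interpolate_grid(samp[1:2, ]), "at least 3")
  col <- samp[1:5, ]; col$latitude <- 0.3
  expect_error(interpolate_grid(col), "collinear")
})

test_that("region partition covers the lower anterior surface exactly once", {
  for (eye in c("right", "left")) {
    regs <- partition_regions(eye)
    expect_equal(regs$lon_max - regs$lon_min, rep(pi / 3, 3), tolerance = 1e-12)
    expect_equal(regs$lon_min[1], 0)
    expect_equal(regs$lon_max[3], pi)
    # contiguous and disjoint bands
    expect_equal(regs$lon_min[-1], regs$lon_max[-3])
  }
  # documented bounds of the temporal region of the right eye
  tr <- partition_regions("right")[1, ]
  expect_equal(tr$region, "temporal")
  expect_equal(tr$lon_max, 1.047, tolerance = 1e-3)

  # zone exhaustiveness: every direction lands in exactly one zone
  set.seed(5)
  lon <- runif(2000, -pi, pi); lat <- runif(2000, -pi / 2, pi / 2)
  z <- classify_zone(lon, lat)
  expect_true(all(z %in% c("temporal", "central", "nasal", "upper", "posterior")))
  expect_equal(classify_zone(0.5, 0.3), "upper")
  expect_equal(classify_zone(0.5, -0.3), "temporal")
  expect_equal(classify_zone(2.0, -0.3), "central")
  expect_equal(classify_zone(2.8, -0.3), "nasal")
  expect_equal(classify_zone(-1, -0.3), "posterior")
})

test_that("locality maxima match an exhaustive grid scan for a Gaussian bump", {
  bump_lon <- 0.5; bump_lat <- -0.4
  f <- function(lon, lat) {
    0.05 + 3 * exp(-((lon - bump_lon)^2 + (lat - bump_lat)^2) / (2 * 0.15^2))
  }
  samp <- synthetic_eye_samples(f, n = 3000, seed = 9)
  g <- interpolate_grid(samp, resolution_deg = 1)
  rep <- locality_report(g, "temporal", eye = "right")
  # the in-region maximum sits at the bump centre
  expect_lt(abs(rep$lon_in - bump_lon), 0.08)
  expect_lt(abs(rep$lat_in - bump_lat), 0.08)
  # brute-force scan over adjacent-zone grid cells
  zones <- classify_zone(rep(g$longitude, times = length(g$latitude)),
                         rep(g$latitude, each = length(g$longitude)))
  zmat <- matrix(zones, length(g$longitude), length(g$latitude))
  brute_adj <- max(g$magnitude[zmat == "central"], na.rm = TRUE)
  expect_equal(rep$delta_adjacent, rep$max_in - brute_adj, tolerance = 1e-12)
  brute_up <- max(g$magnitude[zmat == "upper"], na.rm = TRUE)
  expect_equal(rep$delta_upper, rep$max_in - brute_up, tolerance = 1e-12)
})

test_that("a uniform field yields zero locality deltas", {
  samp <- synthetic_eye_samples(function(lon, lat) rep(1.3, length(lon)), n = 1500)
  g <- interpolate_grid(samp, resolution_deg = 1)
  for (r in c("temporal", "central", "nasal")) {
    rep <- locality_report(g, r, eye = "right")
    expect_equal(rep$delta_upper, 0, tolerance = 1e-9)
    expect_equal(rep$delta_adjacent, 0, tolerance = 1e-9)
  }
})

test_that("locality deltas reproduce the reported worked examples", {
  expect_equal(locality_delta(2.16, 0.68), 1.48)
  expect_equal(locality_delta(1.68, 1.04), 0.64)
  for (a in c(0, 0.5, 3.02)) expect_equal(locality_delta(a, a), 0)
  expect_error(locality_delta(-1, 2), "negative")
  expect_error(locality_delta(Inf, 2), "finite")
})

test_that("locality reports are invariant under a joint rotation of samples and frame", {
  set.seed(21)
  u <- matrix(rnorm(1800), ncol = 3); u <- u / sqrt(rowSums(u^2))
  fvals <- 1 + exp(-((u[, 1] - 0.7)^2 + u[, 3]^2) / 0.1)
  # random rotation
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  fr0 <- eye_frame("right")
  fr1 <- list(temporal = as.vector(qr_R %*% fr0$temporal),
              anterior = as.vector(qr_R %*% fr0$anterior),
              up = as.vector(qr_R %*% fr0$up))
  mk <- function(pts, frame) {
    ll <- to_spherical(pts, c(0, 0, 0), frame)
    tibble::tibble(eye = "right", longitude = ll$longitude,
                   latitude = ll$latitude, magnitude = fvals,
                   element = seq_along(fvals))
  }
  g0 <- interpolate_grid(mk(u, fr0), resolution_deg = 2)
  g1 <- interpolate_grid(mk(u %*% t(qr_R), fr1), resolution_deg = 2)
  r0 <- locality_report(g0, "temporal", eye = "right")
  r1 <- locality_report(g1, "temporal", eye = "right")
  expect_equal(r1$max_in, r0$max_in, tolerance = 1e-9)
  expect_equal(r1$delta_adjacent, r0$delta_adjacent, tolerance = 1e-9)
  expect_equal(r1$lon_in, r0$lon_in, tolerance = 1e-9)
})

test_that("shrinking a region never increases its in-region maximum", {
  samp <- synthetic_eye_samples(function(lon, lat) 1 + sin(2 * lon) + lat^2,
                                n = 2000, seed = 13)
  g <- interpolate_grid(samp, resolution_deg = 1)
  full <- partition_regions("right")[1, ]
  shrunk <- full
  shrunk$lon_min <- full$lon_min + 0.1
  shrunk$lon_max <- full$lon_max - 0.1
  r_full <- locality_report(g, full)
  r_shrunk <- locality_report(g, shrunk)
  expect_lte(r_shrunk$max_in, r_full$max_in)
})

test_that("fellow target regions can be excluded from the adjacent comparison", {
  samp <- synthetic_eye_samples(function(lon, lat) 1 + cos(lon), n = 1500, seed = 3)
  g <- interpolate_grid(samp, resolution_deg = 2)
  r_all <- locality_report(g, "central", eye = "right")
  r_excl <- locality_report(g, "central", eye = "right",
                            exclude_adjacent = "temporal")
  expect_equal(r_excl$adjacent_regions, "nasal")
  expect_true(is.na(locality_report(g, "temporal", eye = "right",
                                    exclude_adjacent = "central")$delta_adjacent))
  expect_gte(r_all$max_adjacent, r_excl$max_adjacent)
})
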