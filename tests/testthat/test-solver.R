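test_that("element fields differentiate P1 potentials exactly", {
  ph <- coarse_phantom()
  # constant potential -> zero field
  ef <- element_field(ph, rep(3.7, nrow(ph$nodes)))
  expect_equal(max(abs(ef$E)), 0)
  # linear ramp V = a*x (volts, mm) -> E = (-1000a, 0, 0) V/m everywhere
  a <- 2e-3
  ef <- element_field(ph, a * ph$nodes[, 1])
  expect_equal(ef$E[, 1], rep(-1000 * a, nrow(ph$tets)), tolerance = 1e-10)
  expect_lt(max(abs(ef$E[, 2:3])), 1e-9)
  expect_equal(ef$magnitude, ocufield:::row_norms(ef$E))
})

test_that("element fields match a brute-force gradient on a 2-tet fixture", {
  m <- two_tet_mesh()
  set.seed(1)
  V <- rnorm(5)
  ef <- element_field(m, V)
  for (i in 1:2) {
    g <- brute_tet_gradient(m$nodes, m$tets[i, ], V)
    expect_equal(ef$E[i, ], -1000 * g, tolerance = 1e-9)
  }
})

test_that("zero drive produces an identically zero field", {
  fix <- coarse_ac_solutions()
  pair <- fix$placed[[1]]
  pair$current <- 0
  s <- solve_pair(coarse_phantom(), pair, gel_patches = fix$pads)
  expect_equal(max(s$magnitude), 0)
})

test_that("solutions are linear in the drive current", {
  fix <- coarse_ac_solutions()
  s1 <- fix$solutions[[1]]
  pair2 <- fix$placed[[1]]
  pair2$current <- 2
  s2 <- solve_pair(coarse_phantom(), pair2, gel_patches = fix$pads)
  expect_equal(s2$magnitude, 2 * s1$magnitude, tolerance = 1e-9)
  # and rescale_solution reproduces the same
  expect_equal(rescale_solution(s1, 2)$magnitude, s2$magnitude, tolerance = 1e-9)
})

test_that("currents are conserved and the residual contract holds", {
  fix <- coarse_ac_solutions()
  for (s in fix$solutions) {
    expect_lt(abs(sum(s$flux)), 1e-6 * abs(s$drive$current))
    expect_equal(unname(s$flux["anode"]), s$drive$current, tolerance = 1e-9)
    expect_lt(s$residual, 1e-8)
  }
})

test_that("superposition follows the phase-sign algebra", {
  fix <- coarse_ac_solutions()
  s1 <- fix$solutions[[1]]; s2 <- fix$solutions[[2]]
  # identity
  same <- superpose(list(s1), 1)
  expect_equal(same$magnitude, s1$magnitude)
  # self-cancellation is exact
  z <- superpose(list(s1, s1), c(1, -1))
  expect_equal(max(z$magnitude), 0)
  # combined magnitude is the norm of the summed vectors, not summed norms
  comb <- superpose(list(s1, s2), c(1, 1))
  expect_true(all(comb$magnitude <= s1$magnitude + s2$magnitude + 1e-12))
  expect_false(isTRUE(all.equal(comb$magnitude, s1$magnitude + s2$magnitude)))
  # sign flips leave magnitudes unchanged
  flip <- superpose(list(s1, s2), c(-1, -1))
  expect_equal(flip$magnitude, comb$magnitude, tolerance = 1e-12)
  expect_error(superpose(list(s1, s2), c(1, 2)), "\\+1 or -1")
  other <- solve_pair(coarse_sphere(),
                      list(anode = place_electrode(coarse_sphere(), c(90, 0), 12, 1),
                           cathode = place_electrode(coarse_sphere(), c(-90, 0), 12, -1),
                           current = 1),
                      sigma = conductivity_map(skin = 0.1, gel = 0.1))
  expect_error(superpose(list(s1, other), c(1, -1)), "different meshes")
})

test_that("joint multi-patch injection solve equals the signed sum of pair solves", {
  ph <- coarse_phantom()
  fix <- coarse_ac_solutions()
  pads <- fix$pads
  sig <- conductivity_map()
  i1 <- solve_injection(ph, pads[1:2], c(1, -1), sigma = sig, gel_patches = pads)
  i2 <- solve_injection(ph, pads[3:4], c(1, -1), sigma = sig, gel_patches = pads)
  for (sgn in c(1, -1)) {
    joint <- solve_injection(ph, pads, c(1, -1, sgn * 1, -sgn * 1),
                             sigma = sig, gel_patches = pads)
    sup <- superpose(list(i1, i2), c(1, sgn))
    denom <- sqrt(sum(joint$magnitude^2))
    err <- sqrt(sum((sup$magnitude - joint$magnitude)^2)) / denom
    expect_lt(err, 1e-6)
  }
  expect_error(solve_injection(ph, pads[1:2], c(1, -0.5)), "sum to zero")
})

test_that("conductivity map carries the study defaults and rejects bad overrides", {
  sig <- conductivity_map()
  expect_equal(unname(sig["white_matter"]), 0.027656)
  expect_equal(unname(sig["gray_matter"]), 0.027512)
  expect_equal(unname(sig["csf"]), 2.0)
  expect_equal(unname(sig["bone"]), 0.020028)
  expect_equal(unname(sig["skin"]), 0.0002)
  expect_equal(unname(sig["eyeball"]), 0.41113)
  expect_equal(attr(sig, "frequency_hz"), 10)
  expect_error(conductivity_map(skin = -1), "positive")
  expect_error(conductivity_map(bogus = 1), "unknown tissue")
})
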