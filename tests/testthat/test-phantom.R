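test_that("default-config phantom satisfies the mesh invariants", {
  ph <- coarse_phantom()
  expect_s3_class(ph, "tissue_phantom")
  expect_true(all(ph$volumes > 0))
  expect_true(all(ph$labels %in% c("skin", "bone", "eyeball", "csf",
                                   "gray_matter", "white_matter")))
  expect_true(all(c("skin", "bone", "eyeball") %in% ph$labels))
  # node indices are in range
  expect_true(all(ph$tets >= 1 & ph$tets <= nrow(ph$nodes)))
})

test_that("eyeball surfaces are closed 2-manifolds", {
  ph <- coarse_phantom()
  for (eye in c("right", "left")) {
    tri <- ph$surface[ph$surface$label == "eyeball" & ph$surface$eye == eye, ]
    expect_gt(nrow(tri), 0)
    edges <- rbind(
      cbind(pmin(tri$n1, tri$n2), pmax(tri$n1, tri$n2)),
      cbind(pmin(tri$n2, tri$n3), pmax(tri$n2, tri$n3)),
      cbind(pmin(tri$n1, tri$n3), pmax(tri$n1, tri$n3))
    )
    key <- paste(edges[, 1], edges[, 2])
    # every edge of a closed triangulated surface is shared by exactly 2 faces
    expect_true(all(table(key) == 2))
  }
})

test_that("eye centres mirror about the midsagittal plane and so does the mesh", {
  ph <- coarse_phantom()
  expect_equal(ph$eye_centers$left * c(-1, 1, 1), ph$eye_centers$right)
  # mirrored node multiset: flipping x maps the node set onto itself
  a <- ph$nodes
  b <- a %*% diag(c(-1, 1, 1))
  key <- function(m) sort(paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6)))
  expect_identical(key(a), key(b))
})

test_that("summed eyeball volume is within 10% of the analytic sphere", {
  ph <- default_phantom()
  # brute-force oracle: sum of |det|/6 over eyeball-labelled tetrahedra
  sel <- ph$labels == "eyeball"
  tets <- ph$tets[sel, , drop = FALSE]
  p1 <- ph$nodes[tets[, 1], ]; p2 <- ph$nodes[tets[, 2], ]
  p3 <- ph$nodes[tets[, 3], ]; p4 <- ph$nodes[tets[, 4], ]
  vol6 <- abs(rowSums((p2 - p1) * ocufield:::cross3(p3 - p1, p4 - p1)))
  per_eye <- sum(vol6) / 6 / 2
  expect_lt(abs(per_eye - 4 / 3 * pi * 12^3) / (4 / 3 * pi * 12^3), 0.10)
})

test_that("same config and seed reproduce identical node coordinates", {
  cfg <- phantom_config(element_size = 10, seed = 99)
  ph1 <- build_head_phantom(cfg)
  ph2 <- build_head_phantom(cfg)
  expect_identical(ph1$nodes, ph2$nodes)
  expect_identical(ph1$tets, ph2$tets)
  expect_identical(ph1$mesh_hash, ph2$mesh_hash)
  ph3 <- build_head_phantom(phantom_config(element_size = 10, seed = 100))
  expect_false(identical(ph1$nodes, ph3$nodes))
})

test_that("mesh refinement preserves invariants and increases node count", {
  coarse <- build_head_phantom(phantom_config(element_size = 12, seed = 5))
  fine <- build_head_phantom(phantom_config(element_size = 6, seed = 5))
  expect_gt(nrow(fine$nodes), nrow(coarse$nodes))
  expect_true(all(fine$volumes > 0))
  expect_true(all(coarse$volumes > 0))
})

test_that("infeasible geometries are rejected as configuration errors", {
  expect_error(phantom_config(eye_radius = -1), "positive")
  expect_error(phantom_config(eye_center = c(5, 61, 0)), "overlap")
  expect_error(phantom_config(eye_center = c(40, 70, 0)), "pokes out")
  expect_error(phantom_config(skin_thickness = 50, bone_thickness = 40),
               "thicker|aperture")
  expect_error(phantom_config(jitter = 0.5), "jitter")
})

test_that("tissue volumes table accounts for the whole mesh", {
  ph <- coarse_phantom()
  tv <- phantom_tissue_volumes(ph)
  expect_equal(sum(tv$volume_mm3), sum(ph$volumes))
})
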