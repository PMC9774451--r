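test_that("a 42 mm pad lands on skin with a plausible contact area", {
  ph <- default_phantom()
  p <- place_electrode(ph, "temporal_active_right", 42, 1)
  expect_s3_class(p, "electrode_patch")
  expect_gt(length(p$nodes), 0)
  # every covered node lies on the exterior skin surface
  ext <- ph$surface[ph$surface$exterior & ph$surface$label == "skin", ]
  skin_nodes <- unique(c(ext$n1, ext$n2, ext$n3))
  expect_true(all(p$nodes %in% skin_nodes))
  expect_lt(abs(p$area - 42^2) / 42^2, 0.25)
  expect_true(all(ph$labels[p$gel_elements] == "skin"))
})

test_that("degenerate or unplaceable pads are rejected", {
  ph <- coarse_phantom()
  expect_error(place_electrode(ph, "temporal_active_right", 0), "positive")
  expect_error(place_electrode(ph, "nonexistent_site"), "unknown electrode site")
  expect_error(place_electrode(ph, c(0, -90)), "pole")
  expect_error(place_electrode(ph, c(10, -10), edge_length = 0.01), "resolution error")
})

test_that("pad placement is deterministic for a fixed phantom seed", {
  cfg <- phantom_config(element_size = 10, seed = 77)
  p1 <- place_electrode(build_head_phantom(cfg), "central_active_right")
  p2 <- place_electrode(build_head_phantom(cfg), "central_active_right")
  expect_identical(p1$nodes, p2$nodes)
  expect_identical(p1$gel_elements, p2$gel_elements)
})

test_that("overlapping cheek pads are detected by node-set intersection", {
  ph <- coarse_phantom()
  p1 <- place_electrode(ph, "overlap_active_b_left")
  p2 <- place_electrode(ph, "overlap_active_d_left")
  ov <- patch_overlap(p1, p2)
  # brute-force oracle
  brute <- length(intersect(p1$nodes, p2$nodes))
  expect_equal(ov$n_shared, brute)
  expect_gt(ov$n_shared, 0)
  far <- place_electrode(ph, "temporal_active_right")
  expect_equal(patch_overlap(p1, far)$n_shared, 0)
})

test_that("montage catalog exposes the studied arrangements and currents", {
  m <- montage_catalog("A+C")
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$current, c(1, 1))
  expect_setequal(m$pairs$region, c("temporal", "central"))
  expect_true(all(m$pairs$eye == "right"))

  m6 <- montage_catalog("B+E_corrected")
  expect_equal(m6$pairs$current, c(0.8, 1.5))
  expect_setequal(m6$pairs$region, c("temporal", "nasal"))

  m6b <- montage_catalog("B+E_boost")
  expect_equal(m6b$pairs$current, c(1, 1.5))

  # electrode-number aliases map onto the pair-combination names
  expect_equal(montage_catalog("electrode_5")$name, "A+C")
  expect_equal(montage_catalog("4")$name, "B+D")
  expect_equal(montage_catalog("revised_4")$name, "B+D_revised")

  expect_error(montage_catalog("nonexistent"), "catalog error")
  expect_error(montage_catalog("A+C", currents = c(-1, 1)), "positive")
})

test_that("placed montage pairs have disjoint anode/cathode node sets", {
  ph <- coarse_phantom()
  for (name in c("A+B", "B+D", "A+C", "B+E", "A+E")) {
    placed <- place_montage(ph, montage_catalog(name))
    for (p in placed) {
      expect_length(intersect(p$anode$nodes, p$cathode$nodes), 0)
      expect_gt(length(p$anode$nodes), 0)
      expect_gt(length(p$cathode$nodes), 0)
    }
  }
})

test_that("montage sites mirror exactly between the two face sides", {
  st <- electrode_sites()
  rights <- st[grepl("_right$", st$site), ]
  for (i in seq_len(nrow(rights))) {
    lname <- sub("_right$", "_left", rights$site[i])
    l <- st[st$site == lname, ]
    expect_equal(l$azimuth_deg, -rights$azimuth_deg[i])
    expect_equal(l$elevation_deg, rights$elevation_deg[i])
  }
})
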