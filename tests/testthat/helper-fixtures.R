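# Shared fixtures, built lazily and cached for the whole test session.
# The coarse phantom keeps unit tests fast; the default-resolution phantom
# is used where the study conditions matter.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

coarse_phantom <- function() {
  fixture("coarse_phantom",
          function() build_head_phantom(phantom_config(element_size = 8, seed = 11)))
}

default_phantom <- function() {
  fixture("default_phantom",
          function() build_head_phantom(phantom_config(seed = 1)))
}

coarse_sphere <- function() {
  fixture("coarse_sphere",
          function() build_sphere_phantom(radius = 50, element_size = 6, seed = 3))
}

# A+C montage placed and solved per pair on the coarse phantom.
coarse_ac_solutions <- function() {
  fixture("coarse_ac_solutions", function() {
    ph <- coarse_phantom()
    placed <- place_montage(ph, montage_catalog("A+C"))
    pads <- unlist(lapply(placed, function(p) list(p$anode, p$cathode)),
                   recursive = FALSE)
    sols <- lapply(placed, function(p) solve_pair(ph, p, gel_patches = pads))
    list(placed = placed, pads = pads, solutions = sols)
  })
}

# Tiny two-tetrahedron mesh with hand-computable shape-function gradients.
two_tet_mesh <- function() {
  nodes <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)
  )
  tets <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  # ensure positive orientation
  v <- ocufield:::tet_signed_volumes(nodes, tets)
  for (i in which(v < 0)) tets[i, c(3, 4)] <- tets[i, c(4, 3)]
  list(nodes = nodes, tets = tets)
}

# Brute-force P1 gradient of one tetrahedron by solving the 4x4 linear
# interpolation system; independent of the solver's cofactor formulas.
brute_tet_gradient <- function(nodes, tet, V) {
  A <- cbind(1, nodes[tet, , drop = FALSE])
  coef <- solve(A, V[tet])
  coef[2:4]
}

# Synthetic unwrapped samples from a function on the unit sphere.
synthetic_eye_samples <- function(f, n = 500, seed = 42, eye = "right") {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  center <- c(0, 0, 0)
  ll <- to_spherical(u * 12, center, eye)
  tibble::tibble(
    eye = eye,
    longitude = ll$longitude,
    latitude = ll$latitude,
    magnitude = f(ll$longitude, ll$latitude),
    element = seq_len(n)
  )
}
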