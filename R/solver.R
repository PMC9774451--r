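#' Tissue conductivity table
#'
#' Conductivities (S/m) of the phantom tissues at the 10 Hz stimulation
#' frequency. Note that the default head-skin value, 0.0002 S/m, is far
#' below common literature values for scalp; it is kept verbatim as the
#' study default and can be overridden. `gel` is the conductivity of the
#' electrode gel pad.
#'
#' @param ... named overrides, e.g. `conductivity_map(skin = 0.1)`.
#' @param frequency_hz informational frequency label.
#' @return named numeric vector of conductivities with a `frequency_hz`
#'   attribute.
#' @export
#' @examples
#' conductivity_map()["eyeball"]
conductivity_map <- function(..., frequency_hz = 10) {
  sig <- c(
    white_matter = 0.027656,
    gray_matter = 0.027512,
    csf = 2.0000,
    bone = 0.020028,
    skin = 0.0002,
    eyeball = 0.41113,
    gel = 1.0
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(sig))
    if (length(bad)) abort(paste0("unknown tissue in conductivity override: ",
                                  paste(bad, collapse = ", ")))
    sig[names(over)] <- as.numeric(over)
  }
  if (any(sig <= 0)) abort("all conductivities must be strictly positive")
  attr(sig, "frequency_hz") <- frequency_hz
  sig
}

# Per-element shape-function gradients (1/mm) and volumes for P1 tetrahedra.
# Returns list(g1..g4: T x 3 matrices, vol: length-T vector).
element_gradients <- function(phantom) {
  nodes <- phantom$nodes; tets <- phantom$tets
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  bc <- cross3(b, c3)
  d <- rowSums(a * bc) # 6 * volume
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    abort(paste0("degenerate tetrahedron (non-positive volume): element ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  g2 <- bc / d
  g3 <- cross3(c3, a) / d
  g4 <- cross3(a, b) / d
  list(g1 = -(g2 + g3 + g4), g2 = g2, g3 = g3, g4 = g4, vol = d / 6)
}

# Per-element conductivities from tissue labels, with gel overrides under the
# given electrode patches.
element_sigma <- function(phantom, sigma, gel_patches = list()) {
  labs <- unique(phantom$labels)
  missing <- setdiff(labs, names(sigma))
  if (length(missing))
    abort(paste0("conductivity map does not cover tissue(s): ",
                 paste(missing, collapse = ", ")))
  sig_e <- unname(sigma[phantom$labels])
  for (p in gel_patches) sig_e[p$gel_elements] <- unname(sigma["gel"])
  sig_e
}

# Assemble the P1 stiffness matrix K (dsCMatrix, N x N). With lengths in mm
# and conductivities in S/m, K %*% V (volts) yields nodal currents in mA.
assemble_stiffness <- function(phantom, sig_e, grads = NULL) {
  grads <- grads %||% element_gradients(phantom)
  tets <- phantom$tets
  w <- sig_e * grads$vol
  G <- list(grads$g1, grads$g2, grads$g3, grads$g4)
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (i in 1:4) for (j in 1:4) {
    ii[[k]] <- tets[, i]
    jj[[k]] <- tets[, j]
    xx[[k]] <- w * rowSums(G[[i]] * G[[j]])
    k <- k + 1
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(nrow(phantom$nodes), nrow(phantom$nodes)), symmetric = FALSE)
}

#' Per-element electric field from a nodal potential
#'
#' Differentiates the piecewise-linear potential on each tetrahedron:
#' `E = -grad(V)`, constant per element, with `|E|` its Euclidean norm.
#' Potentials are in volts and coordinates in mm, so fields are reported in
#' V/m.
#'
#' @param phantom a `tissue_phantom`.
#' @param V nodal potential vector (volts), one value per node.
#' @return list with `E` (T x 3 matrix, V/m) and `magnitude` (length-T,
#'   V/m).
#' @export
element_field <- function(phantom, V) {
  if (length(V) != nrow(phantom$nodes))
    abort("V must have one value per phantom node")
  g <- element_gradients(phantom)
  tets <- phantom$tets
  # V/mm -> V/m
  E <- -(g$g1 * V[tets[, 1]] + g$g2 * V[tets[, 2]] +
           g$g3 * V[tets[, 3]] + g$g4 * V[tets[, 4]]) * 1000
  list(E = E, magnitude = row_norms(E))
}

new_field_solution <- function(phantom, V, drive, residual, flux = NULL) {
  ef <- element_field(phantom, V)
  structure(list(
    V = V, E = ef$E, magnitude = ef$magnitude,
    drive = drive, residual = residual, flux = flux,
    mesh_hash = phantom$mesh_hash
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution>\n")
  cat(sprintf("  drive: %s\n", x$drive$description %||% "custom"))
  cat(sprintf("  nodes: %d, elements: %d\n", length(x$V), nrow(x$E)))
  cat(sprintf("  |E| range: [%.4g, %.4g] V/m; residual %.2e\n",
              min(x$magnitude), max(x$magnitude), x$residual))
  invisible(x)
}

#' Solve the quasi-static conduction problem for one electrode pair
#'
#' Solves `div(sigma grad V) = 0` on the phantom with zero normal current on
#' the non-electrode boundary and fixed potentials on the two pad contacts
#' (the electrode boundary condition), then rescales the solution so that
#' the total current through the anode pad equals the pair's drive current
#' in mA. The gauge is zero-mean potential. Skin elements under each pad in
#' `gel_patches` (by default the driven pair itself) take the gel
#' conductivity.
#'
#' @param phantom a `tissue_phantom`.
#' @param pair list with `anode` and `cathode` (`electrode_patch`) and
#'   optionally `current` (mA; defaults to the anode patch current).
#' @param sigma conductivity map from [conductivity_map()].
#' @param gel_patches list of patches whose gel volumes are conductive
#'   during this solve (pass all pads of a montage when the solution will be
#'   superposed with other pairs).
#' @return a `field_solution` with nodal potential `V` (volts), per-element
#'   field `E` and `magnitude` (V/m), the relative residual of the linear
#'   solve, and the anode/cathode flux balance.
#' @export
solve_pair <- function(phantom, pair, sigma = conductivity_map(),
                       gel_patches = NULL) {
  an <- pair$anode; ca <- pair$cathode
  if (!inherits(an, "electrode_patch") || !inherits(ca, "electrode_patch"))
    abort("precondition error: `pair` must carry `anode` and `cathode` electrode patches")
  if (length(an$nodes) == 0 || length(ca$nodes) == 0)
    abort("precondition error: empty electrode patch")
  if (length(intersect(an$nodes, ca$nodes)) > 0)
    abort("precondition error: anode and cathode patches are not disjoint")
  current <- pair$current %||% an$current
  gel_patches <- gel_patches %||% list(an, ca)

  sig_e <- element_sigma(phantom, sigma, gel_patches)
  K <- assemble_stiffness(phantom, sig_e)
  N <- nrow(phantom$nodes)

  if (current == 0) {
    return(new_field_solution(phantom, rep(0, N),
                              drive = list(description = "zero drive", current = 0),
                              residual = 0, flux = c(anode = 0, cathode = 0)))
  }

  fixed <- c(an$nodes, ca$nodes)
  vfix <- c(rep(0.5, length(an$nodes)), rep(-0.5, length(ca$nodes)))
  free <- setdiff(seq_len(N), fixed)
  V <- numeric(N)
  V[fixed] <- vfix
  rhs <- -K[free, fixed, drop = FALSE] %*% vfix
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  sol <- tryCatch(
    Matrix::solve(Kff, rhs),
    error = function(e) abort(paste0("solver error: sparse factorization failed: ",
                                     conditionMessage(e)))
  )
  V[free] <- as.numeric(sol)
  res_vec <- Kff %*% sol - rhs
  rhs_norm <- sqrt(sum(rhs^2))
  residual <- if (rhs_norm > 0) sqrt(sum(res_vec^2)) / rhs_norm else 0
  if (!is.finite(residual) || residual > 1e-6)
    abort(sprintf("solver error: relative residual %.3e exceeds tolerance", residual))

  # nodal reaction currents (mA) at the constrained pads
  r <- as.numeric(K %*% V)
  i_an <- sum(r[an$nodes]); i_ca <- sum(r[ca$nodes])
  if (abs(i_an + i_ca) > 1e-6 * abs(i_an))
    warn(sprintf("current conservation: |anode+cathode| flux = %.3e mA", i_an + i_ca))
  scale <- current / i_an
  V <- V * scale
  V <- V - mean(V)

  new_field_solution(
    phantom, V,
    drive = list(
      description = sprintf("pair %s -> %s, %g mA", an$name, ca$name, current),
      current = current, anode = an$name, cathode = ca$name,
      anode_nodes = an$nodes, cathode_nodes = ca$nodes
    ),
    residual = residual,
    flux = c(anode = i_an * scale, cathode = i_ca * scale)
  )
}

# Nodal current loads (mA) for a patch: total current distributed over the
# patch's exterior contact faces with uniform areal density (area-lumped to
# nodes).
patch_load <- function(phantom, patch, current) {
  surf <- phantom$surface
  ext_skin <- surf[surf$exterior & surf$label == "skin", , drop = FALSE]
  in_set <- logical(nrow(phantom$nodes)); in_set[patch$nodes] <- TRUE
  sel <- in_set[ext_skin$n1] & in_set[ext_skin$n2] & in_set[ext_skin$n3]
  if (!any(sel)) {
    # point-like pad smaller than one surface face: split the current
    # equally over its nodes
    w <- numeric(nrow(phantom$nodes))
    w[patch$nodes] <- 1
    return(w * (current / sum(w)))
  }
  tri <- as.matrix(ext_skin[sel, c("n1", "n2", "n3")])
  ar <- triangle_areas(phantom$nodes, tri)
  w <- numeric(nrow(phantom$nodes))
  for (k in 1:3) {
    add <- tapply(ar / 3, tri[, k], sum)
    idx <- as.integer(names(add))
    w[idx] <- w[idx] + as.numeric(add)
  }
  w * (current / sum(w))
}

#' Solve a multi-patch drive with prescribed patch currents
#'
#' Current-injection formulation: each patch's total current is applied as a
#' fixed, area-uniform current density over its skin contact and the pure
#' Neumann problem is solved (gauge: zero-mean potential). Because the load
#' of every patch is independent of the other patches, solutions of this
#' drive model superpose exactly; it is the reference for the joint-solve
#' consistency checks.
#'
#' @param phantom a `tissue_phantom`.
#' @param patches list of `electrode_patch` objects.
#' @param currents numeric vector of patch currents (mA); must sum to zero.
#' @param sigma conductivity map.
#' @param gel_patches patches contributing gel volumes (default: `patches`).
#' @return a `field_solution`.
#' @export
solve_injection <- function(phantom, patches, currents,
                            sigma = conductivity_map(), gel_patches = NULL) {
  if (length(patches) != length(currents))
    abort("one current per patch required")
  if (abs(sum(currents)) > 1e-9 * max(1, max(abs(currents))))
    abort("patch currents must sum to zero")
  gel_patches <- gel_patches %||% patches
  sig_e <- element_sigma(phantom, sigma, gel_patches)
  K <- assemble_stiffness(phantom, sig_e)
  N <- nrow(phantom$nodes)
  f <- numeric(N)
  for (i in seq_along(patches)) f <- f + patch_load(phantom, patches[[i]], currents[i])

  # pure Neumann: pin one node (loads are balanced, so this is consistent)
  pin <- which.min(phantom$nodes[, 2]) # a posterior node, far from the pads
  free <- setdiff(seq_len(N), pin)
  V <- numeric(N)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  sol <- Matrix::solve(Kff, f[free])
  V[free] <- as.numeric(sol)
  res_vec <- Kff %*% sol - f[free]
  fn <- sqrt(sum(f^2))
  residual <- if (fn > 0) sqrt(sum(as.numeric(res_vec)^2)) / fn else 0
  V <- V - mean(V)

  new_field_solution(
    phantom, V,
    drive = list(description = sprintf("injection drive, %d patches", length(patches)),
                 currents = currents),
    residual = residual
  )
}

#' Signed (phase) superposition of field solutions
#'
#' Under the quasi-static approximation a 10 Hz multi-pair drive reduces to
#' a signed sum of static per-pair solutions: same-phase pairs add with sign
#' +1, anti-phase pairs with sign -1. The combined field vector is the
#' signed sum per element and the combined magnitude is the norm of that sum
#' (not the sum of magnitudes).
#'
#' @param solutions list of `field_solution` objects on the same phantom.
#' @param phase_signs numeric vector of +1/-1, one per solution.
#' @return a `field_solution` for the combined drive.
#' @export
superpose <- function(solutions, phase_signs) {
  if (length(solutions) != length(phase_signs))
    abort("one phase sign per solution required")
  if (!all(phase_signs %in% c(-1, 1)))
    abort("phase signs must be +1 or -1")
  hashes <- vapply(solutions, function(s) s$mesh_hash, character(1))
  if (length(unique(hashes)) != 1)
    abort("cannot superpose solutions on different meshes")
  V <- Reduce(`+`, Map(function(s, sg) sg * s$V, solutions, phase_signs))
  E <- Reduce(`+`, Map(function(s, sg) sg * s$E, solutions, phase_signs))
  structure(list(
    V = V, E = E, magnitude = row_norms(E),
    drive = list(
      description = sprintf("superposition of %d drives, signs %s",
                            length(solutions), paste(phase_signs, collapse = ",")),
      phase_signs = phase_signs,
      components = lapply(solutions, function(s) s$drive)
    ),
    residual = max(vapply(solutions, function(s) s$residual, numeric(1))),
    mesh_hash = hashes[1]
  ), class = "field_solution")
}

#' Rescale a field solution linearly in its drive current
#'
#' The conduction problem is linear in the drive, so a solution at current
#' `I` scales element-wise to any other current.
#'
#' @param solution a `field_solution`.
#' @param factor scale factor applied to `V` and `E`.
#' @return a `field_solution`.
#' @export
rescale_solution <- function(solution, factor) {
  solution$V <- solution$V * factor
  solution$E <- solution$E * factor
  solution$magnitude <- solution$magnitude * abs(factor)
  if (!is.null(solution$flux)) solution$flux <- solution$flux * factor
  if (!is.null(solution$drive$current))
    solution$drive$current <- solution$drive$current * factor
  solution
}
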