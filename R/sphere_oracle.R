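#' Configuration for the analytic conducting-sphere oracle
#'
#' Point current source and sink on the surface of a homogeneous,
#' insulated conducting sphere. The interior potential has the classical
#' Legendre-series form
#' `V(r) = I/(4 pi sigma R) * sum_{n>=1} (2n+1)/n (r/R)^n P_n(cos gamma)`
#' per source (sink with opposite sign), which also admits a closed form
#' used as an internal cross-check and for evaluation points close to the
#' surface.
#'
#' @param radius sphere radius (mm).
#' @param sigma conductivity (S/m).
#' @param source,sink unit direction vectors of the surface electrodes.
#' @param current injected current (mA): `+current` at `source`, `-current`
#'   at `sink`.
#' @param n_terms series truncation order N.
#' @return a `sphere_source_config`.
#' @export
sphere_source_config <- function(radius = 50, sigma = 0.1,
                                 source = c(0, 0, 1), sink = c(0, 0, -1),
                                 current = 1, n_terms = 100L) {
  if (radius <= 0 || sigma <= 0) abort("radius and sigma must be positive")
  if (!is.finite(current)) abort("current must be finite")
  if (n_terms < 1) abort("n_terms must be >= 1")
  structure(list(
    radius = radius, sigma = sigma,
    source = unit(source), sink = unit(sink),
    current = current, n_terms = as.integer(n_terms)
  ), class = "sphere_source_config")
}

# Legendre polynomials P_0..P_N at u (vector), via the three-term recurrence.
# Returns a length(u) x (N+1) matrix.
legendre_table <- function(u, N) {
  P <- matrix(0, length(u), N + 1)
  P[, 1] <- 1
  if (N >= 1) P[, 2] <- u
  if (N >= 2) for (n in 1:(N - 1)) {
    P[, n + 2] <- ((2 * n + 1) * u * P[, n + 1] - n * P[, n]) / (n + 1)
  }
  P
}

# Derivatives P_n'(u) from P via (u^2-1) P_n' = n (u P_n - P_{n-1}).
legendre_deriv_table <- function(u, P) {
  N <- ncol(P) - 1
  D <- matrix(0, length(u), N + 1)
  if (N >= 1) {
    denom <- u^2 - 1
    safe <- abs(denom) > 1e-12
    for (n in 1:N) {
      D[safe, n + 1] <- n * (u[safe] * P[safe, n + 1] - P[safe, n]) / denom[safe]
      # at |u| ~ 1: P_n'(1) = n(n+1)/2, P_n'(-1) = (-1)^(n+1) n(n+1)/2
      D[!safe, n + 1] <- ifelse(u[!safe] > 0, 1, (-1)^(n + 1)) * n * (n + 1) / 2
    }
  }
  D
}

# Potential (volts) of a single +I surface source at unit direction s,
# truncated series. x = r/R, u = cos(angle to source).
one_source_potential_series <- function(x, u, A, N) {
  P <- legendre_table(u, N)
  n <- 1:N
  coef <- (2 * n + 1) / n
  xn <- outer(x, n, `^`)
  A * rowSums(sweep(xn, 2, coef, `*`) * P[, -1, drop = FALSE])
}

# Closed form of the same series:
# sum (2n+1)/n x^n P_n = 2/D - 2 + log(2 / (1 - x u + D)), D = sqrt(1-2xu+x^2).
one_source_potential_closed <- function(x, u, A) {
  D <- sqrt(pmax(1 - 2 * x * u + x^2, 0))
  if (any(D < 1e-12)) abort("singularity error: evaluation point at a source electrode")
  A * (2 / D - 2 + log(2 / (1 - x * u + D)))
}

eval_geometry <- function(config, eval_points) {
  p <- as.matrix(eval_points)
  if (ncol(p) != 3) abort("eval_points must be an n x 3 matrix")
  r <- row_norms(p)
  if (any(r > config$radius * (1 + 1e-9)))
    abort("eval points must lie inside or on the sphere")
  x <- r / config$radius
  rhat <- p / ifelse(r == 0, 1, r)
  list(p = p, r = r, x = x, rhat = rhat,
       us = clamp(rhat %*% config$source, -1, 1),
       uk = clamp(rhat %*% config$sink, -1, 1))
}

#' Analytic potential of a surface source/sink pair on a homogeneous sphere
#'
#' @param config a [sphere_source_config()].
#' @param eval_points n x 3 matrix of points (mm) inside the sphere, away
#'   from the source singularities.
#' @param method `"series"` (truncated Legendre series of order `n_terms`)
#'   or `"closed"` (closed-form summation, exact up to floating point).
#' @return potential vector in volts (currents in mA, lengths in mm).
#' @export
sphere_potential <- function(config, eval_points, method = c("series", "closed")) {
  method <- match.arg(method)
  g <- eval_geometry(config, eval_points)
  A <- config$current / (4 * pi * config$sigma * config$radius)
  min_gap <- min(sqrt(1 - 2 * g$x * g$us + g$x^2), sqrt(1 - 2 * g$x * g$uk + g$x^2))
  if (min_gap < 1e-9)
    abort("singularity error: evaluation point at a source electrode")
  if (method == "series") {
    N <- config$n_terms
    v <- one_source_potential_series(g$x, as.vector(g$us), A, N) -
      one_source_potential_series(g$x, as.vector(g$uk), A, N)
  } else {
    v <- one_source_potential_closed(g$x, as.vector(g$us), A) -
      one_source_potential_closed(g$x, as.vector(g$uk), A)
  }
  as.numeric(v)
}

# Gradient of the one-source potential w.r.t. (x, u), series form.
one_source_grad_series <- function(x, u, A, N) {
  P <- legendre_table(u, N)
  D <- legendre_deriv_table(u, P)
  n <- 1:N
  coef <- (2 * n + 1) / n
  xn1 <- outer(x, n - 1, `^`) # x^(n-1)
  dx <- A * rowSums(sweep(xn1, 2, (2 * n + 1), `*`) * P[, -1, drop = FALSE])
  du <- A * rowSums(sweep(xn1 * x, 2, coef, `*`) * D[, -1, drop = FALSE])
  list(dx = dx, du = du)
}

# Gradient, closed form.
one_source_grad_closed <- function(x, u, A) {
  D <- sqrt(pmax(1 - 2 * x * u + x^2, 1e-300))
  S <- 1 - x * u + D
  dD_dx <- (x - u) / D
  dD_du <- -x / D
  dx <- A * (-2 * dD_dx / D^2 - (-u + dD_dx) / S)
  du <- A * (-2 * dD_du / D^2 - (-x + dD_du) / S)
  list(dx = dx, du = du)
}

#' Analytic electric field of the sphere source/sink pair
#'
#' Gradient of [sphere_potential()] evaluated analytically; fields are
#' reported in V/m.
#'
#' @inheritParams sphere_potential
#' @return list with `E` (n x 3 matrix, V/m) and `magnitude` (V/m).
#' @export
sphere_field <- function(config, eval_points, method = c("series", "closed")) {
  method <- match.arg(method)
  g <- eval_geometry(config, eval_points)
  A <- config$current / (4 * pi * config$sigma * config$radius)
  R <- config$radius
  grad_fun <- if (method == "series") {
    function(x, u) one_source_grad_series(x, u, A, config$n_terms)
  } else {
    function(x, u) one_source_grad_closed(x, u, A)
  }
  gs <- grad_fun(g$x, as.vector(g$us))
  gk <- grad_fun(g$x, as.vector(g$uk))

  # dV/dp = dV/dx * rhat / R + dV/du * (s - u rhat) / r, per source
  r_safe <- ifelse(g$r == 0, 1, g$r)
  dir_s <- (matrix(config$source, nrow(g$p), 3, byrow = TRUE) -
              g$rhat * as.vector(g$us)) / r_safe
  dir_k <- (matrix(config$sink, nrow(g$p), 3, byrow = TRUE) -
              g$rhat * as.vector(g$uk)) / r_safe
  gradV <- g$rhat * ((gs$dx - gk$dx) / R) + dir_s * gs$du - dir_k * gk$du
  # at the centre r = 0 the tangential term needs the u-derivative via
  # lim r->0: dV/dp = dV/dx * rhat/R is ill-defined; use the series' linear
  # term directly: grad V = (3 A / R) (s - k) for n = 1
  at0 <- g$r == 0
  if (any(at0)) {
    gradV[at0, ] <- matrix((3 * A / R) * (config$source - config$sink),
                           sum(at0), 3, byrow = TRUE)
  }
  E <- -gradV * 1000 # V/mm -> V/m
  list(E = E, magnitude = row_norms(E))
}
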