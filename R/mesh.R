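# Radial meshes, finite-difference stencils and quadrature.
#
# A mesh is a strictly increasing numeric vector of node radii starting at 0;
# the last node is the free boundary R(t).

#' Uniform radial mesh
#'
#' @param N number of nodes (including the origin and the boundary)
#' @param R outer radius (cm)
#' @return numeric vector of node radii, `r[1] = 0`, `r[N] = R`
#' @export
radial_mesh <- function(N, R) {
  if (N < 8) stop("need at least 8 mesh nodes")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  seq(0, R, length.out = N)
}

check_mesh <- function(r) {
  if (length(r) < 3 || r[1] != 0 || any(diff(r) <= 0))
    stop("mesh must start at 0 and be strictly increasing")
  invisible(r)
}

#' Nonuniform first and second derivative stencils
#'
#' Three-point finite-difference quotients on a nonuniform mesh, in the
#' signed-spacing convention `h_-1 = r[i-1] - r[i]` (negative) and
#' `h_1 = r[i+1] - r[i]` (positive):
#' \deqn{X_r = \frac{h_{-1}^2 X_{i+1} - h_1^2 X_{i-1} + (h_1^2-h_{-1}^2)X_i}
#'              {h_1(h_{-1}^2 - h_1 h_{-1})}}
#' \deqn{X_{rr} = 2\frac{h_{-1} X_{i+1} - h_1 X_{i-1} + (h_1-h_{-1})X_i}
#'              {h_1(h_1 h_{-1} - h_{-1}^2)}}
#' Both are exact on polynomials of degree <= 2 and reduce to central
#' differences on a uniform mesh.
#'
#' @param values field values at the nodes
#' @param r node radii
#' @param i interior node index (1-based; `1 < i < length(r)`)
#' @return list with `X_r` and `X_rr`
#' @export
nonuniform_derivatives <- function(values, r, i) {
  n <- length(r)
  if (length(values) != n) stop("values and mesh length differ")
  if (any(i <= 1 | i >= n)) stop("stencil defined at interior nodes only")
  hm <- r[i - 1] - r[i]
  hp <- r[i + 1] - r[i]
  if (any(hm == 0) || any(hp == 0)) stop("degenerate mesh spacing")
  X_r <- (hm^2 * values[i + 1] - hp^2 * values[i - 1] +
            (hp^2 - hm^2) * values[i]) / (hp * (hm^2 - hp * hm))
  X_rr <- 2 * (hm * values[i + 1] - hp * values[i - 1] +
                 (hp - hm) * values[i]) / (hp * (hp * hm - hm^2))
  list(X_r = X_r, X_rr = X_rr)
}

# Gradient on the whole mesh.  Symmetry gives X_r(0) = 0; the outer node
# uses a first-order one-sided difference (only used for the small
# mesh-motion correction term, never for diffusion).
fd_gradient <- function(values, r) {
  n <- length(r)
  g <- numeric(n)
  if (n > 2) {
    d <- nonuniform_derivatives(values, r, 2:(n - 1))
    g[2:(n - 1)] <- d$X_r
  }
  g[n] <- (values[n] - values[n - 1]) / (r[n] - r[n - 1])
  g
}

# Radial Laplacian X_rr + (2/r) X_r using the printed stencils, with the
# symmetric limit 3*X_rr at the origin.  `outer` specifies the ghost used
# at the boundary node: list(type = "noflux") or
# list(type = "robin", alpha = , X0 = ) meaning X_r(R) = -alpha*(X-X0)^+.
fd_laplacian_radial <- function(values, r, outer = list(type = "noflux")) {
  n <- length(r)
  L <- numeric(n)
  if (n > 2) {
    d <- nonuniform_derivatives(values, r, 2:(n - 1))
    L[2:(n - 1)] <- d$X_rr + 2 * d$X_r / r[2:(n - 1)]
  }
  h1 <- r[2] - r[1]
  L[1] <- 3 * 2 * (values[2] - values[1]) / h1^2
  hN <- r[n] - r[n - 1]
  slope <- if (identical(outer$type, "robin"))
    -outer$alpha * max(values[n] - outer$X0, 0) else 0
  ghost <- values[n - 1] + 2 * hN * slope      # symmetric ghost at r_N + hN
  X_rr <- (ghost - 2 * values[n] + values[n - 1]) / hN^2
  L[n] <- X_rr + 2 * slope / r[n]
  L
}

# Conservative (finite-volume) radial Laplacian.  Faces at interval
# midpoints; zero flux through the origin; the outer face lies exactly on
# the boundary and carries the (possibly Robin) boundary flux
# q = -X_r(R) = alpha*(X_N - X0)^+ (outward).  Mass, measured as
# sum(X * shell volume), is conserved exactly under no-flux.
fv_geometry <- function(r) {
  n <- length(r)
  face <- c(0, (r[-n] + r[-1]) / 2, r[n])      # n+1 faces
  vol <- (face[-1]^3 - face[-(n + 1)]^3) / 3   # per-node volume / (4*pi)
  list(face = face, vol = vol, dr = diff(r))
}

fv_laplacian <- function(values, r, outer = list(type = "noflux"),
                         geom = fv_geometry(r)) {
  n <- length(r)
  grad <- diff(values) / geom$dr               # at interior faces
  flux <- c(0, geom$face[2:n]^2 * grad, 0)     # area-weighted, n+1 entries
  if (identical(outer$type, "robin"))
    flux[n + 1] <- geom$face[n + 1]^2 *
      (-outer$alpha * max(values[n] - outer$X0, 0))
  diff(flux) / geom$vol
}

# Backward-Euler diffusion solve: (I - tau*D*L) X = rhs, with L the
# finite-volume Laplacian above.  The Robin clamp is decided on the
# explicit predictor (`robin_on`), making the solve linear.
implicit_diffusion_solve <- function(rhs, r, D, tau,
                                     outer = list(type = "noflux"),
                                     geom = fv_geometry(r)) {
  n <- length(r)
  if (D == 0 || tau == 0) return(rhs)
  wlo <- geom$face[2:n]^2 / geom$dr            # coupling i <-> i+1
  lower <- numeric(n); diagc <- numeric(n); upper <- numeric(n)
  d <- rhs
  for (i in seq_len(n)) {
    aplus <- if (i < n) wlo[i] / geom$vol[i] else 0
    aminus <- if (i > 1) wlo[i - 1] / geom$vol[i] else 0
    diagc[i] <- 1 + tau * D * (aplus + aminus)
    if (i < n) upper[i] <- -tau * D * aplus
    if (i > 1) lower[i] <- -tau * D * aminus
  }
  if (identical(outer$type, "robin")) {
    bflux <- geom$face[n + 1]^2 * outer$alpha / geom$vol[n]
    diagc[n] <- diagc[n] + tau * D * bflux
    d[n] <- d[n] + tau * D * bflux * outer$X0
  }
  thomas_solve(lower, diagc, upper, d)
}

# Tridiagonal (Thomas) solver; lower[1] and upper[n] are ignored.
thomas_solve <- function(lower, diagc, upper, d) {
  n <- length(d)
  cp <- numeric(n); dp <- numeric(n)
  denom <- diagc[1]
  if (denom == 0) stop("singular tridiagonal system")
  cp[1] <- upper[1] / denom
  dp[1] <- d[1] / denom
  for (i in 2:n) {
    denom <- diagc[i] - lower[i] * cp[i - 1]
    if (denom == 0) stop("singular tridiagonal system")
    cp[i] <- if (i < n) upper[i] / denom else 0
    dp[i] <- (d[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Spherical-shell trapezoid integral
#'
#' `int_0^R X(r) r^2 dr` by the trapezoid rule on the mesh nodes.
#'
#' @param values field values
#' @param r node radii
#' @return the integral (units of `values` times cm^3)
#' @export
radial_integral <- function(values, r) {
  f <- values * r^2
  sum((f[-1] + f[-length(f)]) / 2 * diff(r))
}

#' Interpolate fields onto a fresh uniform mesh
#'
#' Linear (hence monotone) interpolation of every field onto a uniform mesh
#' of `N` nodes on `[0, R]`, where `R` is the current outer radius.
#'
#' @param fields named list of per-node field vectors
#' @param r current mesh
#' @param N node count of the new mesh
#' @return list with elements `fields` and `r`
#' @export
regrid <- function(fields, r, N) {
  check_mesh(r)
  r_new <- radial_mesh(N, r[length(r)])
  fields_new <- lapply(fields, function(x)
    approx(r, x, xout = r_new, rule = 2)$y)
  list(fields = fields_new, r = r_new)
}
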