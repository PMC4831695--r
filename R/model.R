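# Model right-hand sides on a radial mesh: reaction terms of the 17 fields,
# the hypoxia modulation, the chemotactic flux divergence, the velocity
# integral and the free-boundary rate.

#' Field names of the model state
#'
#' Nine cytokine/protein concentrations (TF, V, P, uPR, uPi, uPa, PA, q, p),
#' four cell densities (M, E, f, C), oxygen (w), MMP/TIMP (Q, Qr) and ECM
#' (rho); all in g/cm^3.
#' @export
PAS_FIELDS <- c("TF", "V", "P", "uPR", "uPi", "uPa", "PA", "q", "p",
                "M", "E", "f", "C", "w", "Q", "Qr", "rho")

# Fields transported with the cell velocity (divergence term); all other
# fields are spatially redistributed by diffusion only.
PAS_ADVECTED <- c("M", "E", "f", "C", "rho")

# Map field -> its diffusion coefficient name ("" = no diffusion).
PAS_DIFF <- c(TF = "D_T", V = "D_V", P = "D_P", uPR = "D_uPR", uPi = "D_uP",
              uPa = "D_uP", PA = "D_PA", q = "D_q", p = "D_p", M = "D_M",
              E = "D_E", f = "D_f", C = "D_C", w = "D_w", Q = "D_Q",
              Qr = "D_Qr", rho = "")

#' Construct a model state
#'
#' @param fields named list of per-node numeric vectors (all of
#'   [PAS_FIELDS], equal length)
#' @param r mesh node radii (same length)
#' @return object of class `pas_state`: list with `fields` and `r`
#' @export
pas_state <- function(fields, r) {
  check_mesh(r)
  missing <- setdiff(PAS_FIELDS, names(fields))
  if (length(missing)) stop("missing field(s): ", paste(missing, collapse = ", "))
  n <- length(r)
  for (fn in PAS_FIELDS) {
    x <- fields[[fn]]
    if (length(x) != n) stop("field ", fn, " has wrong length")
    if (any(!is.finite(x))) stop("non-finite values in field ", fn)
    if (any(x < 0)) stop("negative values in field ", fn)
  }
  structure(list(fields = fields[PAS_FIELDS], r = r), class = "pas_state")
}

#' Hypoxia-modulated rate
#'
#' A production rate that equals its plateau value for oxygen at or above
#' the hypoxia threshold `w_h` and scales linearly with `w` below it:
#' `plateau * min(w / w_h, 1)`.
#'
#' @param w oxygen concentration(s), g/cm^3
#' @param plateau normoxic rate (1/day)
#' @param w_h hypoxia threshold (g/cm^3)
#' @return modulated rate(s)
#' @export
hypoxia_factor <- function(w, plateau, w_h) {
  if (any(w < 0)) stop("oxygen must be nonnegative")
  plateau * pmin(w / w_h, 1)
}

#' Reaction (non-transport) rates of all fields
#'
#' Evaluates, node by node, the production/degradation terms of the 17
#' field equations exactly as modeled; transport (diffusion, advection,
#' chemotaxis) is handled elsewhere.  Purely local: node i's output
#' depends only on node i's values.
#'
#' @param state a [pas_state()] (or bare named list of field vectors)
#' @param params a `pas_parameters` set
#' @param normalize_EV if TRUE the endothelial proliferation factor
#'   `(V - V0)^+` is divided by `K_V` (exploratory switch; default keeps
#'   the literal form)
#' @return named list of per-node rate vectors (g/cm^3/day)
#' @export
reaction_rates <- function(state, params, normalize_EV = FALSE) {
  s <- if (inherits(state, "pas_state")) state$fields else state
  for (fn in PAS_FIELDS) {
    x <- s[[fn]]
    if (is.null(x) || any(!is.finite(x)) || any(x < 0))
      stop("invalid state in field ", fn)
  }
  p <- params
  Vfac <- pmax(s$V - p$V0, 0)
  if (normalize_EV) Vfac <- Vfac / p$K_V
  uPa_eff <- s$uPa / (p$K_PA + s$PA)
  uPR_eff <- s$uPR / (p$K_uPR + s$uPR)
  list(
    TF  = p$A_T + p$lambda_TC * s$C - p$d_T * s$TF,
    V   = p$lambda_VC * s$C * (1 + p$lambda_VT * s$TF / (p$K_T + s$TF)) +
          p$lambda_VM * s$M - p$d_V * s$V,
    P   = p$lambda_P * (1 + p$lambda_Pu * uPa_eff) - p$d_P * s$P,
    uPR = p$lambda_uPRM * s$M + p$lambda_uPRC * s$C - p$d_uPR * s$uPR,
    uPi = p$lambda_uf * s$f - p$d_uPi * s$uPi,
    uPa = p$lambda_u * s$uPi * uPR_eff - p$d_uPa * s$uPa,
    PA  = p$lambda_PC * s$C + p$lambda_Pf * s$f + p$lambda_PM * s$M -
          p$d_PA * s$PA,
    q   = p$lambda_qC * s$C - p$d_q * s$q,
    p   = hypoxia_factor(s$w, p$lambda_p, p$w_h) * s$q / (p$q0 + s$q) * s$M -
          p$d_p * s$p,
    M   = p$beta * s$p / (p$K_p + s$p) * p$M0 - p$d_M * s$M,
    E   = p$lambda_E * s$E * (1 - s$E / p$K_E) * Vfac - p$d_E * s$E,
    f   = p$A_f + p$lambda_fC * s$f * s$C / (p$K_C + s$C) - p$d_f * s$f,
    C   = (hypoxia_factor(s$w, p$lambda_wC, p$w_h) +
             p$lambda_Cf * s$f / (p$K_f + s$f) +
             p$lambda_CuP * uPa_eff * uPR_eff) * s$C * (1 - s$C / p$C0) -
          p$d_C * s$C,
    w   = p$lambda_w * s$E - (p$d_wM * s$M + p$d_wC * s$C + p$d_wf * s$f) * s$w,
    Q   = p$lambda_QM * s$M * (1 + p$lambda_QP * s$P / (p$K_P + s$P)) -
          p$d_QQr * s$Qr * s$Q - p$d_Q * s$Q,
    Qr  = p$lambda_QrM * s$M - p$d_QrQ * s$Q * s$Qr - p$d_Qr * s$Qr,
    rho = p$lambda_rhof * s$f * pmax(1 - s$rho / p$rho0, 0) -
          p$d_rho * s$rho - p$d_rhoQ * s$Q * s$rho
  )
}

#' Chemotactic flux divergence
#'
#' The chemotaxis contribution to a carrier cell's rate equation,
#' `-div(chi * grad(attractant))`, i.e. `-chi * Laplacian(attractant)` in
#' the literal constant-coefficient form of the model (the carrier density
#' does not enter the flux).  Computed with the conservative radial
#' Laplacian; zero at the origin by symmetry, zero flux through the
#' boundary (the attractants obey no-flux conditions).
#'
#' @param carrier carrier cell density (unused in the literal flux; kept
#'   for the interface and for mesh-consistency checking)
#' @param attractant attractant concentration at the nodes
#' @param chi chemotactic coefficient
#' @param r mesh
#' @return per-node rate contribution
#' @export
chemotaxis_flux_divergence <- function(carrier, attractant, chi, r) {
  if (length(carrier) != length(r) || length(attractant) != length(r))
    stop("fields and mesh have different node counts")
  -chi * fv_laplacian(attractant, r)
}

#' Radial velocity from a volumetric source density
#'
#' Solves `div(u) = S` under radial symmetry with `u(0) = 0`:
#' `u(r) = (1/r^2) * int_0^r s^2 S(s) ds`.  The integral uses
#' spherical-shell (d(s^3)/3) trapezoid weights, which are exact for
#' constant `S` and second-order for smooth `S`.
#'
#' @param S per-node source density (1/day)
#' @param r mesh
#' @return per-node radial velocity (cm/day)
#' @export
velocity_from_source <- function(S, r) {
  dvol <- diff(r^3) / 3
  cum <- c(0, cumsum((S[-1] + S[-length(S)]) / 2 * dvol))
  u <- numeric(length(r))
  u[-1] <- cum[-1] / r[-1]^2
  u
}

#' Tissue velocity field from the total-density constraint
#'
#' The divergence of the common cell velocity balances the net local
#' production of the advected phases (cells plus ECM): `theta * div(u) =
#' sum of the reaction + chemotaxis terms of M, E, f, C, rho  -  D *
#' Laplacian(rho)`, where `theta` is the (constant) total density of the
#' advected phases and `D` the common cell dispersion coefficient.
#'
#' @param state a [pas_state()]
#' @param params parameter set
#' @param theta conserved total density of M+E+f+C+rho (default: the
#'   state's own boundary-node total, which is 0.6 for the standard
#'   initial data)
#' @param normalize_EV passed to [reaction_rates()]
#' @param rates optional precomputed [reaction_rates()] output
#' @return per-node radial velocity (cm/day)
#' @export
velocity_field <- function(state, params, theta = NULL, normalize_EV = FALSE,
                           rates = NULL) {
  s <- state$fields; r <- state$r
  if (is.null(rates)) rates <- reaction_rates(state, params, normalize_EV)
  if (is.null(theta)) theta <- sum(vapply(PAS_ADVECTED, function(fn)
    s[[fn]][length(r)], numeric(1)))
  chem_M <- chemotaxis_flux_divergence(s$M, s$p, params$chi_C, r)
  chem_E <- chemotaxis_flux_divergence(s$E, s$V, params$chi_C, r)
  S <- (rates$M + chem_M + rates$E + chem_E + rates$f + rates$C + rates$rho -
          params$D_M * fv_laplacian(s$rho, r)) / theta
  velocity_from_source(S, r)
}

#' Robin boundary coefficients for oxygen and endothelial cells
#'
#' Flux conditions `dX/dn + alpha_X (X - X0)^+ = 0` at the free boundary,
#' with `alpha_w = alpha_w~ * E/(K_E + E)` and `alpha_E = alpha_E~ *
#' V/(K_V + V)` evaluated at r = R.  The positive-part clamp means the
#' condition degenerates to no-flux whenever the boundary value does not
#' exceed the vascular level `X0`.  All other species satisfy no-flux; the
#' ECM, being purely advected, needs no boundary condition.
#'
#' @param state a [pas_state()]
#' @param params parameter set
#' @return list with `alpha_w`, `alpha_E`, and logicals `active_w`,
#'   `active_E` indicating whether the clamp admits a flux
#' @export
robin_boundary <- function(state, params) {
  n <- length(state$r)
  Eb <- state$fields$E[n]; Vb <- state$fields$V[n]
  wb <- state$fields$w[n]
  list(alpha_w = params$alpha_w_tilde * Eb / (params$K_E + Eb),
       alpha_E = params$alpha_E_tilde * Vb / (params$K_V + Vb),
       active_w = wb > params$w0,
       active_E = Eb > params$E0)
}

#' Free-boundary growth rate
#'
#' `dR/dt = u(R(t), t)`: the radial velocity at the outermost node.
#'
#' @param u per-node velocity (cm/day)
#' @return scalar boundary speed (cm/day)
#' @export
free_boundary_rate <- function(u) u[length(u)]
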