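# Time integration on the moving radial mesh.
#
# Two schemes:
#  * "explicit": the fully explicit total-derivative scheme with the
#    printed nonuniform stencils; subject to the stability rule
#    tau <= min(h)^2 / (2 D_max), so only usable on short fidelity tests.
#  * "implicit-split" (default): reaction + advection + mesh motion advanced
#    explicitly, diffusion by a backward-Euler tridiagonal solve per field
#    on the current mesh (conservative finite-volume form).

#' Solver options
#'
#' @param scheme `"implicit-split"` (default) or `"explicit"`
#' @param tau time step, days
#' @param N mesh nodes
#' @param t_end end time, days
#' @param record_every output cadence, days
#' @param regrid_every regrid to a uniform mesh every this many steps
#'   (0 = never)
#' @param theta conserved total density of the advected phases; `NULL`
#'   means use the initial sum of M+E+f+C+rho
#' @param transport if `FALSE`, diffusion, chemotaxis and velocity are all
#'   switched off (the ODE limit); fields then stay spatially uniform
#' @param reactions if `FALSE`, reaction, chemotaxis and velocity terms are
#'   switched off, leaving pure diffusion on a fixed sphere (conservation
#'   tests)
#' @param normalize_EV divide the endothelial `(V-V0)^+` factor by `K_V`
#' @param literal_advection explicit scheme only: use the literal
#'   printed `(v_r r + v) X` term instead of the radial divergence
#' @param clamp clamp negative values to zero after each step
#' @param engine `"cpp"` (compiled fast path) or `"R"` (reference
#'   implementation); the explicit scheme always runs in R
#' @param blowup_limit abort threshold on any field value (g/cm^3)
#' @param R_min elimination floor (cm): if the free boundary shrinks below
#'   this radius (smaller than a single cell) the tumor is declared
#'   eliminated and the state is frozen for the rest of the run
#' @param snapshots keep full field snapshots at the record times
#' @return list of class `pas_solver_options`
#' @export
solver_options <- function(scheme = c("implicit-split", "explicit"),
                           tau = 0.01, N = 64, t_end = 600,
                           record_every = 1, regrid_every = 50,
                           theta = NULL, transport = TRUE, reactions = TRUE,
                           normalize_EV = FALSE, literal_advection = FALSE,
                           clamp = TRUE, engine = c("cpp", "R"),
                           blowup_limit = 1e3, R_min = 5e-4,
                           snapshots = TRUE) {
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  stopifnot(tau > 0, N >= 8, t_end >= 0, record_every > 0, blowup_limit > 0,
            R_min > 0)
  structure(list(scheme = scheme, tau = tau, N = N, t_end = t_end,
                 record_every = record_every, regrid_every = regrid_every,
                 theta = theta, transport = transport, reactions = reactions,
                 normalize_EV = normalize_EV,
                 literal_advection = literal_advection, clamp = clamp,
                 engine = engine, blowup_limit = blowup_limit,
                 R_min = R_min, snapshots = snapshots),
            class = "pas_solver_options")
}

#' Standard initial state
#'
#' Spatially uniform initial data: rho = 0.02, w = w_h, M = 0.07,
#' E = 0.05, f = 0.06, C = 0.4 (g/cm^3); all cytokines zero.
#'
#' @param R0 initial radius, cm
#' @param params parameter set (supplies `w_h`)
#' @param N mesh nodes
#' @return a [pas_state()]
#' @export
initial_state <- function(R0, params, N = 64) {
  r <- radial_mesh(N, R0)
  vals <- c(TF = 0, V = 0, P = 0, uPR = 0, uPi = 0, uPa = 0, PA = 0,
            q = 0, p = 0, M = 0.07, E = 0.05, f = 0.06, C = 0.4,
            w = params$w_h, Q = 0, Qr = 0, rho = 0.02)
  fields <- lapply(vals, function(v) rep(v, N))
  pas_state(fields, r)
}

# Radial divergence of the node velocity: v_r + 2 v/r, with the symmetric
# limit 3 v_r(0) at the origin (v(0) = 0 so v_r(0) = v(r)/r as r -> 0).
velocity_divergence <- function(u, r) {
  n <- length(r)
  dv <- numeric(n)
  if (n > 2) {
    d <- nonuniform_derivatives(u, r, 2:(n - 1))
    dv[2:(n - 1)] <- d$X_r + 2 * u[2:(n - 1)] / r[2:(n - 1)]
  }
  dv[1] <- 3 * u[2] / r[2]
  dv[n] <- (u[n] - u[n - 1]) / (r[n] - r[n - 1]) + 2 * u[n] / r[n]
  dv
}

# Shared explicit phase: reaction + chemotaxis rates, velocity, divergence.
explicit_phase <- function(state, params, opts) {
  s <- state$fields; r <- state$r
  if (!opts$reactions) {
    zero <- numeric(length(r))
    return(list(rates = setNames(rep(list(zero), length(PAS_FIELDS)),
                                 PAS_FIELDS), u = zero))
  }
  rates <- reaction_rates(state, params, opts$normalize_EV)
  if (opts$transport) {
    rates$M <- rates$M + chemotaxis_flux_divergence(s$M, s$p, params$chi_C, r)
    rates$E <- rates$E + chemotaxis_flux_divergence(s$E, s$V, params$chi_C, r)
    theta <- opts$theta
    if (is.null(theta)) theta <- sum(vapply(PAS_ADVECTED, function(fn)
      s[[fn]][length(r)], numeric(1)))
    S <- (rates$M + rates$E + rates$f + rates$C + rates$rho -
            params$D_M * fv_laplacian(s$rho, r)) / theta
    u <- velocity_from_source(S, r)
  } else {
    u <- numeric(length(r))
  }
  list(rates = rates, u = u)
}

outer_bc <- function(fn, pred, params, n) {
  if (fn == "w") {
    Eb <- pred$E[n]
    if (pred$w[n] > params$w0)
      return(list(type = "robin",
                  alpha = params$alpha_w_tilde * Eb / (params$K_E + Eb),
                  X0 = params$w0))
  } else if (fn == "E") {
    Vb <- pred$V[n]
    if (pred$E[n] > params$E0)
      return(list(type = "robin",
                  alpha = params$alpha_E_tilde * Vb / (params$K_V + Vb),
                  X0 = params$E0))
  }
  list(type = "noflux")
}

#' One operator-split step (explicit reaction/advection, implicit diffusion)
#'
#' @param state a [pas_state()]
#' @param params parameter set
#' @param tau step size, days
#' @param opts [solver_options()]
#' @return list with `state`, and `clamped` (count of negative values
#'   clamped to zero)
#' @export
step_implicit_split <- function(state, params, tau,
                                opts = solver_options(engine = "R")) {
  s <- state$fields; r <- state$r; n <- length(r)
  ph <- explicit_phase(state, params, opts)
  u <- ph$u
  transporting <- opts$transport && any(u != 0)
  divv <- if (transporting) velocity_divergence(u, r) else numeric(n)
  pred <- s
  for (fn in PAS_FIELDS) {
    adv <- if (!transporting) 0
    else if (fn %in% PAS_ADVECTED) -divv * s[[fn]]
    else u * fd_gradient(s[[fn]], r)   # mesh-motion correction
    pred[[fn]] <- s[[fn]] + tau * (ph$rates[[fn]] + adv)
  }
  r_new <- r + tau * u
  out <- pred
  if (opts$transport) {
    geom <- fv_geometry(r_new)
    for (fn in PAS_FIELDS) {
      Dn <- PAS_DIFF[[fn]]
      if (!nzchar(Dn)) next
      out[[fn]] <- implicit_diffusion_solve(
        pred[[fn]], r_new, params[[Dn]], tau,
        outer = outer_bc(fn, pred, params, n), geom = geom)
    }
  }
  clamped <- 0L
  if (opts$clamp) {
    for (fn in PAS_FIELDS) {
      neg <- out[[fn]] < 0
      clamped <- clamped + sum(neg)
      out[[fn]][neg] <- 0
    }
  }
  list(state = structure(list(fields = out, r = r_new), class = "pas_state"),
       clamped = clamped)
}

#' One fully explicit step (the printed moving-mesh scheme)
#'
#' Refuses to step if `tau` violates the stability rule
#' `tau <= min(h)^2 / (2 D_max)` over the diffusing fields.
#'
#' @inheritParams step_implicit_split
#' @return list with `state` and `clamped`
#' @export
step_explicit <- function(state, params, tau,
                          opts = solver_options(scheme = "explicit",
                                                engine = "R")) {
  s <- state$fields; r <- state$r; n <- length(r)
  if (opts$transport) {
    Dmax <- max(unlist(params[PAS_DIFF[nzchar(PAS_DIFF)]]))
    hmin <- min(diff(r))
    tau_max <- hmin^2 / (2 * Dmax)
    if (tau > tau_max)
      stop(sprintf(
        "explicit stability violated: tau = %.3g > min(h)^2/(2 D) = %.3g",
        tau, tau_max))
  }
  ph <- explicit_phase(state, params, opts)
  u <- ph$u
  transporting <- opts$transport && any(u != 0)
  divv <- if (transporting) velocity_divergence(u, r) else numeric(n)
  u_r <- if (transporting) fd_gradient(u, r) else numeric(n)
  out <- s
  for (fn in PAS_FIELDS) {
    adv <- 0
    if (transporting) {
      if (opts$literal_advection && fn %in% PAS_ADVECTED) {
        adv <- -(u_r * r + u) * s[[fn]]          # literal printed term
      } else if (fn %in% PAS_ADVECTED) {
        adv <- -divv * s[[fn]]
      } else {
        adv <- u * fd_gradient(s[[fn]], r)
      }
    }
    diff_term <- 0
    Dn <- PAS_DIFF[[fn]]
    if (opts$transport && nzchar(Dn) && params[[Dn]] > 0)
      diff_term <- params[[Dn]] *
        fd_laplacian_radial(s[[fn]], r, outer_bc(fn, s, params, n))
    out[[fn]] <- s[[fn]] + tau * (ph$rates[[fn]] + adv + diff_term)
  }
  r_new <- if (opts$transport) r + tau * u else r
  clamped <- 0L
  if (opts$clamp) {
    for (fn in PAS_FIELDS) {
      neg <- out[[fn]] < 0
      clamped <- clamped + sum(neg)
      out[[fn]][neg] <- 0
    }
  }
  list(state = structure(list(fields = out, r = r_new), class = "pas_state"),
       clamped = clamped)
}

#' Simulate tumor growth from an initial radius
#'
#' Advances the full moving-mesh model from the standard initial state and
#' returns a trajectory of fields, mesh, free boundary and the two summary
#' observables (average density and total mass) per field.
#'
#' @param R0 initial radius, cm (0.005 to 0.05 is the intended range)
#' @param params parameter set (default [baseline_parameter_set()])
#' @param options a [solver_options()]
#' @param state optional custom initial [pas_state()] (overrides `R0`)
#' @return object of class `pas_trajectory`: list with `times`, `R`,
#'   `mass` and `ave` (time x field matrices), `snapshots`/`mesh` (if
#'   requested), `clamped`, `aborted`, `params`, `options`
#' @export
simulate <- function(R0 = 0.01, params = baseline_parameter_set(),
                     options = solver_options(), state = NULL) {
  params <- validate_parameters(params)
  if (is.null(state)) state <- initial_state(R0, params, options$N)
  if (is.null(options$theta))
    options$theta <- sum(vapply(PAS_ADVECTED, function(fn)
      state$fields[[fn]][length(state$r)], numeric(1)))
  if (options$engine == "cpp" && options$scheme == "implicit-split") {
    traj <- simulate_cpp_engine(state, params, options)
  } else {
    traj <- simulate_r_engine(state, params, options)
  }
  traj
}

record_row <- function(state) {
  r <- state$r
  m <- vapply(PAS_FIELDS, function(fn)
    4 * pi * radial_integral(state$fields[[fn]], r), numeric(1))
  a <- vapply(PAS_FIELDS, function(fn)
    radial_integral(state$fields[[fn]], r) / r[length(r)]^3, numeric(1))
  list(mass = m, ave = a, R = r[length(r)])
}

finish_trajectory <- function(times, Rs, mass, ave, snaps, meshes, clamped,
                              aborted, eliminated, params, options) {
  structure(list(times = times, R = Rs,
                 mass = do.call(rbind, mass), ave = do.call(rbind, ave),
                 snapshots = snaps, mesh = meshes, clamped = clamped,
                 aborted = aborted, eliminated = eliminated,
                 params = params, options = options),
            class = "pas_trajectory")
}

simulate_r_engine <- function(state, params, options) {
  tau <- options$tau
  nsteps <- round(options$t_end / tau)
  stride <- max(1L, as.integer(round(options$record_every / tau)))
  stepper <- if (options$scheme == "implicit-split") step_implicit_split
             else step_explicit
  times <- 0; Rs <- state$r[length(state$r)]
  rec <- record_row(state)
  mass <- list(rec$mass); ave <- list(rec$ave)
  snaps <- if (options$snapshots) list(state$fields) else NULL
  meshes <- if (options$snapshots) list(state$r) else NULL
  clamped <- 0L; aborted <- FALSE; eliminated <- FALSE
  if (nsteps > 0) for (k in seq_len(nsteps)) {
    if (!eliminated) {
      st <- stepper(state, params, tau, options)
      state <- st$state
      clamped <- clamped + st$clamped
      if (state$r[length(state$r)] < options$R_min) eliminated <- TRUE
    }
    if (!eliminated && options$transport && options$regrid_every > 0 &&
        k %% options$regrid_every == 0) {
      rg <- regrid(state$fields, state$r, options$N)
      state <- structure(list(fields = rg$fields, r = rg$r),
                         class = "pas_state")
    }
    if (k %% stride == 0 || k == nsteps) {
      vals <- unlist(state$fields, use.names = FALSE)
      if (any(!is.finite(vals)) || any(abs(vals) > options$blowup_limit) ||
          !is.finite(state$r[length(state$r)]) || state$r[length(state$r)] <= 0) {
        aborted <- TRUE
        warning("simulation aborted: field blow-up or boundary collapse at t = ",
                k * tau, call. = FALSE)
        break
      }
      times <- c(times, k * tau)
      rec <- record_row(state)
      Rs <- c(Rs, rec$R)
      mass <- c(mass, list(rec$mass)); ave <- c(ave, list(rec$ave))
      if (options$snapshots) {
        snaps <- c(snaps, list(state$fields))
        meshes <- c(meshes, list(state$r))
      }
    }
  }
  finish_trajectory(times, Rs, mass, ave, snaps, meshes, clamped, aborted,
                    eliminated, params, options)
}

simulate_cpp_engine <- function(state, params, options) {
  pv <- unlist(validate_parameters(params)[names(pas_units())])
  init <- do.call(cbind, state$fields[PAS_FIELDS])
  res <- pas_simulate_cpp(init, state$r, pv, options$tau,
                          as.integer(round(options$t_end / options$tau)),
                          max(1L, as.integer(round(options$record_every /
                                                     options$tau))),
                          as.integer(options$regrid_every), options$theta,
                          options$transport, options$reactions,
                          options$normalize_EV,
                          options$clamp, options$blowup_limit,
                          options$R_min, options$snapshots)
  nt <- length(res$times)
  snaps <- meshes <- NULL
  if (options$snapshots) {
    snaps <- lapply(res$snapshots, function(m) {
      colnames(m) <- PAS_FIELDS
      lapply(setNames(seq_along(PAS_FIELDS), PAS_FIELDS), function(j) m[, j])
    })
    meshes <- res$mesh
  }
  colnames(res$mass) <- PAS_FIELDS
  colnames(res$ave) <- PAS_FIELDS
  if (res$aborted)
    warning("simulation aborted: field blow-up or boundary collapse at t = ",
            res$times[nt], call. = FALSE)
  finish_trajectory(res$times, res$R,
                    lapply(seq_len(nt), function(i) res$mass[i, ]),
                    lapply(seq_len(nt), function(i) res$ave[i, ]),
                    snaps, meshes, res$clamped, res$aborted, res$eliminated,
                    params, options)
}

#' @export
print.pas_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat("<pas_trajectory> ", nt, " records over ",
      x$times[nt], " days; R: ", signif(x$R[1], 4), " -> ",
      signif(x$R[nt], 4), " cm",
      if (x$aborted) "  [ABORTED]",
      if (x$eliminated) "  [ELIMINATED]", "\n", sep = "")
  invisible(x)
}
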