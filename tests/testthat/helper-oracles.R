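# Independent oracles used across the suite.
#
# oracle_rhs() is a from-scratch scalar transcription of the 17 reaction
# equations, deliberately separate from reaction_rates(); oracle_rk4()
# integrates it with classic fixed-step RK4.  Together they provide the
# ODE-limit reference trajectory.

oracle_rhs <- function(y, p) {
  TF <- y[["TF"]]; V <- y[["V"]]; P <- y[["P"]]; uPR <- y[["uPR"]]
  uPi <- y[["uPi"]]; uPa <- y[["uPa"]]; PA <- y[["PA"]]; q <- y[["q"]]
  pp <- y[["p"]]; M <- y[["M"]]; E <- y[["E"]]; f <- y[["f"]]
  C <- y[["C"]]; w <- y[["w"]]; Q <- y[["Q"]]; Qr <- y[["Qr"]]
  rho <- y[["rho"]]
  lam_p_w <- p$lambda_p * min(w / p$w_h, 1)
  lam_C_w <- p$lambda_wC * min(w / p$w_h, 1)
  c(
    TF  = p$A_T + p$lambda_TC * C - p$d_T * TF,
    V   = p$lambda_VC * C * (1 + p$lambda_VT * TF / (p$K_T + TF)) +
          p$lambda_VM * M - p$d_V * V,
    P   = p$lambda_P * (1 + p$lambda_Pu * uPa / (p$K_PA + PA)) - p$d_P * P,
    uPR = p$lambda_uPRM * M + p$lambda_uPRC * C - p$d_uPR * uPR,
    uPi = p$lambda_uf * f - p$d_uPi * uPi,
    uPa = p$lambda_u * uPi * uPR / (p$K_uPR + uPR) - p$d_uPa * uPa,
    PA  = p$lambda_PC * C + p$lambda_Pf * f + p$lambda_PM * M - p$d_PA * PA,
    q   = p$lambda_qC * C - p$d_q * q,
    p   = lam_p_w * q / (p$q0 + q) * M - p$d_p * pp,
    M   = p$beta * pp / (p$K_p + pp) * p$M0 - p$d_M * M,
    E   = p$lambda_E * E * (1 - E / p$K_E) * max(V - p$V0, 0) - p$d_E * E,
    f   = p$A_f + p$lambda_fC * f * C / (p$K_C + C) - p$d_f * f,
    C   = (lam_C_w + p$lambda_Cf * f / (p$K_f + f) +
             p$lambda_CuP * (uPa / (p$K_PA + PA)) *
               (uPR / (p$K_uPR + uPR))) * C * (1 - C / p$C0) - p$d_C * C,
    w   = p$lambda_w * E - (p$d_wM * M + p$d_wC * C + p$d_wf * f) * w,
    Q   = p$lambda_QM * M * (1 + p$lambda_QP * P / (p$K_P + P)) -
          p$d_QQr * Qr * Q - p$d_Q * Q,
    Qr  = p$lambda_QrM * M - p$d_QrQ * Q * Qr - p$d_Qr * Qr,
    rho = p$lambda_rhof * f * max(1 - rho / p$rho0, 0) - p$d_rho * rho -
          p$d_rhoQ * Q * rho
  )
}

# Stiff fixed-step integrator: BDF2 with Newton iteration and a forward
# difference Jacobian (first step by implicit Euler).  L-stable, second
# order; the TIMP/MMP depletion terms make the system stiff (relaxation
# rates of order 1e3-1e4 per day), which rules out explicit oracles.
oracle_jac <- function(y, p, f0) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dy <- max(1e-8 * abs(y[j]), 1e-14)
    yp <- y; yp[j] <- yp[j] + dy
    J[, j] <- (oracle_rhs(yp, p) - f0) / dy
  }
  J
}

oracle_newton <- function(target, coef_h, y_guess, p) {
  # solve y = target + coef_h * f(y)
  y <- y_guess
  I <- diag(length(y))
  for (it in 1:8) {
    f <- oracle_rhs(y, p)
    G <- y - target - coef_h * f
    if (max(abs(G)) < 1e-16 + 1e-12 * max(abs(y))) break
    J <- I - coef_h * oracle_jac(y, p, f)
    y <- y - solve(J, G)
  }
  pmax(y, 0)
}

oracle_bdf2 <- function(y0, p, t_out, h) {
  nstep <- round(max(t_out) / h)
  out <- matrix(NA_real_, length(t_out), length(y0),
                dimnames = list(NULL, names(y0)))
  hits <- as.integer(round(t_out / h))
  if (any(hits == 0L)) out[hits == 0L, ] <- y0
  y_prev <- y0
  y <- oracle_newton(y0, h, y0, p)                  # implicit Euler start
  if (any(hits == 1L)) out[hits == 1L, ] <- y
  if (nstep >= 2) for (k in 2:nstep) {
    target <- (4 * y - y_prev) / 3
    y_new <- oracle_newton(target, 2 * h / 3, y, p)
    y_prev <- y; y <- y_new
    if (any(hits == k)) out[hits == k, ] <- y
  }
  out
}

# Uniform initial condition as a named vector (matches initial_state()).
oracle_y0 <- function(params) {
  c(TF = 0, V = 0, P = 0, uPR = 0, uPi = 0, uPa = 0, PA = 0, q = 0, p = 0,
    M = 0.07, E = 0.05, f = 0.06, C = 0.4, w = params$w_h, Q = 0, Qr = 0,
    rho = 0.02)
}

# Baseline parameters with all diffusivities scaled down so the explicit
# scheme is affordable on coarse meshes (numerics cross-checks only).
slow_diffusion_params <- function(D = 1e-5) {
  p <- baseline_parameter_set()
  for (nm in grep("^D_", names(p), value = TRUE)) p[[nm]] <- min(p[[nm]], D)
  validate_parameters(p)
}

expect_rel_equal <- function(actual, expected, tol, atol = 0) {
  err <- abs(actual - expected) / pmax(abs(expected), atol / tol)
  expect_true(all(err <= tol),
              label = sprintf("max relative error %.3g <= %.3g",
                              max(err), tol))
}
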