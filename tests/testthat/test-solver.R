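base_params <- baseline_parameter_set()

test_that("no rates, no velocity: state and mesh are unchanged", {
  st <- make_fixture("bump", N = 16, seed = 7)
  o <- solver_options(reactions = FALSE, transport = FALSE, engine = "R")
  out <- step_explicit(st, base_params, 0.01, o)
  expect_identical(out$state$fields, st$fields)
  expect_identical(out$state$r, st$r)
  out2 <- step_implicit_split(st, base_params, 0.01, o)
  expect_identical(out2$state$fields, st$fields)
})

test_that("pure decay follows the explicit Euler closed form", {
  # zero everything except inactive uPA; with f = 0 its equation is pure
  # first-order decay, so one Euler step must be exact
  st <- initial_state(0.01, base_params, 12)
  for (fn in PAS_FIELDS) st$fields[[fn]] <- rep(0, 12)
  st$fields$uPi <- rep(1e-6, 12)
  o <- solver_options(transport = FALSE, engine = "R")
  tau <- 0.01
  out <- step_explicit(st, base_params, tau, o)
  expect_equal(out$state$fields$uPi,
               rep(1e-6 * (1 - base_params$d_uPi * tau), 12))
  # n steps: fibroblast source contaminates only at O(tau^2) per step
  x <- st
  for (k in 1:10) x <- step_explicit(x, base_params, tau, o)$state
  expect_equal(x$fields$uPi, rep(1e-6 * (1 - base_params$d_uPi * tau)^10, 12),
               tolerance = 1e-6)
})

test_that("explicit scheme refuses an unstable step", {
  st <- initial_state(0.01, base_params, 20)
  o <- solver_options(scheme = "explicit", engine = "R")
  expect_error(step_explicit(st, base_params, 0.01, o), "stability")
})

test_that("diffusion on a fixed sphere conserves mass and flattens bumps", {
  st <- make_fixture("bump", N = 48, seed = 1)
  st$fields$E <- st$fields$E * 0.2          # keep Robin clamps shut
  st$fields$w <- st$fields$w * 0.5
  o <- solver_options(t_end = 2, tau = 0.01, reactions = FALSE,
                      regrid_every = 0, snapshots = TRUE)
  tr <- simulate(state = st, options = o)
  nt <- length(tr$times)
  drift <- abs(tr$mass[nt, ] - tr$mass[1, ]) / pmax(tr$mass[1, ], 1e-300)
  expect_lt(max(drift), 1e-3)
  # variance of a diffusing profile decreases monotonically (max principle)
  v0 <- var(tr$snapshots[[1]]$q)
  v1 <- var(tr$snapshots[[nt]]$q)
  expect_lt(v1, v0)
  expect_equal(tr$R[nt], tr$R[1])
})

test_that("implicit-split and explicit agree on a tiny instance", {
  p <- slow_diffusion_params(1e-5)
  oE <- solver_options(scheme = "explicit", tau = 0.005, N = 20,
                       t_end = 1, regrid_every = 0, engine = "R",
                       snapshots = TRUE)
  oI <- solver_options(scheme = "implicit-split", tau = 0.005, N = 20,
                       t_end = 1, regrid_every = 0, engine = "R",
                       snapshots = TRUE)
  tE <- simulate(0.01, p, oE)
  tI <- simulate(0.01, p, oI)
  nt <- length(tE$times)
  for (fn in PAS_FIELDS) {
    a <- tE$snapshots[[nt]][[fn]]; b <- tI$snapshots[[nt]][[fn]]
    scale <- max(abs(a), 1e-300)
    expect_lt(max(abs(a - b)) / scale, 0.01, label = fn)
  }
  expect_lt(abs(tE$R[nt] - tI$R[nt]) / tI$R[nt], 1e-4)
})

test_that("zero-diffusion parameters make the split step a pure reaction step", {
  # with negligible diffusivity the implicit diffusion solve is the
  # identity, so both schemes reduce to the same explicit step
  p <- slow_diffusion_params(1e-30)
  st <- make_fixture("bump", N = 12, seed = 2)
  oE <- solver_options(scheme = "explicit", engine = "R")
  oI <- solver_options(engine = "R")
  a <- step_explicit(st, p, 0.01, oE)$state
  b <- step_implicit_split(st, p, 0.01, oI)$state
  for (fn in PAS_FIELDS)
    expect_equal(a$fields[[fn]], b$fields[[fn]], tolerance = 1e-10,
                 label = fn)
  expect_equal(a$r, b$r)
})

test_that("compiled and R engines produce the same trajectory", {
  oR <- solver_options(t_end = 2, tau = 0.005, N = 24, engine = "R")
  oC <- solver_options(t_end = 2, tau = 0.005, N = 24, engine = "cpp")
  tR <- simulate(0.01, base_params, oR)
  tC <- simulate(0.01, base_params, oC)
  expect_equal(tR$R, tC$R, tolerance = 1e-10)
  expect_equal(tR$mass, tC$mass, tolerance = 1e-9)
  expect_equal(tR$clamped, tC$clamped)
})

test_that("convergence: halving tau and h reduces cross-resolution error", {
  run <- function(tau, N) {
    o <- solver_options(t_end = 5, tau = tau, N = N, snapshots = FALSE)
    simulate(0.01, base_params, o)
  }
  ref <- run(0.0025, 96)
  coarse <- run(0.02, 24)
  fine <- run(0.01, 48)
  nt <- length(ref$times)
  err_c <- abs(coarse$R[nt] - ref$R[nt])
  err_f <- abs(fine$R[nt] - ref$R[nt])
  expect_lt(err_f, err_c)
  # mass observable converges too
  errm_c <- abs(coarse$mass[nt, "C"] - ref$mass[nt, "C"])
  errm_f <- abs(fine$mass[nt, "C"] - ref$mass[nt, "C"])
  expect_lt(errm_f, errm_c)
})

test_that("t_end = 0 returns only the initial condition", {
  tr <- simulate(0.01, base_params, solver_options(t_end = 0))
  expect_equal(tr$times, 0)
  expect_equal(tr$R, 0.01)
  expect_equal(unname(tr$mass[1, "uPR"]), 0)
})

test_that("trajectories are deterministic", {
  o <- solver_options(t_end = 20, snapshots = FALSE)
  t1 <- simulate(0.01, base_params, o)
  t2 <- simulate(0.01, base_params, o)
  expect_identical(t1$mass, t2$mass)
  expect_identical(t1$R, t2$R)
})

test_that("elimination floor freezes a collapsing run instead of NaN", {
  o <- solver_options(t_end = 600, snapshots = FALSE)
  tr <- simulate(0.01, base_params, o)
  expect_false(tr$aborted)
  expect_true(all(is.finite(tr$R)))
  expect_true(tr$eliminated)
  expect_lt(tr$R[length(tr$R)], 2 * o$R_min)
})
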