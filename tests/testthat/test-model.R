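base_params <- baseline_parameter_set()

uniform_state <- function(vals = NULL, N = 12, R = 0.01) {
  st <- initial_state(R, base_params, N)
  if (!is.null(vals))
    for (fn in names(vals)) st$fields[[fn]] <- rep(vals[[fn]], N)
  st
}

test_that("hypoxia factor: continuity, zero and half-threshold", {
  wh <- base_params$w_h
  expect_equal(hypoxia_factor(wh, 0.6, wh), 0.6)
  expect_equal(hypoxia_factor(0, 0.6, wh), 0)
  expect_equal(hypoxia_factor(wh / 2, 0.6, wh), 0.3)
  expect_equal(hypoxia_factor(10 * wh, 0.6, wh), 0.6)   # plateau above
  # nondecreasing in w
  w <- seq(0, 3 * wh, length.out = 50)
  expect_true(all(diff(hypoxia_factor(w, 0.6, wh)) >= 0))
})

test_that("single-node tissue factor rate matches hand arithmetic", {
  st <- uniform_state(list(TF = 3.5e-5, C = 0.5))
  rr <- reaction_rates(st, base_params)
  want <- base_params$A_T + base_params$lambda_TC * 0.5 -
    base_params$d_T * 3.5e-5
  expect_equal(rr$TF, rep(want, 12))
})

test_that("logistic and threshold clamps act as written", {
  st <- uniform_state(list(C = base_params$C0, w = base_params$w_h,
                           f = 0.06))
  rr <- reaction_rates(st, base_params)
  # proliferation term vanishes at carrying capacity: rate is pure death
  expect_equal(rr$C, rep(-base_params$d_C * base_params$C0, 12))
  # V below threshold: endothelial proliferation identically zero
  st2 <- uniform_state(list(V = base_params$V0 / 2, E = 1e-3))
  rr2 <- reaction_rates(st2, base_params)
  expect_equal(rr2$E, rep(-base_params$d_E * 1e-3, 12))
})

test_that("all-zero state leaves only the constant sources", {
  st <- uniform_state()
  for (fn in PAS_FIELDS) st$fields[[fn]] <- rep(0, 12)
  rr <- reaction_rates(st, base_params)
  expect_equal(rr$TF, rep(base_params$A_T, 12))
  expect_equal(rr$f, rep(base_params$A_f, 12))
  expect_equal(rr$P, rep(base_params$lambda_P, 12))
  for (fn in setdiff(PAS_FIELDS, c("TF", "f", "P")))
    expect_equal(rr[[fn]], rep(0, 12), label = fn)
})

test_that("reaction rates are local to each node", {
  st <- make_fixture("bump", N = 16, seed = 5)
  rr1 <- reaction_rates(st, base_params)
  st2 <- st
  for (fn in PAS_FIELDS) st2$fields[[fn]][16] <- st2$fields[[fn]][16] * 2
  rr2 <- reaction_rates(st2, base_params)
  for (fn in PAS_FIELDS)
    expect_identical(rr1[[fn]][1:15], rr2[[fn]][1:15], label = fn)
})

test_that("invalid states are rejected", {
  st <- uniform_state()
  st$fields$C[3] <- -1
  expect_error(reaction_rates(st, base_params), "invalid state")
  st$fields$C[3] <- NaN
  expect_error(reaction_rates(st, base_params), "invalid state")
})

test_that("chemotaxis divergence: closed form, linearity, mesh checks", {
  r <- radial_mesh(20, 1)
  carrier <- rep(1, 20)
  expect_equal(chemotaxis_flux_divergence(carrier, rep(3, 20), 10, r),
               rep(0, 20))
  out <- chemotaxis_flux_divergence(carrier, r^2, 2.5, r)
  expect_equal(out[2:19], rep(-6 * 2.5, 18), tolerance = 1e-10)
  expect_equal(chemotaxis_flux_divergence(carrier, r^2, 5, r),
               2 * chemotaxis_flux_divergence(carrier, r^2, 2.5, r))
  expect_error(chemotaxis_flux_divergence(rep(1, 19), r^2, 1, r),
               "node counts")
})

test_that("velocity from source: closed forms and sign", {
  r <- radial_mesh(40, 0.02)
  expect_equal(velocity_from_source(rep(0, 40), r), rep(0, 40))
  u <- velocity_from_source(rep(1.5, 40), r)
  expect_equal(u, 1.5 * r / 3, tolerance = 1e-3)
  expect_equal(u[1], 0)
  expect_gt(free_boundary_rate(u), 0)
})

test_that("velocity field matches the uniform-state closed form", {
  # spatially uniform state: S is constant, so u = S r / 3 with
  # theta * S = sum of the advected-phase reaction rates
  st <- uniform_state()
  u <- velocity_field(st, base_params)
  rr <- reaction_rates(st, base_params)
  S <- (rr$M[1] + rr$E[1] + rr$f[1] + rr$C[1] + rr$rho[1]) / 0.6
  expect_equal(u, S * st$r / 3, tolerance = 1e-10)
  expect_equal(u[1], 0)
  # the standard initial state has net cell loss, so the boundary retreats
  expect_lt(free_boundary_rate(u), 0)
})

test_that("robin boundary coefficients and clamps", {
  st <- uniform_state(list(E = 0))
  rb <- robin_boundary(st, base_params)
  expect_equal(rb$alpha_w, 0)
  st2 <- uniform_state(list(E = base_params$K_E))
  rb2 <- robin_boundary(st2, base_params)
  expect_equal(rb2$alpha_w, base_params$alpha_w_tilde / 2)
  # w below vascular level: clamp shuts the flux off
  st3 <- uniform_state(list(w = base_params$w0 / 2, E = 0.05))
  rb3 <- robin_boundary(st3, base_params)
  expect_false(rb3$active_w)
  expect_gt(rb3$alpha_w, 0)
  st4 <- uniform_state(list(w = 2 * base_params$w0))
  expect_true(robin_boundary(st4, base_params)$active_w)
})

test_that("free boundary rate under frozen velocity integrates linearly", {
  u_R <- 1e-4
  expect_equal(0.01 + 10 * u_R, 0.011)   # trivially linear motion
  expect_equal(free_boundary_rate(c(0, 2e-5, u_R)), u_R)
})
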