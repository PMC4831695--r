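test_that("average density: uniform, zero and linear closed forms", {
  r <- radial_mesh(200, 1)
  expect_equal(average_density(rep(3, 200), r), 1, tolerance = 1e-4)
  expect_equal(average_density(rep(0, 200), r), 0)
  expect_equal(average_density(r, r), 1 / 4, tolerance = 1e-4)
  expect_equal(average_density(rep(3, 200), r, true_mean = TRUE), 3,
               tolerance = 1e-4)
})

test_that("total mass: sphere volume, linearity, Ave/TM identity", {
  r <- radial_mesh(150, 0.02)
  c0 <- 0.4
  expect_equal(total_mass(rep(c0, 150), r), 4 / 3 * pi * 0.02^3 * c0,
               tolerance = 1e-3)
  set.seed(8)
  X <- runif(150); Y <- runif(150)
  expect_equal(total_mass(2 * X + 3 * Y, r),
               2 * total_mass(X, r) + 3 * total_mass(Y, r))
  # TM = 4*pi*R^3*Ave holds to machine precision for any field
  expect_equal(total_mass(X, r), 4 * pi * 0.02^3 * average_density(X, r))
})

synthetic_map <- function() {
  # monotone analytic surfaces: U grows in R0 and t, R grows in R0 and t
  R0 <- seq(0.01, 0.05, length.out = 9)
  t <- seq(0, 200, length.out = 21)
  U <- outer(R0^3, 1 + t / 50)
  R <- outer(R0, 1 + t / 400)
  structure(list(R0 = R0, t = t, R = R, U = U, partial = FALSE,
                 failed_rows = integer(0),
                 params = baseline_parameter_set()),
            class = "pas_biomarker_map")
}

test_that("inversion is a right-inverse on a synthetic monotone map", {
  map <- synthetic_map()
  for (i in c(1, 4, 9)) for (j in c(2, 11, 21)) {
    res <- invert_biomarker(map$U[i, j], map$t[j], map)
    expect_equal(res$R0_est, map$R0[i], tolerance = 1e-8)
    expect_equal(res$R_now, map$R[i, j], tolerance = 1e-8)
  }
})

test_that("inversion boundary and monotonicity behavior", {
  map <- synthetic_map()
  t <- 100
  Ucol <- vapply(seq_along(map$R0), function(i)
    approx(map$t, map$U[i, ], xout = t)$y, numeric(1))
  res_lo <- invert_biomarker(min(Ucol), t, map)
  expect_equal(res_lo$R0_est, map$R0[1])
  u_seq <- seq(min(Ucol), max(Ucol), length.out = 17)
  est <- vapply(u_seq, function(u) invert_biomarker(u, t, map)$R0_est,
                numeric(1))
  expect_true(all(diff(est) >= 0))
  expect_error(invert_biomarker(max(Ucol) * 1.01, t, map), "attainable")
  expect_error(invert_biomarker(min(Ucol), 1e4, map), "time grid")
})

test_that("radius prediction: consistency, grid nodes, refusal", {
  map <- synthetic_map()
  res <- invert_biomarker(map$U[4, 11], map$t[11], map)
  expect_equal(predict_radius(res$R0_est, map$t[11], map), res$R_now)
  expect_equal(predict_radius(map$R0[6], map$t[3], map), map$R[6, 3],
               tolerance = 1e-12)
  expect_error(predict_radius(map$R0[1], 250, map), "time grid")
  expect_error(predict_radius(0.06, 100, map), "R0 grid")
  # on monotone surfaces later predictions are at least the current radius
  expect_gte(predict_radius(res$R0_est, 150, map), res$R_now)
})

test_that("map build works on the early monotone window of the model", {
  # total uPAR mass rises from zero during roughly the first 1.5 days
  # (before the collapse of its cellular sources); build the forward
  # surfaces on that window and round-trip them
  o <- solver_options(N = 24, tau = 0.01, record_every = 0.25,
                      snapshots = FALSE)
  map <- build_biomarker_map(R0_grid = seq(0.01, 0.03, length.out = 3),
                             t_grid = seq(0, 1, length.out = 5),
                             options = o)
  expect_false(map$partial)
  expect_equal(map$R[, 1], map$R0)
  expect_equal(map$U[, 1], rep(0, 3))   # cytokines start at zero
  expect_true(all(diff(map$U[2, ]) > 0))
  # U increases with R0 at fixed t
  expect_true(all(apply(map$U[, -1], 2, function(u) all(diff(u) > 0))))
  res <- invert_biomarker(map$U[2, 3], map$t[3], map)
  expect_lt(abs(res$R0_est - map$R0[2]), diff(map$R0)[1])
})

test_that("map grid validation", {
  expect_error(build_biomarker_map(R0_grid = c(0.001, 0.01)), "0.005")
  expect_error(build_biomarker_map(t_grid = c(5, 10)), "start at 0")
  expect_error(build_biomarker_map(t_grid = c(0, 2000)), "1000")
})

test_that("PAI-1 to active-uPA ratio is reported per record time", {
  tr <- simulate(0.01, options = solver_options(t_end = 5, N = 24,
                                                snapshots = FALSE))
  ratio <- pai1_to_upa_ratio(tr)
  expect_length(ratio, length(tr$times))
  expect_true(all(is.finite(ratio[-1])))
})
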