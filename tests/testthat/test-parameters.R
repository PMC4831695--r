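test_that("diffusion scaling law reproduces the tabled coefficients", {
  # reference: VEGF, 24 kDa, 8.64e-2 cm^2/day
  cases <- list(list(mw = 92, want = 0.212),   # plasmin(ogen)
                list(mw = 35, want = 0.111),   # tissue factor
                list(mw = 43, want = 0.127),   # PAI-1
                list(mw = 38, want = 0.117))   # uPA
  for (cs in cases)
    expect_equal(diffusion_from_molecular_weight(cs$mw, 24, 8.64e-2),
                 cs$want, tolerance = 0.005)
  expect_identical(diffusion_from_molecular_weight(24, 24, 8.64e-2), 8.64e-2)
  expect_error(diffusion_from_molecular_weight(-1, 24, 1), "positive")
})

test_that("diffusion scaling is homogeneous of degree 2/3 in mw, 1 in ref_D", {
  for (s in c(0.5, 2, 7.3)) {
    expect_equal(diffusion_from_molecular_weight(s * 40, 24, 0.1),
                 s^(2 / 3) * diffusion_from_molecular_weight(40, 24, 0.1))
    expect_equal(diffusion_from_molecular_weight(40, 24, s * 0.1),
                 s * diffusion_from_molecular_weight(40, 24, 0.1))
  }
})

test_that("decay rates from half-lives", {
  expect_equal(decay_rate_from_half_life(9 / 24), 1.85, tolerance = 0.005)
  expect_equal(decay_rate_from_half_life(0.5), 1.39, tolerance = 0.005)
  expect_identical(decay_rate_from_half_life(log(2)), 1)
  for (t in c(0.01, 0.4, 3, 100))
    expect_equal(decay_rate_from_half_life(t) * t, log(2))
  expect_error(decay_rate_from_half_life(0), "positive")
})

test_that("plasmin constants match the printed derivation", {
  pl <- estimate_plasmin_constants()
  expect_equal(signif(pl$P_disease, 2), 4.4e-6)
  expect_equal(pl$lambda_Pu, 10.5, tolerance = 0.01)
  expect_equal(pl$lambda_P, 2.42e-6, tolerance = 0.01)
  expect_equal(pl$K_P, 4.4e-6)
})

test_that("uPAR production rates match and the feasibility edge is caught", {
  up <- estimate_upar_production()
  expect_equal(up$lambda_uPRM, 6.21e-6, tolerance = 1e-6)
  expect_equal(up$lambda_uPRC, 1.242e-6, tolerance = 1e-6)
  # boundary of feasibility: disease uPAR exactly covered by macrophages
  ctx <- estimation_context()
  uPR_edge <- 6.21e-6 * 0.3 / 1.38
  expect_equal(estimate_upar_production(
    estimation_context(uPR_disease = uPR_edge))$lambda_uPRC, 0,
    tolerance = 1e-12)
  expect_error(estimate_upar_production(
    estimation_context(uPR_disease = uPR_edge * 0.9)), "inconsistent")
})

test_that("uPA rates match the printed derivation", {
  ua <- estimate_upa_rates()
  expect_equal(ua$lambda_uf, 2.057e-4, tolerance = 1e-3)
  expect_equal(ua$lambda_u, 1.92)    # 2 * 3.2 * (1.8/6) is exact
})

test_that("PAI-1 derivation matches, with the documented lambda_Pf override", {
  pa <- suppressWarnings(estimate_pai1_rates())
  expect_equal(pa$P_A, 8.39e-6, tolerance = 1e-3)
  expect_equal(signif(8.32 * pa$P_A, 2), 7e-5)
  expect_equal(pa$lambda_PC, 8e-5)
  expect_equal(pa$lambda_PM, 4e-4)
  expect_equal(pa$lambda_Pf, 8.4e-4)
  expect_equal(pa$lambda_Pf_arithmetic, 8.571e-4, tolerance = 1e-4)
  expect_warning(estimate_pai1_rates(), "8.57e-04|8\\.57")
})

test_that("miscellaneous steady-state anchors match", {
  ms <- estimate_misc_steadystates()
  expect_equal(ms$f_healthy, 6.02e-2, tolerance = 1e-3)
  expect_equal(ms$P_nouPA, 1.74e-6, tolerance = 1e-3)
  expect_equal(ms$V_approx, 7e-8)
  expect_equal(ms$K_V, 7e-8)
})

test_that("estimators are pure and order-independent", {
  a <- estimate_upa_rates(); b <- estimate_upa_rates()
  expect_identical(a, b)
  p1 <- baseline_parameter_set(); p2 <- baseline_parameter_set()
  expect_identical(unclass(p1), unclass(p2))
})

test_that("steady-state round trip reproduces the anchor concentrations", {
  p <- baseline_parameter_set()
  ctx <- estimation_context()
  # healthy uPAR: lambda_uPRM * M_h / d_uPR
  expect_equal(p$lambda_uPRM * ctx$M_healthy / p$d_uPR, ctx$uPR_healthy,
               tolerance = 0.02)
  # disease uPAR
  expect_equal((p$lambda_uPRM * ctx$M_disease +
                  p$lambda_uPRC * ctx$C_disease) / p$d_uPR,
               ctx$uPR_disease, tolerance = 0.02)
  # healthy inactive uPA
  expect_equal(p$lambda_uf * ctx$f_lit / p$d_uPi, ctx$uPi_healthy,
               tolerance = 0.02)
  # disease plasmin: lambda_P (1 + 3/2) / d_P
  expect_equal(p$lambda_P * 2.5 / p$d_P,
               (92 / 38) * ctx$uPa_disease, tolerance = 0.02)
  # healthy fibroblasts
  expect_equal(p$A_f / p$d_f, 6.02e-2, tolerance = 0.02)
})

test_that("baseline table entries and validation", {
  p <- baseline_parameter_set()
  expect_equal(p$D_q, 0.013)
  expect_equal(p$d_C, 0.5)
  expect_equal(length(unclass(p)), 85)
  bad <- p; bad$d_C <- -1
  expect_error(validate_parameters(bad), "non-positive")
  bad <- p; bad$C0 <- 1.5
  expect_error(validate_parameters(bad), "C0")
  bad <- unclass(p); bad$D_T <- NULL
  expect_error(validate_parameters(bad), "missing")
  bad <- c(unclass(p), list(lambda_XX = 1))
  expect_error(validate_parameters(bad), "lambda_XX")
})

test_that("derivation table flags only the documented overrides", {
  tab <- derivation_table()
  off <- tab$parameter[!tab$ok]
  expect_setequal(off, c("A_T", "lambda_TC", "lambda_Pf", "d_uPa"))
  expect_true(all(tab$override[!tab$ok]))
})

test_that("parameter sets round-trip through JSON", {
  p <- baseline_parameter_set()
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q), unclass(p))
  expect_error(read_parameters(withr::local_tempfile(fileext = ".json",
    lines = '{"schema": "other/9", "values": {}}')), "schema")
})
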