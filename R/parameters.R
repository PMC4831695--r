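#' @useDynLib tumorPAS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor pt runif setNames var
#' @importFrom utils modifyList write.csv
"_PACKAGE"

PAS_PARAM_SCHEMA <- "tumorPAS-parameters/1"

# ---------------------------------------------------------------------------
# Estimation context: the literature anchor values that the parameter
# derivations hang on.  Kept in one auditable place rather than buried in
# the individual estimators.
# ---------------------------------------------------------------------------

#' Anchor values used to derive the estimated model parameters
#'
#' Collects the molecular weights, steady-state anchor concentrations and
#' half-lives from which every "estimated" entry of the baseline parameter
#' table is re-derived.  Concentrations are in g/ml (treated as identical to
#' g/cm^3 throughout), molecular weights in kDa, half-lives in days.
#'
#' @param ... named overrides of individual anchors (rarely needed; mainly
#'   for exercising the feasibility checks of the estimators).
#' @return An object of class `pas_estimation_context`: a named list of
#'   anchors.
#' @export
estimation_context <- function(...) {
  ctx <- list(
    # molecular weights (kDa); VEGF is the diffusion reference
    M_V = 24, M_P = 92, M_uP = 38, M_T = 35, M_PA = 43,
    D_V_ref = 8.64e-2,            # VEGF diffusion coefficient, cm^2/day
    # steady-state anchors (g/ml)
    uPa_disease  = 1.8e-6,        # active uPA in breast cancer tissue
    uPR_disease  = 1.8e-6,        # uPAR in breast cancer tissue
    uPR_healthy  = 1.8e-7,        # taken 10x smaller than disease
    uPi_healthy  = 6e-6,          # inactive uPA in healthy tissue
    M_healthy    = 0.04,          # macrophage density, healthy
    M_disease    = 0.3,           # macrophage density, disease
    C_disease    = 0.5,           # cancer cell density in tumor bulk
    f_lit        = 0.07,          # fibroblast density (literature, uPA calc)
    f_disease    = 0.14,          # fibroblast density used in PAI-1 calc
    PA_per_mg    = 12e-9,         # PAI-1: 12 ng per mg tissue protein
    mg_protein_ratio = 1.43,      # mg protein per mg tissue
    tissue_density   = 1e-3,      # mg tissue per ml scale factor
    # half-lives (days)
    t_half_T   = 9 / 24,
    t_half_P   = 0.5,
    t_half_uPR = 0.5,
    t_half_uPa = 5 / 24,
    # degradation rates as tabled (the printed, rounded values)
    d_uPR = 1.38, d_uPi = 2.4, d_uPa = 3.2, d_PA = 8.32,
    # misc
    lambda_VM = 2e-6, d_V = 12.6, eps_V = 0.5,
    A_f = 1e-3, d_f = 1.66e-2
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(ctx))
    if (length(bad)) stop("unknown anchor(s): ", paste(bad, collapse = ", "))
    ctx <- modifyList(ctx, over)
  }
  stopifnot(all(vapply(ctx, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(ctx, class = "pas_estimation_context")
}

# ---------------------------------------------------------------------------
# Elementary derivation rules
# ---------------------------------------------------------------------------

#' Diffusion coefficient from molecular weight
#'
#' Protein diffusivity is assumed proportional to molecular surface area,
#' i.e. to the 2/3 power of molecular weight, scaled against a reference
#' protein (VEGF in the baseline table).
#'
#' @param mw molecular weight of the target protein (kDa)
#' @param ref_mw molecular weight of the reference protein (kDa)
#' @param ref_D diffusion coefficient of the reference protein (cm^2/day)
#' @return diffusion coefficient in cm^2/day
#' @export
diffusion_from_molecular_weight <- function(mw, ref_mw, ref_D) {
  if (any(!is.finite(mw)) || any(mw <= 0) || ref_mw <= 0 || ref_D <= 0)
    stop("molecular weights and reference diffusivity must be positive")
  ref_D * (mw / ref_mw)^(2 / 3)
}

#' Decay rate from half-life
#'
#' @param t_half half-life in days
#' @return first-order decay rate, 1/day
#' @export
decay_rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("half-life must be positive")
  log(2) / t_half
}

# ---------------------------------------------------------------------------
# Steady-state estimators, one per derivation paragraph
# ---------------------------------------------------------------------------

#' Plasmin equation constants
#'
#' Derives the disease plasmin level from the uPA level via the molecular
#' weight ratio (assuming equal protein copy numbers), the uPA enhancement
#' factor from the 3/2 disease/healthy plasminogen-binding ratio, and the
#' baseline activation rate from the steady state of the plasmin equation.
#'
#' @param ctx a [estimation_context()]
#' @return list with `P_disease`, `lambda_Pu`, `lambda_P`, `K_P`
#' @export
estimate_plasmin_constants <- function(ctx = estimation_context()) {
  PA   <- ctx$PA_per_mg / ctx$mg_protein_ratio / ctx$tissue_density
  K_PA <- PA / 2
  P_disease <- (ctx$M_P / ctx$M_uP) * ctx$uPa_disease
  lambda_Pu <- 1.5 * (K_PA + PA) / ctx$uPa_disease
  d_P <- decay_rate_from_half_life(ctx$t_half_P)
  lambda_P <- d_P * P_disease / (1 + 1.5)
  list(P_disease = P_disease, lambda_Pu = lambda_Pu,
       lambda_P = lambda_P, K_P = signif(P_disease, 2))
}

#' uPAR production rates
#'
#' Production by macrophages from the healthy steady state, then production
#' by cancer cells from the disease steady state.
#'
#' @param ctx a [estimation_context()]
#' @return list with `lambda_uPRM`, `lambda_uPRC`
#' @export
estimate_upar_production <- function(ctx = estimation_context()) {
  lambda_uPRM <- ctx$d_uPR * ctx$uPR_healthy / ctx$M_healthy
  lambda_uPRC <- (ctx$d_uPR * ctx$uPR_disease - lambda_uPRM * ctx$M_disease) /
    ctx$C_disease
  if (lambda_uPRC < 0)
    stop("inconsistent anchors: disease uPAR below macrophage-only production")
  list(lambda_uPRM = lambda_uPRM, lambda_uPRC = lambda_uPRC)
}

#' uPA production and activation rates
#'
#' Inactive-uPA production by fibroblasts from the healthy steady state;
#' activation rate from the active-uPA steady state with uPAR at its
#' half-saturation level (receptor factor = 1/2).
#'
#' @param ctx a [estimation_context()]
#' @return list with `lambda_uf`, `lambda_u`
#' @export
estimate_upa_rates <- function(ctx = estimation_context()) {
  lambda_uf <- ctx$d_uPi * ctx$uPi_healthy / ctx$f_lit
  # lambda_u * uPi * 1/2 = d_uPa * uPa, with the unrounded uPi/uPa ratio
  lambda_u <- 2 * ctx$d_uPa * ctx$uPa_disease / ctx$uPi_healthy
  list(lambda_uf = lambda_uf, lambda_u = lambda_u)
}

#' PAI-1 level and production rates
#'
#' Converts the tissue PAI-1 content (ng per mg protein) to g/ml, then
#' splits a 4-fold-growth production total 1/7 : 3/7 : 3/7 among cancer
#' cells, fibroblasts and macrophages.  The printed fibroblast rate
#' (8.4e-4/day) is returned as canonical even though the stated arithmetic
#' gives 8.57e-4/day; a warning documents the discrepancy.
#'
#' @param ctx a [estimation_context()]
#' @return list with `P_A`, `lambda_PC`, `lambda_Pf`, `lambda_PM`
#' @export
estimate_pai1_rates <- function(ctx = estimation_context()) {
  P_A <- ctx$PA_per_mg / ctx$mg_protein_ratio / ctx$tissue_density
  turnover <- signif(ctx$d_PA * P_A, 2)       # 7e-5 g/ml/day as printed
  total <- 4 * turnover
  lambda_PC <- (total / 7) / ctx$C_disease
  lambda_PM <- (3 * total / 7) / ctx$M_disease
  lambda_Pf_arith <- (3 * total / 7) / ctx$f_disease
  lambda_Pf <- 8.4e-4
  warning(sprintf(paste0(
    "lambda_Pf: returning the tabled value %.2e/day; the stated arithmetic ",
    "(1.2e-4 g/ml/day over f = %.2f g/ml) gives %.3e/day"),
    lambda_Pf, ctx$f_disease, lambda_Pf_arith), call. = FALSE)
  list(P_A = P_A, lambda_PC = lambda_PC, lambda_Pf = lambda_Pf,
       lambda_PM = lambda_PM, lambda_Pf_arithmetic = lambda_Pf_arith)
}

#' Miscellaneous steady-state levels and half-saturations
#'
#' Healthy fibroblast density, plasmin level without active uPA, the
#' approximate VEGF level (and hence its half-saturation), and the MCP-1
#' half-saturation.
#'
#' @param ctx a [estimation_context()]
#' @return list with `f_healthy`, `P_nouPA`, `V_approx`, `K_V`, `K_p`
#' @export
estimate_misc_steadystates <- function(ctx = estimation_context()) {
  f_healthy <- ctx$A_f / ctx$d_f
  P_nouPA <- 2.42e-6 / 1.39        # tabled lambda_P over tabled d_P
  V_approx <- signif((1 + ctx$eps_V) * ctx$lambda_VM * ctx$M_disease / ctx$d_V, 1)
  list(f_healthy = f_healthy, P_nouPA = P_nouPA,
       V_approx = V_approx, K_V = V_approx, K_p = 2e-7)
}

# ---------------------------------------------------------------------------
# Baseline table
# ---------------------------------------------------------------------------

pas_units <- function() c(
  D_T = "cm2/day", D_V = "cm2/day", D_P = "cm2/day", D_uPR = "cm2/day",
  D_uP = "cm2/day", D_PA = "cm2/day", D_q = "cm2/day", D_p = "cm2/day",
  D_M = "cm2/day", D_E = "cm2/day", D_f = "cm2/day", D_C = "cm2/day",
  D_w = "cm2/day", D_Q = "cm2/day", D_Qr = "cm2/day",
  A_T = "g/ml/day", lambda_TC = "1/day", lambda_VC = "g/ml/day",
  lambda_VT = "1", lambda_VM = "g/ml/day", lambda_P = "g/ml/day",
  lambda_Pu = "1", lambda_uPRM = "1/day", lambda_uPRC = "1/day",
  lambda_uf = "1/day", lambda_u = "1/day", lambda_PC = "1/day",
  lambda_Pf = "1/day", lambda_PM = "1/day", lambda_qC = "1/day",
  lambda_p = "1/day", lambda_E = "1/day", A_f = "g/ml/day",
  lambda_fC = "1/day", beta = "1/day", lambda_Cf = "1/day",
  lambda_CuP = "1/day", lambda_wC = "1/day", lambda_w = "1/day",
  lambda_QM = "1/day", lambda_QP = "1", lambda_QrM = "1/day",
  lambda_rhof = "1/day",
  d_T = "1/day", d_V = "1/day", d_P = "1/day", d_uPR = "1/day",
  d_uPa = "1/day", d_uPi = "1/day", d_PA = "1/day", d_q = "1/day",
  d_p = "1/day", d_M = "1/day", d_E = "1/day", d_f = "1/day", d_C = "1/day",
  d_wM = "ml/g/day", d_wC = "ml/g/day", d_wf = "ml/g/day",
  d_QQr = "cm3/g/day", d_Q = "1/day", d_QrQ = "cm3/g/day", d_Qr = "1/day",
  d_rho = "1/day", d_rhoQ = "cm3/g/day",
  K_T = "g/cm3", K_PA = "g/ml", K_uPR = "g/ml", K_p = "g/ml", K_E = "g/cm3",
  K_C = "g/cm3", K_f = "g/cm3", K_P = "g/ml", K_V = "g/ml",
  M0 = "g/ml", V0 = "g/cm3", C0 = "g/cm3", q0 = "g/cm3", w0 = "g/ml",
  E0 = "g/ml", rho0 = "g/ml", chi_C = "cm2/day per (g/cm3)", w_h = "g/cm3",
  alpha_w_tilde = "1/cm", alpha_E_tilde = "1/cm"
)

#' Baseline model parameter set
#'
#' The full baseline parameter table.  When `validate = TRUE` every entry
#' flagged "estimated" in the table is cross-checked against the
#' corresponding `estimate_*()` derivation; a mismatch above 2% that is not
#' one of the three documented inconsistencies (`A_T`, `lambda_TC`,
#' `lambda_Pf`) is an error.
#'
#' @param validate logical; run the derivation cross-check
#' @return object of class `pas_parameters` (a named list with a `units`
#'   attribute)
#' @export
baseline_parameter_set <- function(validate = TRUE) {
  p <- list(
    # diffusion, cm^2/day
    D_T = 0.111, D_V = 8.64e-2, D_P = 0.212, D_uPR = 8.64e-7, D_uP = 0.117,
    D_PA = 0.127, D_q = 0.013, D_p = 1.29e-2, D_M = 8.64e-7, D_E = 8.64e-7,
    D_f = 8.64e-7, D_C = 8.64e-7, D_w = 4.32e-2, D_Q = 4.32e-2, D_Qr = 4.32e-2,
    # production / activation
    A_T = 3.23e-5, lambda_TC = 5.7e-5, lambda_VC = 2e-8, lambda_VT = 2,
    lambda_VM = 2e-6, lambda_P = 2.42e-6, lambda_Pu = 10.5,
    lambda_uPRM = 6.21e-6, lambda_uPRC = 1.242e-6, lambda_uf = 2.057e-4,
    lambda_u = 1.92, lambda_PC = 8e-5, lambda_Pf = 8.4e-4, lambda_PM = 4e-4,
    lambda_qC = 3e-8, lambda_p = 1.9e-6, lambda_E = 0.7, A_f = 1e-3,
    lambda_fC = 5e-3, beta = 0.3, lambda_Cf = 0.06, lambda_CuP = 0.05,
    lambda_wC = 0.6, lambda_w = 7e-2, lambda_QM = 3e-4, lambda_QP = 2,
    lambda_QrM = 6e-5, lambda_rhof = 3e-3,
    # degradation / consumption
    d_T = 1.85, d_V = 12.6, d_P = 1.39, d_uPR = 1.38, d_uPa = 3.2,
    d_uPi = 2.4, d_PA = 8.32, d_q = 4.8, d_p = 1.73, d_M = 0.015,
    d_E = 0.69, d_f = 1.66e-2, d_C = 0.5, d_wM = 80, d_wC = 40, d_wf = 80,
    d_QQr = 4.98e8, d_Q = 4.32, d_QrQ = 1.04e9, d_Qr = 21.6,
    d_rho = 0.37, d_rhoQ = 2.59e7,
    # saturations / thresholds
    K_T = 1e-4, K_PA = 4.19e-6, K_uPR = 1.8e-6, K_p = 2e-7, K_E = 5e-3,
    K_C = 0.5, K_f = 0.1, K_P = 4.4e-6, K_V = 7e-8, M0 = 5e-5, V0 = 3.65e-10,
    C0 = 0.75, q0 = 1e-9, w0 = 4.65e-4, E0 = 2.5e-3, rho0 = 1e-3,
    chi_C = 10, w_h = 1e-4, alpha_w_tilde = 1, alpha_E_tilde = 1
  )
  params <- structure(p, units = pas_units(), class = "pas_parameters")
  validate_parameters(params)
  if (validate) {
    tab <- derivation_table(params)
    bad <- tab[!tab$ok & !tab$override, , drop = FALSE]
    if (nrow(bad))
      stop("derivation cross-check failed for: ",
           paste(bad$parameter, collapse = ", "))
  }
  params
}

#' Validate a parameter set
#'
#' Checks completeness against the baseline key set, strict positivity of
#' all rates/diffusivities/saturations (`V0` is a threshold and may be any
#' nonnegative value), and the carrying-capacity constraints.
#'
#' @param params a `pas_parameters` object or named list
#' @return the validated `pas_parameters`, invisibly
#' @export
validate_parameters <- function(params) {
  keys <- names(pas_units())
  missing <- setdiff(keys, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), keys)
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  vals <- unlist(params[keys])
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  nonneg_ok <- "V0"  # threshold, zero allowed
  strict <- setdiff(keys, nonneg_ok)
  if (any(vals[strict] <= 0))
    stop("non-positive parameter(s): ",
         paste(strict[vals[strict] <= 0], collapse = ", "))
  if (vals["V0"] < 0) stop("V0 must be nonnegative")
  if (!(vals["C0"] > 0 && vals["C0"] <= 1)) stop("require 0 < C0 <= 1")
  if (vals["K_E"] <= 0) stop("require K_E > 0")
  invisible(structure(as.list(params[keys]), units = pas_units(),
                      class = "pas_parameters"))
}

#' Derivation cross-check table
#'
#' One row per derivable parameter: the tabled (printed) value, the value
#' recomputed from the anchor chain, their relative difference, whether they
#' agree within `tol`, and whether the entry carries a documented override
#' (printed value canonical despite a larger discrepancy).
#'
#' @param params parameter set to check (default baseline, unvalidated to
#'   avoid recursion)
#' @param ctx estimation context
#' @param tol relative tolerance for agreement (default 2%)
#' @return data.frame with columns parameter, tabled, derived, rel_diff,
#'   ok, override, note
#' @export
derivation_table <- function(params = baseline_parameter_set(validate = FALSE),
                             ctx = estimation_context(), tol = 0.02) {
  pl <- suppressWarnings(estimate_plasmin_constants(ctx))
  up <- estimate_upar_production(ctx)
  ua <- estimate_upa_rates(ctx)
  pa <- suppressWarnings(estimate_pai1_rates(ctx))
  ms <- estimate_misc_steadystates(ctx)
  dmw <- function(mw) diffusion_from_molecular_weight(mw, ctx$M_V, ctx$D_V_ref)
  rows <- list(
    list("D_T",  dmw(ctx$M_T),  FALSE, "MW 2/3 scaling vs VEGF"),
    list("D_P",  dmw(ctx$M_P),  FALSE, "MW 2/3 scaling vs VEGF"),
    list("D_uP", dmw(ctx$M_uP), FALSE, "MW 2/3 scaling vs VEGF"),
    list("D_PA", dmw(ctx$M_PA), FALSE, "MW 2/3 scaling vs VEGF"),
    list("d_T",  decay_rate_from_half_life(ctx$t_half_T), FALSE, "9 h half-life"),
    list("d_P",  decay_rate_from_half_life(ctx$t_half_P), FALSE, "0.5 day half-life"),
    list("d_uPR", decay_rate_from_half_life(ctx$t_half_uPR), FALSE,
         "12 h half-life (printed 1.38, exact 1.386)"),
    list("d_uPa", decay_rate_from_half_life(ctx$t_half_uPa), TRUE,
         "printed 3.2 kept; 5 h half-life gives 3.33"),
    list("lambda_P",  pl$lambda_P,  FALSE, "plasmin steady state"),
    list("lambda_Pu", pl$lambda_Pu, FALSE, "3/2 binding enhancement"),
    list("K_P",  pl$K_P,  FALSE, "rounded disease plasmin level"),
    list("K_PA", signif(pa$P_A / 2, 3), FALSE, "half the disease PAI-1 level"),
    list("lambda_uPRM", up$lambda_uPRM, FALSE, "healthy uPAR steady state"),
    list("lambda_uPRC", up$lambda_uPRC, FALSE, "disease uPAR steady state"),
    list("lambda_uf", ua$lambda_uf, FALSE, "healthy inactive-uPA steady state"),
    list("lambda_u",  ua$lambda_u,  FALSE, "active-uPA steady state, uPR = K_uPR"),
    list("lambda_PC", pa$lambda_PC, FALSE, "1/7 of 4x PAI-1 turnover"),
    list("lambda_PM", pa$lambda_PM, FALSE, "3/7 of 4x PAI-1 turnover"),
    list("lambda_Pf", pa$lambda_Pf_arithmetic, TRUE,
         "printed 8.4e-4 kept; arithmetic gives 8.57e-4"),
    list("K_V", ms$K_V, FALSE, "approximate VEGF level"),
    list("K_p", ms$K_p, FALSE, "approximate MCP-1 steady state"),
    list("A_T", 3.7e-4, TRUE,
         "printed 3.23e-5 follows from d_T*3.5e-5/2, not from d_T*2e-4"),
    list("lambda_TC", (1.85 * 3.5e-5 - unlist(params["A_T"])) / 0.5, TRUE,
         "printed 5.7e-5; stated relation gives ~6.5e-5")
  )
  tab <- data.frame(
    parameter = vapply(rows, function(r) r[[1]], character(1)),
    tabled    = vapply(rows, function(r) unlist(params[r[[1]]]), numeric(1)),
    derived   = vapply(rows, function(r) r[[2]], numeric(1)),
    override  = vapply(rows, function(r) r[[3]], logical(1)),
    note      = vapply(rows, function(r) r[[4]], character(1)),
    stringsAsFactors = FALSE
  )
  tab$rel_diff <- abs(tab$derived - tab$tabled) / abs(tab$tabled)
  tab$ok <- tab$rel_diff <= tol
  tab[, c("parameter", "tabled", "derived", "rel_diff", "ok", "override", "note")]
}

#' @export
print.pas_parameters <- function(x, ...) {
  cat("<pas_parameters> ", length(x), " entries\n", sep = "")
  u <- attr(x, "units")
  df <- data.frame(value = unlist(x), unit = u[names(x)])
  print(df, ...)
  invisible(x)
}

#' Write a parameter set to a JSON file
#'
#' @param params a `pas_parameters` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  obj <- list(schema = PAS_PARAM_SCHEMA,
              values = params[names(pas_units())],
              units = as.list(pas_units()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from a JSON file
#'
#' @param path file written by [write_parameters()]
#' @return a validated `pas_parameters` object
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != PAS_PARAM_SCHEMA)
    stop("unrecognized parameter schema: ", obj$schema)
  validate_parameters(as.list(obj$values))
}
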