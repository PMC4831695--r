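# Latin hypercube sampling over the production parameters and partial rank
# correlation of the day-600 tumor radius.

#' Production parameters of the model
#'
#' The production/activation-rate parameters entering the 17 field
#' equations; the default sampling set for the sensitivity analysis.
#' @export
PAS_PRODUCTION_PARAMS <- c(
  "A_T", "lambda_TC", "lambda_VC", "lambda_VT", "lambda_VM", "lambda_P",
  "lambda_Pu", "lambda_uPRM", "lambda_uPRC", "lambda_uf", "lambda_u",
  "lambda_PC", "lambda_Pf", "lambda_PM", "lambda_qC", "lambda_p",
  "lambda_E", "A_f", "lambda_fC", "beta", "lambda_Cf", "lambda_CuP",
  "lambda_wC", "lambda_w", "lambda_QM", "lambda_QP", "lambda_QrM",
  "lambda_rhof")

#' Sensitivity design
#'
#' @param names parameters to sample
#' @param n number of samples
#' @param seed RNG seed
#' @param range_frac half-width of the uniform sampling range as a
#'   fraction of the baseline value (default 50%)
#' @param readout_day day at which the tumor radius is read out
#' @param params baseline parameter set supplying the range centers
#' @return list of class `pas_sensitivity_design` with `names`, `lower`,
#'   `upper`, `n`, `seed`, `readout_day`
#' @export
sensitivity_design <- function(names = PAS_PRODUCTION_PARAMS, n = 1000,
                               seed = 1, range_frac = 0.5,
                               readout_day = 600,
                               params = baseline_parameter_set()) {
  stopifnot(all(names %in% names(pas_units())), n >= 2 + length(names),
            range_frac > 0, range_frac < 1)
  base <- unlist(params[names])
  structure(list(names = names, lower = base * (1 - range_frac),
                 upper = base * (1 + range_frac), n = as.integer(n),
                 seed = as.integer(seed),
                 readout_day = readout_day),
            class = "pas_sensitivity_design")
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Latin hypercube sample
#'
#' For each parameter the range is split into `n` equal-probability bins,
#' one uniform draw is placed in each bin, and the bins are permuted
#' independently per parameter.  Deterministic given the design seed.
#'
#' @param design a [sensitivity_design()]
#' @return `n` x `k` matrix with parameter names as column names
#' @export
latin_hypercube <- function(design) {
  k <- length(design$names); n <- design$n
  with_local_seed(design$seed, {
    m <- vapply(seq_len(k), function(j) {
      strata <- (sample(n) - 1 + runif(n)) / n
      design$lower[j] + strata * (design$upper[j] - design$lower[j])
    }, numeric(n))
  })
  colnames(m) <- design$names
  m
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms all columns and the readout; for each parameter the
#' residuals of its ranks regressed on all other parameters' ranks are
#' correlated with the analogous readout residuals.  p-values come from
#' the t statistic `prcc * sqrt((n-2-k)/(1-prcc^2))` with `n-2-k` degrees
#' of freedom.
#'
#' @param samples `n` x `k` sample matrix
#' @param readout length-`n` model readout
#' @return object of class `pas_sensitivity_result`: list with a `table`
#'   data.frame (parameter, prcc, p, rank), `samples`, `readout`
#' @export
prcc <- function(samples, readout) {
  n <- nrow(samples); k <- ncol(samples)
  if (length(readout) != n) stop("readout length must match sample rows")
  if (n <= k + 2) stop("need n > k + 2 samples")
  rx <- apply(samples, 2, rank, ties.method = "average")
  ry <- rank(readout, ties.method = "average")
  out <- numeric(k); dropped <- logical(k)
  for (j in seq_len(k)) {
    Z <- cbind(1, rx[, -j, drop = FALSE])
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      warning("rank-deficient regressors when partialling out for ",
              colnames(samples)[j], "; parameter excluded", call. = FALSE)
      dropped[j] <- TRUE
      out[j] <- NA_real_
      next
    }
    res_x <- qr.resid(qrz, rx[, j])
    res_y <- qr.resid(qrz, ry)
    out[j] <- suppressWarnings(cor(res_x, res_y))
  }
  df <- n - 2 - k
  tstat <- out * sqrt(df / pmax(1 - out^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df)
  tab <- data.frame(parameter = colnames(samples), prcc = out, p = pval,
                    excluded = dropped, stringsAsFactors = FALSE)
  tab$rank <- rank(-abs(tab$prcc), na.last = "keep")
  structure(list(table = tab, samples = samples, readout = readout,
                 n = n, k = k),
            class = "pas_sensitivity_result")
}

#' Run the model-based sensitivity analysis
#'
#' Simulates the model once per Latin hypercube sample at reduced
#' fidelity, reads the tumor radius at the design's readout day, and
#' computes PRCCs.  Failed simulations are dropped (with a count); more
#' than 10% failures marks the result unreliable.
#'
#' @param params baseline parameter set
#' @param design a [sensitivity_design()]
#' @param solver_opts reduced-fidelity [solver_options()]
#' @param R0 initial radius for every run (cm)
#' @return a `pas_sensitivity_result` with extra elements `failed`,
#'   `unreliable`, `design`
#' @export
run_sensitivity <- function(params = baseline_parameter_set(),
                            design = sensitivity_design(params = params),
                            solver_opts = solver_options(
                              N = 32, tau = 0.02, record_every = 50,
                              snapshots = FALSE),
                            R0 = 0.01) {
  solver_opts$t_end <- design$readout_day
  samples <- latin_hypercube(design)
  n <- nrow(samples)
  readout <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pi_ <- params
    pi_[colnames(samples)] <- samples[i, ]
    traj <- tryCatch(
      withCallingHandlers(simulate(R0, pi_, solver_opts),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(traj) && !traj$aborted &&
        abs(max(traj$times) - design$readout_day) < solver_opts$tau)
      readout[i] <- traj$R[length(traj$R)]
  }
  ok <- !is.na(readout)
  nfail <- sum(!ok)
  res <- prcc(samples[ok, , drop = FALSE], readout[ok])
  res$failed <- nfail
  res$unreliable <- nfail > 0.1 * n
  res$design <- design
  if (res$unreliable)
    warning(sprintf("%d of %d runs failed; result marked unreliable",
                    nfail, n), call. = FALSE)
  res
}

#' @export
print.pas_sensitivity_result <- function(x, ...) {
  cat("<pas_sensitivity_result> n = ", x$n, ", k = ", x$k, "\n", sep = "")
  tab <- x$table[order(-abs(x$table$prcc)), ]
  print(tab, row.names = FALSE, ...)
  invisible(x)
}
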