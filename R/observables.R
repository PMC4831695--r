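# Summary observables and the uPAR <-> radius biomarker surfaces.

#' Average density observable
#'
#' The literal average observable `(1/R^3) * int_0^R X r^2 dr` (trapezoid
#' on the nodes).  Note that for a uniform field this equals X/3; set
#' `true_mean = TRUE` to multiply by 3 and obtain the volume mean proper.
#'
#' @param field per-node values
#' @param r mesh
#' @param true_mean multiply by 3 (volume mean)
#' @return scalar, g/cm^3
#' @export
average_density <- function(field, r, true_mean = FALSE) {
  a <- radial_integral(field, r) / r[length(r)]^3
  if (true_mean) 3 * a else a
}

#' Total mass observable
#'
#' `4 * pi * int_0^R X r^2 dr` (trapezoid on the nodes).
#'
#' @param field per-node values
#' @param r mesh
#' @return scalar, g
#' @export
total_mass <- function(field, r) 4 * pi * radial_integral(field, r)

#' PAI-1 to active-uPA average ratio over a trajectory
#'
#' Soft diagnostic: the ratio of the PAI-1 average concentration to the
#' active-uPA average concentration, per record time (high-risk recurrence
#' cohorts show roughly a 5:1 tissue proportion).
#'
#' @param traj a `pas_trajectory`
#' @return numeric vector (one ratio per record time; NaN where uPa = 0)
#' @export
pai1_to_upa_ratio <- function(traj) {
  traj$ave[, "PA"] / traj$ave[, "uPa"]
}

#' Build the forward biomarker surfaces R(R0, t) and totaluPAR(R0, t)
#'
#' Runs one simulation per initial radius and tabulates the tumor radius
#' and the total uPAR mass on a common time grid.  On the baseline
#' parameter set the total uPAR mass is expected to increase strictly with
#' time along every row; with `check = TRUE` a violation aborts the build.
#'
#' @param R0_grid initial radii (cm), within [0.005, 0.05]
#' @param t_grid output times (days), within [0, 1000], starting at 0
#' @param params parameter set
#' @param options [solver_options()]; `t_end` is overridden by
#'   `max(t_grid)`
#' @param check enforce the monotonicity invariant at build time
#' @return object of class `pas_biomarker_map`: list with `R0`, `t`,
#'   matrices `R` and `U` (rows = R0), `partial`, `failed_rows`
#' @export
build_biomarker_map <- function(R0_grid = seq(0.01, 0.05, length.out = 17),
                                t_grid = seq(0, 1000, length.out = 101),
                                params = baseline_parameter_set(),
                                options = solver_options(snapshots = FALSE),
                                check = TRUE) {
  if (any(R0_grid < 0.005 - 1e-12) || any(R0_grid > 0.05 + 1e-12))
    stop("R0_grid outside [0.005, 0.05] cm")
  if (any(diff(R0_grid) <= 0) || any(diff(t_grid) <= 0) || t_grid[1] != 0)
    stop("grids must be strictly increasing and t_grid must start at 0")
  if (max(t_grid) > 1000) stop("t_grid outside [0, 1000] days")
  options$t_end <- max(t_grid)
  options$snapshots <- TRUE     # need uPR profiles at record times
  options$record_every <- min(min(diff(t_grid)), options$record_every)
  nR <- length(R0_grid); nt <- length(t_grid)
  Rmat <- matrix(NA_real_, nR, nt)
  Umat <- matrix(NA_real_, nR, nt)
  failed <- integer(0)
  for (i in seq_len(nR)) {
    traj <- tryCatch(
      withCallingHandlers(
        simulate(R0_grid[i], params, options),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(traj) || traj$aborted ||
        max(traj$times) < max(t_grid) - 1e-9) {
      failed <- c(failed, i)
      next
    }
    U_rec <- vapply(seq_along(traj$times), function(k)
      total_mass(traj$snapshots[[k]]$uPR, traj$mesh[[k]]), numeric(1))
    Rmat[i, ] <- approx(traj$times, traj$R, xout = t_grid)$y
    Umat[i, ] <- approx(traj$times, U_rec, xout = t_grid)$y
    Rmat[i, 1] <- R0_grid[i]
  }
  if (check && length(failed) == 0) {
    nonmono <- which(apply(Umat, 1, function(u) any(diff(u) <= 0)))
    if (length(nonmono))
      stop("biomarker map build failed: total uPAR mass not strictly ",
           "increasing in t for R0 = ",
           paste(signif(R0_grid[nonmono], 3), collapse = ", "))
  }
  structure(list(R0 = R0_grid, t = t_grid, R = Rmat, U = Umat,
                 partial = length(failed) > 0, failed_rows = failed,
                 params = params),
            class = "pas_biomarker_map")
}

# Interpolate one row of a map surface at time t.
map_row_at <- function(map, surface, i, t) {
  approx(map$t, map[[surface]][i, ], xout = t)$y
}

#' Invert the biomarker map: total uPAR at time t -> initial radius and
#' current radius
#'
#' Solves `U(R0, t) = u_measured` for `R0` by bracketing along the
#' interpolated column (the column is monotone increasing in `R0` on the
#' baseline map), then reads the radius surface at the estimate.
#'
#' @param u_measured total uPAR mass (g)
#' @param t measurement time (days), within the map's time grid
#' @param map a [build_biomarker_map()] result
#' @return list with `R0_est` (cm) and `R_now` (cm)
#' @export
invert_biomarker <- function(u_measured, t, map) {
  if (t < min(map$t) || t > max(map$t)) stop("t outside the map's time grid")
  Ucol <- vapply(seq_along(map$R0), function(i) map_row_at(map, "U", i, t),
                 numeric(1))
  if (any(is.na(Ucol))) stop("map is partial at t = ", t)
  lo <- min(Ucol); hi <- max(Ucol)
  if (u_measured < lo || u_measured > hi)
    stop(sprintf(
      "uPAR mass %.4g g outside the attainable interval [%.4g, %.4g] g at day %g",
      u_measured, lo, hi, t))
  # monotone bracketing along R0
  idx <- which((Ucol[-length(Ucol)] - u_measured) *
                 (Ucol[-1] - u_measured) <= 0)[1]
  if (Ucol[idx + 1] == Ucol[idx]) {
    R0_est <- map$R0[idx]
  } else {
    frac <- (u_measured - Ucol[idx]) / (Ucol[idx + 1] - Ucol[idx])
    R0_est <- map$R0[idx] + frac * (map$R0[idx + 1] - map$R0[idx])
  }
  list(R0_est = R0_est, R_now = predict_radius(R0_est, t, map))
}

#' Predict the tumor radius from an estimated initial radius
#'
#' Bilinear interpolation of the `R(R0, t)` surface; extrapolation beyond
#' either grid is refused.
#'
#' @param R0_est initial radius estimate (cm), within the map's R0 grid
#' @param t1 prediction time (days), within the map's time grid
#' @param map a [build_biomarker_map()] result
#' @return radius in cm
#' @export
predict_radius <- function(R0_est, t1, map) {
  if (t1 < min(map$t) || t1 > max(map$t)) stop("t1 outside the map's time grid")
  if (R0_est < min(map$R0) || R0_est > max(map$R0))
    stop("R0_est outside the map's R0 grid")
  i <- findInterval(R0_est, map$R0, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(map$R0) - 1)
  R_lo <- map_row_at(map, "R", i, t1)
  R_hi <- map_row_at(map, "R", i + 1, t1)
  frac <- (R0_est - map$R0[i]) / (map$R0[i + 1] - map$R0[i])
  (1 - frac) * R_lo + frac * R_hi
}

#' @export
print.pas_biomarker_map <- function(x, ...) {
  cat("<pas_biomarker_map> ", length(x$R0), " R0 x ", length(x$t),
      " t; R0 in [", min(x$R0), ", ", max(x$R0), "] cm, t in [",
      min(x$t), ", ", max(x$t), "] days",
      if (x$partial) "  [PARTIAL]", "\n", sep = "")
  invisible(x)
}
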