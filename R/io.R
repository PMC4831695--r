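# Configuration, serialization and test-fixture generation.

PAS_CONFIG_SCHEMA <- "tumorPAS-config/1"

default_config <- function() {
  list(schema = PAS_CONFIG_SCHEMA,
       seed = 1L,
       params = list(),           # overrides of baseline entries
       solver = list(),           # overrides of solver_options() args
       observables = list(true_mean = FALSE),
       outdir = ".")
}

#' Load a run configuration
#'
#' JSON config with defaults filled in.  Unknown keys, at the top level or
#' inside `params`/`solver`/`observables`, are rejected by name.  An empty
#' file yields the defaults.
#'
#' @param path JSON file
#' @return validated config list of class `pas_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- if (!nzchar(trimws(txt))) list()
         else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(obj)
}

#' @rdname load_config
#' @param config a config list (possibly partial)
#' @export
validate_config <- function(config) {
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(def, config)
  if (!identical(cfg$schema, PAS_CONFIG_SCHEMA))
    stop("unsupported config schema: ", cfg$schema)
  badp <- setdiff(names(cfg$params), names(pas_units()))
  if (length(badp))
    stop("unknown parameter override key(s): ", paste(badp, collapse = ", "))
  bads <- setdiff(names(cfg$solver),
                  setdiff(names(formals(solver_options)), ""))
  if (length(bads))
    stop("unknown solver option key(s): ", paste(bads, collapse = ", "))
  bado <- setdiff(names(cfg$observables), "true_mean")
  if (length(bado))
    stop("unknown observable option key(s): ", paste(bado, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pas_config")
}

#' Save a run configuration
#'
#' @param config a `pas_config`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  cfg <- validate_config(unclass(config))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Resolve a config into parameters and solver options
#'
#' @param config a `pas_config`
#' @return list with `params` and `options`
#' @export
resolve_config <- function(config) {
  cfg <- validate_config(unclass(config))
  params <- baseline_parameter_set()
  params[names(cfg$params)] <- cfg$params
  params <- validate_parameters(params)
  options <- do.call(solver_options, cfg$solver)
  list(params = params, options = options)
}

# 32-bit FNV-1a over a text rendering; stable across platforms, good
# enough for manifest provenance (not cryptographic).  Arithmetic is done
# in split 16-bit halves: R has no unsigned 32-bit integers and doubles
# lose bits above 2^53.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(format(x, digits = 17),
                                      collapse = ",")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * prime) %% 65536 * 65536 + lo * prime) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Hash of a parameter set (for run manifests)
#'
#' @param params a `pas_parameters`
#' @return 8-hex-digit string
#' @export
params_hash <- function(params) fnv1a_hash(unlist(params[names(pas_units())]))

#' Write a run manifest
#'
#' @param path output JSON path
#' @param config the `pas_config` used
#' @param params the resolved parameter set
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(path, config, params) {
  obj <- list(schema = "tumorPAS-manifest/1",
              package_version = as.character(utils::packageVersion("tumorPAS")),
              params_hash = params_hash(params),
              config = unclass(validate_config(unclass(config))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Synthetic state fixtures for solver tests
#'
#' `"standard-initial"` reproduces the standard initial condition exactly
#' (rho = 0.02, w = w_h, M = 0.07, E = 0.05, f = 0.06, C = 0.4, cytokines
#' zero).  `"uniform"` draws one positive constant per field;
#' `"bump"` adds a smooth Gaussian bump to each field.  Deterministic
#' given `seed`.
#'
#' @param kind one of `"uniform"`, `"bump"`, `"standard-initial"`
#' @param N mesh nodes
#' @param seed RNG seed for the synthetic kinds
#' @param R0 outer radius (cm)
#' @param params parameter set (for `w_h`)
#' @return a [pas_state()]
#' @export
make_fixture <- function(kind = c("uniform", "bump", "standard-initial"),
                         N = 24, seed = 1, R0 = 0.01,
                         params = baseline_parameter_set()) {
  kind <- match.arg(kind)
  if (kind == "standard-initial") return(initial_state(R0, params, N))
  r <- radial_mesh(N, R0)
  scales <- c(TF = 3e-5, V = 5e-8, P = 2e-6, uPR = 1e-6, uPi = 5e-6,
              uPa = 1e-6, PA = 8e-6, q = 1e-9, p = 2e-7, M = 0.05,
              E = 5e-3, f = 0.06, C = 0.4, w = 1e-4, Q = 1e-8, Qr = 1e-9,
              rho = 0.02)
  fields <- with_local_seed(seed, {
    lapply(scales, function(sc) {
      base <- sc * runif(1, 0.5, 1.5)
      if (kind == "uniform") rep(base, N)
      else {
        ctr <- runif(1, 0.2, 0.8) * R0
        wid <- runif(1, 0.15, 0.35) * R0
        base * (1 + 0.5 * exp(-((r - ctr) / wid)^2))
      }
    })
  })
  pas_state(fields, r)
}

#' Write a trajectory to CSV files
#'
#' `<prefix>_summary.csv` holds one row per record time (time, R, per-field
#' total masses and averages); `<prefix>_fields.csv` (if snapshots were
#' kept) one row per (time, node) with all field values.
#'
#' @param traj a `pas_trajectory`
#' @param prefix output path prefix
#' @return character vector of files written, invisibly
#' @export
write_trajectory_csv <- function(traj, prefix) {
  summary_df <- data.frame(time = traj$times, R = traj$R)
  for (fn in PAS_FIELDS) {
    summary_df[[paste0("mass_", fn)]] <- traj$mass[, fn]
    summary_df[[paste0("ave_", fn)]] <- traj$ave[, fn]
  }
  f1 <- paste0(prefix, "_summary.csv")
  write.csv(summary_df, f1, row.names = FALSE)
  files <- f1
  if (!is.null(traj$snapshots)) {
    rows <- lapply(seq_along(traj$times), function(k) {
      df <- data.frame(time = traj$times[k], r = traj$mesh[[k]])
      for (fn in PAS_FIELDS) df[[fn]] <- traj$snapshots[[k]][[fn]]
      df
    })
    f2 <- paste0(prefix, "_fields.csv")
    write.csv(do.call(rbind, rows), f2, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}

#' Export a biomarker map as CSV matrices plus a JSON sidecar
#'
#' @param map a `pas_biomarker_map`
#' @param prefix output path prefix
#' @return files written, invisibly
#' @export
write_biomarker_map <- function(map, prefix) {
  dimn <- list(R0 = as.character(map$R0), t = as.character(map$t))
  Rm <- map$R; dimnames(Rm) <- dimn
  Um <- map$U; dimnames(Um) <- dimn
  fR <- paste0(prefix, "_radius.csv")
  fU <- paste0(prefix, "_upar.csv")
  fM <- paste0(prefix, "_meta.json")
  write.csv(Rm, fR)
  write.csv(Um, fU)
  jsonlite::write_json(
    list(schema = "tumorPAS-map/1", params_hash = params_hash(map$params),
         R0 = map$R0, t = map$t, partial = map$partial,
         failed_rows = map$failed_rows),
    fM, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fR, fU, fM))
}
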