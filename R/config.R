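.config_env_keys <- c("fe_diss", "o2_ext", "light", "i_max", "i_const",
                      "photoperiod")
.config_scenario_keys <- c("name", "mode", "fe_diss", "o2_ext", "light",
                           "i_max", "i_const", "photoperiod", "dt")

config_env_from_list <- function(x, where = "environment") {
  unknown <- setdiff(names(x), .config_env_keys)
  if (length(unknown)) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$fe_diss)) {
    stop("configuration error: required field 'fe_diss' missing in ",
         where, call. = FALSE)
  }
  tricho_env(Fe_diss = x$fe_diss,
             O2_ext = x$o2_ext %||% 0.213,
             light = x$light %||% "sine",
             I_max = x$i_max %||% 140,
             I_const = x$i_const %||% 90,
             photoperiod = x$photoperiod %||% 12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model configuration
#'
#' Reads a YAML configuration with sections `schema_version`, `params`
#' (registry overrides, with geometry under `params$geometry`),
#' `calibrated` (optional explicit rate vector), `environment` (baseline
#' forcing) and `scenarios` (a list; each entry needs at least `name`,
#' `mode` and `fe_diss`). Unknown keys anywhere are rejected; every
#' registry constant not named in the file keeps its documented default,
#' and the filled defaults are reported via `message()` when `verbose`.
#'
#' @param path YAML file path.
#' @param verbose report defaulted values.
#' @return A list of class `tricho_config`: `params` ([tricho_params()]),
#'   `env` ([tricho_env()]), `scenarios` (list), `schema_version`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  top_keys <- c("schema_version", "params", "calibrated", "environment",
                "scenarios")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sv <- raw$schema_version %||% 1L
  if (!identical(as.integer(sv), 1L)) {
    stop("unsupported schema_version: ", sv, call. = FALSE)
  }
  p_over <- raw$params %||% list()
  geom_over <- p_over$geometry %||% list()
  p_over$geometry <- NULL
  geom_keys <- c("R", "L", "Lg", "Lb", "V")
  unknown <- setdiff(names(geom_over), geom_keys)
  if (length(unknown)) {
    stop("unknown geometry key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  geometry <- do.call(tricho_geometry, geom_over)
  calibrated <- if (!is.null(raw$calibrated)) {
    validate_calibrated(unlist(raw$calibrated))
  } else NULL
  params <- do.call(tricho_params,
                    c(p_over, list(geometry = geometry,
                                   calibrated = calibrated)))
  if (verbose) {
    defaulted <- setdiff(names(.tricho_defaults()), names(p_over))
    message("config: ", length(defaulted),
            " registry constants filled from documented defaults",
            if (length(geom_over) == 0) "; geometry uses uncalibrated defaults" else "")
  }
  env <- config_env_from_list(raw$environment %||%
                                list(fe_diss = 40))
  scenarios <- lapply(seq_along(raw$scenarios %||% list()), function(i) {
    sc <- raw$scenarios[[i]]
    unknown <- setdiff(names(sc), .config_scenario_keys)
    if (length(unknown)) {
      stop("scenario ", i, ": unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (req in c("name", "mode", "fe_diss")) {
      if (is.null(sc[[req]])) {
        stop("configuration error: scenario ", i,
             " is missing required field '", req, "'", call. = FALSE)
      }
    }
    if (!sc$mode %in% c("dynamic", "fixed")) {
      stop("scenario ", i, ": mode must be 'dynamic' or 'fixed'",
           call. = FALSE)
    }
    sc
  })
  structure(list(schema_version = 1L, params = params, env = env,
                 scenarios = scenarios),
            class = "tricho_config")
}

#' Save a model configuration
#'
#' Serializes a `tricho_config` back to YAML such that
#' `load_config(save_config(cfg, path))` reproduces it field-for-field.
#'
#' @param config a `tricho_config` from [load_config()] (or assembled with
#'   the same structure).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "tricho_config"))
  p <- config$params
  scalars <- p[names(.tricho_defaults())]
  g <- p$geometry
  out <- list(
    schema_version = config$schema_version,
    params = c(scalars,
               list(geometry = list(R = g$R, L = g$L, Lg = g$Lg,
                                    Lb = g$Lb, V = g$V))),
    environment = list(fe_diss = config$env$Fe_diss,
                       o2_ext = config$env$O2_ext,
                       light = config$env$light,
                       i_max = config$env$I_max,
                       i_const = config$env$I_const,
                       photoperiod = config$env$photoperiod),
    scenarios = config$scenarios)
  if (!is.null(p$calibrated)) out$calibrated <- as.list(p$calibrated)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
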