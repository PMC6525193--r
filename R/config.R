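# Structured-text (YAML) run configuration shared by all modules, with an
# explicit versioned schema, plus tidy-CSV writers and a run manifest.

config_schema <- function() {
  list(
    schema_version = 1,
    seed = 1,
    units = "mM",
    network = list(
      scenario = "A",
      fe = as.list(default_fe())
    ),
    kinetics = stats::setNames(
      lapply(default_kinetics(), function(p) {
        p <- unclass(p)
        p$I <- if (is.finite(p$I)) p$I else "none"
        p
      }),
      names(default_fe())),
    batch = list(
      nitrate_mg_l = c(0, 200, 500, 700, 1000),
      sulfate_mg_l = 1000,
      lactate_mg_l = 2500,
      ammonium_mM = 5,
      t_end_h = 12,
      n_times = 13,
      frozen_biomass = TRUE,
      sse_species = c("sulfate", "sulfide", "nitrate", "nitrite")
    ),
    fitting = list(
      pop_size = 60,
      generations = 200,
      elite_frac = 0.1,
      early_stop_tol = 1e-8,
      early_stop_gens = 20,
      max_total_X0 = 8000
    ),
    column = list(
      length_cm = 64,
      n_cells = 64,
      diameter_cm = 4.5,
      porosity = 0.375,
      dispersivity_cm = 0.1,
      Dm_cm2_s = 1e-5,
      dt_d = 0.01,
      sample_every_d = 0.25,
      splitting = "sequential",
      startup_sulfate_mM = 0.1
    ),
    synthetic = list(
      noise_sd = 0.05,
      noise_floor_mg_l = 0.5
    )
  )
}

# recursively fill defaults and flag unknown keys
merge_config <- function(defaults, user, path = character()) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, "")[1], unknown, sep = ""), collapse = ", "),
         if (length(path)) paste0(" (under '",
                                  paste(path, collapse = "."), "')"))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates it against the package schema
#' (unknown keys are an error naming the offending key) and fills in the
#' documented defaults for everything omitted. `load_config` of a file
#' written by [write_config()] is the identity.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (a named list following
#'   `config_schema`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_schema(), user)
  if (!identical(cfg$schema_version, 1L) && !identical(cfg$schema_version, 1)) {
    stop("unsupported schema_version: ", cfg$schema_version)
  }
  if (!cfg$units %in% c("mM", "mg/l")) {
    stop("units must be 'mM' or 'mg/l'")
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param config A `run_config` (or plain list following the schema).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Kinetics list from a configuration
#'
#' @param config A [load_config()] result.
#' @param communities Communities to extract.
#' @return Named list of [kinetic_params()].
#' @export
config_kinetics <- function(config, communities = names(config$kinetics)) {
  lapply(stats::setNames(nm = communities), function(cm) {
    p <- config$kinetics[[cm]]
    if (is.null(p)) stop("no kinetics configured for '", cm, "'")
    I <- if (identical(p$I, "none") || is.null(p$I)) Inf else p$I
    kinetic_params(p$mu_max, p$K_d, p$K_a, I = I, b = p$b, X0 = p$X0)
  })
}

#' Write run outputs with a reproducibility manifest
#'
#' Writes each table of a run as a CSV file and a `manifest.json`
#' recording the configuration (and its MD5 hash), the seed, and package
#' versions, so a run directory is self-describing.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to embed.
#' @param seed Seed used for the run.
#' @return Invisibly, the manifest path.
#' @export
write_outputs <- function(tables, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg_hash <- NULL
  if (!is.null(config)) {
    cfg_path <- file.path(dir, "config.yaml")
    write_config(config, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  }
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_md5 = cfg_hash,
    tables = names(tables),
    package = list(
      soursim = as.character(utils::packageVersion("soursim")),
      deSolve = as.character(utils::packageVersion("deSolve")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
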