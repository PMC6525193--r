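#' Batch experiment design
#'
#' The five-flask anaerobic batch design used throughout the package:
#' initial sulfate 1000 mg/l and lactate 2500 mg/l in every flask, nitrate
#' at 0, 200, 500, 700 or 1000 mg/l, and a total inoculum of 8000 mg/l
#' biomass. An ammonium pool (default 5 mM) supplies the nitrogen source
#' for cell synthesis, as in a standard anaerobic growth medium.
#'
#' @param nitrate_mg_l Nitrate levels, mg/l (one experiment each).
#' @param sulfate_mg_l,lactate_mg_l Common initial concentrations, mg/l.
#' @param ammonium_M Initial ammonium, mol/l.
#' @return Named list of initial-condition vectors (mol/l), names
#'   `"no3_<level>"`.
#' @export
batch_design <- function(nitrate_mg_l = c(0, 200, 500, 700, 1000),
                         sulfate_mg_l = 1000, lactate_mg_l = 2500,
                         ammonium_M = 5e-3) {
  out <- lapply(nitrate_mg_l, function(n) {
    c(sulfate = to_molar(sulfate_mg_l, "sulfate", "mg/l"),
      lactate = to_molar(lactate_mg_l, "lactate", "mg/l"),
      nitrate = to_molar(n, "nitrate", "mg/l"),
      ammonium = ammonium_M)
  })
  stats::setNames(out, paste0("no3_", nitrate_mg_l))
}

apply_noise <- function(value, sd_rel, floor_mg_l, species) {
  if (sd_rel <= 0) return(value)
  sd_abs <- pmax(abs(value) * sd_rel,
                 to_molar(floor_mg_l, species, "mg/l"))
  pmax(value + stats::rnorm(length(value), 0, sd_abs), 0)
}

#' Generate a synthetic batch data set
#'
#' Simulates the batch design under known ground-truth parameters and adds
#' multiplicative Gaussian observation noise (relative sd `noise_sd`, with
#' an absolute floor per species, truncated at zero). Noise is applied to
#' the observations only; the noiseless trajectories are retained. The
#' data set is regenerated bit-identically from `(truth, seed)`.
#'
#' @param scen Scenario of the ground truth (a [scenario()] or group
#'   labels); must be admissible.
#' @param kinetics Ground-truth kinetics (defaults: [default_kinetics()]).
#' @param fe Energy-fraction overrides.
#' @param design Experiment design from [batch_design()].
#' @param times Observation times, seconds.
#' @param noise_sd Relative noise standard deviation (0.05 default).
#' @param noise_floor_mg_l Absolute noise floor, mg/l.
#' @param species Observed species.
#' @param seed Integer seed.
#' @param frozen_biomass Forwarded to [simulate_batch()].
#' @return Object of class `synthetic_batch`: `data` (noisy tidy table
#'   with columns `experiment_id`, `time`, `species`, `value`, `unit`),
#'   `truth_data` (noiseless), `experiments`, `times`, `truth`
#'   (scenario label, kinetics, fe), `seed`.
#' @export
make_batch_set <- function(scen = "A", kinetics = NULL, fe = default_fe(),
                           design = batch_design(),
                           times = seq(0, 12 * 3600, by = 3600),
                           noise_sd = 0.05, noise_floor_mg_l = 0.5,
                           species = c("sulfate", "sulfide", "nitrate",
                                       "nitrite", "lactate"),
                           seed = 1, frozen_biomass = TRUE) {
  scen_obj <- if (inherits(scen, "scenario")) scen else scenario(scen)
  if (!scen_obj$admissible) {
    stop("ground-truth scenario {",
         paste(scen_obj$groups, collapse = ","), "} is not admissible")
  }
  net <- reaction_network(scen_obj, fe = fe)
  if (is.null(kinetics)) kinetics <- default_kinetics(net$communities)
  set.seed(seed)
  rows <- list()
  clean <- list()
  for (eid in names(design)) {
    traj <- simulate_batch(net, kinetics, design[[eid]], times,
                           frozen_biomass = frozen_biomass)
    for (s in species) {
      noiseless <- traj[[s]]
      rows[[length(rows) + 1]] <- data.frame(
        experiment_id = eid, time = times, species = s,
        value = apply_noise(noiseless, noise_sd, noise_floor_mg_l, s),
        unit = "mol/l", stringsAsFactors = FALSE)
      clean[[length(clean) + 1]] <- data.frame(
        experiment_id = eid, time = times, species = s,
        value = noiseless, unit = "mol/l", stringsAsFactors = FALSE)
    }
  }
  structure(
    list(data = do.call(rbind, rows),
         truth_data = do.call(rbind, clean),
         experiments = design, times = times,
         truth = list(scenario = scen_obj$label, kinetics = kinetics,
                      fe = fe),
         noise = list(sd = noise_sd, floor_mg_l = noise_floor_mg_l),
         seed = seed),
    class = "synthetic_batch"
  )
}

#' Generate a synthetic column data set
#'
#' Runs the packed-bed column model under ground-truth parameters and adds
#' observation noise to the sampled port series (noise on observations
#' only; the true series is retained).
#'
#' @param scen Ground-truth scenario or community names (e.g. `"SRB"`).
#' @param kinetics Ground-truth kinetics.
#' @param grid A [column_grid()].
#' @param schedule A schedule table (see [column_schedule()]).
#' @param initial Named initial concentrations, mol/l.
#' @param fe Energy-fraction overrides.
#' @param noise_sd,noise_floor_mg_l Noise model as in [make_batch_set()].
#' @param seed Integer seed.
#' @param ... Forwarded to [run_column()].
#' @return Object of class `synthetic_column`: `data` (noisy port table),
#'   `truth_data` (noiseless), `truth`, `seed`.
#' @export
make_column_set <- function(scen, kinetics, grid, schedule, initial,
                            fe = default_fe(), noise_sd = 0.05,
                            noise_floor_mg_l = 0.5, seed = 1, ...) {
  net <- if (inherits(scen, "reaction_network")) scen
         else reaction_network(scen, fe = fe)
  run <- run_column(grid, schedule, net, kinetics, initial, ...)
  ports <- run$ports
  set.seed(seed)
  noisy <- ports
  for (s in unique(ports$species)) {
    ix <- ports$species == s
    noisy$value_mM[ix] <- from_molar(
      apply_noise(to_molar(ports$value_mM[ix], s, "mM"),
                  noise_sd, noise_floor_mg_l, s), s, "mM")
  }
  structure(
    list(data = noisy, truth_data = ports, run = run,
         truth = list(communities = net$communities, kinetics = kinetics),
         noise = list(sd = noise_sd, floor_mg_l = noise_floor_mg_l),
         seed = seed),
    class = "synthetic_column"
  )
}
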