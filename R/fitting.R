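#' Default parameter bounds for fitting
#'
#' Box bounds for the free kinetic parameters, spanning literature-typical
#' ranges for anaerobic respirers: `mu_max` in [1e-6, 1e-3] 1/s, half
#' saturation constants and the inhibition coefficient in [1e-6, 1e-2]
#' mol/l, decay in [0, 1e-5] 1/s, initial biomass in [0, 8000] mg/l.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_param_bounds <- function() {
  list(mu_max = c(1e-6, 1e-3),
       K_d    = c(1e-6, 1e-2),
       K_a    = c(1e-6, 1e-2),
       I      = c(1e-6, 1e-2),
       b      = c(0, 1e-5),
       X0     = c(0, 8000))
}

#' Define a parameter-estimation problem
#'
#' Bundles the free parameters (an ordered `(community, parameter)` list
#' with box bounds), the fixed baseline kinetics, the batch experiment
#' designs and observations, and the linear biomass-sum constraint.
#' Parameters with strictly positive bounds are searched in log10 space.
#'
#' @param network A [reaction_network()].
#' @param free_params `data.frame` with columns `community`, `param` and
#'   optionally `lower`, `upper` (defaults from [default_param_bounds()]).
#' @param kinetics Baseline [kinetic_params()] list; free entries are
#'   overwritten during the fit, everything else stays fixed.
#' @param experiments Named list of initial-condition vectors (mol/l), one
#'   per experiment id.
#' @param data Observation table (see [sse_score()]).
#' @param t_grid Simulation output times, seconds.
#' @param max_total_X0 Biomass-sum constraint in mg/l: the sum of all
#'   community `X0` values must not exceed this (candidates are repaired by
#'   proportional scaling of the free `X0` entries).
#' @param sse_species,frozen_biomass,rtol,atol Forwarded to the simulator
#'   and scorer.
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(network, free_params, kinetics, experiments, data,
                        t_grid, max_total_X0 = 8000,
                        sse_species = c("sulfate", "sulfide",
                                        "nitrate", "nitrite"),
                        frozen_biomass = TRUE, rtol = 1e-7, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"),
            is.data.frame(free_params),
            all(c("community", "param") %in% names(free_params)))
  defaults <- default_param_bounds()
  if (is.null(free_params$lower)) {
    free_params$lower <- vapply(free_params$param,
                                function(p) defaults[[p]][1], 0)
  }
  if (is.null(free_params$upper)) {
    free_params$upper <- vapply(free_params$param,
                                function(p) defaults[[p]][2], 0)
  }
  if (any(free_params$lower > free_params$upper)) {
    stop("lower bound exceeds upper bound")
  }
  bad <- setdiff(free_params$community, network$communities)
  if (length(bad)) stop("free parameters for communities outside the ",
                        "network: ", paste(bad, collapse = ", "))
  free_params$log_scale <- free_params$lower > 0
  structure(
    list(network = network, free_params = free_params,
         kinetics = kinetics, experiments = experiments, data = data,
         t_grid = t_grid, max_total_X0 = max_total_X0,
         sse_species = sse_species, frozen_biomass = frozen_biomass,
         rtol = rtol, atol = atol),
    class = "fit_problem"
  )
}

# theta (search space) -> kinetics list
decode_theta <- function(problem, theta) {
  kin <- problem$kinetics
  fp <- problem$free_params
  for (i in seq_len(nrow(fp))) {
    val <- if (fp$log_scale[i]) 10^theta[i] else theta[i]
    kin[[fp$community[i]]][[fp$param[i]]] <- val
  }
  kin
}

encode_values <- function(problem, values) {
  ifelse(problem$free_params$log_scale, log10(values), values)
}

theta_bounds <- function(problem) {
  fp <- problem$free_params
  list(lower = ifelse(fp$log_scale, log10(fp$lower), fp$lower),
       upper = ifelse(fp$log_scale, log10(fp$upper), fp$upper))
}

# repair in search space: scale free X0 entries so the community biomass
# sum stays within the constraint
make_repair <- function(problem) {
  fp <- problem$free_params
  ix <- which(fp$param == "X0")
  if (length(ix) == 0) return(NULL)
  fixed_X0 <- sum(vapply(
    problem$kinetics[setdiff(problem$network$communities,
                             fp$community[ix])],
    `[[`, 0, "X0"))
  cap <- problem$max_total_X0 - fixed_X0
  if (cap < 0) stop("fixed biomass already exceeds the total-biomass ",
                    "constraint")
  function(theta) {
    x0 <- ifelse(fp$log_scale[ix], 10^theta[ix], theta[ix])
    tot <- sum(x0)
    if (tot > cap) {
      x0 <- x0 * cap / tot
      theta[ix] <- ifelse(fp$log_scale[ix], log10(x0), x0)
    }
    theta
  }
}

problem_objective <- function(problem) {
  function(theta) {
    kin <- decode_theta(problem, theta)
    traj <- vector("list", length(problem$experiments))
    names(traj) <- names(problem$experiments)
    for (eid in names(problem$experiments)) {
      sim <- try(simulate_batch(problem$network, kin,
                                problem$experiments[[eid]],
                                problem$t_grid,
                                frozen_biomass = problem$frozen_biomass,
                                rtol = problem$rtol, atol = problem$atol),
                 silent = TRUE)
      if (inherits(sim, "try-error")) return(1e12)
      traj[[eid]] <- sim
    }
    sse_score(traj, problem$data, species = problem$sse_species)$sse
  }
}

#' Fit a problem with the GA + local refinement procedure
#'
#' Global search with [ga_optimize()] followed (optionally) by a bounded
#' local polish with [stats::nlminb()] from the GA optimum.
#'
#' @param problem A [fit_problem()].
#' @param seed Integer seed for the GA.
#' @param ga_control List of overrides for [ga_optimize()] arguments
#'   (`pop_size`, `generations`, ...).
#' @param polish Run the local refinement stage?
#' @param polish_control Control list for [stats::nlminb()] (e.g.
#'   `iter.max`) to cap the refinement budget.
#' @return Object of class `fit_result`: `kinetics` (full updated list),
#'   `par` (named free-parameter values on their natural scale), `sse`,
#'   `trace`, `n_generations`, `seed`, `converged`.
#' @export
fit_parameters <- function(problem, seed = 1, ga_control = list(),
                           polish = TRUE, polish_control = list()) {
  obj <- problem_objective(problem)
  tb <- theta_bounds(problem)
  args <- utils::modifyList(
    list(fn = obj, lower = tb$lower, upper = tb$upper,
         repair = make_repair(problem), seed = seed),
    ga_control)
  ga <- do.call(ga_optimize, args)
  theta <- ga$par
  value <- ga$value
  if (polish && any(tb$upper > tb$lower)) {
    ctrl <- utils::modifyList(list(iter.max = 300, eval.max = 600),
                              polish_control)
    loc <- stats::nlminb(theta, obj, lower = tb$lower, upper = tb$upper,
                         control = ctrl)
    if (is.finite(loc$objective) && loc$objective <= value) {
      repair <- make_repair(problem)
      cand <- if (is.null(repair)) loc$par else repair(loc$par)
      cand_val <- if (identical(cand, loc$par)) loc$objective else obj(cand)
      if (cand_val <= value) {
        theta <- cand
        value <- cand_val
      }
    }
  }
  fp <- problem$free_params
  natural <- ifelse(fp$log_scale, 10^theta, theta)
  names(natural) <- paste(fp$community, fp$param, sep = ".")
  structure(
    list(kinetics = decode_theta(problem, theta), par = natural,
         theta = theta, sse = value, trace = c(ga$trace, value),
         n_generations = ga$n_generations, n_evals = ga$n_evals,
         seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> SSE = %.6g after %d GA generations\n",
              x$sse, x$n_generations))
  print(signif(x$par, 4))
  invisible(x)
}

srb_free_params <- function(free = c("mu_max", "K_d", "K_a")) {
  data.frame(community = "SRB", param = free, stringsAsFactors = FALSE)
}

#' Stage 1: fit SRB kinetics on sulfate-only data
#'
#' Estimates the kinetic parameters of the sulfate reducers (KPSR) from the
#' nitrate-free part of the batch data set. The inhibition coefficient `I`
#' cannot be identified without a nitrite signal and is left at its
#' baseline value here; it is fitted in the second stage.
#'
#' @param data Observations restricted to nitrate-free experiments (an
#'   error is raised if a nitrate/nitrite signal is present).
#' @param experiments Initial-condition list for those experiments.
#' @param kinetics Baseline kinetics for SRB (fixes `X0`, `b`, `I`).
#' @param free Which SRB parameters to fit.
#' @param t_grid,seed,ga_control,polish,polish_control,... Forwarded to
#'   [fit_problem()] and [fit_parameters()].
#' @return A `fit_result` whose `kinetics$SRB` is the fixed KPSR for all
#'   downstream fits.
#' @export
fit_kpsr <- function(data, experiments, kinetics = default_kinetics("SRB"),
                     free = c("mu_max", "K_a"), t_grid,
                     seed = 1, ga_control = list(), polish = TRUE,
                     polish_control = list(), ...) {
  nsig <- data$species %in% c("nitrate", "nitrite") & data$value > 0
  if (any(nsig)) {
    stop("KPSR data must contain no nitrate/nitrite signal")
  }
  net <- reaction_network("SRB")
  problem <- fit_problem(net, srb_free_params(free), kinetics,
                         experiments, data, t_grid,
                         sse_species = c("sulfate", "sulfide"), ...)
  fit_parameters(problem, seed = seed, ga_control = ga_control,
                 polish = polish, polish_control = polish_control)
}

#' Default free-parameter table for a scenario's KPNR fit
#'
#' One `(mu_max, K_d, K_a)` triple per nitrate/nitrite-reducing community
#' of the scenario, plus the SRB inhibition coefficient `I` (identifiable
#' only once nitrite appears).
#'
#' @param scen A [scenario()].
#' @param per_community Parameters freed for each N-cycle community.
#' @param fit_srb_I Also free SRB's `I`?
#' @return `data.frame` suitable for [fit_problem()].
#' @export
kpnr_free_params <- function(scen, per_community = c("mu_max", "K_a"),
                             fit_srb_I = TRUE) {
  comms <- setdiff(scen$communities, "SRB")
  fp <- data.frame(
    community = rep(comms, each = length(per_community)),
    param = rep(per_community, length(comms)),
    stringsAsFactors = FALSE)
  if (fit_srb_I) {
    fp <- rbind(fp, data.frame(community = "SRB", param = "I"))
  }
  fp
}

#' Stage 2: fit a scenario's nitrate-reducer kinetics
#'
#' With the KPSR fixed, estimates the kinetic parameters of the nitrate
#' reducers (KPNR) of one admissible scenario against the nitrate-amended
#' batch data.
#'
#' @param scen An admissible [scenario()].
#' @param kpsr_kinetics Kinetics list containing the fixed SRB entry (e.g.
#'   `fit_kpsr(...)$kinetics`).
#' @param data,experiments,t_grid As in [fit_kpsr()].
#' @param kinetics Baseline kinetics for the scenario's other communities.
#' @param free_params Optional override of [kpnr_free_params()].
#' @param seed,ga_control,polish,polish_control,... Forwarded to the
#'   optimizer.
#' @return A `fit_result`.
#' @export
fit_kpnr <- function(scen, kpsr_kinetics, data, experiments, t_grid,
                     kinetics = default_kinetics(scen$communities),
                     free_params = kpnr_free_params(scen),
                     seed = 1, ga_control = list(), polish = TRUE,
                     polish_control = list(), ...) {
  stopifnot(inherits(scen, "scenario"))
  if (!scen$admissible) stop("scenario {",
    paste(scen$groups, collapse = ","), "} is not admissible")
  kinetics[["SRB"]] <- kpsr_kinetics[["SRB"]]
  net <- reaction_network(scen)
  problem <- fit_problem(net, free_params, kinetics, experiments, data,
                         t_grid, ...)
  fit_parameters(problem, seed = seed, ga_control = ga_control,
                 polish = polish, polish_control = polish_control)
}

#' Screen scenarios by SSE
#'
#' Fits every supplied scenario with [fit_kpnr()] and ranks them by SSE;
#' the relative SSE (`RSSE`, percent above the best) is computed against
#' the minimum. Ties are broken by the canonical scenario order.
#'
#' @param scenarios List of scenarios (default: the full enumeration).
#' @param kpsr_kinetics,data,experiments,t_grid,seed,ga_control,polish,polish_control,...
#'   Forwarded to [fit_kpnr()].
#' @return A `data.frame` (one row per scenario, ascending SSE) with
#'   columns `scenario`, `sse`, `rsse`, `n_free`, plus the list-column
#'   `fit` holding each `fit_result`.
#' @export
screen_scenarios <- function(scenarios = enumerate_scenarios(),
                             kpsr_kinetics, data, experiments, t_grid,
                             seed = 1, ga_control = list(), polish = TRUE,
                             polish_control = list(), ...) {
  fits <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    fits[[i]] <- fit_kpnr(scenarios[[i]], kpsr_kinetics, data, experiments,
                          t_grid, seed = seed + i - 1L,
                          ga_control = ga_control, polish = polish,
                          polish_control = polish_control, ...)
  }
  sse <- vapply(fits, `[[`, 0, "sse")
  out <- data.frame(
    scenario = vapply(scenarios, `[[`, "", "label"),
    sse = sse,
    rsse = rsse(sse),
    n_free = vapply(fits, function(f) length(f$par), 0L),
    stringsAsFactors = FALSE)
  ord <- order(out$sse, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$fit <- fits[ord]
  rownames(out) <- NULL
  out
}
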