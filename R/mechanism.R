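#' Build a model variant with mechanisms toggled off
#'
#' The mechanism-dissection simulations compare a base model against
#' variants in which (a) the nitrite inhibition factor is removed from the
#' SRB rate law and/or (b) whole communities are removed (dropping the
#' nitrate reducers removes biocompetition, dropping the sulfide oxidizers
#' removes sulfur cycling). Removing the inhibition factor is exactly
#' setting the inhibition coefficient to infinity.
#'
#' @param network A [reaction_network()].
#' @param kinetics Kinetics list for the network.
#' @param inhibition_on Keep the nitrite inhibition factor on SRB?
#' @param drop Character vector of community names to remove (error if not
#'   present in the network).
#' @return List with modified `network` and `kinetics`.
#' @export
sim_variant <- function(network, kinetics, inhibition_on = TRUE,
                        drop = character()) {
  bad <- setdiff(drop, network$communities)
  if (length(bad)) {
    stop("cannot remove communities not in the model: ",
         paste(bad, collapse = ", "))
  }
  keep <- setdiff(network$communities, drop)
  net <- reaction_network(keep, fe = default_fe())
  kin <- kinetics[keep]
  if (!inhibition_on) {
    for (cm in names(kin)) kin[[cm]]$I <- Inf
  }
  list(network = net, kinetics = kin)
}

#' Run a batch or column simulation of a model variant
#'
#' @param variant Output of [sim_variant()].
#' @param setting `"batch"` or `"column"`.
#' @param ... Arguments of [simulate_batch()] (batch) or [run_column()]
#'   (column), minus `network`/`kinetics`.
#' @return The simulator's return value with attribute `variant`.
#' @export
run_variant <- function(variant, setting = c("batch", "column"), ...) {
  setting <- match.arg(setting)
  out <- if (setting == "batch") {
    simulate_batch(variant$network, variant$kinetics, ...)
  } else {
    run_column(network = variant$network, kinetics = variant$kinetics, ...)
  }
  attr(out, "variant") <- variant
  out
}

#' Minimum inhibitory nitrate concentration (MINC)
#'
#' Stoichiometric nitrate demand that exhausts the electron donor
#' regardless of distance or nitrite inhibition: the donor concentration
#' times the sulfate reduced per donor, divided by the total sulfide
#' (direct plus indirect) oxidized per nitrate. MINC is exactly linear in
#' the donor concentration.
#'
#' @param lactate_mM Electron-donor (lactate) concentration, mM.
#' @param yield_sulfate_per_lactate Mol sulfate reduced per mol lactate
#'   (SRB reaction; 1.2748 with the default fe values).
#' @param yield_sulfide_per_nitrate_total Mol sulfide oxidized per mol
#'   nitrate, direct plus via the produced nitrite (1.1564 by default).
#' @return Nitrate demand, mM.
#' @examples
#' minc(25)  # 27.56 mM
#' @export
minc <- function(lactate_mM,
                 yield_sulfate_per_lactate = minc_yields()$sulfate_per_lactate,
                 yield_sulfide_per_nitrate_total =
                   minc_yields()$sulfide_per_nitrate_total) {
  if (yield_sulfate_per_lactate <= 0 ||
      yield_sulfide_per_nitrate_total <= 0) {
    stop("yields must be positive")
  }
  lactate_mM * yield_sulfate_per_lactate / yield_sulfide_per_nitrate_total
}

#' Stoichiometric yields entering the MINC calculation
#'
#' Derives, from the community reactions, the sulfate reduced per lactate
#' (SRB), the sulfide oxidized directly per nitrate (nitrate-step sulfide
#' oxidizer), the sulfide oxidized per nitrite (nitrite step, equal to the
#' indirect yield per nitrate since each nitrate yields one nitrite), and
#' their total.
#'
#' @param fe Energy-fraction overrides.
#' @return Named list: `sulfate_per_lactate`, `sulfide_per_nitrate_direct`,
#'   `sulfide_per_nitrate_indirect`, `sulfide_per_nitrate_total`.
#' @export
minc_yields <- function(fe = default_fe()) {
  cs <- community_set(fe)
  direct <- stoich_yield(cs$NRSOB1, "sulfide", "nitrate")
  nitrite_per_nitrate <- stoich_yield(cs$NRSOB1, "nitrite", "nitrate")
  indirect <- stoich_yield(cs$NRSOB2, "sulfide", "nitrite") *
    nitrite_per_nitrate
  list(sulfate_per_lactate = stoich_yield(cs$SRB, "sulfate", "lactate"),
       sulfide_per_nitrate_direct = direct,
       sulfide_per_nitrate_indirect = indirect,
       sulfide_per_nitrate_total = direct + indirect)
}

#' Quasi-steady sulfide at an observation distance
#'
#' Runs the column at a constant flow and influent (with the given nitrate
#' injection concentration) and returns the sulfide level at the
#' observation distance once quasi-steady, defined as a relative change
#' below `steady_rel` over the trailing `steady_window_d` days.
#'
#' @param nitrate_mM Injected nitrate concentration, mM.
#' @param grid,network,kinetics,initial Column model inputs.
#' @param influent_mM Named vector of the other influent concentrations
#'   (mM), e.g. `c(sulfate = 10, lactate = 25, ammonium = 5)`.
#' @param flow_ml_h Constant flow rate, ml/h.
#' @param distance_cm Observation distance from the inlet, cm.
#' @param t_end_d Simulation horizon, days.
#' @param steady_window_d,steady_rel Quasi-steady criterion.
#' @param warn_unsteady Warn if the criterion is not met at `t_end_d`.
#' @param ... Forwarded to [run_column()].
#' @return Sulfide concentration, mM, with attribute `steady` (logical).
#' @export
quasi_steady_sulfide <- function(nitrate_mM, grid, network, kinetics,
                                 initial, influent_mM, flow_ml_h,
                                 distance_cm, t_end_d,
                                 steady_window_d = 5, steady_rel = 0.01,
                                 warn_unsteady = TRUE, ...) {
  sched <- do.call(column_schedule, c(
    list(time_d = 0, flow_ml_h = flow_ml_h, nitrate = nitrate_mM),
    as.list(influent_mM)))
  cells <- cells_at(grid, distance_cm, n = 1)
  run <- run_column(grid, sched, network, kinetics, initial,
                    t_end_d = t_end_d,
                    ports = list(obs = cells), ...)
  s <- run$ports[run$ports$species == "sulfide" &
                 run$ports$port == "obs", ]
  tail_win <- s[s$time_d >= max(s$time_d) - steady_window_d, ]
  final <- s$value_mM[which.max(s$time_d)]
  span <- diff(range(tail_win$value_mM))
  steady <- span <= steady_rel * max(final, 1e-6)
  if (!steady && warn_unsteady) {
    warning("sulfide not quasi-steady at t_end (relative span ",
            signif(span / max(final, 1e-6), 2), ")")
  }
  structure(final, steady = steady)
}

#' Required inhibitory nitrate concentration (RINC) by bisection
#'
#' Finds the lowest nitrate injection concentration keeping the
#' quasi-steady sulfide at the observation distance below the threshold,
#' assuming a monotone (non-increasing) sulfide response to the nitrate
#' dose. If the system is already below the threshold with no nitrate
#' (e.g. no SRB in the network), the RINC is 0.
#'
#' @param lo,hi Bracket for the injected nitrate, mM; `hi` must suppress
#'   sulfide below the threshold (otherwise a search error is raised).
#' @param sulfide_threshold_mM "Souring inhibited" criterion (0.1 mM
#'   default).
#' @param tol_mM Bisection tolerance, mM.
#' @param ... Forwarded to [quasi_steady_sulfide()].
#' @return The RINC in mM, with attribute `evals` (doses evaluated).
#' @export
rinc_search <- function(lo = 0, hi, sulfide_threshold_mM = 0.1,
                        tol_mM = 0.25, ...) {
  evals <- numeric()
  f <- function(dose) {
    evals[[length(evals) + 1]] <<- dose
    as.numeric(quasi_steady_sulfide(dose, ...))
  }
  if (f(lo) < sulfide_threshold_mM) {
    return(structure(lo, evals = evals))
  }
  if (f(hi) >= sulfide_threshold_mM) {
    stop("upper bracket ", hi, " mM does not suppress sulfide below ",
         sulfide_threshold_mM, " mM")
  }
  while (hi - lo > tol_mM) {
    mid <- (lo + hi) / 2
    if (f(mid) < sulfide_threshold_mM) hi <- mid else lo <- mid
  }
  structure(hi, evals = evals)
}

#' Set the nitrite-to-nitrate reduction rate ratio (R)
#'
#' R is the ratio of the maximum specific turnover rates of the nitrite
#' step to the nitrate step, evaluated at substrate saturation with the
#' initial biomass: `R = (mu2 X2 nu2) / (mu1 X1 nu1)` with `nu` the
#' acceptor coefficient per mol biomass. The nitrite-step `mu_max` is
#' rescaled to reach the target; doubling the target exactly doubles it.
#'
#' @param network A [reaction_network()] containing both steps.
#' @param kinetics Kinetics list.
#' @param target_R Desired ratio (> 0).
#' @param nitrate_step,nitrite_step Community names of the two steps.
#' @return List with updated `kinetics` and the `achieved_R`.
#' @export
set_r_ratio <- function(network, kinetics, target_R,
                        nitrate_step, nitrite_step) {
  if (target_R <= 0) stop("target_R must be positive")
  for (cm in c(nitrate_step, nitrite_step)) {
    if (!cm %in% network$communities) {
      stop("community '", cm, "' not in the network")
    }
  }
  nu <- function(cm) abs(network$stoich[network$acceptor[cm],
                                        cm])
  rate1 <- kinetics[[nitrate_step]]$mu_max * kinetics[[nitrate_step]]$X0 *
    nu(nitrate_step)
  if (rate1 <= 0) stop("nitrate-step maximum rate is zero")
  denom <- kinetics[[nitrite_step]]$X0 * nu(nitrite_step)
  if (denom <= 0) stop("nitrite-step biomass or stoichiometry is zero")
  kinetics[[nitrite_step]]$mu_max <- target_R * rate1 / denom
  achieved <- kinetics[[nitrite_step]]$mu_max * denom / rate1
  list(kinetics = kinetics, achieved_R = achieved)
}

#' Time to half-maximal concentration
#'
#' First time a trajectory reaches half of its maximum, by linear
#' interpolation; a simple summary of how fast souring develops.
#'
#' @param traj Trajectory from [simulate_batch()].
#' @param species Species column to summarize.
#' @return Time in the trajectory's time unit (`NA` if never reached).
#' @export
time_to_half_max <- function(traj, species = "sulfide") {
  v <- traj[[species]]
  half <- max(v) / 2
  if (max(v) <= 0) return(NA_real_)
  i <- which(v >= half)[1]
  if (i == 1) return(traj$time[1])
  t1 <- traj$time[i - 1]; t2 <- traj$time[i]
  v1 <- v[i - 1]; v2 <- v[i]
  t1 + (half - v1) / (v2 - v1) * (t2 - t1)
}
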