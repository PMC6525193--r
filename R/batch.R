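# Vectorized reaction right-hand side shared by the batch simulator and the
# column model's reaction step. Concentrations and biomass are matrices with
# one column per cell (a batch reactor is a single cell); all rate algebra
# is column-parallel.

# conc: n_species x n_cells (mol/l, rows = network$species)
# X:    n_comm x n_cells (mol/l biomass)
# returns list(dconc, dX_growth, dX_decay)
reaction_rates <- function(network, kinetics, conc, X, inhibitor = "nitrite",
                           cutoff = 1e-12, frozen_biomass = FALSE) {
  ncell <- ncol(conc)
  ncomm <- length(network$communities)
  growth <- matrix(0, ncomm, ncell)
  cpos <- pmax(conc, 0)
  c_inh <- cpos[inhibitor, ]
  for (j in seq_len(ncomm)) {
    p <- kinetics[[network$communities[j]]]
    cd <- cpos[network$donor[j], ]
    ca <- cpos[network$acceptor[j], ]
    inh <- if (network$inhibited[j] && is.finite(p$I)) {
      p$I / (c_inh + p$I)
    } else 1
    g <- p$mu_max * X[j, ] * cd / (cd + p$K_d) * ca / (ca + p$K_a) * inh
    # smooth cutoff: taper consumption of any reactant approaching zero so
    # the system stays Lipschitz instead of hard-clipping at 0
    nu <- network$stoich[, j]
    for (s in which(nu < 0)) {
      g <- g * cpos[s, ] / (cpos[s, ] + cutoff)
    }
    growth[j, ] <- g
  }
  dconc <- network$stoich %*% growth
  decay <- matrix(0, ncomm, ncell)
  if (!frozen_biomass) {
    for (j in seq_len(ncomm)) {
      decay[j, ] <- kinetics[[network$communities[j]]]$b * X[j, ]
    }
  }
  list(dconc = dconc, dX = if (frozen_biomass) matrix(0, ncomm, ncell)
                           else growth - decay)
}

# Precompute the flat index/parameter context the compiled RHS consumes.
# State layout (matching as.vector of the species x cell matrices): species
# concentrations cell-by-cell, then biomass cell-by-cell.
make_rhs_parms <- function(network, kinetics, ncell, cutoff,
                           frozen_biomass, inhibitor = "nitrite") {
  sp <- network$species
  comms <- network$communities
  par <- vapply(comms, function(cm) {
    p <- kinetics[[cm]]
    c(p$mu_max, p$K_d, p$K_a, p$I, p$b)
  }, numeric(5))
  list(dims = as.integer(c(length(sp), length(comms), ncell)),
       stoich = network$stoich,
       don = as.integer(match(network$donor, sp) - 1L),
       acc = as.integer(match(network$acceptor, sp) - 1L),
       inh = as.integer(match(inhibitor, sp) - 1L),
       par = matrix(as.numeric(par), nrow = 5),
       inhibited = as.integer(network$inhibited),
       frozen = as.integer(frozen_biomass),
       cutoff = as.numeric(cutoff))
}

# Flattened deSolve RHS over an arbitrary number of cells (compiled kernel).
reaction_ode_rhs <- function(t, y, parms) {
  list(.Call(C_reaction_rhs, y, parms$dims, parms$stoich, parms$don,
             parms$acc, parms$inh, parms$par, parms$inhibited,
             parms$frozen, parms$cutoff))
}

#' Simulate a well-mixed batch reactor
#'
#' Integrates the scenario's reaction network under the Monod rate law with
#' nitrite inhibition of SRB. Species turnover is the stoichiometric
#' coefficient (per mol biomass) times the growth term; the endogenous decay
#' term removes biomass only. With `frozen_biomass = TRUE` (the default,
#' matching a heavy-inoculum short-horizon experiment) biomass is held at
#' its initial value while substrates still turn over.
#'
#' @param network A [reaction_network()].
#' @param kinetics Named list of [kinetic_params()], one per community; the
#'   `X0` fields (mg/l) set the initial biomass.
#' @param initial Named numeric vector of initial concentrations in mol/l
#'   over (a subset of) `network$species`; absent species start at 0.
#' @param t_grid Increasing numeric vector of output times, seconds.
#' @param frozen_biomass Hold biomass constant (`dX/dt = 0`)?
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#' @param cutoff Smooth non-negativity cutoff concentration, mol/l.
#' @return A `data.frame` with column `time` (s), one column per tracked
#'   species (mol/l) and one `X_<community>` column per community (mol/l).
#' @examples
#' net <- reaction_network("SRB")
#' kin <- default_kinetics("SRB")
#' out <- simulate_batch(net, kin,
#'   c(sulfate = to_molar(1000, "sulfate", "mg/l"),
#'     lactate = to_molar(2500, "lactate", "mg/l")),
#'   t_grid = seq(0, 12 * 3600, by = 3600))
#' @export
simulate_batch <- function(network, kinetics, initial, t_grid,
                           frozen_biomass = TRUE,
                           rtol = 1e-8, atol = 1e-12, cutoff = 1e-12) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing")
  }
  missing_kin <- setdiff(network$communities, names(kinetics))
  if (length(missing_kin)) {
    stop("kinetics missing for: ", paste(missing_kin, collapse = ", "))
  }
  conc0 <- stats::setNames(numeric(length(network$species)), network$species)
  bad <- setdiff(names(initial), network$species)
  if (length(bad)) stop("initial concentrations for untracked species: ",
                        paste(bad, collapse = ", "))
  conc0[names(initial)] <- initial
  if (any(conc0 < 0)) stop("initial concentrations must be non-negative")
  X0 <- vapply(network$communities,
               function(cm) to_molar(kinetics[[cm]]$X0, "biomass", "mg/l"),
               0)
  y0 <- c(conc0, X0)
  parms <- make_rhs_parms(network, kinetics, 1L, cutoff, frozen_biomass)
  sol <- deSolve::lsoda(y = unname(y0), times = t_grid,
                        func = reaction_ode_rhs, parms = parms,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("batch ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", network$species,
                  paste0("X_", network$communities))
  out
}

#' Score simulated trajectories against tabular data
#'
#' Sum of squared errors between model trajectories and observations, with
#' the model linearly interpolated onto the observation times. Residuals
#' are normalized per species by the observed range of that species across
#' the whole data set (`weighting = "range"`), so species measured on very
#' different concentration scales contribute comparably, or used raw
#' (`weighting = "none"`).
#'
#' @param model_traj Named list of trajectory data frames from
#'   [simulate_batch()], one per experiment id.
#' @param data_table Data frame with columns `experiment_id`, `time`
#'   (seconds), `species`, `value` (mol/l).
#' @param species Species entering the score; defaults to sulfate, sulfide,
#'   nitrate and nitrite (lactate excluded because fermentation is not
#'   modelled).
#' @param weighting `"range"` or `"none"`.
#' @return List with `sse` (total), `per_species_sse` and `n_obs`.
#' @export
sse_score <- function(model_traj, data_table,
                      species = c("sulfate", "sulfide", "nitrate", "nitrite"),
                      weighting = c("range", "none")) {
  weighting <- match.arg(weighting)
  need <- c("experiment_id", "time", "species", "value")
  if (!all(need %in% names(data_table))) {
    stop("data_table must have columns: ", paste(need, collapse = ", "))
  }
  dat <- data_table[data_table$species %in% species, , drop = FALSE]
  if (nrow(dat) == 0) stop("no observations for the scored species")
  wts <- stats::setNames(rep(1, length(species)), species)
  if (weighting == "range") {
    for (s in species) {
      v <- dat$value[dat$species == s]
      rng <- if (length(v)) diff(range(v)) else 0
      wts[s] <- if (rng > 0) 1 / rng else 1
    }
  }
  per <- stats::setNames(numeric(length(species)), species)
  n_obs <- 0L
  for (eid in unique(dat$experiment_id)) {
    traj <- model_traj[[as.character(eid)]]
    if (is.null(traj)) stop("no model trajectory for experiment '", eid, "'")
    d <- dat[dat$experiment_id == eid, , drop = FALSE]
    for (s in unique(d$species)) {
      ds <- d[d$species == s, , drop = FALSE]
      if (any(ds$time < min(traj$time) - 1e-9) ||
          any(ds$time > max(traj$time) + 1e-9)) {
        stop("observation times outside the simulated range")
      }
      pred <- stats::approx(traj$time, traj[[s]], xout = ds$time,
                            rule = 2)$y
      per[s] <- per[s] + sum(((pred - ds$value) * wts[s])^2)
      n_obs <- n_obs + nrow(ds)
    }
  }
  list(sse = sum(per), per_species_sse = per, n_obs = n_obs)
}

#' Relative SSE of a set of models
#'
#' `RSSE_i = ((SSE_i - min SSE) / min SSE) * 100`, the percent excess of
#' each model's SSE over the best model's.
#'
#' @param sse Numeric vector of SSE values.
#' @return Numeric vector of RSSE values in percent (0 for the best model).
#' @export
rsse <- function(sse) {
  if (length(sse) == 0) stop("empty SSE vector")
  (sse - min(sse)) / min(sse) * 100
}
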