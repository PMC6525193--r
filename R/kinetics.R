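#' Kinetic parameters of a community
#'
#' Parameters of the dual-Monod growth law with optional nitrite product
#' inhibition and endogenous decay (see [monod_rate()]).
#'
#' @param mu_max Maximum specific growth rate, 1/s.
#' @param K_d Electron-donor half-saturation constant, mol/l.
#' @param K_a Electron-acceptor half-saturation constant, mol/l.
#' @param I Inhibition coefficient, mol/l; only used by communities whose
#'   rate carries the nitrite inhibition factor (SRB). `Inf` disables it.
#' @param b Endogenous decay coefficient, 1/s.
#' @param X0 Initial biomass of the community, mg/l.
#' @return Object of class `kinetic_params` (a named list).
#' @export
kinetic_params <- function(mu_max, K_d, K_a, I = Inf, b = 0, X0 = 0) {
  vals <- c(mu_max = mu_max, K_d = K_d, K_a = K_a, b = b, X0 = X0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic parameters must be finite and non-negative")
  }
  if (!(is.numeric(I) && length(I) == 1 && I > 0)) {
    stop("I must be a positive number (Inf to disable inhibition)")
  }
  structure(list(mu_max = mu_max, K_d = K_d, K_a = K_a, I = I, b = b,
                 X0 = X0),
            class = "kinetic_params")
}

#' Monod growth rate with product inhibition
#'
#' Growth rate of one community:
#' \deqn{r = \mu_{max} X \frac{C_d}{C_d + K_d}\frac{C_a}{C_a + K_a}
#'           \frac{I}{C_{inh} + I} - b X}
#' The inhibition factor is present only when `p$I` is finite (it equals 1
#' as `I` tends to infinity); in this package only the SRB community
#' carries it, with nitrite as the inhibitor.
#'
#' @param p A [kinetic_params()] object.
#' @param X Biomass concentration, mol/l (vectorized).
#' @param C_d,C_a Donor and acceptor concentrations, mol/l (vectorized).
#' @param C_inhibitor Inhibitor (nitrite) concentration, mol/l.
#' @return Net biomass rate, mol biomass/l/s.
#' @export
monod_rate <- function(p, X, C_d, C_a, C_inhibitor = 0) {
  if (any(c(X, C_d, C_a, C_inhibitor) < 0)) {
    stop("monod_rate inputs must be non-negative")
  }
  mu_growth_rate(p, X, C_d, C_a, C_inhibitor) - p$b * X
}

# growth-only part of the rate law (no decay); used for substrate turnover
mu_growth_rate <- function(p, X, C_d, C_a, C_inhibitor = 0) {
  inh <- if (is.finite(p$I)) p$I / (C_inhibitor + p$I) else 1
  p$mu_max * X * C_d / (C_d + p$K_d) * C_a / (C_a + p$K_a) * inh
}

#' Default fixture kinetics
#'
#' A self-consistent parameter set for the eleven communities, scaled so
#' that with the batch design (1000 mg/l sulfate, 2500 mg/l lactate,
#' nitrate up to 1000 mg/l, 8000 mg/l inoculum) substrate turnover happens
#' on the experiments' 4.5-12 h horizon. These are fixture/ground-truth
#' values for synthetic data, not literature measurements.
#'
#' @param communities Character vector of community names to include.
#' @return Named list of [kinetic_params()].
#' @export
default_kinetics <- function(communities = names(default_fe())) {
  base <- list(
    SRB    = kinetic_params(2.0e-6, 5e-4, 2e-4, I = 1e-4, b = 0, X0 = 2000),
    NRB1   = kinetic_params(1.5e-6, 5e-4, 2e-4, b = 0, X0 = 1000),
    NRB2   = kinetic_params(2.0e-6, 5e-4, 2e-4, b = 0, X0 = 1000),
    NRB3   = kinetic_params(2.0e-6, 5e-4, 2e-4, b = 0, X0 = 1000),
    NRSOB1 = kinetic_params(2.0e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB2 = kinetic_params(2.5e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB3 = kinetic_params(2.5e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB4 = kinetic_params(2.0e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB5 = kinetic_params(2.5e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB6 = kinetic_params(2.0e-6, 2e-4, 2e-4, b = 0, X0 = 500),
    NRSOB7 = kinetic_params(2.5e-6, 2e-4, 2e-4, b = 0, X0 = 500)
  )
  missing <- setdiff(communities, names(base))
  if (length(missing)) stop("no default kinetics for: ",
                            paste(missing, collapse = ", "))
  base[communities]
}
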