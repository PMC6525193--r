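#' Construct an electron-equivalent half-reaction
#'
#' A half-reaction is written per one electron equivalent, with signed
#' stoichiometric coefficients (products positive, reactants negative) and the
#' electron carried explicitly as the pseudo-species `electron` (+1 for donor
#' oxidations, -1 for acceptor/synthesis reductions). Element and charge
#' balance are checked at construction.
#'
#' @param id Short name, e.g. `"don_lactate"`.
#' @param role One of `"donor"`, `"acceptor"`, `"synthesis"`.
#' @param stoich Named numeric vector, species -> signed coefficient per
#'   electron equivalent.
#' @param e_eq_per_mole Electron equivalents per mole of the reference
#'   species (positive).
#' @param reference_species Name of the species the electron count refers to.
#' @return An object of class `half_reaction`.
#' @export
half_reaction <- function(id, role = c("donor", "acceptor", "synthesis"),
                          stoich, e_eq_per_mole, reference_species) {
  role <- match.arg(role)
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  if (!is.numeric(e_eq_per_mole) || length(e_eq_per_mole) != 1 ||
      e_eq_per_mole <= 0) {
    stop("e_eq_per_mole must be a single positive number")
  }
  if (!reference_species %in% names(stoich)) {
    stop("reference_species '", reference_species, "' absent from stoich")
  }
  hr <- structure(
    list(id = id, role = role, stoich = stoich,
         e_eq_per_mole = e_eq_per_mole,
         reference_species = reference_species),
    class = "half_reaction"
  )
  res <- check_balance(hr)
  bad <- res[abs(res) >= 1e-8]
  if (length(bad)) {
    stop("half-reaction '", id, "' is unbalanced: ",
         paste(names(bad), signif(bad, 3), sep = "=", collapse = ", "))
  }
  hr
}

#' @export
print.half_reaction <- function(x, ...) {
  cat(sprintf("<half_reaction> %s (%s, %g e-eq/mol %s)\n",
              x$id, x$role, x$e_eq_per_mole, x$reference_species))
  print(x$stoich)
  invisible(x)
}

#' Built-in half-reaction inventory
#'
#' The electron-equivalent half-reactions used to assemble the community
#' reactions: lactate full oxidation to CO2 (12 e-eq/mol), sulfate reduction
#' to sulfide (8), nitrate reduction to nitrite (2), nitrite reduction to
#' ammonium (6) or to dinitrogen (3), sulfide oxidation to sulfate (8) or to
#' elemental sulfur (2), elemental sulfur oxidation to sulfate (6), and cell
#' synthesis to C5H7O2N with ammonium as the nitrogen source (20 e-eq/mol
#' biomass).
#'
#' @return Named list of [half_reaction()] objects.
#' @export
half_reaction_set <- function() {
  list(
    # C3H5O3- + 3 H2O -> 3 CO2 + 11 H+ + 12 e-
    don_lactate = half_reaction(
      "don_lactate", "donor",
      c(lactate = -1 / 12, water = -3 / 12, co2 = 3 / 12,
        proton = 11 / 12, electron = 1),
      12, "lactate"),
    # H2S + 4 H2O -> SO4^2- + 10 H+ + 8 e-
    don_sulfide_sulfate = half_reaction(
      "don_sulfide_sulfate", "donor",
      c(sulfide = -1 / 8, water = -4 / 8, sulfate = 1 / 8,
        proton = 10 / 8, electron = 1),
      8, "sulfide"),
    # H2S -> S0 + 2 H+ + 2 e-
    don_sulfide_s0 = half_reaction(
      "don_sulfide_s0", "donor",
      c(sulfide = -1 / 2, s0 = 1 / 2, proton = 1, electron = 1),
      2, "sulfide"),
    # S0 + 4 H2O -> SO4^2- + 8 H+ + 6 e-
    don_s0_sulfate = half_reaction(
      "don_s0_sulfate", "donor",
      c(s0 = -1 / 6, water = -4 / 6, sulfate = 1 / 6,
        proton = 8 / 6, electron = 1),
      6, "s0"),
    # SO4^2- + 10 H+ + 8 e- -> H2S + 4 H2O
    acc_sulfate_sulfide = half_reaction(
      "acc_sulfate_sulfide", "acceptor",
      c(sulfate = -1 / 8, proton = -10 / 8, electron = -1,
        sulfide = 1 / 8, water = 4 / 8),
      8, "sulfate"),
    # NO3- + 2 H+ + 2 e- -> NO2- + H2O
    acc_nitrate_nitrite = half_reaction(
      "acc_nitrate_nitrite", "acceptor",
      c(nitrate = -1 / 2, proton = -1, electron = -1,
        nitrite = 1 / 2, water = 1 / 2),
      2, "nitrate"),
    # NO2- + 8 H+ + 6 e- -> NH4+ + 2 H2O
    acc_nitrite_ammonium = half_reaction(
      "acc_nitrite_ammonium", "acceptor",
      c(nitrite = -1 / 6, proton = -8 / 6, electron = -1,
        ammonium = 1 / 6, water = 2 / 6),
      6, "nitrite"),
    # NO2- + 4 H+ + 3 e- -> 1/2 N2 + 2 H2O
    acc_nitrite_n2 = half_reaction(
      "acc_nitrite_n2", "acceptor",
      c(nitrite = -1 / 3, proton = -4 / 3, electron = -1,
        n2 = 1 / 6, water = 2 / 3),
      3, "nitrite"),
    # 1/4 CO2 + 1/20 NH4+ + 19/20 H+ + e- -> 1/20 C5H7O2N + 2/5 H2O
    syn_biomass = half_reaction(
      "syn_biomass", "synthesis",
      c(co2 = -5 / 20, ammonium = -1 / 20, proton = -19 / 20,
        electron = -1, biomass = 1 / 20, water = 8 / 20),
      20, "biomass")
  )
}

#' Element and charge balance of a reaction
#'
#' Computes the per-element residual `sum(coefficient * atom count)` and the
#' charge residual of a half-reaction or community reaction. A balanced
#' reaction has all residuals below 1e-8 in magnitude.
#'
#' @param rxn A `half_reaction` or `community_reaction`, or a named numeric
#'   stoichiometry vector.
#' @return Named numeric vector with elements `C`, `H`, `O`, `N`, `S` and
#'   `charge`.
#' @export
check_balance <- function(rxn) {
  stoich <- if (is.numeric(rxn)) rxn else rxn$stoich
  tab <- species_table()
  unknown <- setdiff(names(stoich), tab$species)
  if (length(unknown)) {
    stop("species with unknown composition: ", paste(unknown, collapse = ", "))
  }
  m <- as.matrix(tab[names(stoich), c("C", "H", "O", "N", "S", "charge")])
  drop(stoich %*% m)
}

#' @rdname check_balance
#' @param tol Residual magnitude above which the reaction is unbalanced.
#' @return `is_balanced()`: a single logical.
#' @export
is_balanced <- function(rxn, tol = 1e-8) {
  all(abs(check_balance(rxn)) < tol)
}
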