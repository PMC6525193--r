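#' Chemical species used by the reaction networks
#'
#' Returns the table of aqueous species the package knows about, with their
#' elemental composition (C, H, O, N, S), formal charge and molar mass.
#' Sulfide is carried as total dissolved S(-II) on an H2S basis; biomass uses
#' the conventional cell formula C5H7O2N (113.1 g/mol).
#'
#' @return A `data.frame` with one row per species and columns `species`,
#'   `C`, `H`, `O`, `N`, `S`, `charge`, `molar_mass` (g/mol).
#' @examples
#' species_table()
#' @export
species_table <- function() {
  tab <- data.frame(
    species    = c("lactate", "sulfate", "sulfide", "s0", "nitrate", "nitrite",
                   "ammonium", "n2", "biomass", "co2", "water", "proton",
                   "electron"),
    C          = c(3, 0, 0, 0, 0, 0, 0, 0, 5, 1, 0, 0, 0),
    H          = c(5, 0, 2, 0, 0, 0, 4, 0, 7, 0, 2, 1, 0),
    O          = c(3, 4, 0, 0, 3, 2, 0, 0, 2, 2, 1, 0, 0),
    N          = c(0, 0, 0, 0, 1, 1, 1, 2, 1, 0, 0, 0, 0),
    S          = c(0, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    charge     = c(-1, -2, 0, 0, -1, -1, 1, 0, 0, 0, 0, 1, -1),
    molar_mass = c(89.07, 96.06, 34.08, 32.06, 62.00, 46.01,
                   18.04, 28.01, 113.10, 44.01, 18.02, 1.008, 0),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$species
  tab
}

# Species whose concentrations are integrated by the ODE models. CO2, water
# and protons are balanced stoichiometrically but treated as buffered.
tracked_species <- function() {
  c("lactate", "sulfate", "sulfide", "s0", "nitrate", "nitrite",
    "ammonium", "n2")
}

#' Molar mass lookup
#'
#' @param species Character vector of species names (see [species_table()]).
#' @return Numeric vector of molar masses in g/mol.
#' @export
molar_mass <- function(species) {
  tab <- species_table()
  unknown <- setdiff(species, tab$species)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  tab[species, "molar_mass"]
}

#' Concentration unit conversions
#'
#' Convert between the external units used in the field's data tables (mg/l
#' or mM) and the internal unit of mol/l. Conversions are exact inverses of
#' each other.
#'
#' @param value Numeric vector of concentrations.
#' @param species Species name(s), recycled against `value`.
#' @param unit `"mg/l"` or `"mM"`.
#' @return Numeric vector in the requested unit (or mol/l for `to_molar`).
#' @examples
#' to_molar(96.06, "sulfate", "mg/l")   # 1 mM
#' from_molar(1e-3, "sulfate", "mg/l")
#' @export
to_molar <- function(value, species, unit = c("mg/l", "mM")) {
  unit <- match.arg(unit)
  mm <- molar_mass(species)   # validates the species name
  switch(unit,
    "mg/l" = value / 1000 / mm,
    "mM"   = value / 1000
  )
}

#' @rdname to_molar
#' @export
from_molar <- function(value, species, unit = c("mg/l", "mM")) {
  unit <- match.arg(unit)
  mm <- molar_mass(species)
  switch(unit,
    "mg/l" = value * 1000 * mm,
    "mM"   = value * 1000
  )
}
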