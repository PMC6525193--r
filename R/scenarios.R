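#' Community groups A-F
#'
#' Each group pairs a nitrate-step reaction (nitrate -> nitrite) with a
#' nitrite-step reaction sharing the same electron donor. Groups A-D follow
#' the DNRA pathway (nitrite -> ammonium), E and F denitrification (nitrite
#' -> N2). A and E are heterotrophic (NRB, lactate donor); B, C, D and F are
#' autotrophic (NRSOB): B/F oxidize sulfide to sulfate, C oxidizes sulfide
#' to elemental sulfur, D oxidizes elemental sulfur to sulfate.
#'
#' @return A `data.frame` with columns `label`, `nitrate_step`,
#'   `nitrite_step`, `trophic_mode`, `pathway`, `sulfur_role`.
#' @export
group_table <- function() {
  data.frame(
    label        = c("A", "B", "C", "D", "E", "F"),
    nitrate_step = c("NRB1", "NRSOB1", "NRSOB4", "NRSOB6", "NRB1", "NRSOB1"),
    nitrite_step = c("NRB2", "NRSOB2", "NRSOB5", "NRSOB7", "NRB3", "NRSOB3"),
    trophic_mode = c("heterotrophic", "autotrophic", "autotrophic",
                     "autotrophic", "heterotrophic", "autotrophic"),
    pathway      = c("DNRA", "DNRA", "DNRA", "DNRA",
                     "denitrification", "denitrification"),
    sulfur_role  = c("none", "sulfide->sulfate", "sulfide->S0",
                     "S0->sulfate", "none", "sulfide->sulfate"),
    stringsAsFactors = FALSE
  )
}

#' Is a set of groups an admissible scenario?
#'
#' A scenario is admissible iff it is non-empty, all its groups belong to
#' the same pathway family (DNRA: A-D; denitrification: E-F), and group D
#' (elemental-sulfur oxidation) is only present together with group C, the
#' pair that produces the elemental sulfur.
#'
#' @param groups Character vector of group labels.
#' @return Single logical.
#' @export
scenario_admissible <- function(groups) {
  if (length(groups) == 0) return(FALSE)
  gt <- group_table()
  if (!all(groups %in% gt$label)) return(FALSE)
  pathways <- unique(gt$pathway[match(groups, gt$label)])
  if (length(pathways) != 1) return(FALSE)
  if ("D" %in% groups && !"C" %in% groups) return(FALSE)
  TRUE
}

#' Create a scenario object
#'
#' @param groups Character vector of group labels (subset of A-F). The SRB
#'   community is always part of every scenario.
#' @return Object of class `scenario` with fields `groups`, `label`,
#'   `includes_srb` (always `TRUE`), `admissible`, `communities` and
#'   `fit_result` (initially `NULL`).
#' @export
scenario <- function(groups) {
  groups <- sort(unique(as.character(groups)))
  gt <- group_table()
  comms <- unique(c("SRB", as.vector(t(
    gt[match(groups, gt$label), c("nitrate_step", "nitrite_step")]))))
  structure(
    list(groups = groups,
         label = paste(groups, collapse = ""),
         includes_srb = TRUE,
         admissible = scenario_admissible(groups),
         communities = comms[!is.na(comms)],
         fit_result = NULL),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> {%s}%s: communities %s\n",
              paste(x$groups, collapse = ","),
              if (x$admissible) "" else " (inadmissible)",
              paste(x$communities, collapse = ", ")))
  invisible(x)
}

#' Enumerate all admissible scenarios
#'
#' Returns every non-empty subset of the DNRA groups `{A, B, C, D}` that
#' does not contain D without C (11 scenarios), followed by every non-empty
#' subset of the denitrification groups `{E, F}` (3 scenarios), in canonical
#' lexicographic order of the label set within each family. The enumeration
#' is deterministic.
#'
#' @param restrict Optional character vector limiting the group universe,
#'   e.g. `c("E", "F")`.
#' @return List of [scenario()] objects (14 by default).
#' @examples
#' length(enumerate_scenarios())          # 14
#' length(enumerate_scenarios(c("E","F"))) # 3
#' @export
enumerate_scenarios <- function(restrict = NULL) {
  subsets_of <- function(labels) {
    n <- length(labels)
    out <- list()
    for (mask in seq_len(2^n - 1)) {
      out[[length(out) + 1]] <- labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    }
    out
  }
  families <- list(dnra = c("A", "B", "C", "D"),
                   denit = c("E", "F"))
  if (!is.null(restrict)) {
    families <- lapply(families, intersect, restrict)
  }
  cand <- unlist(lapply(families, subsets_of), recursive = FALSE,
                 use.names = FALSE)
  cand <- Filter(scenario_admissible, cand)
  labels <- vapply(cand, function(g) paste(sort(g), collapse = ""), "")
  fam <- vapply(cand, function(g) any(g %in% c("E", "F")), NA)
  ord <- order(fam, labels)
  lapply(cand[ord], scenario)
}

#' Assemble the reaction network of a scenario
#'
#' Collects the SRB reaction plus the reactions of the scenario's groups
#' into a network object used by the batch and column simulators: a
#' stoichiometry matrix over the tracked species, per-community donor and
#' acceptor species, and the flag marking which communities are subject to
#' nitrite product inhibition (SRB only).
#'
#' @param scen A [scenario()], a character vector of group labels, or a
#'   character vector of community names (e.g. `"SRB"` alone).
#' @param fe Named fe overrides passed to [community_set()].
#' @return Object of class `reaction_network` with fields `communities`,
#'   `reactions`, `species`, `stoich` (tracked species x communities),
#'   `donor`, `acceptor`, `inhibited`.
#' @export
reaction_network <- function(scen, fe = default_fe()) {
  all_rxns <- community_set(fe)
  comms <- if (inherits(scen, "scenario")) {
    if (!scen$admissible) stop("scenario {",
      paste(scen$groups, collapse = ","), "} is not admissible")
    scen$communities
  } else if (all(scen %in% group_table()$label)) {
    scenario(scen)$communities
  } else if (all(scen %in% names(all_rxns))) {
    unique(scen)
  } else {
    stop("scen must be a scenario, group labels, or community names")
  }
  rxns <- all_rxns[comms]
  sp <- tracked_species()
  structure(
    list(communities = comms,
         reactions = rxns,
         species = sp,
         stoich = stoich_matrix(rxns, sp),
         donor = vapply(rxns, `[[`, "", "donor_species"),
         acceptor = vapply(rxns, `[[`, "", "acceptor_species"),
         inhibited = stats::setNames(comms == "SRB", comms)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d communities: %s\n",
              length(x$communities), paste(x$communities, collapse = ", ")))
  invisible(x)
}
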