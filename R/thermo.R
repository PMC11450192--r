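# Standard-transformed Gibbs energy bookkeeping (biochemical convention:
# pH 7, 298 K, 1 atm, unit concentrations; values in kJ/mol). Annotated
# values are read from the model; absence is a distinct state ("undefined"),
# never zero.

.R_GAS <- 8.314e-3 # kJ/(mol K)

# metabolites treated at activity 1 in reaction quotients
.UNIT_ACTIVITY <- function(model) {
  model$mets$id[tolower(model$mets$name) %in% c("water", "h2o", "proton", "h+", "h") |
                  model$mets$formula %in% c("H2O", "H")]
}

#' Reaction dG0' from metabolite formation energies
#'
#' Sums coefficient-weighted metabolite standard-transformed formation
#' energies. Protons and water are excluded (their activity is fixed at 1 in
#' the biochemical convention). Returns `NA` ("undefined") when any required
#' metabolite lacks an annotation.
#'
#' @param model A `gem`.
#' @param rxn_id Reaction id.
#' @return dG0' in kJ/mol, or `NA_real_`.
#' @export
reaction_deltaG_from_metabolites <- function(model, rxn_id) {
  stopifnot_ids(rxn_id, model$rxns$id, "reaction")
  st <- model$stoich[[rxn_id]]
  skip <- .UNIT_ACTIVITY(model)
  st <- st[!names(st) %in% skip]
  if (!length(st)) return(0)
  dg <- model$mets[names(st), "deltaG0"]
  if (any(is.na(dg))) return(NA_real_)
  sum(st * dg)
}

#' Total pathway dG0'
#'
#' Signed sum of per-reaction dG0' along a pathway: each entry's sign gives
#' the direction the pathway traverses that reaction (+1 forward, -1 reverse).
#'
#' @param model A `gem`.
#' @param rxn_ids Character vector of reaction ids.
#' @param directions Numeric vector of +1/-1, recycled; default all forward.
#' @return Pathway dG0' in kJ/mol (0 for an empty list).
#' @export
pathway_deltaG <- function(model, rxn_ids, directions = 1) {
  if (!length(rxn_ids)) return(0)
  stopifnot_ids(rxn_ids, model$rxns$id, "reaction")
  directions <- rep_len(directions, length(rxn_ids))
  dg <- model$rxns[rxn_ids, "deltaG0"]
  if (any(is.na(dg))) {
    stop("missing dG0' for reactions: ",
         paste(rxn_ids[is.na(dg)], collapse = ", "), call. = FALSE)
  }
  sum(directions * dg)
}

#' In vivo Gibbs energy change
#'
#' \eqn{\Delta G = \Delta G^{\circ\prime} + RT \ln Q} with
#' \eqn{R = 8.314\times10^{-3}} kJ/(mol K) and
#' \eqn{Q = \prod [\mathrm{products}]^{c} / \prod [\mathrm{substrates}]^{|c|}}.
#' Water and protons take activity 1 regardless of the supplied
#' concentrations (biochemical-standard convention).
#'
#' @param deltaG0 Standard-transformed dG0' in kJ/mol.
#' @param stoichiometry Named numeric vector, metabolite -> signed coefficient.
#' @param concentrations Named numeric vector, metabolite -> mol/L; must cover
#'   every participant other than water/protons.
#' @param temperature Kelvin, default 298.
#' @param unit_activity Character vector of metabolite ids held at activity 1
#'   (typically water and protons).
#' @return dG in kJ/mol.
#' @export
in_vivo_deltaG <- function(deltaG0, stoichiometry, concentrations,
                           temperature = 298, unit_activity = character(0)) {
  st <- stoichiometry[!names(stoichiometry) %in% unit_activity]
  if (!length(st)) return(deltaG0)
  conc <- concentrations[names(st)]
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("all participating concentrations must be positive", call. = FALSE)
  }
  deltaG0 + .R_GAS * temperature * sum(st * log(conc))
}
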