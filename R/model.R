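# The `gem` class: an in-memory genome-scale metabolic model.
#
# Components:
#   id            model id string
#   compartments  named character, compartment id -> display name
#   mets          data.frame: id, name, compartment, formula, charge, deltaG0
#                 (deltaG0 in kJ/mol; NA means "not annotated", never zero)
#   rxns          data.frame: id, name, lb, ub, subsystem, deltaG0, pseudo, gpr
#   stoich        named list: reaction id -> named numeric (metabolite -> coeff,
#                 negative = substrate)
#   gprs          named list: reaction id -> parsed GPR tree or NULL
#   genes         character vector of gene ids
#   objective     reaction id of the objective (typically growth)
#   extra         opaque per-entity key-value data preserved on YAML round-trip

#' Construct a genome-scale metabolic model
#'
#' @param id Model id string.
#' @param compartments Named character vector (id -> name).
#' @param mets data.frame with columns id, name, compartment, formula, charge,
#'   deltaG0 (kJ/mol, `NA` = unannotated).
#' @param rxns data.frame with columns id, name, lb, ub, subsystem, deltaG0,
#'   pseudo (logical), gpr (rule string).
#' @param stoich Named list mapping each reaction id to a named numeric vector
#'   of metabolite coefficients (negative = consumed).
#' @param objective Reaction id to optimise.
#' @param genes Optional character vector of gene ids; defaults to the union of
#'   GPR leaves.
#' @param extra Optional opaque annotation list, preserved on round-trip.
#' @param validate Check model invariants (default TRUE).
#' @return An object of class `gem`.
#' @export
gem <- function(id, compartments, mets, rxns, stoich, objective,
                genes = NULL, extra = list(), validate = TRUE) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  for (col in c("name", "subsystem")) {
    if (is.null(rxns[[col]])) rxns[[col]] <- ""
    if (is.null(mets[[col]]) && col == "name") mets[[col]] <- ""
  }
  if (is.null(mets$deltaG0)) mets$deltaG0 <- NA_real_
  if (is.null(rxns$deltaG0)) rxns$deltaG0 <- NA_real_
  if (is.null(rxns$pseudo)) rxns$pseudo <- FALSE
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  rownames(mets) <- mets$id
  rownames(rxns) <- rxns$id
  gprs <- lapply(stats::setNames(rxns$gpr, rxns$id), parse_gpr)
  if (is.null(genes)) genes <- sort(unique(unlist(lapply(gprs, gpr_genes))))
  stoich <- stoich[rxns$id]
  m <- structure(list(
    id = id, compartments = compartments, mets = mets, rxns = rxns,
    stoich = stoich, gprs = gprs, genes = genes, objective = objective,
    extra = extra
  ), class = "gem")
  if (validate) validate_gem(m)
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry referencing declared metabolites,
#' compartment membership, bound ordering, objective resolution, exchange
#' shape (exactly one metabolite) and that GPR leaves reference declared genes.
#'
#' @param model A `gem`.
#' @return Invisibly TRUE; stops with a message listing offending ids otherwise.
#' @export
validate_gem <- function(model) {
  probs <- character(0)
  if (anyDuplicated(model$mets$id)) probs <- c(probs, "duplicate metabolite ids")
  if (anyDuplicated(model$rxns$id)) probs <- c(probs, "duplicate reaction ids")
  bad_comp <- setdiff(model$mets$compartment, names(model$compartments))
  if (length(bad_comp)) {
    probs <- c(probs, paste("undeclared compartments:", paste(bad_comp, collapse = ", ")))
  }
  for (rid in model$rxns$id) {
    st <- model$stoich[[rid]]
    if (is.null(st) || !length(st)) {
      probs <- c(probs, paste("empty stoichiometry:", rid))
      next
    }
    miss <- setdiff(names(st), model$mets$id)
    if (length(miss)) {
      probs <- c(probs, paste0(rid, ": unknown metabolites ", paste(miss, collapse = ", ")))
    }
  }
  bad_b <- model$rxns$id[model$rxns$lb > model$rxns$ub]
  if (length(bad_b)) probs <- c(probs, paste("lb > ub:", paste(bad_b, collapse = ", ")))
  if (!model$objective %in% model$rxns$id) {
    probs <- c(probs, paste("objective not a reaction:", model$objective))
  }
  gpr_g <- unique(unlist(lapply(model$gprs, gpr_genes)))
  miss_g <- setdiff(gpr_g, model$genes)
  if (length(miss_g)) {
    probs <- c(probs, paste("GPR genes missing from gene list:", paste(miss_g, collapse = ", ")))
  }
  if (length(probs)) {
    stop("invalid model:\n  ", paste(probs, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$genes)))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' @export
summary.gem <- function(object, ...) {
  s <- model_stats(object)
  print(object)
  cat(sprintf("  dG0' coverage: %.1f%% metabolites, %.1f%% reactions\n",
              s$pct_mets_with_dG, s$pct_rxns_with_dG))
  cat(sprintf("  exchanges: %d, pseudo reactions: %d\n",
              length(find_exchanges(object)), sum(object$rxns$pseudo)))
  invisible(s)
}

#' Exchange reactions of a model
#'
#' An exchange is a boundary pseudo-reaction touching exactly one metabolite
#' (negative flux = uptake by convention).
#'
#' @param model A `gem`.
#' @return Character vector of reaction ids.
#' @export
find_exchanges <- function(model) {
  n_mets <- vapply(model$stoich, length, 0L)
  model$rxns$id[n_mets == 1L]
}

#' Stoichiometric matrix
#' @param model A `gem`.
#' @return Dense numeric matrix S (metabolites x reactions).
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$id, model$rxns$id))
  for (rid in model$rxns$id) {
    st <- model$stoich[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Model summary statistics
#'
#' Entity counts, standard-transformed Gibbs energy annotation coverage and a
#' subsystem histogram.
#'
#' @param model A `gem`.
#' @return List with `n_genes`, `n_mets`, `n_rxns`, `pct_mets_with_dG`,
#'   `pct_rxns_with_dG` (percentages in 0-100) and `subsystems` (named table).
#' @export
model_stats <- function(model) {
  list(
    n_genes = length(model$genes),
    n_mets = nrow(model$mets),
    n_rxns = nrow(model$rxns),
    pct_mets_with_dG = 100 * mean(!is.na(model$mets$deltaG0)),
    pct_rxns_with_dG = 100 * mean(!is.na(model$rxns$deltaG0)),
    subsystems = table(model$rxns$subsystem[nzchar(model$rxns$subsystem)])
  )
}

#' Audit mass and charge balance
#'
#' For every non-pseudo reaction, sums coefficient-weighted element counts and
#' charges across participants. A reaction is balanced iff every element
#' imbalance and the charge imbalance are exactly zero. Reactions involving a
#' metabolite without a formula, or with a generic R/X residue, are
#' unauditable and counted as unbalanced in the summary percentage. Pseudo
#' reactions (exchange, biomass, maintenance, sink, lumped) are excluded from
#' the denominator: they are unbalanced by construction.
#'
#' @param model A `gem`.
#' @return List of class `balance_report`: `per_reaction` data.frame (id,
#'   balanced, auditable, charge_imbalance, element_imbalance as list-column),
#'   and `pct_balanced` over audited (non-pseudo) reactions.
#' @export
check_balance <- function(model) {
  met_counts <- lapply(stats::setNames(model$mets$formula, model$mets$id), parse_formula)
  met_generic <- vapply(model$mets$formula, formula_is_generic, NA)
  names(met_generic) <- model$mets$id
  met_has_formula <- vapply(met_counts, length, 0L) > 0L
  charge <- stats::setNames(model$mets$charge, model$mets$id)

  audited <- model$rxns$id[!model$rxns$pseudo]
  rows <- lapply(model$rxns$id, function(rid) {
    st <- model$stoich[[rid]]
    mets <- names(st)
    if (any(!met_has_formula[mets]) || any(met_generic[mets])) {
      return(list(id = rid, auditable = FALSE, balanced = FALSE,
                  charge_imbalance = NA_real_, element_imbalance = list()))
    }
    acc <- list()
    for (i in seq_along(st)) {
      cts <- met_counts[[mets[i]]] * st[i]
      for (el in names(cts)) acc[[el]] <- (acc[[el]] %||% 0) + cts[[el]]
    }
    imb <- unlist(acc)
    imb <- imb[abs(imb) > 1e-9]
    ch <- sum(st * charge[mets])
    balanced <- length(imb) == 0L && abs(ch) <= 1e-9
    list(id = rid, auditable = TRUE, balanced = balanced,
         charge_imbalance = ch, element_imbalance = as.list(imb))
  })
  per <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    auditable = vapply(rows, `[[`, NA, "auditable"),
    balanced = vapply(rows, `[[`, NA, "balanced"),
    charge_imbalance = vapply(rows, `[[`, 0, "charge_imbalance"),
    pseudo = model$rxns$pseudo,
    stringsAsFactors = FALSE
  )
  per$element_imbalance <- lapply(rows, `[[`, "element_imbalance")
  rownames(per) <- per$id
  pct <- 100 * mean(per$balanced[per$id %in% audited])
  structure(list(per_reaction = per, pct_balanced = pct), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  aud <- x$per_reaction[!x$per_reaction$pseudo, ]
  cat(sprintf("<balance_report> %.1f%% of %d audited reactions balanced (%d unauditable)\n",
              x$pct_balanced, nrow(aud), sum(!aud$auditable)))
  invisible(x)
}
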