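# yeast-GEM YAML dialect reader/writer.
#
# The file is a YAML list of single-key sections: metaData, metabolites,
# reactions, genes, compartments. Metabolites carry `metDeltaG`, reactions
# `rxnDeltaG` (kJ/mol); a missing key means "not annotated". Unknown keys are
# preserved opaquely and written back on round-trip.

.MET_KEYS <- c("id", "name", "compartment", "formula", "charge", "metDeltaG")
.RXN_KEYS <- c("id", "name", "metabolites", "lower_bound", "upper_bound",
               "gene_reaction_rule", "subsystem", "rxnDeltaG",
               "objective_coefficient", "pseudo")

read_gem_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  sec <- list()
  for (entry in doc) sec[names(entry)] <- entry
  if (is.null(sec$metabolites) || is.null(sec$reactions)) {
    stop("format error: YAML model lacks a 'metabolites' or 'reactions' section",
         call. = FALSE)
  }
  comp <- unlist(sec$compartments %||% list())
  meta <- sec$metaData %||% list()

  extra <- list(metaData = meta[setdiff(names(meta), c("id", "name"))],
                mets = list(), rxns = list())

  mets <- do.call(rbind, lapply(sec$metabolites, function(m) {
    if (is.null(m$id)) stop("format error: metabolite entry without id", call. = FALSE)
    data.frame(id = m$id, name = m$name %||% "", compartment = m$compartment %||% "",
               formula = m$formula %||% "", charge = as.numeric(m$charge %||% 0),
               deltaG0 = as.numeric(m$metDeltaG %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  for (m in sec$metabolites) {
    left <- m[setdiff(names(m), .MET_KEYS)]
    if (length(left)) extra$mets[[m$id]] <- left
  }

  stoich <- list()
  objective <- NULL
  rxns <- do.call(rbind, lapply(sec$reactions, function(r) {
    if (is.null(r$id)) stop("format error: reaction entry without id", call. = FALSE)
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st)) {
      stop("format error: reaction '", r$id, "' has empty stoichiometry", call. = FALSE)
    }
    stoich[[r$id]] <<- st
    oc <- as.numeric(r$objective_coefficient %||% 0)
    if (!is.na(oc) && oc != 0) objective <<- r$id
    data.frame(id = r$id, name = r$name %||% "",
               lb = as.numeric(r$lower_bound %||% -1000),
               ub = as.numeric(r$upper_bound %||% 1000),
               subsystem = paste(unlist(r$subsystem %||% ""), collapse = "; "),
               deltaG0 = as.numeric(r$rxnDeltaG %||% NA_real_),
               pseudo = isTRUE(r$pseudo) || length(unlist(r$metabolites)) == 1L,
               gpr = r$gene_reaction_rule %||% "",
               stringsAsFactors = FALSE)
  }))
  for (r in sec$reactions) {
    left <- r[setdiff(names(r), .RXN_KEYS)]
    if (length(left)) extra$rxns[[r$id]] <- left
  }

  genes <- vapply(sec$genes %||% list(), function(g) g$id %||% g, "")
  if (is.null(objective)) objective <- rxns$id[nrow(rxns)]

  gem(id = meta$id %||% basename(path), compartments = comp,
      mets = mets, rxns = rxns, stoich = stoich, objective = objective,
      genes = if (length(genes)) genes else NULL, extra = extra)
}

write_gem_yaml <- function(model, path) {
  validate_gem(model)
  met_list <- lapply(seq_len(nrow(model$mets)), function(i) {
    m <- model$mets[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                formula = m$formula, charge = as.integer(m$charge))
    if (!is.na(m$deltaG0)) out$metDeltaG <- m$deltaG0
    c(out, model$extra$mets[[m$id]] %||% list())
  })
  rxn_list <- lapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    st <- model$stoich[[r$id]]
    out <- list(id = r$id, name = r$name, metabolites = as.list(st),
                lower_bound = r$lb, upper_bound = r$ub,
                gene_reaction_rule = r$gpr, subsystem = r$subsystem,
                pseudo = r$pseudo)
    if (!is.na(r$deltaG0)) out$rxnDeltaG <- r$deltaG0
    if (identical(r$id, model$objective)) out$objective_coefficient <- 1
    c(out, model$extra$rxns[[r$id]] %||% list())
  })
  doc <- list(
    list(metaData = c(list(id = model$id), model$extra$metaData %||% list())),
    list(metabolites = met_list),
    list(reactions = rxn_list),
    list(genes = lapply(model$genes, function(g) list(id = g))),
    list(compartments = as.list(model$compartments))
  )
  yaml::write_yaml(doc, path, indent.mapping.sequence = TRUE)
  invisible(path)
}
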