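# SBML Level 3 + FBC v2 reader/writer (the constraint-based subset: species
# formula/charge via the fbc namespace, flux bounds as shared parameters,
# gene associations as fbc:geneProductAssociation trees, the active fbc
# objective, and subsystems as groups). dG0' annotations travel in a small
# custom annotation element so SBML round-trips preserve them.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
.GK_NS <- "https://gemkit.invalid/annotation"

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

read_gem_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS, g = .GROUPS_NS, gk = .GK_NS)
  model_node <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("format error: no <model> element in ", path, call. = FALSE)
  }
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  comp_nodes <- xml2::xml_find_all(model_node, ".//s:listOfCompartments/s:compartment", ns)
  comps <- stats::setNames(
    vapply(comp_nodes, function(n) attr1(n, "name") %||% xml2::xml_attr(n, "id"), ""),
    vapply(comp_nodes, xml2::xml_attr, "", attr = "id"))

  dg_of <- function(node) {
    a <- xml2::xml_find_first(node, ".//gk:deltaG0", ns)
    if (inherits(a, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(a))
  }

  sp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("format error: model has no species", call. = FALSE)
  mets <- data.frame(
    id = strip(vapply(sp, xml2::xml_attr, "", attr = "id"), "M_"),
    name = vapply(sp, function(n) attr1(n, "name") %||% "", ""),
    compartment = vapply(sp, xml2::xml_attr, "", attr = "compartment"),
    formula = vapply(sp, function(n) attr1(n, "chemicalFormula") %||% "", ""),
    charge = as.numeric(vapply(sp, function(n) attr1(n, "charge") %||% "0", "")),
    deltaG0 = vapply(sp, dg_of, 0.0),
    stringsAsFactors = FALSE
  )

  params <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    as.numeric(vapply(params, xml2::xml_attr, "", attr = "value")),
    vapply(params, xml2::xml_attr, "", attr = "id"))

  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(list(kind = "gene", gene = strip(xml2::xml_attr(node, "geneProduct"), "G_")))
    }
    kids <- lapply(xml2::xml_children(node), parse_gpa)
    kids <- Filter(Negate(is.null), kids)
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    flatten_node(if (nm == "and") "and" else "or", kids)
  }

  rxn_nodes <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  stoich <- list()
  objective <- NULL
  rows <- lapply(rxn_nodes, function(n) {
    rid <- strip(xml2::xml_attr(n, "id"), "R_")
    subs <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prods <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      stats::setNames(sign * as.numeric(vapply(nodes, function(x)
        attr1(x, "stoichiometry") %||% "1", "")),
        strip(vapply(nodes, xml2::xml_attr, "", attr = "species"), "M_"))
    }
    st <- c(coef(subs, -1), coef(prods, +1))
    st <- tapply(st, names(st), sum)
    stoich[[rid]] <<- stats::setNames(as.numeric(st), names(st))
    gpa <- xml2::xml_find_first(n, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      tree <- parse_gpa(xml2::xml_child(gpa))
      deparse_gpr(tree)
    }
    lb_id <- xml2::xml_attr(n, "lowerFluxBound")
    ub_id <- xml2::xml_attr(n, "upperFluxBound")
    pseudo_attr <- xml2::xml_find_first(n, ".//gk:pseudo", ns)
    data.frame(
      id = rid, name = attr1(n, "name") %||% "",
      lb = if (is.na(lb_id)) -1000 else unname(pval[lb_id]),
      ub = if (is.na(ub_id)) 1000 else unname(pval[ub_id]),
      subsystem = "", deltaG0 = dg_of(n),
      pseudo = !inherits(pseudo_attr, "xml_missing") || length(stoich[[rid]]) == 1L,
      gpr = gpr, stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rows)

  # subsystems from groups
  grp <- xml2::xml_find_all(model_node, ".//g:listOfGroups/g:group", ns)
  for (g in grp) {
    nm <- xml2::xml_attr(g, "name")
    members <- strip(vapply(
      xml2::xml_find_all(g, ".//g:member", ns), xml2::xml_attr, "", attr = "idRef"), "R_")
    rxns$subsystem[rxns$id %in% members] <- nm
  }

  obj_node <- xml2::xml_find_first(
    model_node, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (!inherits(obj_node, "xml_missing")) {
    objective <- strip(xml2::xml_attr(obj_node, "reaction"), "R_")
  }
  if (is.null(objective)) objective <- rxns$id[nrow(rxns)]

  gp <- xml2::xml_find_all(model_node, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- strip(vapply(gp, xml2::xml_attr, "", attr = "id"), "G_")

  gem(id = xml2::xml_attr(model_node, "id") %||% basename(path),
      compartments = comps, mets = mets, rxns = rxns, stoich = stoich,
      objective = objective, genes = if (length(genes)) genes else NULL)
}

write_gem_sbml <- function(model, path) {
  validate_gem(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))

  anno <- function(dg, pseudo = FALSE, indent = "        ") {
    if (is.na(dg) && !pseudo) return(invisible())
    push(indent, "<annotation>")
    if (!is.na(dg)) push(indent, '  <gk:deltaG0 xmlns:gk="', .GK_NS, '">', num(dg), "</gk:deltaG0>")
    if (pseudo) push(indent, '  <gk:pseudo xmlns:gk="', .GK_NS, '"/>')
    push(indent, "</annotation>")
  }

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="', .SBML_NS, '" xmlns:fbc="', .FBC_NS, '" xmlns:groups="',
       .GROUPS_NS, '" level="3" version="1" fbc:required="false" groups:required="false">')
  push('  <model id="', esc(sbml_sanitize(model$id)), '" fbc:strict="true">')

  push("    <listOfCompartments>")
  for (i in seq_along(model$compartments)) {
    push('      <compartment id="', names(model$compartments)[i], '" name="',
         esc(model$compartments[[i]]), '" constant="true"/>')
  }
  push("    </listOfCompartments>")

  push("    <listOfSpecies>")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    open <- paste0('      <species id="M_', sbml_sanitize(m$id), '" name="', esc(m$name),
                   '" compartment="', m$compartment,
                   '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
                   ' fbc:charge="', as.integer(m$charge), '"',
                   if (nzchar(m$formula)) paste0(' fbc:chemicalFormula="', m$formula, '"') else "")
    if (is.na(m$deltaG0)) push(open, "/>")
    else {
      push(open, ">")
      anno(m$deltaG0)
      push("      </species>")
    }
  }
    push("    </listOfSpecies>")

  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- stats::setNames(paste0("b_", seq_along(bounds)), num(bounds))
  push("    <listOfParameters>")
  for (i in seq_along(bounds)) {
    push('      <parameter id="b_', i, '" value="', num(bounds[i]),
         '" constant="true" sboTerm="SBO:0000626"/>')
  }
  push("    </listOfParameters>")

  gpa_xml <- function(node, indent) {
    if (node$kind == "gene") {
      return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="G_',
                    sbml_sanitize(node$gene), '"/>'))
    }
    tag <- if (node$kind == "and") "fbc:and" else "fbc:or"
    c(paste0(indent, "<", tag, ">"),
      unlist(lapply(node$children, gpa_xml, indent = paste0(indent, "  "))),
      paste0(indent, "</", tag, ">"))
  }

  push("    <listOfReactions>")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    st <- model$stoich[[r$id]]
    push('      <reaction id="R_', sbml_sanitize(r$id), '" name="', esc(r$name),
         '" reversible="', tolower(r$lb < 0), '" fast="false"',
         ' fbc:lowerFluxBound="', bid[num(r$lb)], '" fbc:upperFluxBound="', bid[num(r$ub)], '">')
    anno(r$deltaG0, pseudo = r$pseudo)
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      push("        <listOfReactants>")
      for (j in seq_along(subs)) {
        push('          <speciesReference species="M_', sbml_sanitize(names(subs)[j]),
             '" stoichiometry="', num(-subs[j]), '" constant="true"/>')
      }
      push("        </listOfReactants>")
    }
    if (length(prods)) {
      push("        <listOfProducts>")
      for (j in seq_along(prods)) {
        push('          <speciesReference species="M_', sbml_sanitize(names(prods)[j]),
             '" stoichiometry="', num(prods[j]), '" constant="true"/>')
      }
      push("        </listOfProducts>")
    }
    tree <- model$gprs[[r$id]]
    if (!is.null(tree)) {
      push("        <fbc:geneProductAssociation>")
      push(gpa_xml(tree, "          "))
      push("        </fbc:geneProductAssociation>")
    }
    push("      </reaction>")
  }
  push("    </listOfReactions>")

  push("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
  push('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  push("        <fbc:listOfFluxObjectives>")
  push('          <fbc:fluxObjective fbc:reaction="R_', sbml_sanitize(model$objective),
       '" fbc:coefficient="1"/>')
  push("        </fbc:listOfFluxObjectives>")
  push("      </fbc:objective>")
  push("    </fbc:listOfObjectives>")

  push("    <fbc:listOfGeneProducts>")
  for (g in model$genes) {
    push('      <fbc:geneProduct fbc:id="G_', sbml_sanitize(g), '" fbc:label="', esc(g), '"/>')
  }
  push("    </fbc:listOfGeneProducts>")

  subs_tab <- split(model$rxns$id, model$rxns$subsystem)
  subs_tab <- subs_tab[nzchar(names(subs_tab))]
  if (length(subs_tab)) {
    push("    <groups:listOfGroups>")
    for (i in seq_along(subs_tab)) {
      push('      <groups:group groups:id="g', i, '" groups:name="', esc(names(subs_tab)[i]),
           '" groups:kind="partonomy">')
      push("        <groups:listOfMembers>")
      for (rid in subs_tab[[i]]) {
        push('          <groups:member groups:idRef="R_', sbml_sanitize(rid), '"/>')
      }
      push("        </groups:listOfMembers>")
      push("      </groups:group>")
    }
    push("    </groups:listOfGroups>")
  }

  push("  </model>")
  push("</sbml>")
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Read a genome-scale model
#'
#' Reads SBML Level 3 + FBC v2 or the yeast-GEM YAML dialect (with
#' `metDeltaG`/`rxnDeltaG` thermodynamic annotations). Missing dG0' values are
#' recorded as absent (`NA`), never zero; bounds are taken verbatim.
#'
#' @param path Path to a model file.
#' @param format `"sbml"`, `"yaml"`, or `"auto"` (by file extension).
#' @return A [gem()] object.
#' @export
read_model <- function(path, format = c("auto", "sbml", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "yaml"
  }
  switch(format, sbml = read_gem_sbml(path), yaml = read_gem_yaml(path))
}

#' Write a genome-scale model
#'
#' @param model A [gem()] object (validated before writing).
#' @param path Output path.
#' @param format `"sbml"`, `"yaml"`, or `"auto"` (by file extension).
#' @return The path, invisibly. Re-reading yields a field-equal model; absent
#'   dG0' annotations stay absent.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "yaml"
  }
  switch(format, sbml = write_gem_sbml(model, path), yaml = write_gem_yaml(model, path))
}
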