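# Gene-protein-reaction (GPR) rules
#
# A GPR is a boolean expression over gene ids in which AND joins the subunits
# of an enzyme complex and OR joins isoenzymes. gemkit represents a rule as a
# recursive list: a leaf is list(kind = "gene", gene = <id>); internal nodes
# are list(kind = "and"|"or", children = list(...)) with >= 2 children; the
# empty rule (no gene association) is NULL.

#' Parse a GPR rule string
#'
#' Parses boolean gene association strings such as
#' \code{"(YDL022W and YOL059W) or YGR192C"} into a GPR tree. \code{and}/\code{or}
#' are matched case-insensitively; parentheses group as usual; \code{or} binds
#' more loosely than \code{and}.
#'
#' @param rule Character scalar. An empty string or `NA` yields `NULL`
#'   (no gene association).
#' @return A GPR tree (nested list), or `NULL`.
#' @examples
#' gpr <- parse_gpr("(g1 and g2) or g3")
#' gpr_genes(gpr)
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)

  # tokenize: parens, AND/OR keywords, gene ids (anything else non-space)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()\\s]+", rule, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek(); pos <<- pos + 1L; t
  }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_or <- function() {
    children <- list(parse_and())
    while (is_kw(peek(), "or")) {
      advance()
      children <- c(children, list(parse_and()))
    }
    if (length(children) == 1L) children[[1]] else flatten_node("or", children)
  }
  parse_and <- function() {
    children <- list(parse_atom())
    while (is_kw(peek(), "and")) {
      advance()
      children <- c(children, list(parse_atom()))
    }
    if (length(children) == 1L) children[[1]] else flatten_node("and", children)
  }
  parse_atom <- function() {
    t <- advance()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", rule, "'", call. = FALSE)
    if (t == "(") {
      node <- parse_or()
      if (!identical(advance(), ")")) {
        stop("GPR parse error: unbalanced parentheses in '", rule, "'", call. = FALSE)
      }
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR parse error: unexpected token '", t, "' in '", rule, "'", call. = FALSE)
    }
    list(kind = "gene", gene = t)
  }

  tree <- parse_or()
  if (pos <= length(toks)) {
    stop("GPR parse error: trailing tokens near '", toks[pos], "' in '", rule, "'",
         call. = FALSE)
  }
  tree
}

flatten_node <- function(kind, children) {
  # merge nested nodes of the same kind so AND/OR nodes keep >= 2 flat children
  out <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind) out <- c(out, ch$children)
    else out <- c(out, list(ch))
  }
  list(kind = kind, children = out)
}

#' Deparse a GPR tree back to a rule string
#' @param gpr A GPR tree or `NULL`.
#' @return Character scalar (empty string for `NULL`).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent_kind) {
    if (node$kind == "gene") return(node$gene)
    op <- if (node$kind == "and") " and " else " or "
    s <- paste(vapply(node$children, rec, "", node$kind), collapse = op)
    # parenthesize AND under OR context and vice versa for unambiguous output
    if (!is.na(parent_kind) && node$kind != parent_kind) paste0("(", s, ")") else s
  }
  rec(gpr, NA_character_)
}

#' Genes referenced by a GPR tree
#' @param gpr A GPR tree or `NULL`.
#' @return Character vector of unique gene ids.
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' A reaction stays catalytically active when its GPR evaluates TRUE with
#' knocked-out genes set FALSE: an AND node (complex) needs all children,
#' an OR node (isoenzymes) needs any child. The empty rule is always active.
#'
#' @param gpr A GPR tree (see [parse_gpr()]) or `NULL`.
#' @param knocked_out Character vector of deleted gene ids.
#' @return Logical scalar.
#' @examples
#' evaluate_gpr_boolean(parse_gpr("g1 or g2"), "g1")   # TRUE: isozyme survives
#' evaluate_gpr_boolean(parse_gpr("g1 and g2"), "g1")  # FALSE: complex broken
#' @export
evaluate_gpr_boolean <- function(gpr, knocked_out = character(0)) {
  if (is.null(gpr)) return(TRUE)
  switch(gpr$kind,
    gene = !(gpr$gene %in% knocked_out),
    and  = all(vapply(gpr$children, evaluate_gpr_boolean, NA, knocked_out = knocked_out)),
    or   = any(vapply(gpr$children, evaluate_gpr_boolean, NA, knocked_out = knocked_out)),
    stop("invalid GPR node kind: ", gpr$kind, call. = FALSE)
  )
}

#' Map gene-level values to a reaction-level value through a GPR
#'
#' Collapses gene expression (or fold-change) onto a reaction: the minimum
#' over AND children (a complex is limited by its scarcest subunit) and the
#' maximum over OR children (isoenzymes add up to the best-expressed one).
#' Genes absent from `expr` carry no information and are skipped; if every
#' leaf is missing (or the rule is empty) the sentinel `NA` is returned.
#'
#' @param gpr A GPR tree or `NULL`.
#' @param expr Named numeric vector, gene id -> value.
#' @return Numeric scalar, or `NA_real_` when no leaf has a value.
#' @examples
#' reaction_expression(parse_gpr("g1 and g2"), c(g1 = 2, g2 = 5)) # 2
#' reaction_expression(parse_gpr("g1 or g2"),  c(g1 = 2, g2 = 5)) # 5
#' @export
reaction_expression <- function(gpr, expr) {
  if (is.null(gpr)) return(NA_real_)
  rec <- function(node) {
    if (node$kind == "gene") {
      v <- expr[node$gene]
      return(if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else unname(v))
    }
    vals <- vapply(node$children, rec, 0)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$kind == "and") min(vals) else max(vals)
  }
  rec(gpr)
}
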