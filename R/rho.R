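# Protein regulation coefficients (rho) and directional-consistency screens.
#
# rho is the OLS slope of log |flux| on log protein concentration across a
# condition series: rho ~ 1 means flux changes are explained by enzyme-level
# changes, rho ~ 0 means regulation happens elsewhere (allostery, substrate
# levels, post-translational control). Complexes (AND) collapse to the
# per-condition minimum subunit concentration before one slope is fitted;
# isoenzymes (OR) get a slope per protein, averaged arithmetically.

ols_slope <- function(x, y) {
  # closed-form simple-regression slope
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Genes whose protein and flux both move in the favoured direction
#'
#' A gene is selected when its protein abundance is higher in condition A
#' than in the reference condition B and at least one reaction carrying the
#' gene in its GPR has higher flux magnitude in A than in B.
#'
#' @param model A [gem()].
#' @param flux_a,flux_b Named numeric flux vectors (reaction -> flux).
#' @param protein_a,protein_b Named numeric protein abundances (gene -> value).
#' @return Character vector of selected gene ids; genes absent from the
#'   proteomics are skipped.
#' @export
directional_consistency <- function(model, flux_a, flux_b, protein_a, protein_b) {
  genes <- intersect(model$genes, intersect(names(protein_a), names(protein_b)))
  sel <- character(0)
  for (g in genes) {
    if (!(protein_a[g] > protein_b[g])) next
    rxns <- model$rxns$id[vapply(model$gprs, function(tr)
      !is.null(tr) && g %in% gpr_genes(tr), NA)]
    rxns <- intersect(rxns, intersect(names(flux_a), names(flux_b)))
    if (any(abs(flux_a[rxns]) > abs(flux_b[rxns]))) sel <- c(sel, g)
  }
  sel
}

# decompose a GPR into isoenzyme branches; each branch is a character vector
# of subunit genes to be collapsed by per-condition minimum
gpr_branches <- function(tree) {
  if (is.null(tree)) return(list())
  if (tree$kind == "gene") return(list(tree$gene))
  if (tree$kind == "and") return(list(gpr_genes(tree)))
  # OR: each child is a branch (a gene or an AND complex; nested ORs flattened)
  unlist(lapply(tree$children, gpr_branches), recursive = FALSE)
}

#' Protein regulation coefficients per reaction
#'
#' For each GPR-bearing reaction whose flux does not change sign across
#' conditions, fits the OLS slope of log flux magnitude on log protein over
#' the conditions where both are nonzero (the joint filter; `filter =
#' "entitywise"` instead requires each entity alone to pass `min_nonzero` and
#' then drops zero conditions pairwise). Complex branches use the minimum
#' subunit series; with several isoenzyme branches the reaction coefficient
#' is the arithmetic mean of the per-branch slopes.
#'
#' @param model A [gem()].
#' @param flux Reaction x condition numeric matrix (mmol/gDW/h).
#' @param protein Gene x condition numeric matrix (abundance, >= 0).
#' @param min_nonzero Minimum usable conditions per pair (default 5).
#' @param filter `"joint"` or `"entitywise"`.
#' @return data.frame of class `regulation_records`: reaction, rho, n, rule,
#'   genes (semicolon-joined). Reactions with too few usable conditions or
#'   sign-changing flux are omitted.
#' @export
compute_rho <- function(model, flux, protein, min_nonzero = 5,
                        filter = c("joint", "entitywise")) {
  filter <- match.arg(filter)
  stopifnot(ncol(flux) == ncol(protein))
  rows <- list()
  for (rid in intersect(model$rxns$id, rownames(flux))) {
    tree <- model$gprs[[rid]]
    branches <- gpr_branches(tree)
    branches <- Filter(function(b) all(b %in% rownames(protein)), branches)
    if (!length(branches)) next
    f <- flux[rid, ]
    nz <- abs(f) > 1e-12
    if (any(f[nz] > 0) && any(f[nz] < 0)) next  # sign change: log undefined
    fmag <- abs(f)
    slopes <- numeric(0); used_n <- integer(0)
    for (b in branches) {
      p <- if (length(b) == 1L) protein[b, ] else apply(protein[b, , drop = FALSE], 2, min)
      if (filter == "joint") {
        ok <- fmag > 0 & p > 0
        if (sum(ok) < min_nonzero) next
      } else {
        if (sum(fmag > 0) < min_nonzero || sum(p > 0) < min_nonzero) next
        ok <- fmag > 0 & p > 0
        if (sum(ok) < 2L) next
      }
      slopes <- c(slopes, ols_slope(log(p[ok]), log(fmag[ok])))
      used_n <- c(used_n, sum(ok))
    }
    if (!length(slopes)) next
    rule <- if (length(branches) > 1L) "isoenzyme-average"
            else if (length(branches[[1]]) > 1L) "complex-min" else "single"
    rows[[rid]] <- data.frame(
      reaction = rid, rho = mean(slopes), n = min(used_n), rule = rule,
      genes = paste(unique(unlist(branches)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(0), rho = numeric(0), n = integer(0),
               rule = character(0), genes = character(0))
  rownames(out) <- NULL
  class(out) <- c("regulation_records", "data.frame")
  out
}

#' Fraction of reactions with high regulation coefficients
#'
#' @param records Output of [compute_rho()].
#' @param cutoff rho threshold, default 0.5.
#' @return Share of records with `rho > cutoff`.
#' @export
high_rho_fraction <- function(records, cutoff = 0.5) {
  if (!nrow(records)) stop("no regulation records", call. = FALSE)
  mean(records$rho > cutoff)
}
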