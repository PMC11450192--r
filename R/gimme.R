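# GIMME context-specific model extraction.
#
# Given gene expression for one cell or condition, reactions whose mapped
# expression falls below a threshold t are penalised in proportion to their
# shortfall, and the LP
#     min sum_i max(0, t - x_i) * |v_i|   s.t. S v = 0, bounds,
#                                              v_obj >= f * v_obj_max
# finds the flux pattern most consistent with the data that still reaches a
# fraction f of the optimal objective. The kept submodel contains reactions
# expressed at or above t, reactions with no expression evidence, and
# below-threshold reactions that nonetheless carry flux at the optimum.

#' GIMME configuration
#'
#' @param threshold Absolute expression threshold t; if `NULL`, derived per
#'   profile as the `threshold_quantile` quantile of nonzero expression.
#' @param threshold_quantile Quantile in (0,1), default 0.25.
#' @param fraction Required objective fraction f in (0,1], default 0.9.
#' @return A `gimme_config` list.
#' @export
gimme_config <- function(threshold = NULL, threshold_quantile = 0.25, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(threshold = threshold, threshold_quantile = threshold_quantile,
                 fraction = fraction), class = "gimme_config")
}

resolve_threshold <- function(config, expression) {
  if (!is.null(config$threshold)) return(config$threshold)
  nz <- expression[!is.na(expression) & expression > 0]
  if (!length(nz)) return(0)
  unname(stats::quantile(nz, config$threshold_quantile, type = 7))
}

#' Extract a context-specific model with GIMME
#'
#' @param model A [gem()] constrained to its medium.
#' @param expression Named numeric vector, gene -> expression. A zero is a
#'   real value (maximal penalty), not missing; genes absent from the vector
#'   carry no information.
#' @param config A [gimme_config()].
#' @param label Optional cell/condition label.
#' @return Object of class `context_model`: `kept_rxns`, `kept_mets`,
#'   `inconsistency` (optimal penalty sum), `threshold`, `fraction`, `label`,
#'   `fluxes` at the GIMME optimum, and `parent` model id.
#' @export
gimme_extract <- function(model, expression, config = gimme_config(), label = NULL) {
  t <- resolve_threshold(config, expression)
  f <- config$fraction
  base <- fba(model)
  if (base$status != "optimal") stop("parent model infeasible", call. = FALSE)
  opt <- base$objective

  rxn_expr <- vapply(model$rxns$id, function(rid)
    reaction_expression(model$gprs[[rid]], expression), 0.0)
  penalty <- ifelse(is.na(rxn_expr), 0, pmax(0, t - rxn_expr))

  p <- model_lp_parts(model)
  sp <- split_parts(p)
  obj_idx <- match(model$objective, colnames(p$S))
  A <- rbind(sp$S2, 0)
  A[nrow(A), c(obj_idx, sp$n + obj_idx)] <- c(1, -1)
  dir <- c(rep("=", nrow(p$S)), ">=")
  rhs <- c(numeric(nrow(p$S)), f * opt)
  res <- solve_lp(rep(penalty, 2), A = A, dir = dir, rhs = rhs,
                  lb = sp$lb2, ub = sp$ub2, maximize = FALSE)
  if (res$status != "optimal") {
    stop("GIMME infeasible at objective fraction ", f, "; try a smaller fraction",
         call. = FALSE)
  }
  # parsimony refinement: among penalty-optimal flux patterns, take the one
  # with minimal total flux (makes the solution, and hence the kept set,
  # well defined even where penalties leave the optimum degenerate)
  A2 <- rbind(A, rep(penalty, 2))
  res2 <- solve_lp(rep(1, 2 * sp$n), A = A2,
                   dir = c(dir, "<="),
                   rhs = c(rhs, res$objective * (1 + 1e-12) + 1e-11),
                   lb = sp$lb2, ub = sp$ub2, maximize = FALSE)
  if (res2$status == "optimal") res <- list(status = "optimal", x = res2$x,
                                            objective = res$objective)
  v <- res$x[seq_len(sp$n)] - res$x[sp$n + seq_len(sp$n)]
  names(v) <- colnames(p$S)
  kept <- model$rxns$id[is.na(rxn_expr) | rxn_expr >= t | abs(v) > 1e-9]
  kept_mets <- unique(unlist(lapply(model$stoich[kept], names)))
  structure(list(parent = model$id, kept_rxns = kept, kept_mets = kept_mets,
                 inconsistency = res$objective, threshold = t, fraction = f,
                 label = label, fluxes = v),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("<context_model> %s: %d reactions, %d metabolites, inconsistency %.4g\n",
              x$label %||% x$parent, length(x$kept_rxns), length(x$kept_mets),
              x$inconsistency))
  invisible(x)
}

#' Restrict a model to a context's kept reactions
#' @param model The parent [gem()].
#' @param context A `context_model`.
#' @return The parent model with non-kept reactions closed.
#' @export
context_submodel <- function(model, context) {
  drop <- setdiff(model$rxns$id, context$kept_rxns)
  model$rxns[drop, c("lb", "ub")] <- 0
  model
}

#' Build context models for a set of profiles
#'
#' When the config carries no absolute threshold, one shared threshold is
#' derived from the pooled nonzero expression of all profiles: a per-cell
#' quantile would drift with each cell's own expression shifts (a strongly
#' induced regulon inflates that cell's quantile and spuriously penalises
#' unshifted genes), whereas a dataset-wide threshold means "low" refers to
#' the same expression level in every cell.
#'
#' @param model A [gem()].
#' @param profiles Named list (label -> expression vector) or a gene x sample
#'   matrix with column names as labels.
#' @param config A [gimme_config()].
#' @return List of `context_model`s (one per profile); per-profile failures
#'   are collected as `NULL` entries with a warning, not fatal.
#' @export
batch_contexts <- function(model, profiles, config = gimme_config()) {
  if (is.matrix(profiles)) {
    profiles <- stats::setNames(
      lapply(seq_len(ncol(profiles)), function(j) profiles[, j]),
      colnames(profiles))
  }
  if (is.null(config$threshold) && length(profiles)) {
    pooled <- unlist(profiles, use.names = FALSE)
    config$threshold <- resolve_threshold(config, pooled)
  }
  out <- vector("list", length(profiles))
  names(out) <- names(profiles)
  for (lab in names(profiles)) {
    out[[lab]] <- tryCatch(gimme_extract(model, profiles[[lab]], config, label = lab),
                           error = function(e) {
                             warning("context '", lab, "' failed: ", conditionMessage(e),
                                     call. = FALSE)
                             NULL
                           })
  }
  out
}

#' Growth and pFBA fluxes per context
#'
#' @param model The parent [gem()].
#' @param contexts List of `context_model`s.
#' @param medium Optional medium to apply first.
#' @return List with `growth` (named numeric) and `fluxes` (reaction x context
#'   matrix of pFBA fluxes); infeasible contexts get `NA` growth and are
#'   excluded from the flux matrix.
#' @export
context_growth_and_fluxes <- function(model, contexts, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  contexts <- Filter(Negate(is.null), contexts)
  growth <- stats::setNames(rep(NA_real_, length(contexts)), names(contexts))
  cols <- list()
  for (lab in names(contexts)) {
    sub <- context_submodel(model, contexts[[lab]])
    sol <- pfba(sub)
    if (sol$status == "optimal") {
      growth[lab] <- sol$objective
      cols[[lab]] <- sol$fluxes
    }
  }
  fluxes <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(model$rxns), 0, dimnames = list(model$rxns$id, NULL))
  list(growth = growth, fluxes = fluxes)
}

#' Compare flux distributions between two groups
#'
#' Per active reaction (nonzero flux in at least one sample), a two-sided
#' two-sample t-test between groups; reactions constant in both groups get
#' p = 1 by convention. The divergent fraction is the share of active
#' reactions with raw p below `alpha`; Benjamini-Hochberg q-values are
#' reported alongside.
#'
#' @param flux_table Reaction x sample numeric matrix.
#' @param groups Factor/character of length `ncol(flux_table)` with 2 levels.
#' @param alpha Divergence threshold on the raw p-value, default 0.05.
#' @return List with `table` (reaction, mean_a, mean_b, p, q) over active
#'   reactions and `divergent_fraction`.
#' @export
compare_conditions <- function(flux_table, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group", call. = FALSE)
  a <- levels(groups)[1]; b <- levels(groups)[2]
  active <- rownames(flux_table)[rowSums(abs(flux_table) > 1e-9) > 0]
  res <- lapply(active, function(rid) {
    xa <- flux_table[rid, groups == a]
    xb <- flux_table[rid, groups == b]
    p <- if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12) 1 else
      tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) 1)
    c(mean_a = mean(xa), mean_b = mean(xb), p = p)
  })
  tab <- data.frame(reaction = active, do.call(rbind, res), stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  list(table = tab,
       divergent_fraction = if (nrow(tab)) mean(tab$p < alpha) else 0)
}
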