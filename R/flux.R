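# LP flux analyses: FBA, parsimonious FBA, solution-space sampling, gene
# deletion in two modes, synthetic-lethality classification and substrate
# usage screening. Fluxes are in mmol/gDW/h (growth in 1/h).

.FLUX_CAP <- 1000

new_flux_distribution <- function(fluxes, objective, status) {
  structure(list(fluxes = fluxes, objective = objective, status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s, objective %.6g, %d reactions\n",
              x$status, x$objective, length(x$fluxes)))
  invisible(x)
}

model_lp_parts <- function(model) {
  list(S = stoich_matrix(model),
       lb = pmax(stats::setNames(model$rxns$lb, model$rxns$id), -.FLUX_CAP),
       ub = pmin(stats::setNames(model$rxns$ub, model$rxns$id), .FLUX_CAP))
}

#' Apply a growth medium
#'
#' A medium maps exchange-reaction ids to maximum uptake magnitudes
#' (mmol/gDW/h). Listed exchanges get lower bound `-magnitude`; every other
#' exchange is closed to uptake (`lb = 0`); secretion bounds are untouched.
#'
#' @param model A [gem()].
#' @param medium Named numeric vector, exchange id -> uptake magnitude (>= 0).
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium) {
  ex <- find_exchanges(model)
  stopifnot_ids(names(medium), ex, "exchange reaction")
  if (any(medium < 0)) stop("medium magnitudes must be >= 0", call. = FALSE)
  model$rxns[ex, "lb"] <- pmax(model$rxns[ex, "lb"], 0)
  model$rxns[names(medium), "lb"] <- -unname(medium)
  model
}

#' Flux balance analysis
#'
#' Solves \eqn{\max c^T v} (or min) subject to \eqn{S v = 0} and
#' \eqn{lb \le v \le ub}.
#'
#' @param model A [gem()], already constrained to its medium.
#' @param objective Reaction id; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_distribution` (status `"infeasible"` carries no fluxes).
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot_ids(objective, model$rxns$id, "reaction")
  p <- model_lp_parts(model)
  n <- ncol(p$S)
  obj <- stats::setNames(numeric(n), colnames(p$S))
  obj[objective] <- 1
  res <- solve_lp(obj, A = p$S, dir = rep("=", nrow(p$S)), rhs = numeric(nrow(p$S)),
                  lb = p$lb, ub = p$ub, maximize = sense == "max")
  if (res$status != "optimal") {
    return(new_flux_distribution(NULL, NA_real_, res$status))
  }
  new_flux_distribution(stats::setNames(res$x, colnames(p$S)), res$objective, "optimal")
}

# split a model's LP into irreversible halves: v = v_fwd - v_rev
split_parts <- function(p) {
  n <- ncol(p$S)
  list(S2 = cbind(p$S, -p$S),
       lb2 = c(pmax(p$lb, 0), pmax(-p$ub, 0)),
       ub2 = c(pmax(p$ub, 0), pmax(-p$lb, 0)),
       n = n)
}

#' Parsimonious FBA
#'
#' Two-stage LP: first the FBA optimum of the objective reaction, then, with
#' the objective fixed at that optimum (1e-9 relative), the minimum total
#' absolute flux \eqn{\sum_i |v_i|} via splitting each reaction into
#' irreversible forward/reverse parts.
#'
#' @inheritParams fba
#' @return A `flux_distribution`; its `objective` is the stage-one optimum and
#'   `sum_abs_flux` holds the minimised total flux.
#' @export
pfba <- function(model, objective = model$objective) {
  stage1 <- fba(model, objective)
  if (stage1$status != "optimal") return(stage1)
  opt <- stage1$objective
  p <- model_lp_parts(model)
  # fix the objective reaction at its optimum
  tol <- 1e-9 * max(1, abs(opt))
  p$lb[objective] <- opt - tol
  p$ub[objective] <- min(p$ub[objective], opt + tol)
  sp <- split_parts(p)
  res <- solve_lp(rep(1, 2 * sp$n), A = sp$S2, dir = rep("=", nrow(sp$S2)),
                  rhs = numeric(nrow(sp$S2)), lb = sp$lb2, ub = sp$ub2,
                  maximize = FALSE)
  if (res$status != "optimal") return(new_flux_distribution(NULL, NA_real_, res$status))
  v <- res$x[seq_len(sp$n)] - res$x[sp$n + seq_len(sp$n)]
  out <- new_flux_distribution(stats::setNames(v, colnames(p$S)), opt, "optimal")
  out$sum_abs_flux <- res$objective
  out
}

#' Sample the flux solution space
#'
#' Uniform-target hit-and-run over \eqn{\{v : Sv = 0, lb \le v \le ub\}} from
#' an interior start (maximum-slack LP), moving along random directions in the
#' null space of S with a thinning interval. Reactions with unbounded bounds
#' are capped at +/-1000 mmol/gDW/h first.
#'
#' @param model A [gem()].
#' @param n Number of samples (default 1000).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param thinning Steps between recorded samples (default 100).
#' @return List with `samples` (n x reactions matrix) and `mean` (named
#'   per-reaction mean flux).
#' @export
sample_fluxes <- function(model, n = 1000, seed = 1, thinning = 100) {
  p <- model_lp_parts(model)
  nr <- ncol(p$S)
  free <- which(p$ub - p$lb > 1e-12)

  # interior start: maximise the uniform slack s with v_i -/+ s inside bounds
  obj <- c(numeric(nr), 1)
  A <- rbind(cbind(p$S, 0),
             cbind(diag(nr)[free, , drop = FALSE], -1),   # v - s >= lb
             cbind(diag(nr)[free, , drop = FALSE], +1))   # v + s <= ub
  dir <- c(rep("=", nrow(p$S)), rep(">=", length(free)), rep("<=", length(free)))
  rhs <- c(numeric(nrow(p$S)), p$lb[free], p$ub[free])
  res <- solve_lp(obj, A, dir, rhs, lb = c(p$lb, 0),
                  ub = c(p$ub, max(p$ub - p$lb) / 2 + 1), maximize = TRUE)
  if (res$status != "optimal") stop("sampling start infeasible", call. = FALSE)
  v <- res$x[seq_len(nr)]

  # null-space basis of S
  sv <- svd(p$S, nu = 0, nv = nr)
  rank <- sum(sv$d > max(dim(p$S)) * max(sv$d, 0) * 1e-12)
  N <- sv$v[, setdiff(seq_len(nr), seq_len(rank)), drop = FALSE]
  k <- ncol(N)
  samples <- matrix(0, n, nr, dimnames = list(NULL, colnames(p$S)))
  if (k == 0L) {
    samples[] <- rep(v, each = n)
  } else {
    with_seed(seed, {
      for (i in seq_len(n)) {
        for (s in seq_len(thinning)) {
          d <- as.numeric(N %*% stats::rnorm(k))
          nz <- abs(d) > 1e-10
          if (!any(nz)) next
          tt <- c((p$lb[nz] - v[nz]) / d[nz], (p$ub[nz] - v[nz]) / d[nz])
          tmin <- max(tt[tt <= 1e-12], -Inf)
          tmax <- min(tt[tt >= -1e-12], Inf)
          if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) next
          v <- v + stats::runif(1, tmin, tmax) * d
          v <- pmin(pmax(v, p$lb), p$ub) # guard accumulation error
        }
        samples[i, ] <- v
      }
    })
  }
  list(samples = samples, mean = colMeans(samples))
}

#' Delete genes from a model
#'
#' Two modes mirror the two published conventions. `"gpr"` honours the AND/OR
#' rule: a reaction is closed only when its GPR evaluates inactive (an
#' isoenzyme survives its partner's deletion). `"reaction_removal"` ignores
#' the rule: every reaction whose GPR mentions any deleted gene is closed, no
#' matter what other genes are associated. Deleting a gene absent from every
#' GPR is legal and a no-op (knockout strains may delete non-metabolic genes).
#'
#' @param model A [gem()].
#' @param genes Character vector of gene ids.
#' @param mode `"gpr"` or `"reaction_removal"`.
#' @return The constrained model (closed reactions get `lb = ub = 0`).
#' @export
delete_genes <- function(model, genes, mode = c("gpr", "reaction_removal")) {
  mode <- match.arg(mode)
  closed <- affected_reactions(model, genes, mode)
  if (length(closed)) {
    model$rxns[closed, "lb"] <- 0
    model$rxns[closed, "ub"] <- 0
  }
  model
}

affected_reactions <- function(model, genes, mode) {
  out <- character(0)
  for (rid in model$rxns$id) {
    tree <- model$gprs[[rid]]
    if (is.null(tree)) next
    hit <- if (mode == "gpr") {
      !evaluate_gpr_boolean(tree, genes)
    } else {
      length(intersect(gpr_genes(tree), genes)) > 0L
    }
    if (hit) out <- c(out, rid)
  }
  out
}

#' Double gene deletion grid
#'
#' Maximal growth after deleting every unordered pair from `genes_a` x
#' `genes_b`; the diagonal holds single-deletion growth. LPs are cached on
#' the set of closed reactions, so pairs hitting no reaction cost nothing.
#'
#' @param model A [gem()] constrained to its medium.
#' @param genes_a,genes_b Character vectors of gene ids.
#' @param mode Deletion mode, see [delete_genes()].
#' @return Object of class `deletion_grid`: `growth` matrix (a x b), `mode`,
#'   `wildtype` growth.
#' @export
double_gene_deletion <- function(model, genes_a, genes_b = genes_a,
                                 mode = c("gpr", "reaction_removal")) {
  mode <- match.arg(mode)
  wt <- fba(model)
  if (wt$status != "optimal") stop("wildtype model infeasible", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  assign("k:", wt$objective, envir = cache)
  growth_of <- function(pair) {
    closed <- affected_reactions(model, pair, mode)
    key <- paste0("k:", paste(sort(closed), collapse = ","))
    if (!is.null(g <- cache[[key]])) return(g)
    m2 <- model
    m2$rxns[closed, c("lb", "ub")] <- 0
    sol <- fba(m2)
    g <- if (sol$status == "optimal") sol$objective else NA_real_
    cache[[key]] <- g
    g
  }
  grid <- matrix(NA_real_, length(genes_a), length(genes_b),
                 dimnames = list(genes_a, genes_b))
  for (a in genes_a) {
    for (b in genes_b) {
      if (!is.na(grid[a, b])) next
      g <- growth_of(unique(c(a, b)))
      grid[a, b] <- g
      if (b %in% genes_a && a %in% genes_b) grid[b, a] <- g
    }
  }
  structure(list(growth = grid, mode = mode, wildtype = wt$objective),
            class = "deletion_grid")
}

#' @export
print.deletion_grid <- function(x, ...) {
  cat(sprintf("<deletion_grid> %d x %d pairs, mode %s, wildtype growth %.4g\n",
              nrow(x$growth), ncol(x$growth), x$mode, x$wildtype))
  invisible(x)
}

#' Classify deletion outcomes as lethal or viable
#'
#' A pair is lethal when its post-deletion growth falls below
#' `cutoff * wildtype` (default 1\% of wildtype).
#'
#' @param grid A `deletion_grid` or a growth matrix.
#' @param wildtype Wildtype growth (taken from the grid if omitted).
#' @param cutoff Fraction of wildtype growth below which a pair is lethal.
#' @return Character matrix of `"lethal"`/`"viable"` labels.
#' @export
classify_lethality <- function(grid, wildtype = NULL, cutoff = 0.01) {
  g <- if (inherits(grid, "deletion_grid")) grid$growth else grid
  wt <- wildtype %||% if (inherits(grid, "deletion_grid")) grid$wildtype else
    stop("wildtype growth required", call. = FALSE)
  if (wt <= 0) stop("wildtype growth must be positive", call. = FALSE)
  out <- ifelse(is.na(g) | g < cutoff * wt, "lethal", "viable")
  dimnames(out) <- dimnames(g)
  out
}

#' Confusion metrics against experimental labels
#'
#' Standard confusion counts with `"lethal"` as the positive class.
#'
#' @param predicted,truth Named character vectors (or matrices) of
#'   `"lethal"`/`"viable"` over the same keys.
#' @return List with TP, FP, TN, FN, accuracy, precision, recall, f1.
#' @export
confusion_metrics <- function(predicted, truth) {
  p <- as.vector(predicted); t <- as.vector(truth)
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stop("predicted and truth keys differ", call. = FALSE)
    }
    t <- truth[names(predicted)]
  } else if (length(p) != length(t)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  tp <- sum(p == "lethal" & t == "lethal")
  fp <- sum(p == "lethal" & t == "viable")
  tn <- sum(p == "viable" & t == "viable")
  fn <- sum(p == "viable" & t == "lethal")
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       accuracy = (tp + tn) / length(p), precision = prec, recall = rec, f1 = f1)
}

#' Substrate usage screen
#'
#' For each candidate exchange, opens it as the sole source of the stated
#' element on top of a base medium lacking that element, and tests whether FBA
#' growth exceeds a small cutoff (Biolog-plate style usability call).
#'
#' @param model A [gem()].
#' @param candidates Exchange reaction ids to test.
#' @param role Element supplied: `"C"`, `"N"`, `"P"` or `"S"`.
#' @param base_medium Named numeric medium lacking a source of `role`.
#' @param uptake Uptake magnitude granted to each candidate (default 10).
#' @param growth_cutoff Growth above this counts as usable (default 1e-6 1/h).
#' @return Named logical vector over candidates.
#' @export
substrate_usage <- function(model, candidates, role = c("C", "N", "P", "S"),
                            base_medium, uptake = 10, growth_cutoff = 1e-6) {
  role <- match.arg(role)
  ex <- find_exchanges(model)
  stopifnot_ids(candidates, ex, "exchange reaction")
  out <- stats::setNames(logical(length(candidates)), candidates)
  for (cand in candidates) {
    med <- base_medium
    med[cand] <- uptake
    m2 <- apply_medium(model, med)
    sol <- fba(m2)
    out[cand] <- sol$status == "optimal" && sol$objective > growth_cutoff
  }
  out
}
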