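# Strain-specific models from knockout-strain expression fold-changes.
#
# Non-log fold-changes versus wildtype multiply the wildtype reaction bounds
# (min over complex subunits, max over isoenzymes), after per-strain
# winsorization of extreme values with the knockout gene(s) exempt; knocked
# out metabolic genes are additionally closed through the GPR.

#' Winsorize a fold-change profile
#'
#' Values below the lower / above the upper percentile of the strain's own
#' profile are replaced by those percentile values (rank-linear-interpolation
#' percentiles). Knockout genes are exempt and untouched.
#'
#' @param profile Named numeric vector of positive fold-changes.
#' @param ko_genes Genes to exempt (the strain's knockouts).
#' @param lower,upper Percentiles, defaults 1 and 99.
#' @return The winsorized profile.
#' @export
winsorize_profile <- function(profile, ko_genes = character(0), lower = 1, upper = 99) {
  if (length(profile) < 2L) stop("need >= 2 genes to winsorize", call. = FALSE)
  if (any(profile <= 0, na.rm = TRUE)) stop("fold-changes must be > 0", call. = FALSE)
  qs <- stats::quantile(profile, c(lower, upper) / 100, type = 7, na.rm = TRUE)
  out <- pmin(pmax(profile, qs[1]), qs[2])
  out[names(profile) %in% ko_genes] <- profile[names(profile) %in% ko_genes]
  out
}

#' Scale reaction bounds by expression fold-changes
#'
#' For each reaction with a GPR, the reaction-level factor is the GPR
#' collapse of the gene fold-changes ([reaction_expression()]: min over AND,
#' max over OR); both bounds are multiplied by it. Reactions without a GPR,
#' or whose genes are all absent from the profile, are untouched. Knocked-out
#' genes present in the model are then closed via [delete_genes()] in GPR
#' mode. Scaling always applies to the wildtype parent bounds.
#'
#' @param model The wildtype [gem()].
#' @param profile Winsorized fold-change vector (gene -> factor > 0).
#' @param ko_genes Knockout gene ids (may be absent from the model).
#' @return The strain-specific model.
#' @export
scale_bounds <- function(model, profile, ko_genes = character(0)) {
  for (rid in model$rxns$id) {
    tree <- model$gprs[[rid]]
    if (is.null(tree)) next
    f <- reaction_expression(tree, profile)
    if (is.na(f)) next
    if (f <= 0) stop("non-positive bound factor for ", rid, call. = FALSE)
    model$rxns[rid, "lb"] <- model$rxns[rid, "lb"] * f
    model$rxns[rid, "ub"] <- model$rxns[rid, "ub"] * f
  }
  delete_genes(model, ko_genes, mode = "gpr")
}

#' Predict growth of knockout strains
#'
#' Builds each strain-specific model (winsorize, scale bounds, close
#' knockouts) and maximises growth by FBA. Infeasible strains are reported as
#' growth 0 with a flag.
#'
#' @param model The wildtype [gem()].
#' @param strains List of strain profiles: each a list with `id`, `ko_genes`
#'   (character, 1 or 2), `folds` (named positive numeric).
#' @param medium Optional medium applied to the wildtype first.
#' @param winsorize Apply per-strain winsorization first (default TRUE).
#' @return data.frame with columns strain, growth, status.
#' @export
predict_strain_growth <- function(model, strains, medium = NULL, winsorize = TRUE) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  rows <- lapply(strains, function(s) {
    folds <- s$folds
    if (winsorize && length(folds) >= 2L) {
      folds <- winsorize_profile(folds, ko_genes = s$ko_genes)
    }
    m2 <- scale_bounds(model, folds, ko_genes = s$ko_genes)
    sol <- fba(m2)
    data.frame(strain = s$id,
               growth = if (sol$status == "optimal") sol$objective else 0,
               status = sol$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate predicted growth with measured doubling times
#'
#' Growth rate and doubling time are inversely related, so the default
#' correlates predicted growth against the reciprocal of the relative
#' doubling time and reports |r| with the two-sided t-based p-value;
#' `raw = TRUE` correlates against the measured value untransformed.
#'
#' @param predicted Named numeric, strain -> predicted growth (1/h).
#' @param measured Named numeric, strain -> relative doubling time.
#' @param raw Skip the reciprocal transform (default FALSE).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_growth <- function(predicted, measured, raw = FALSE) {
  shared <- intersect(names(predicted), names(measured))
  if (length(shared) < 3L) stop("need >= 3 overlapping strains", call. = FALSE)
  x <- predicted[shared]
  y <- if (raw) measured[shared] else 1 / measured[shared]
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("zero variance in growth or doubling time", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = abs(unname(ct$estimate)), p_value = ct$p.value, n = length(shared))
}
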