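# Nitrogen-source preference scoring and nitrogen-limited condition models.
#
# The preference protocol: grow at a fixed rate on one nitrogen source at a
# time, find the minimal nitrogen uptake, step it up from 100 to 150% of that
# minimum (five steps, fixed as an equality so the extra nitrogen actually
# enters), re-minimise glucose uptake at each step, and score the source by
# the absolute slope of glucose uptake on nitrogen uptake. Scores over the
# compared set are scaled to sum to one.

# nitrogen atoms carried by the metabolite behind an exchange reaction
exchange_n_atoms <- function(model, ex_id) {
  met <- names(model$stoich[[ex_id]])
  counts <- parse_formula(model$mets[met, "formula"])
  unname(counts["N"] %||% 0) %||% 0
}

# close uptake of every nitrogen-carrying exchange except `keep`; secretion
# stays open (nitrogen overflow is allowed)
sole_nitrogen_source <- function(model, keep) {
  ex <- find_exchanges(model)
  for (e in ex) {
    n <- exchange_n_atoms(model, e)
    if (!is.na(n) && n > 0 && e != keep) {
      model$rxns[e, "lb"] <- max(model$rxns[e, "lb"], 0)
    }
  }
  model
}

fix_growth <- function(model, growth) {
  model$rxns[model$objective, c("lb", "ub")] <- growth
  model
}

#' Minimal nitrogen uptake at fixed growth
#'
#' Opens `n_exchange` as the sole nitrogen source, fixes the growth reaction
#' at `growth` (default 0.1 1/h) and minimises the uptake magnitude of the
#' nitrogen exchange by LP.
#'
#' @param model A [gem()] constrained to its medium (carbon source open).
#' @param n_exchange Exchange reaction id of the nitrogen source.
#' @param growth Fixed growth rate (1/h), default 0.1.
#' @param uptake_cap Maximum uptake magnitude allowed (default 1000).
#' @return Minimal uptake in mmol/gDW/h (non-negative).
#' @export
min_nitrogen_uptake <- function(model, n_exchange, growth = 0.1, uptake_cap = 1000) {
  ex <- find_exchanges(model)
  stopifnot_ids(n_exchange, ex, "exchange reaction")
  m <- sole_nitrogen_source(model, n_exchange)
  m$rxns[n_exchange, "lb"] <- -uptake_cap
  m <- fix_growth(m, growth)
  sol <- fba(m, objective = n_exchange, sense = "max")
  if (sol$status != "optimal") {
    stop("infeasible at growth ", growth, " on ", n_exchange,
         ": nitrogen source cannot support growth", call. = FALSE)
  }
  max(0, -sol$objective)
}

#' Glucose response to stepped nitrogen uptake
#'
#' Fixes nitrogen uptake (as an equality) at each of `steps` values spanning
#' `span` times the minimal uptake, keeps growth fixed, and minimises glucose
#' uptake magnitude at each step.
#'
#' @inheritParams min_nitrogen_uptake
#' @param glc_exchange Glucose exchange id.
#' @param steps Number of steps, default 5.
#' @param span Multiplier range over the minimum, default c(1, 1.5).
#' @return data.frame with columns `n_uptake`, `glc_uptake` (magnitudes).
#' @export
glucose_response <- function(model, n_exchange, glc_exchange, growth = 0.1,
                             steps = 5, span = c(1, 1.5)) {
  n_min <- min_nitrogen_uptake(model, n_exchange, growth)
  m <- sole_nitrogen_source(model, n_exchange)
  m <- fix_growth(m, growth)
  m$rxns[glc_exchange, "lb"] <- -1000
  levels <- n_min * seq(span[1], span[2], length.out = steps)
  glc <- vapply(seq_along(levels), function(i) {
    mi <- m
    mi$rxns[n_exchange, c("lb", "ub")] <- -levels[i]
    sol <- fba(mi, objective = glc_exchange, sense = "max")
    if (sol$status != "optimal") {
      stop("glucose minimisation infeasible at step ", i, " (N uptake ",
           signif(levels[i], 6), ")", call. = FALSE)
    }
    max(0, -sol$objective)
  }, 0.0)
  data.frame(n_uptake = levels, glc_uptake = glc)
}

#' Preference score from response points
#'
#' Ordinary least-squares slope of glucose uptake on nitrogen uptake; the
#' score is its absolute value. `endpoints = TRUE` uses only the first and
#' last point instead of the full OLS fit.
#'
#' @param points data.frame from [glucose_response()].
#' @param endpoints Use endpoint slope instead of OLS (default FALSE).
#' @return Non-negative score.
#' @export
preference_score <- function(points, endpoints = FALSE) {
  if (nrow(points) < 2L) stop("need >= 2 points", call. = FALSE)
  if (stats::sd(points$n_uptake) < 1e-12) {
    stop("zero variance in nitrogen uptake", call. = FALSE)
  }
  slope <- if (endpoints) {
    i <- c(1L, nrow(points))
    diff(points$glc_uptake[i]) / diff(points$n_uptake[i])
  } else {
    stats::cov(points$glc_uptake, points$n_uptake) / stats::var(points$n_uptake)
  }
  abs(slope)
}

#' Scale preference scores to sum to one
#'
#' \eqn{scaled_i = i / \sum I} over exactly the set of sources compared.
#'
#' @param raw Named numeric vector of raw scores (>= 0, not all zero).
#' @return Scaled scores summing to 1.
#' @export
scale_scores <- function(raw) {
  s <- sum(raw)
  if (s <= 0) stop("all scores zero: nothing to scale", call. = FALSE)
  raw / s
}

#' Nitrogen preference scores for a set of sources
#'
#' Runs the full protocol ([min_nitrogen_uptake()], [glucose_response()],
#' [preference_score()], [scale_scores()]) for each nitrogen exchange.
#'
#' @inheritParams glucose_response
#' @param n_exchanges Character vector of nitrogen exchange ids.
#' @return data.frame: n_exchange, min_uptake, raw_score, scaled_score.
#' @export
nitrogen_preference <- function(model, n_exchanges, glc_exchange, growth = 0.1,
                                steps = 5, span = c(1, 1.5)) {
  rows <- lapply(n_exchanges, function(e) {
    pts <- glucose_response(model, e, glc_exchange, growth, steps, span)
    data.frame(n_exchange = e, min_uptake = pts$n_uptake[1] / span[1],
               raw_score = preference_score(pts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$scaled_score <- as.numeric(scale_scores(stats::setNames(out$raw_score, out$n_exchange)))
  out
}

#' Rescale biomass macro-composition
#'
#' Multiplies the biomass coefficients of each component class (protein,
#' carbohydrate, RNA) so the class masses match the targets (g/gDW), then
#' renormalises all classified substrates so total biomass mass is 1 g/gDW.
#' Component classes are read from `model$extra$biomass_class` (metabolite ->
#' class); cofactor-class components (ATP, water, products) are untouched.
#'
#' @param model A [gem()] whose biomass substrates are class-tagged.
#' @param protein,carbohydrate,rna Target masses in g/gDW (positive).
#' @return The rescaled model.
#' @export
scale_biomass <- function(model, protein, carbohydrate, rna) {
  targets <- c(protein = protein, carbohydrate = carbohydrate, rna = rna)
  if (any(targets <= 0)) stop("biomass fractions must be positive", call. = FALSE)
  classes <- model$extra$biomass_class
  if (is.null(classes)) stop("model has no biomass class annotation", call. = FALSE)
  bid <- model$objective
  st <- model$stoich[[bid]]
  subs <- names(st)[st < 0]
  cls <- classes[subs]
  if (any(is.na(cls) | !nzchar(cls))) {
    stop("unclassified biomass components: ",
         paste(subs[is.na(cls) | !nzchar(cls)], collapse = ", "), call. = FALSE)
  }
  mw <- vapply(model$mets[subs, "formula"], formula_weight, 0.0)
  scaled <- st
  for (k in names(targets)) {
    idx <- subs[cls == k]
    if (!length(idx)) stop("no biomass component of class '", k, "'", call. = FALSE)
    cur_mass <- sum(-st[idx] * mw[match(idx, subs)]) / 1000  # coeffs in mmol/gDW
    scaled[idx] <- st[idx] * targets[[k]] / cur_mass
  }
  mass_idx <- subs[cls %in% names(targets)]
  total <- sum(-scaled[mass_idx] * mw[match(mass_idx, subs)]) / 1000
  scaled[mass_idx] <- scaled[mass_idx] / total
  model$stoich[[bid]] <- scaled
  model
}

#' Condition-specific pFBA under nitrogen limitation
#'
#' Staged pipeline: (1) constrain each measured exchange to 0.8x its measured
#' magnitude and fix growth at the measured rate (rescaling the biomass
#' composition first when fractions are supplied); (2) minimise nitrogen
#' uptake, then cap it at `n_cap_factor` (1.5) times that minimum; (3)
#' release growth and recompute all fluxes by pFBA maximising growth.
#'
#' @param model A [gem()].
#' @param condition List with `exchanges` (named numeric measured fluxes,
#'   signed, uptake negative), `growth` (1/h), and optionally `protein`,
#'   `carbohydrate`, `rna` biomass fractions (g/gDW).
#' @param n_exchange Nitrogen exchange id.
#' @param n_cap_factor Cap on nitrogen uptake relative to its minimum.
#' @param measurement_factor Relaxation applied to measured magnitudes (0.8).
#' @return A `flux_distribution` from the final pFBA stage.
#' @export
nitrogen_condition_pfba <- function(model, condition, n_exchange,
                                    n_cap_factor = 1.5, measurement_factor = 0.8) {
  ex <- find_exchanges(model)
  stopifnot_ids(names(condition$exchanges), ex, "exchange reaction")
  if (!is.null(condition$protein)) {
    model <- scale_biomass(model, condition$protein, condition$carbohydrate,
                           condition$rna)
  }
  # stage 1: measured exchange bounds at 0.8x magnitude, growth fixed
  # uptake (negative): magnitude capped at 0.8x measured; secretion (positive):
  # at least 0.8x measured must leave. Both put the relaxed measurement on lb.
  for (e in names(condition$exchanges)) {
    model$rxns[e, "lb"] <- condition$exchanges[[e]] * measurement_factor
  }
  m1 <- fix_growth(model, condition$growth)
  m1$rxns[n_exchange, "lb"] <- -1000
  sol <- fba(m1, objective = n_exchange, sense = "max")
  if (sol$status != "optimal") {
    stop("stage 2 (nitrogen minimisation) infeasible at measured growth",
         call. = FALSE)
  }
  n_min <- max(0, -sol$objective)
  # stage 2 cap, stage 3 release growth and pFBA
  model$rxns[n_exchange, "lb"] <- -n_cap_factor * n_min
  model$rxns[n_exchange, "ub"] <- 0
  model$rxns[model$objective, "lb"] <- 0
  model$rxns[model$objective, "ub"] <- 1000
  out <- pfba(model)
  if (out$status != "optimal") {
    stop("stage 3 (growth pFBA) infeasible under nitrogen cap", call. = FALSE)
  }
  out
}
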