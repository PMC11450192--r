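test_that("minimal nitrogen uptake follows biomass stoichiometry", {
  # ammonium carries one N: uptake = biomass N content x growth
  expect_equal(min_nitrogen_uptake(TOY$model, "EX_nh4", growth = 0.1),
               TOY$truth$n_per_gdw * 0.1, tolerance = 1e-6)
  # glutamine carries two: half the molar uptake
  expect_equal(min_nitrogen_uptake(TOY$model, "EX_gln", growth = 0.1),
               TOY$truth$n_per_gdw * 0.1 / 2, tolerance = 1e-6)
  # no growth, no maintenance: no nitrogen needed
  expect_equal(min_nitrogen_uptake(TOY$model, "EX_nh4", growth = 0), 0,
               tolerance = 1e-8)
  # linear in the fixed growth rate (LP homogeneity)
  u1 <- min_nitrogen_uptake(TOY$model, "EX_nh4", growth = 0.05)
  u2 <- min_nitrogen_uptake(TOY$model, "EX_nh4", growth = 0.2)
  expect_equal(u2, 4 * u1, tolerance = 1e-6)
})

test_that("the glucose response is linear with the planted marginal economics", {
  for (ex in names(TOY$truth$n_marginal_atp)) {
    pts <- glucose_response(TOY$model, ex, "EX_glc")
    expect_equal(nrow(pts), 5L)
    expect_equal(pts$n_uptake / pts$n_uptake[1],
                 seq(1, 1.5, length.out = 5), tolerance = 1e-9)
    slope <- preference_score(pts)
    planted <- abs(TOY$truth$n_marginal_atp[[ex]]) / TOY$truth$atp_per_glc
    expect_equal(slope, planted, tolerance = 1e-6, label = ex)
  }
  # degenerate span: five identical points
  pts0 <- glucose_response(TOY$model, "EX_nh4", "EX_glc", span = c(1, 1))
  expect_equal(stats::sd(pts0$n_uptake), 0)
  expect_equal(stats::sd(pts0$glc_uptake), 0, tolerance = 1e-9)
})

test_that("slope scoring is exact OLS with its stated degenerate errors", {
  pts <- data.frame(n_uptake = 1:5, glc_uptake = 10 - 3 * (1:5))
  expect_equal(preference_score(pts), 3, tolerance = 1e-12)
  flat <- data.frame(n_uptake = 1:5, glc_uptake = rep(2, 5))
  expect_equal(preference_score(flat), 0)
  # noisy planted slope matches the closed-form normal equations
  set.seed(13)
  x <- seq(1, 2, length.out = 5)
  y <- 4 - 2.5 * x + rnorm(5, 0, 0.01)
  ols <- solve(cbind(1, x) |> crossprod(), crossprod(cbind(1, x), y))[2]
  expect_equal(preference_score(data.frame(n_uptake = x, glc_uptake = y)),
               abs(ols), tolerance = 1e-12)
  expect_equal(preference_score(pts, endpoints = TRUE), 3)
  expect_error(preference_score(pts[1, , drop = FALSE]), ">= 2")
  expect_error(preference_score(data.frame(n_uptake = c(1, 1), glc_uptake = 1:2)),
               "variance")
})

test_that("score scaling conserves unit mass and ignores common factors", {
  expect_equal(scale_scores(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(scale_scores(7), 1)
  expect_equal(scale_scores(2 * c(2, 3, 5)), scale_scores(c(2, 3, 5)))
  expect_equal(sum(scale_scores(runif(10))), 1)
  expect_error(scale_scores(c(0, 0)), "zero")
})

test_that("preference ranking reproduces the planted nitrogen economics", {
  pref <- nitrogen_preference(TOY$model,
                              c("EX_phe", "EX_nh4", "EX_gln", "EX_ile"),
                              "EX_glc")
  expect_equal(sum(pref$scaled_score), 1, tolerance = 1e-12)
  ranked <- pref$n_exchange[order(pref$scaled_score, decreasing = TRUE)]
  expect_equal(ranked, TOY$truth$n_pref_order)
})

test_that("biomass rescaling hits targets and renormalises to 1 g/gDW", {
  m <- TOY$model
  cur <- TOY$truth$biomass$fractions # 0.5 / 0.4 / 0.1, already unit mass
  same <- scale_biomass(m, cur[["protein"]], cur[["carb"]], cur[["rna"]])
  expect_equal(same$stoich$GROWTH, m$stoich$GROWTH, tolerance = 1e-12)
  # doubling the protein target doubles its coefficient before renormalising
  dbl <- scale_biomass(m, 2 * cur[["protein"]], cur[["carb"]], cur[["rna"]])
  ratio_raw <- (2 * cur[["protein"]]) / cur[["protein"]]
  total <- 2 * cur[["protein"]] + cur[["carb"]] + cur[["rna"]]
  expect_equal(dbl$stoich$GROWTH[["protein_c"]],
               m$stoich$GROWTH[["protein_c"]] * ratio_raw / total,
               tolerance = 1e-9)
  # mass closure: sum coeff x MW over mass components = 1 g/gDW
  mw <- TOY$truth$biomass$mw
  st <- dbl$stoich$GROWTH
  mass <- -(st[["protein_c"]] * mw[["protein"]] + st[["carb_c"]] * mw[["carb"]] +
              st[["rna_c"]] * mw[["rna"]]) / 1000
  expect_equal(mass, 1, tolerance = 1e-6)
  # untagged component is an error
  m2 <- m
  m2$extra$biomass_class <- m2$extra$biomass_class[-1]
  expect_error(scale_biomass(m2, 0.5, 0.4, 0.1), "unclassified")
})

test_that("the staged nitrogen-limited pFBA pipeline is order-sensitive", {
  conds <- make_phenotype_conditions(TOY, n = 2, seed = 11)
  for (cond in conds) {
    out <- nitrogen_condition_pfba(TOY$model, cond, "EX_nh4")
    # relaxed final stage can only grow at least as fast as measured
    expect_gte(out$objective, cond$growth - 1e-8)
    # the nitrogen cap binds in the planted conditions: uptake sits at 1.5x
    # the stage-2 minimum, which itself scales with the measured growth
    n_upt <- -out$fluxes[["EX_nh4"]]
    expect_equal(out$objective, 1.5 * cond$growth, tolerance = 1e-4)
    expect_gt(n_upt, 0)
  }
  # omitting the cap stage yields at-least-equal nitrogen uptake
  cond <- conds[[1]]
  m <- TOY$model
  for (e in names(cond$exchanges)) m$rxns[e, "lb"] <- 0.8 * cond$exchanges[[e]]
  free <- pfba(m)
  capped <- nitrogen_condition_pfba(TOY$model, cond, "EX_nh4")
  expect_gte(-free$fluxes[["EX_nh4"]], -capped$fluxes[["EX_nh4"]] - 1e-8)
})
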