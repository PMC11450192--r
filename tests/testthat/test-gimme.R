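scgem_parent <- make_scgem_parent(TOY)
above_all <- stats::setNames(rep(100, length(TOY$model$genes)), TOY$model$genes)

test_that("fully expressed profiles keep everything at zero inconsistency", {
  ctx <- gimme_extract(scgem_parent, above_all, gimme_config(threshold = 1))
  expect_setequal(ctx$kept_rxns, TOY$model$rxns$id)
  expect_equal(ctx$inconsistency, 0)
})

test_that("a below-threshold route with an adequate alternative is excluded", {
  # fermentation under-expressed, respiration fine: the oxygen-limited
  # glucose-forced parent can still reach 90% of optimal growth without it
  e <- above_all
  e["gADH1"] <- 0.1
  ctx <- gimme_extract(scgem_parent, e, gimme_config(threshold = 1, fraction = 0.9))
  expect_false("FERM" %in% ctx$kept_rxns)
  expect_gte(fba(context_submodel(scgem_parent, ctx))$objective,
             0.9 * fba(scgem_parent)$objective - 1e-8)
  # kept sets are closed: every kept reaction's metabolites are kept
  for (rid in ctx$kept_rxns) {
    expect_true(all(names(scgem_parent$stoich[[rid]]) %in% ctx$kept_mets))
  }
})

test_that("an essential below-threshold reaction is retained and scored", {
  e <- above_all
  e["gZWF1"] <- 0.1 # sole NADPH source: no alternative route
  ctx <- gimme_extract(scgem_parent, e, gimme_config(threshold = 1, fraction = 0.9))
  expect_true("PPP" %in% ctx$kept_rxns)
  expect_gt(ctx$inconsistency, 0)
})

test_that("lowering the threshold never shrinks the kept set", {
  sc <- make_single_cell_profiles(TOY, n_stressed = 1, n_unstressed = 0, seed = 9)
  e <- sc$profiles[, 1]
  kept_hi <- gimme_extract(scgem_parent, e, gimme_config(threshold = 12))$kept_rxns
  kept_lo <- gimme_extract(scgem_parent, e, gimme_config(threshold = 4))$kept_rxns
  expect_true(all(kept_hi %in% kept_lo))
})

test_that("context growth always honours the objective fraction", {
  sc <- make_single_cell_profiles(TOY, n_stressed = 3, n_unstressed = 3, seed = 21)
  opt <- fba(scgem_parent)$objective
  ctx <- batch_contexts(scgem_parent, sc$profiles)
  gf <- context_growth_and_fluxes(scgem_parent, ctx)
  expect_true(all(gf$growth >= 0.9 * opt - 1e-6))
  # identical profiles give identical contexts
  two <- batch_contexts(scgem_parent,
                        cbind(a = sc$profiles[, 1], b = sc$profiles[, 1]))
  expect_equal(two$a$kept_rxns, two$b$kept_rxns)
  expect_equal(two$a$inconsistency, two$b$inconsistency)
  # empty profile set gives an empty list
  expect_length(batch_contexts(scgem_parent, list()), 0L)
})

test_that("stressed contexts reroute overflow through the glycerol branch", {
  sc <- make_single_cell_profiles(TOY, n_stressed = 5, n_unstressed = 5, seed = 31)
  ctx <- batch_contexts(scgem_parent, sc$profiles)
  gf <- context_growth_and_fluxes(scgem_parent, ctx)
  gpd <- gf$fluxes["GPD", ]
  groups <- split(gpd, sc$labels[colnames(gf$fluxes)])
  expect_gt(mean(groups$stressed), mean(groups$unstressed))
  expect_gt(mean(groups$stressed), 0.5) # planted overflow carries real flux
  # reactions absent from a context carry no flux
  for (lab in names(ctx)) {
    dropped <- setdiff(TOY$model$rxns$id, ctx[[lab]]$kept_rxns)
    expect_true(all(abs(gf$fluxes[dropped, lab]) < 1e-9))
  }
})

test_that("condition comparison calibrates p-values and divergence", {
  # identical groups: every p is 1, nothing divergent
  f <- matrix(rep(c(1, 2, 0), 8), nrow = 3,
              dimnames = list(c("r1", "r2", "r3"), NULL))
  res <- compare_conditions(f, rep(c("a", "b"), each = 4))
  expect_true(all(res$table$p == 1))
  expect_equal(res$divergent_fraction, 0)
  expect_false("r3" %in% res$table$reaction) # inactive reactions excluded
  # a planted 5-sigma shift is found at p < 0.001
  set.seed(7)
  shift <- rbind(r1 = c(rnorm(20, 0, 1), rnorm(20, 5, 1)),
                 r2 = rnorm(40))
  res2 <- compare_conditions(shift, rep(c("a", "b"), each = 20))
  expect_lt(res2$table$p[res2$table$reaction == "r1"], 1e-3)
  expect_error(compare_conditions(f, rep("a", 8)), "two groups")
})

test_that("with full objective demand and no penalties GIMME reduces to pFBA", {
  ctx <- gimme_extract(scgem_parent, above_all,
                       gimme_config(threshold = 1, fraction = 1))
  ref <- pfba(scgem_parent)
  expect_equal(ctx$inconsistency, 0)
  # same support: the parsimony refinement pins the degenerate optimum
  expect_setequal(names(ctx$fluxes)[abs(ctx$fluxes) > 1e-6],
                  names(ref$fluxes)[abs(ref$fluxes) > 1e-6])
  expect_equal(sum(abs(ctx$fluxes)), ref$sum_abs_flux, tolerance = 1e-6)
})
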