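test_that("winsorization caps at the percentile values and exempts knockouts", {
  # 100 genes at 1.0 plus one extreme value: the outlier is pulled to p99
  prof <- stats::setNames(c(rep(1, 100), 200), paste0("g", 1:101))
  w <- winsorize_profile(prof)
  q99 <- stats::quantile(prof, 0.99, type = 7)
  expect_equal(unname(w["g101"]), unname(q99))
  expect_true(all(w >= stats::quantile(prof, 0.01, type = 7) - 1e-12))
  # the knockout gene stays untouched however extreme
  prof2 <- prof
  prof2["g101"] <- 1 / 117
  w2 <- winsorize_profile(prof2, ko_genes = "g101")
  expect_equal(unname(w2["g101"]), 1 / 117)
  # identical values pass through; winsorization is idempotent
  flat <- stats::setNames(rep(2, 10), paste0("g", 1:10))
  expect_equal(winsorize_profile(flat), flat)
  expect_equal(winsorize_profile(w), w)
  # order preserved (non-strict)
  expect_true(all(diff(w[order(prof)]) >= -1e-12))
  expect_error(winsorize_profile(c(g1 = 1)), ">= 2")
  expect_error(winsorize_profile(c(g1 = 1, g2 = -1)), "> 0")
})

test_that("bound scaling multiplies through the GPR and keeps sign structure", {
  m <- TOY$model
  # all factors 1: untouched
  ones <- stats::setNames(rep(1, length(m$genes)), m$genes)
  expect_equal(scale_bounds(m, ones)$rxns, m$rxns)
  # isoenzymes take the maximum fold
  f <- ones; f[c("gGLY1A", "gGLY1B")] <- c(0.1, 2)
  m2 <- scale_bounds(m, f)
  expect_equal(m2$rxns["HXK", "ub"], 2000)
  # a reversible reaction scales both bounds
  f2 <- ones
  m3 <- m
  m3$rxns["CO2t", "gpr"] <- "gX1"
  m3$gprs$CO2t <- parse_gpr("gX1")
  m3$genes <- union(m3$genes, "gX1")
  m4 <- scale_bounds(m3, c(f2, gX1 = 0.5))
  expect_equal(unlist(m4$rxns["CO2t", c("lb", "ub")]),
               c(lb = -500, ub = 500))
  expect_true(all(m4$rxns$lb <= m4$rxns$ub))
  # knocked-out model genes close their reactions on top of scaling
  m5 <- scale_bounds(m, ones, ko_genes = "gZWF1")
  expect_equal(m5$rxns["PPP", "ub"], 0)
})

test_that("strain growth prediction matches the planted bound-scaling oracle", {
  wt <- TOY$truth$max_growth
  ones <- stats::setNames(rep(1, length(TOY$model$genes)), TOY$model$genes)
  # wildtype profile reproduces parent growth
  res <- predict_strain_growth(TOY$model, list(
    list(id = "wt", ko_genes = character(0), folds = ones)))
  expect_equal(res$growth, wt, tolerance = 1e-8)
  # halving the sole glucose-transporter gene halves carbon-limited growth
  half <- ones; half[TOY$truth$glc_gene] <- 0.5
  res2 <- predict_strain_growth(TOY$model, list(
    list(id = "half", ko_genes = character(0), folds = half)), winsorize = FALSE)
  expect_equal(res2$growth, wt / 2, tolerance = 1e-6)
  # knocking out a planted essential gene abolishes growth
  res3 <- predict_strain_growth(TOY$model, list(
    list(id = "ko", ko_genes = "gZWF1", folds = ones)))
  expect_equal(res3$growth, 0, tolerance = 1e-9)
})

test_that("predicted growth recovers planted effects across synthetic strains", {
  ko <- make_knockout_profiles(TOY, n_strains = 40, seed = 17)
  res <- predict_strain_growth(TOY$model, ko$strains)
  planted <- ko$truth$planted_growth[res$strain]
  expect_gte(stats::cor(res$growth, planted), 0.9)
  # correlation against measured relative doubling times after the
  # reciprocal transform
  cg <- correlate_growth(stats::setNames(res$growth, res$strain),
                         stats::setNames(ko$meta$rel_doubling_time, ko$meta$strain))
  expect_gte(cg$r, 0.9)
  expect_lt(cg$p_value, 1e-6)
})

test_that("growth correlation needs variance and enough strains", {
  pred <- c(s1 = 0.2, s2 = 0.4, s3 = 0.8)
  meas <- 1 / pred # doubling time exactly reciprocal
  expect_equal(correlate_growth(pred, meas)$r, 1, tolerance = 1e-12)
  expect_error(correlate_growth(pred[1:2], meas[1:2]), ">= 3")
  expect_error(correlate_growth(c(s1 = 1, s2 = 1, s3 = 1), meas), "variance")
})

test_that("tightening all bounds can only lower the optimum", {
  set.seed(23)
  ones <- stats::setNames(rep(1, length(TOY$model$genes)), TOY$model$genes)
  for (i in 1:5) {
    f <- ones * stats::runif(length(ones), 0.3, 1)
    g <- fba(scale_bounds(TOY$model, f))$objective
    expect_lte(g, TOY$truth$max_growth + 1e-8)
  }
})
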