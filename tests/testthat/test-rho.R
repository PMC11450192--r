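test_that("directional consistency selects exactly the qualifying genes", {
  m <- TOY$model
  rxns <- m$rxns$id
  fa <- stats::setNames(rep(1, length(rxns)), rxns)
  fb <- fa
  pa <- stats::setNames(rep(1, length(m$genes)), m$genes)
  pb <- pa
  # higher protein and higher flux on its only reaction: selected
  pa["gGLY2"] <- 2; fa["PYK"] <- 3
  # higher protein, all fluxes lower: not selected
  pa["gZWF1"] <- 2; fa["PPP"] <- 0.5
  sel <- directional_consistency(m, fa, fb, pa, pb)
  expect_true("gGLY2" %in% sel)
  expect_false("gZWF1" %in% sel)
  # exhaustive-scan oracle over all genes
  oracle <- Filter(function(g) {
    if (!(pa[g] > pb[g])) return(FALSE)
    rids <- rxns[vapply(m$gprs, function(tr) !is.null(tr) && g %in% gpr_genes(tr), NA)]
    any(abs(fa[rids]) > abs(fb[rids]))
  }, m$genes)
  expect_setequal(sel, oracle)
})

test_that("rho recovers proportionality, constancy and planted power laws", {
  fp0 <- make_flux_protein_series(TOY, sigma = 0, seed = 5)
  rec <- compute_rho(TOY$model, fp0$flux, fp0$protein)
  planted <- fp0$truth$rho[rec$reaction]
  expect_equal(rec$rho, unname(planted), tolerance = 1e-9)
  # flux exactly proportional to protein: rho = 1
  expect_equal(rec$rho[rec$reaction == "PYK"], 1, tolerance = 1e-9)
  # constant flux, varying protein: rho = 0
  flux <- fp0$flux; flux["GDH", ] <- 2
  rec0 <- compute_rho(TOY$model, flux, fp0$protein)
  expect_equal(rec0$rho[rec0$reaction == "GDH"], 0, tolerance = 1e-12)
  # noisy planted slope lands near its target
  fp <- make_flux_protein_series(TOY, sigma = 0.1, seed = 6)
  recn <- compute_rho(TOY$model, fp$flux, fp$protein)
  expect_lt(abs(recn$rho[recn$reaction == "PPP"] - 0.6), 0.15)
})

test_that("rho is invariant to protein unit rescaling", {
  fp <- make_flux_protein_series(TOY, sigma = 0.05, seed = 8)
  r1 <- compute_rho(TOY$model, fp$flux, fp$protein)
  r2 <- compute_rho(TOY$model, fp$flux, fp$protein * 1e3)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-9)
})

test_that("complex-min and isoenzyme-average rules compose as stated", {
  fp0 <- make_flux_protein_series(TOY, sigma = 0, seed = 5)
  rec <- compute_rho(TOY$model, fp0$flux, fp0$protein)
  # complex: the planted limiting subunit determines the slope
  tca <- rec[rec$reaction == "TCA", ]
  expect_equal(tca$rule, "complex-min")
  lim <- apply(fp0$protein[c("gTCA1", "gTCA2"), ], 2, min)
  expect_equal(lim, fp0$protein["gTCA1", ]) # planted limiting subunit
  # isoenzymes: reaction rho is exactly the mean of per-protein slopes
  hxk <- rec[rec$reaction == "HXK", ]
  expect_equal(hxk$rule, "isoenzyme-average")
  betas <- fp0$truth$iso_slopes$HXK
  expect_equal(hxk$rho, mean(betas), tolerance = 1e-9)
})

test_that("the five-of-twelve joint nonzero filter drops sparse reactions", {
  fp0 <- make_flux_protein_series(TOY, sigma = 0, seed = 5)
  flux <- fp0$flux
  flux["GPD", 1:8] <- 0 # nonzero in only 4 of 12 conditions
  rec <- compute_rho(TOY$model, flux, fp0$protein)
  expect_false("GPD" %in% rec$reaction)
  flux2 <- fp0$flux
  flux2["GPD", 1:7] <- 0 # exactly 5 remain: kept
  rec2 <- compute_rho(TOY$model, flux2, fp0$protein)
  expect_true("GPD" %in% rec2$reaction)
  expect_equal(rec2$n[rec2$reaction == "GPD"], 5L)
  # sign-changing fluxes are excluded from the log regression
  flux3 <- fp0$flux
  flux3["GPD", 1] <- -flux3["GPD", 1]
  expect_false("GPD" %in% compute_rho(TOY$model, flux3, fp0$protein)$reaction)
})

test_that("high-rho fractions count planted mixtures exactly", {
  rec <- data.frame(reaction = paste0("r", 1:10),
                    rho = c(rep(0.9, 1), rep(0.1, 9)), n = 12,
                    rule = "single", genes = "g")
  expect_equal(high_rho_fraction(rec), 0.1)
  rec$rho <- 1
  expect_equal(high_rho_fraction(rec), 1)
  rec$rho <- 0
  expect_equal(high_rho_fraction(rec), 0)
  expect_error(high_rho_fraction(rec[0, ]), "no regulation")
})
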