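test_that("FBA solves hand-derivable chains and scales linearly", {
  m <- micro_chain(uptake = 10)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5) # yield 1/2 x uptake 10
  expect_equal(max(abs(stoich_matrix(m) %*% sol$fluxes)), 0, tolerance = 1e-9)
  # doubling the uptake bound doubles the optimum on a carbon-limited chain
  m2 <- micro_chain(uptake = 20)
  expect_equal(fba(m2)$objective, 2 * sol$objective)
  # all exchanges closed: nothing to eat
  m0 <- apply_medium(m, stats::setNames(numeric(0), character(0)))
  expect_equal(fba(m0)$objective, 0)
})

test_that("FBA optimum is invariant under reordering and reversible splitting", {
  m <- TOY$model
  ref <- fba(m)$objective
  set.seed(5)
  perm <- sample(nrow(m$rxns))
  m2 <- m
  m2$rxns <- m2$rxns[perm, ]
  m2$stoich <- m2$stoich[m2$rxns$id]
  m2$gprs <- m2$gprs[m2$rxns$id]
  expect_equal(fba(m2)$objective, ref, tolerance = 1e-6)
  # split a reversible transport into two irreversible halves
  m3 <- m
  for (rid in c("CO2t", "PIt")) {
    fwd <- m3$stoich[[rid]]
    nid <- paste0(rid, "_rev")
    m3$stoich[[nid]] <- -fwd
    m3$rxns[nid, ] <- m3$rxns[rid, ]
    m3$rxns[nid, "id"] <- nid
    m3$rxns[nid, c("lb", "ub")] <- c(0, 1000)
    m3$rxns[rid, "lb"] <- 0
    m3$gprs[nid] <- list(NULL)
  }
  expect_equal(fba(m3)$objective, ref, tolerance = 1e-6)
})

test_that("applying a medium controls exactly the listed uptakes", {
  m <- TOY$model
  glc_only <- apply_medium(m, c(EX_glc = 5))
  ex <- find_exchanges(glc_only)
  lbs <- glc_only$rxns[ex, "lb"]
  expect_equal(sum(lbs < 0), 1L)
  expect_equal(glc_only$rxns["EX_glc", "lb"], -5)
  # idempotent
  again <- apply_medium(glc_only, c(EX_glc = 5))
  expect_equal(again$rxns, glc_only$rxns)
  expect_error(apply_medium(m, c(HXK = 1)), "exchange")
  # empty medium starves the model
  expect_equal(fba(apply_medium(m, stats::setNames(numeric(0), character(0))))$objective,
               0, tolerance = 1e-9)
})

test_that("pFBA reaches the FBA optimum with minimal total flux", {
  m <- micro_two_routes()
  sol <- pfba(m)
  expect_equal(sol$objective, 10) # all source routed to sink
  # the one-reaction route wins; the two-reaction route carries nothing
  expect_equal(unname(sol$fluxes["R1"]), 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["R2a"]), 0, tolerance = 1e-8)
  # single-path model: pFBA flux equals FBA flux
  ch <- micro_chain()
  expect_equal(pfba(ch)$fluxes, fba(ch)$fluxes, tolerance = 1e-8)
  # minimisation contract on the toy: no alternate optimum beats pFBA's sum
  toy_sol <- pfba(TOY$model)
  expect_equal(toy_sol$objective, fba(TOY$model)$objective, tolerance = 1e-8)
  expect_lte(toy_sol$sum_abs_flux, sum(abs(fba(TOY$model)$fluxes)) + 1e-6)
})

test_that("gene deletion honours the two published modes", {
  m <- micro_two_routes()
  # isozyme-style survival only in GPR mode
  iso <- m
  iso$rxns["R1", "gpr"] <- "g1 or g9"
  iso$gprs$R1 <- parse_gpr("g1 or g9")
  iso$genes <- union(iso$genes, "g9")
  kept <- delete_genes(iso, "g1", mode = "gpr")
  expect_equal(kept$rxns["R1", "ub"], 1000)
  removed <- delete_genes(iso, "g1", mode = "reaction_removal")
  expect_equal(removed$rxns["R1", c("lb", "ub")], data.frame(lb = 0, ub = 0),
               ignore_attr = TRUE)
  # complexes close in both modes
  cx <- m
  cx$rxns["R1", "gpr"] <- "g1 and g9"
  cx$gprs$R1 <- parse_gpr("g1 and g9")
  cx$genes <- union(cx$genes, "g9")
  for (mode in c("gpr", "reaction_removal")) {
    expect_equal(delete_genes(cx, "g9", mode = mode)$rxns["R1", "ub"], 0)
  }
  # deleting a gene absent from all GPRs is a legal no-op
  expect_equal(delete_genes(m, "gNOT_IN_MODEL")$rxns, m$rxns)
})

test_that("deletion grids are symmetric with single deletions on the diagonal", {
  genes <- c("gGLY1A", "gGLY1B", "gADH1", "gGPD1")
  grid <- double_gene_deletion(TOY$model, genes, mode = "gpr")
  expect_equal(grid$growth, t(grid$growth))
  for (g in genes) {
    single <- fba(delete_genes(TOY$model, g, "gpr"))$objective
    expect_equal(grid$growth[g, g], single, tolerance = 1e-8)
  }
  # genes absent from any GPR leave growth at wildtype
  grid2 <- double_gene_deletion(TOY$model, c("gNOPE1", "gNOPE2"), mode = "gpr")
  expect_equal(unname(grid2$growth["gNOPE1", "gNOPE2"]), grid2$wildtype)
  # reaction removal is at least as destructive as GPR evaluation
  gridr <- double_gene_deletion(TOY$model, genes, mode = "reaction_removal")
  expect_true(all(grid$growth - gridr$growth >= -1e-9))
})

test_that("lethality classification and confusion metrics are forced arithmetic", {
  g <- matrix(c(0, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  lab <- classify_lethality(g, wildtype = 1, cutoff = 0.01)
  expect_equal(unname(lab["a", "a"]), "lethal")
  expect_equal(unname(lab["b", "b"]), "viable")
  truth <- c(p1 = "lethal", p2 = "lethal", p3 = "viable", p4 = "viable")
  pred_all_viable <- stats::setNames(rep("viable", 4), names(truth))
  cm <- confusion_metrics(pred_all_viable, truth)
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$recall, 0)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_error(confusion_metrics(truth[1:3], truth), "keys differ")
  # hand-tabulated mixed case
  pred <- c(p1 = "lethal", p2 = "viable", p3 = "lethal", p4 = "viable")
  cm2 <- confusion_metrics(pred, truth)
  expect_equal(unlist(cm2[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(cm2$precision, 0.5)
})

test_that("substrate screening opens one candidate source at a time", {
  base <- TOY$truth$medium[setdiff(names(TOY$truth$medium), "EX_nh4")]
  res <- substrate_usage(TOY$model, c("EX_nh4", "EX_gln", "EX_urea"), "N", base)
  expect_true(res[["EX_nh4"]])
  expect_true(res[["EX_gln"]])
  expect_false(res[["EX_urea"]]) # planted: no urease, nitrogen locked
  expect_error(substrate_usage(TOY$model, "HXK", "N", base), "exchange")
  expect_length(substrate_usage(TOY$model, character(0), "N", base), 0L)
})

test_that("flux sampling is deterministic and respects the polytope", {
  # a model pinned to a single feasible point returns that point always
  ch <- micro_chain()
  ch$rxns["EX_a", c("lb", "ub")] <- -10
  s <- sample_fluxes(ch, n = 20, seed = 1, thinning = 5)
  expect_equal(max(apply(s$samples, 2, stats::sd)), 0, tolerance = 1e-9)
  expect_equal(unname(s$mean["GROW"]), 5, tolerance = 1e-8)
  # 1-D free reaction: uniform mean near the midpoint
  m1 <- ch
  m1$rxns["EX_a", c("lb", "ub")] <- c(-10, 0)
  s1 <- sample_fluxes(m1, n = 400, seed = 3, thinning = 10)
  expect_gt(unname(s1$mean["GROW"]), 1.5)
  expect_lt(unname(s1$mean["GROW"]), 3.5)
  # same seed, bit-identical; different seed, different draw
  s2 <- sample_fluxes(m1, n = 400, seed = 3, thinning = 10)
  expect_identical(s1$mean, s2$mean)
  s3 <- sample_fluxes(m1, n = 400, seed = 4, thinning = 10)
  expect_false(identical(s1$mean, s3$mean))
  # every sample satisfies S v = 0 and the bounds
  S <- stoich_matrix(m1)
  expect_lt(max(abs(S %*% t(s1$samples))), 1e-8)
  expect_true(all(t(s1$samples) >= m1$rxns$lb - 1e-9))
  expect_true(all(t(s1$samples) <= m1$rxns$ub + 1e-9))
})
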