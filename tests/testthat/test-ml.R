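make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(centers), function(i)
    matrix(rnorm(n_per * 4, centers[[i]], sd), n_per)))
  list(x = x, y = factor(rep(names(centers), each = n_per)))
}

test_that("linear-kernel kPCA reproduces classical PCA up to sign", {
  b <- make_blobs(30, list(a = 0, b = 3), seed = 5)
  k <- kpca_features(b$x, 3, kernel = "vanilladot")
  p <- stats::prcomp(scale(b$x))$x[, 1:3]
  for (j in 1:3) expect_gt(abs(stats::cor(k[, j], p[, j])), 1 - 1e-6)
  # duplicated samples yield identical feature rows
  x2 <- rbind(b$x, b$x[1, ])
  k2 <- kpca_features(x2, 2, kernel = "vanilladot")
  expect_equal(unname(k2[1, ]), unname(k2[nrow(k2), ]), tolerance = 1e-8)
  expect_error(kpca_features(b$x[1:5, ], 10), "n_components")
  # one component separates two well-separated clusters perfectly
  k1 <- kpca_features(b$x, 1, kernel = "vanilladot")
  expect_true(max(k1[b$y == "a", 1]) < min(k1[b$y == "b", 1]) ||
                min(k1[b$y == "a", 1]) > max(k1[b$y == "b", 1]))
})

test_that("separable classes are learned by every algorithm", {
  b <- make_blobs(40, list(a = 0, b = 4), seed = 9)
  for (alg in c("svm", "logistic", "naive_bayes", "random_forest", "knn", "mlp")) {
    rep <- split_and_tune(b$x, b$y, alg, seed = 3)
    expect_gte(rep$metrics$accuracy, 0.95)
    expect_gte(rep$roc$macro_auc, 0.95)
    # train/test disjoint and metrics computed on held-out data only
    expect_length(intersect(rep$train_idx, rep$test_idx), 0L)
    expect_equal(sort(c(rep$train_idx, rep$test_idx)), seq_along(b$y))
  }
})

test_that("splitting is stratified, seeded and reproducible", {
  b <- make_blobs(30, list(a = 0, b = 1, c = 2), seed = 2)
  r1 <- split_and_tune(b$x, b$y, "naive_bayes", seed = 11)
  r2 <- split_and_tune(b$x, b$y, "naive_bayes", seed = 11)
  expect_identical(r1$train_idx, r2$train_idx)
  expect_identical(r1$metrics, r2$metrics)
  # stratification: every class appears in train at ~70%
  tab <- table(b$y[r1$train_idx])
  expect_true(all(tab == 21))
  expect_error(split_and_tune(b$x[c(1:30, 31:34), ], b$y[c(1:30, 31:34)],
                              "naive_bayes", k = 5),
               "smaller k")
})

test_that("ROC/AUC equals exhaustive pair counting on a small fixture", {
  scores <- cbind(pos = c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1))
  scores <- cbind(scores, neg = 1 - scores[, 1])
  labels <- factor(c("pos", "pos", "neg", "pos", "neg",
                     "pos", "neg", "neg", "pos", "neg"))
  r <- roc_auc(scores, labels)
  # Mann-Whitney normalisation: share of (pos, neg) pairs ranked correctly
  s <- scores[, "pos"]
  pos <- which(labels == "pos"); neg <- which(labels == "neg")
  mw <- mean(outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(unname(r$auc["pos"]), mw, tolerance = 1e-12)
  # perfect scores give AUC 1 per class
  perf <- cbind(pos = as.numeric(labels == "pos"),
                neg = as.numeric(labels == "neg"))
  expect_equal(unname(roc_auc(perf, labels)$auc), c(1, 1))
  expect_error(roc_auc(scores, factor(rep("pos", 10))), "2 classes")
})

test_that("the condition-classification pipeline recovers planted labels and
           collapses to chance when labels are permuted", {
  parent <- make_scgem_parent(TOY)
  sc <- make_single_cell_profiles(TOY, n_stressed = 16, n_unstressed = 16,
                                  dropout = 0, seed = 71)
  ctx <- batch_contexts(parent, sc$profiles)
  gf <- context_growth_and_fluxes(parent, ctx)
  feats <- cbind(t(gf$fluxes),
                 n_rxns = vapply(ctx, function(c) length(c$kept_rxns), 0))
  labels <- sc$labels[rownames(feats)]
  kp <- kpca_features(feats, 2, kernel = "vanilladot", seed = 8)
  rep <- split_and_tune(kp, labels, "random_forest", seed = 8)
  expect_gte(rep$metrics$accuracy, 0.9)
  # permuted labels on the same features: accuracy near chance, averaged
  # over several deterministic splits
  accs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    perm <- sample(labels)
    split_and_tune(kp, perm, "random_forest", seed = 2000 + s)$metrics$accuracy
  }, 0.0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})
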