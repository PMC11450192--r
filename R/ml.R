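# Feature extraction and classification harness.
#
# The module owns the protocol — standardisation, kernel PCA features,
# stratified 70/30 splitting, grid search with k-fold cross-validation, and
# held-out metric computation (accuracy, macro recall/F1, one-vs-rest ROC
# with macro AUC) — while the learners themselves come from the standard R
# machine-learning packages.

#' Kernel PCA features
#'
#' Standardises the columns and projects onto the leading kernel principal
#' components (kernlab). A linear kernel on mean-centred data reproduces
#' classical PCA scores up to sign.
#'
#' @param x Sample x feature numeric matrix (no missing values).
#' @param n_components Number of components (< number of samples).
#' @param kernel kernlab kernel name, default `"rbfdot"`; use `"vanilladot"`
#'   for linear.
#' @param kpar Kernel parameter list (default `"automatic"` for rbf).
#' @param seed Integer seed (kPCA is deterministic; kept for interface
#'   uniformity and any kernel-parameter estimation).
#' @return Sample x component score matrix.
#' @export
kpca_features <- function(x, n_components, kernel = "rbfdot", kpar = NULL, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (n_components > nrow(x) - 1L) {
    stop("n_components must be < number of samples", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  if (is.null(kpar)) kpar <- if (kernel == "rbfdot") "automatic" else list()
  with_seed(seed, {
    kp <- kernlab::kpca(x, kernel = kernel, kpar = kpar, features = n_components)
    scores <- kernlab::rotated(kp)
  })
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("KPC", seq_len(ncol(scores)))
  scores
}

# learner registry: fit(x, y, params) -> model; prob(model, x) -> class-prob matrix
.LEARNERS <- list(
  svm = list(
    grid = list(cost = c(0.1, 1, 10)),
    fit = function(x, y, p) e1071::svm(x, y, kernel = "radial", cost = p$cost,
                                       probability = TRUE),
    prob = function(m, x) attr(stats::predict(m, x, probability = TRUE), "probabilities")
  ),
  mlp = list(
    grid = list(size = c(3, 8), decay = c(0, 0.1)),
    fit = function(x, y, p) nnet::nnet(x, nnet::class.ind(y), size = p$size,
                                       decay = p$decay, softmax = TRUE,
                                       maxit = 200, trace = FALSE),
    prob = function(m, x) stats::predict(m, x)
  ),
  naive_bayes = list(
    grid = list(laplace = c(0, 1)),
    fit = function(x, y, p) e1071::naiveBayes(x, y, laplace = p$laplace),
    prob = function(m, x) stats::predict(m, x, type = "raw")
  ),
  random_forest = list(
    grid = list(ntree = c(200), mtry_frac = c(0.33, 0.8)),
    fit = function(x, y, p) randomForest::randomForest(
      x, y, ntree = p$ntree, mtry = max(1, floor(p$mtry_frac * ncol(x)))),
    prob = function(m, x) stats::predict(m, x, type = "prob")
  ),
  knn = list(
    grid = list(k = c(1, 3, 7)),
    fit = function(x, y, p) list(x = x, y = y, k = p$k),
    prob = function(m, x) {
      pr <- class::knn(m$x, x, m$y, k = m$k, prob = TRUE)
      lev <- levels(m$y)
      out <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
      win <- attr(pr, "prob")
      for (i in seq_along(pr)) {
        out[i, ] <- (1 - win[i]) / max(1, length(lev) - 1)
        out[i, as.character(pr[i])] <- win[i]
      }
      out
    }
  ),
  logistic = list(
    grid = list(decay = c(0, 0.01)),
    fit = function(x, y, p) nnet::multinom(y ~ ., data = data.frame(x, y = y),
                                           decay = p$decay, maxit = 200,
                                           trace = FALSE),
    prob = function(m, x) {
      pr <- stats::predict(m, data.frame(x), type = "probs")
      if (is.null(dim(pr))) { # binomial case: vector of P(second level)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- m$lev
      }
      pr
    }
  )
)

stratified_indices <- function(y, frac) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    n <- max(1L, round(frac * length(idx)))
    sample(idx, n)
  }), use.names = FALSE)
}

expand_grid_list <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

macro_metrics <- function(pred, truth) {
  lev <- levels(truth)
  per <- vapply(lev, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else 0
    c(recall = rec, f1 = f1, class_acc = rec)
  }, numeric(3))
  list(accuracy = mean(pred == truth),
       macro_recall = mean(per["recall", ], na.rm = TRUE),
       macro_f1 = mean(per["f1", ], na.rm = TRUE),
       per_class_accuracy = per["class_acc", ])
}

#' Stratified split, grid-tuned fit, and held-out evaluation
#'
#' Stratified 70/30 train/test split with a fixed seed; exhaustive grid
#' search over hyperparameters by k-fold cross-validation on the training
#' portion; final metrics (accuracy, macro recall, macro F1, per-class
#' accuracy, one-vs-rest ROC and macro AUC) on the untouched test portion.
#'
#' @param x Sample x feature matrix.
#' @param y Class labels (factor or coercible).
#' @param algorithm One of `"svm"`, `"mlp"`, `"naive_bayes"`,
#'   `"random_forest"`, `"knn"`, `"logistic"`.
#' @param grid Named list of hyperparameter vectors; default per algorithm.
#' @param k Cross-validation folds, default 5.
#' @param train_frac Training fraction, default 0.7.
#' @param seed Integer seed governing split, folds and stochastic learners.
#' @return List of class `ml_report`: `algorithm`, `best_params`, `metrics`
#'   (test-set), `roc` (from [roc_auc()]), `train_idx`, `test_idx`.
#' @export
split_and_tune <- function(x, y, algorithm = names(.LEARNERS), grid = NULL,
                           k = 5, train_frac = 0.7, seed = 1) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need >= 2 classes", call. = FALSE)
  spec <- .LEARNERS[[algorithm]]
  grid <- grid %||% spec$grid
  with_seed(seed, {
    train_idx <- sort(stratified_indices(y, train_frac))
    test_idx <- setdiff(seq_along(y), train_idx)
    ytr <- droplevels(y[train_idx])
    if (min(table(ytr)) < k) {
      stop("a class has fewer than k = ", k,
           " training members; use a smaller k", call. = FALSE)
    }
    xtr <- x[train_idx, , drop = FALSE]
    folds <- integer(length(ytr))
    for (idx in split(seq_along(ytr), ytr)) {
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }

    cand <- expand_grid_list(grid)
    cv_acc <- vapply(cand, function(p) {
      accs <- vapply(seq_len(k), function(fold) {
        tr <- folds != fold
        m <- spec$fit(xtr[tr, , drop = FALSE], droplevels(ytr[tr]), p)
        pr <- spec$prob(m, xtr[!tr, , drop = FALSE])
        pred <- colnames(pr)[max.col(pr, ties.method = "first")]
        mean(pred == as.character(ytr[!tr]))
      }, 0.0)
      mean(accs)
    }, 0.0)
    best <- cand[[which.max(cv_acc)]]

    final <- spec$fit(xtr, ytr, best)
    prob <- spec$prob(final, x[test_idx, , drop = FALSE])
    prob <- prob[, levels(y), drop = FALSE]
  })
  yte <- y[test_idx]
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")], levels(y))
  metrics <- macro_metrics(pred, yte)
  roc <- roc_auc(prob, yte)
  structure(list(algorithm = algorithm, best_params = best, metrics = metrics,
                 roc = roc, train_idx = train_idx, test_idx = test_idx,
                 model = final),
            class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat(sprintf("<ml_report> %s: test accuracy %.3f, macro F1 %.3f, macro AUC %.3f\n",
              x$algorithm, x$metrics$accuracy, x$metrics$macro_f1, x$roc$macro_auc))
  invisible(x)
}

#' One-vs-rest ROC curves and macro AUC
#'
#' Per class, treats that class as positive, sweeps all score thresholds and
#' integrates the ROC curve by the trapezoid rule; the macro AUC is the mean
#' of the per-class AUCs.
#'
#' @param scores Sample x class score/probability matrix (named columns).
#' @param labels True class labels.
#' @return List with `per_class` (list of data.frames fpr/tpr), `auc` (named
#'   per-class), `macro_auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 classes", call. = FALSE)
  lev <- colnames(scores)
  curves <- list(); aucs <- stats::setNames(numeric(0), character(0))
  for (cl in lev) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) next
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    # collapse ties: keep the last point at each distinct score
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tp[keep] / sum(pos))
    fpr <- c(0, fp[keep] / sum(!pos))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    curves[[cl]] <- data.frame(fpr = fpr, tpr = tpr)
    aucs[cl] <- auc
  }
  list(per_class = curves, auc = aucs, macro_auc = mean(aucs))
}
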