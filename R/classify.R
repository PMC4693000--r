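#' SVM configuration for structural class prediction
#'
#' Holds the RBF-SVM hyperparameters and the grid-search / cross-validation
#' settings.  The defaults C = 2 and gamma = 2^-9 are the pair obtained by
#' grid search with fifteenfold cross-validation on the PCA-reduced 224D
#' representation of the 1189 benchmark; the grids span integer powers of 2
#' over C in [2^-5, 2^15] and gamma in [2^-15, 2^5].
#'
#' @param C Cost parameter (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @param C_grid,gamma_grid Candidate grids for [grid_search()].
#' @param cv_folds Number of stratified cross-validation folds.
#' @param seed Seed used for fold shuffling (recorded in outputs).
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 2, gamma = 2^-9,
                       C_grid = 2^(-5:15), gamma_grid = 2^(-15:5),
                       cv_folds = 15L, seed = 42L) {
  stopifnot(C > 0, gamma > 0, all(C_grid > 0), all(gamma_grid > 0),
            cv_folds >= 2L)
  structure(list(C = C, gamma = gamma,
                 C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "svm_config")
}

validate_training_input <- function(x, y) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values in training data")
  }
  if (!is.factor(y)) {
    lev <- if (all(y %in% structural_classes())) structural_classes()
    else sort(unique(as.character(y)))
    y <- factor(as.character(y), levels = lev)
  }
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  missing <- levels(y)[tabulate(y, nbins = nlevels(y)) == 0L]
  if (length(missing) > 0L) {
    stop("training error: class(es) absent from the data: ",
         paste(missing, collapse = ", "))
  }
  list(x = x, y = y)
}

#' Train a one-vs-all RBF-SVM ensemble
#'
#' Converts the four-class problem into four binary class-vs-rest RBF-SVMs
#' (libsvm via e1071, `scale = FALSE`).  Prediction assigns the class whose
#' binary real-valued decision score is largest, with ties broken by class
#' order.
#'
#' @param x Numeric N x k feature matrix.
#' @param y Class labels (all classes must be present).
#' @param config An [svm_config()]; `C` and `gamma` are used.
#' @return Object of class `ova_svm` holding the four binary machines.
#' @export
train_ova_svm <- function(x, y, config = svm_config()) {
  v <- validate_training_input(x, y)
  models <- lapply(levels(v$y), function(cls) {
    yk <- factor(ifelse(v$y == cls, "pos", "rest"),
                 levels = c("pos", "rest"))
    e1071::svm(v$x, yk, type = "C-classification", kernel = "radial",
               cost = config$C, gamma = config$gamma, scale = FALSE)
  })
  names(models) <- levels(v$y)
  structure(list(models = models, classes = levels(v$y),
                 C = config$C, gamma = config$gamma),
            class = "ova_svm")
}

# real-valued class-vs-rest decision scores, oriented so larger = more
# likely the positive class (libsvm's sign depends on label order, so the
# orientation is read off the decision-value column name)
decision_scores <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  scores <- vapply(object$classes, function(cls) {
    p <- stats::predict(object$models[[cls]], newdata,
                        decision.values = TRUE)
    dv <- attr(p, "decision.values")
    flip <- !startsWith(colnames(dv)[1L], "pos")
    if (flip) -dv[, 1L] else dv[, 1L]
  }, numeric(nrow(newdata)))
  matrix(scores, nrow = nrow(newdata),
         dimnames = list(rownames(newdata), object$classes))
}

#' @describeIn train_ova_svm Predict structural classes; returns a factor
#'   (or, with `decision = TRUE`, a list with the N x 4 score matrix).
#' @param object A fitted `ova_svm` ensemble.
#' @param newdata Numeric matrix of feature rows to classify.
#' @param decision Also return the decision-score matrix.
#' @param ... Unused.
#' @export
predict.ova_svm <- function(object, newdata, decision = FALSE, ...) {
  sc <- decision_scores(object, newdata)
  pred <- factor(object$classes[apply(sc, 1L, which.max)],
                 levels = object$classes)
  if (decision) list(class = pred, scores = sc) else pred
}

# stratified fold assignment, deterministic given the seed
stratified_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validated overall accuracy of the one-vs-all ensemble
#'
#' @param x,y Features and labels.
#' @param config An [svm_config()]; folds are stratified by class and
#'   shuffled with `config$seed`.
#' @param folds Optional precomputed fold assignment vector.
#' @return Mean overall accuracy across folds.
#' @export
cv_accuracy <- function(x, y, config = svm_config(), folds = NULL) {
  v <- validate_training_input(x, y)
  if (length(v$y) < config$cv_folds) {
    stop("fewer samples than cross-validation folds")
  }
  if (is.null(folds)) {
    folds <- stratified_folds(v$y, config$cv_folds, config$seed)
  }
  correct <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- train_ova_svm(v$x[!test, , drop = FALSE], v$y[!test], config)
    pred <- predict(fit, v$x[test, , drop = FALSE])
    correct <- correct + sum(pred == v$y[test])
  }
  correct / length(v$y)
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair of the configured power-of-2 grids by
#' stratified k-fold cross-validated overall accuracy (default fifteenfold)
#' and returns the maximiser.  Ties are broken towards smaller C, then
#' smaller gamma (the grids are scanned in ascending order and only a
#' strictly better accuracy replaces the incumbent).  The same fold
#' assignment is reused for every pair.
#'
#' @param x,y Features and labels.
#' @param config An [svm_config()] supplying the grids, fold count and
#'   seed.
#' @return List with `C`, `gamma`, `accuracy`, and the full `table` of
#'   grid accuracies.
#' @export
grid_search <- function(x, y, config = svm_config()) {
  v <- validate_training_input(x, y)
  if (length(v$y) < config$cv_folds) {
    stop("fewer samples than cross-validation folds")
  }
  folds <- stratified_folds(v$y, config$cv_folds, config$seed)
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), ]
  grid$accuracy <- NA_real_
  best <- list(C = NA_real_, gamma = NA_real_, accuracy = -Inf)
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    cfg$C <- grid$C[r]
    cfg$gamma <- grid$gamma[r]
    acc <- cv_accuracy(v$x, v$y, cfg, folds = folds)
    grid$accuracy[r] <- acc
    if (acc > best$accuracy) {
      best <- list(C = cfg$C, gamma = cfg$gamma, accuracy = acc)
    }
  }
  best$table <- grid
  best
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each protein is singled out in turn and predicted by an ensemble trained
#' on all the others, until every protein has been singled out once.  With
#' `pca_scope = "global"` (the default) the PCA reduction, when requested
#' via `k`, is fitted once on the full dataset before the jackknife —
#' mirroring a protocol that selects the reduced space on the whole
#' benchmark; `"fold-safe"` refits the PCA inside every fold so the
#' held-out protein never influences the subspace, at the cost of N PCA
#' fits.
#'
#' @param x Numeric N x p feature matrix (full 700D features when `k` is
#'   given, otherwise any representation to use directly).
#' @param y Class labels.
#' @param config An [svm_config()]; its fixed `C`/`gamma` pair is reused in
#'   every fold.
#' @param k Optional number of principal components; `NULL` skips the
#'   reduction.
#' @param pca_scope `"global"` or `"fold-safe"`, see Details.
#' @param scale Passed to [fit_pca()].
#' @return Factor of N leave-one-out predictions (names = row names).
#' @export
jackknife <- function(x, y, config = svm_config(), k = NULL,
                      pca_scope = c("global", "fold-safe"),
                      scale = FALSE) {
  pca_scope <- match.arg(pca_scope)
  if (nrow(as.matrix(x)) < 5L) {
    stop("jackknife requires at least 5 proteins")
  }
  v <- validate_training_input(x, y)
  n <- nrow(v$x)
  if (!is.null(k) && pca_scope == "global") {
    v$x <- fit_pca(v$x, k = k, scale = scale)$scores
  }
  preds <- character(n)
  for (i in seq_len(n)) {
    xtr <- v$x[-i, , drop = FALSE]
    ytr <- v$y[-i]
    xte <- v$x[i, , drop = FALSE]
    if (!is.null(k) && pca_scope == "fold-safe") {
      m <- fit_pca(xtr, k = min(k, nrow(xtr) - 1L), scale = scale)
      xtr <- m$scores
      xte <- apply_pca(m, xte)
    }
    fit <- train_ova_svm(xtr, ytr, config)
    preds[i] <- as.character(predict(fit, xte))
  }
  factor(preds, levels = levels(v$y))
}
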