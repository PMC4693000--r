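test_that("one-vs-all ensemble separates well-separated blobs", {
  blobs <- make_separable_blobs(n_per_class = 10, sd = 0.2, seed = 71)
  fit <- train_ova_svm(blobs$x, blobs$y, svm_config(C = 2, gamma = 0.5))
  pred <- predict(fit, blobs$x)
  expect_equal(mean(pred == blobs$y), 1)
  out <- predict(fit, blobs$x, decision = TRUE)
  expect_equal(dim(out$scores), c(40, 4))
  expect_equal(colnames(out$scores), structural_classes())
})

test_that("training validates class presence and finite features", {
  blobs <- make_separable_blobs(seed = 72)
  keep <- blobs$y != "alpha+beta"
  expect_error(train_ova_svm(blobs$x[keep, ], blobs$y[keep]),
               "absent")
  xbad <- blobs$x
  xbad[1, 1] <- NA
  expect_error(train_ova_svm(xbad, blobs$y), "non-finite")
})

test_that("duplicating every point leaves the decision function intact", {
  blobs <- make_separable_blobs(n_per_class = 8, sd = 0.3, seed = 73)
  cfg <- svm_config(C = 2, gamma = 0.5)
  fit1 <- train_ova_svm(blobs$x, blobs$y, cfg)
  fit2 <- train_ova_svm(rbind(blobs$x, blobs$x), c(blobs$y, blobs$y), cfg)
  probe <- as.matrix(expand.grid(seq(-1, 5, length.out = 7),
                                 seq(-1, 5, length.out = 7)))
  s1 <- predict(fit1, probe, decision = TRUE)$scores
  s2 <- predict(fit2, probe, decision = TRUE)$scores
  expect_equal(s2, s1, tolerance = 1e-6)
})

test_that("grid search honours the printed bounds and tie-breaks", {
  cfg <- svm_config()
  expect_equal(range(cfg$C_grid), c(2^-5, 2^15))
  expect_equal(range(cfg$gamma_grid), c(2^-15, 2^5))
  # single-point grid returns that point
  blobs <- make_separable_blobs(n_per_class = 8, seed = 74)
  one <- svm_config(C_grid = 4, gamma_grid = 0.25, cv_folds = 4)
  res <- grid_search(blobs$x, blobs$y, one)
  expect_equal(res$C, 4)
  expect_equal(res$gamma, 0.25)
  # all-tie degenerate data -> smallest (C, gamma) of the grid
  xconst <- matrix(0, length(blobs$y), 2)
  tie_cfg <- svm_config(C_grid = c(1, 2), gamma_grid = c(0.1, 1),
                        cv_folds = 4)
  res_tie <- grid_search(xconst, blobs$y, tie_cfg)
  expect_equal(res_tie$C, 1)
  expect_equal(res_tie$gamma, 0.1)
  expect_equal(nrow(res_tie$table), 4)
})

test_that("grid search recovers a planted RBF scale to within two steps", {
  # XOR-style geometry: each class is a pair of diagonally opposed blobs,
  # so class-vs-rest is not linearly separable and a near-linear (tiny
  # gamma) kernel fails, while a huge gamma cannot generalise across CV
  # folds; the planted squared scale is ~1/(2 d^2) with d = 4 the
  # inter-class spacing, i.e. gamma ~ 2^-5
  make_xor <- function(n, sd, seed) {
    centers <- list(
      rbind(c(0, 0), c(4, 4)), rbind(c(0, 4), c(4, 0)),
      rbind(c(8, 8), c(12, 12)), rbind(c(8, 12), c(12, 8)))
    withr::with_seed(seed, {
      x <- do.call(rbind, lapply(1:4, function(k) {
        ctr <- centers[[k]][rep(1:2, length.out = n), ]
        ctr + matrix(rnorm(2 * n, 0, sd), n, 2)
      }))
    })
    y <- factor(rep(structural_classes(), each = n),
                levels = structural_classes())
    list(x = x, y = y)
  }
  for (seed in c(7, 75)) {
    b <- make_xor(12, 0.5, seed)
    cfg <- svm_config(C_grid = 2^c(0, 2, 4), gamma_grid = 2^seq(-8, 6, 2),
                      cv_folds = 4, seed = seed)
    res <- grid_search(b$x, b$y, cfg)
    # within two grid steps (step = 2^2) of the planted 2^-5
    expect_gte(res$gamma, 2^-9)
    expect_lte(res$gamma, 2^-1)
    expect_gte(res$accuracy, 0.9)
  }
})

test_that("jackknife returns one leave-one-out prediction per protein", {
  blobs <- make_separable_blobs(n_per_class = 6, sd = 0.25, seed = 76)
  preds <- jackknife(blobs$x, blobs$y, svm_config(C = 2, gamma = 0.5))
  expect_length(preds, 24)
  expect_equal(levels(preds), structural_classes())
  expect_gte(mean(preds == blobs$y), 0.9)
  expect_error(jackknife(blobs$x[1:4, ], blobs$y[1:4]), "at least 5")
})

test_that("jackknife accuracy tracks k-fold CV accuracy on separable data", {
  blobs <- make_separable_blobs(n_per_class = 10, sd = 0.4, seed = 77)
  cfg <- svm_config(C = 2, gamma = 0.5, cv_folds = 5, seed = 77)
  jk <- mean(jackknife(blobs$x, blobs$y, cfg) == blobs$y)
  cv <- cv_accuracy(blobs$x, blobs$y, cfg)
  expect_lte(abs(jk - cv), 0.05)
})

test_that("fold-safe PCA jackknife projects each held-out protein", {
  d <- generate_dataset(synthetic_spec(n_per_class = 3, seed = 78))
  ds <- extract_dataset(d$profiles, d$labels$class)
  preds <- jackknife(ds$x, ds$labels, svm_config(), k = 5,
                     pca_scope = "fold-safe")
  expect_length(preds, nrow(ds$x))
  expect_true(all(!is.na(preds)))
})
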