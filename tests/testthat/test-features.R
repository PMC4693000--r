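test_that("the 700D vector matches the block layout and the full oracle", {
  withr::with_seed(61, {
    p <- random_raw_profile(37)
    v <- extract_features(p)
    expect_length(v, 700)
    expect_equal(unname(v), oracle_full_vector(p$matrix),
                 tolerance = 1e-12)
    # block boundaries in layout order
    prefixes <- sub("\\..*$", "", names(v))
    expect_equal(rle(prefixes)$values,
                 c("csaac", "cscm", "seg2_psep", "seg3_psep",
                   "seg2_act", "seg3_act"))
    expect_equal(rle(prefixes)$lengths, c(20, 20, 200, 180, 160, 120))
  })
})

test_that("group selections give the ablation dimensionalities", {
  withr::with_seed(62, {
    p <- random_raw_profile(45)
    dims <- c(csaac = 20, cscm = 20, csp = 40, seg2_psep = 200,
              seg3_psep = 180, seg2_act = 160, seg3_act = 120,
              segpsep = 380, segact = 280, full = 700)
    for (g in names(dims)) {
      expect_length(extract_features(p, g), dims[[g]])
    }
    expect_length(extract_features(p, c("csp", "seg2_psep")), 240)
    expect_length(extract_features(p, c("csp", "segpsep")), 420)
    expect_length(extract_features(p, c("csp", "segpsep", "seg2_act")),
                  40 + 380 + 160)
    expect_length(extract_features(p, "csp,segpsep,segact"), 700)
    expect_error(extract_features(p, character(0)), "empty")
    expect_error(extract_features(p, "nonsense"), "unknown feature group")
  })
})

test_that("extract_dataset stacks profiles with ids and labels", {
  d <- generate_dataset(synthetic_spec(n_per_class = 2, seed = 3))
  ds <- extract_dataset(d$profiles, d$labels$class)
  expect_equal(dim(ds$x), c(8, 700))
  expect_equal(rownames(ds$x), d$labels$protein_id)
  expect_equal(levels(ds$labels), structural_classes())
  expect_error(extract_dataset(d$profiles, d$labels$class[-1]),
               "length")
})

test_that("feature TSV writer and reader round-trip", {
  d <- generate_dataset(synthetic_spec(n_per_class = 1, seed = 4))
  ds <- extract_dataset(d$profiles, groups = "csp")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(ds$x, path)
  back <- read_features(path)
  expect_equal(back, ds$x, tolerance = 1e-12)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header[1:3], c("protein_id", "csaac.A", "csaac.R"))
})

test_that("PCA projections match an independent eigendecomposition", {
  withr::with_seed(63, {
    x <- matrix(rnorm(100 * 30), 100, 30)
    k <- 10
    model <- fit_pca(x, k = k)
    # oracle: eigenvectors of the sample covariance matrix
    eig <- eigen(stats::cov(x), symmetric = TRUE)
    scores_oracle <- sweep(x, 2, colMeans(x)) %*% eig$vectors[, 1:k]
    expect_equal(abs(unname(model$scores)), abs(unname(scores_oracle)),
                 tolerance = 1e-8)
    expect_equal(model$explained_variance, eig$values[1:k],
                 tolerance = 1e-8)
    # orthonormal loadings, non-increasing spectrum
    expect_equal(crossprod(model$rotation), diag(k), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(diff(model$explained_variance) <= 1e-10))
  })
})

test_that("PCA recovers exact low-rank structure and full variance", {
  withr::with_seed(64, {
    basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
    x <- matrix(rnorm(40 * 3), 40, 3) %*% t(basis) +
      matrix(1.5, 40, 20)  # affine 3D subspace
    model <- fit_pca(x, k = 3)
    recon <- model$scores %*% t(model$rotation)
    expect_equal(recon, sweep(x, 2, colMeans(x)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # full decomposition captures all the variance
    full <- fit_pca(x, k = min(nrow(x) - 1, ncol(x)))
    expect_equal(sum(full$explained_variance), full$total_variance,
                 tolerance = 1e-10)
  })
})

test_that("apply_pca is consistent with fitting and centres the mean", {
  withr::with_seed(65, {
    x <- matrix(rnorm(30 * 12), 30, 12)
    model <- fit_pca(x, k = 5)
    expect_equal(apply_pca(model, x), model$scores, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(as.vector(apply_pca(model, matrix(model$mean, 1))),
                 rep(0, 5), tolerance = 1e-10)
    # a held-out point inside the training subspace reconstructs exactly
    held <- colMeans(x) + as.vector(model$rotation %*% c(1, -2, 0.5, 0, 3))
    z <- apply_pca(model, matrix(held, 1))
    recon <- as.vector(model$rotation %*% t(z)) + model$mean
    expect_equal(recon, held, tolerance = 1e-10, ignore_attr = TRUE)
    expect_error(apply_pca(model, matrix(0, 2, 5)), "mismatch")
    expect_error(fit_pca(x, k = 30), "out of range")
  })
})

test_that("PCA is equivariant under feature permutation", {
  withr::with_seed(66, {
    x <- matrix(rnorm(50 * 15), 50, 15)
    perm <- sample(15)
    m1 <- fit_pca(x, k = 4)
    m2 <- fit_pca(x[, perm], k = 4)
    expect_equal(abs(unname(m2$scores)), abs(unname(m1$scores)),
                 tolerance = 1e-8)
    expect_equal(m2$explained_variance, m1$explained_variance,
                 tolerance = 1e-8)
  })
})

test_that("PCA JSON serialisation round-trips the model", {
  withr::with_seed(67, {
    x <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    model <- fit_pca(x, k = 3)
    path <- withr::local_tempfile(fileext = ".json")
    write_pca_json(model, path)
    back <- read_pca_json(path)
    expect_equal(back$rotation, model$rotation, tolerance = 1e-12)
    expect_equal(back$mean, model$mean, tolerance = 1e-12)
    expect_equal(apply_pca(back, x), apply_pca(model, x),
                 tolerance = 1e-12)
  })
})
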