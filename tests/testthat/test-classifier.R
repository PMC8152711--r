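# two well-separated Gaussian classes with rare positives, mirroring the
# low-prevalence geometry the classifier faces
separable_gaussians <- function(n = 300, prev = 0.05, sep = 4, d = 2,
                                seed = 71) {
  set.seed(seed)
  n_pos <- round(n * prev)
  X <- rbind(matrix(rnorm((n - n_pos) * d), ncol = d),
             matrix(rnorm(n_pos * d, mean = sep / sqrt(d)), ncol = d))
  y <- c(rep(0L, n - n_pos), rep(1L, n_pos))
  ids <- sprintf("d%04d", seq_len(n))
  rownames(X) <- ids
  colnames(X) <- paste0("sv", seq_len(d))
  list(X = X, y = y, ids = ids,
       vectors = doc_vectors(X, "svd"))
}

test_that("SMOTE interpolants stay on the segment between two minority points", {
  Xm <- rbind(c(0, 0), c(1, 1))
  XM <- matrix(rnorm(40), 20, 2)
  out <- smote_oversample(Xm, XM, k = 1, seed = 5)
  synth <- out$X[out$synthetic, , drop = FALSE]
  expect_gt(nrow(synth), 0)
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth >= 0 & synth <= 1))
})

test_that("SMOTE balances 95:5 to 95:95 and is seed-reproducible", {
  set.seed(9)
  Xm <- matrix(rnorm(10), 5, 2)
  XM <- matrix(rnorm(190), 95, 2)
  out <- smote_oversample(Xm, XM, k = 3, seed = 11)
  expect_equal(sum(out$y == 1), 95)
  expect_equal(sum(out$y == 0), 95)
  out2 <- smote_oversample(Xm, XM, k = 3, seed = 11)
  expect_identical(out$X, out2$X)
  expect_error(smote_oversample(Xm[1, , drop = FALSE], XM, 1, 1),
               "at least 2")
  expect_warning(smote_oversample(Xm, XM, k = 10, seed = 1), "clamped")
})

test_that("synthetic rows lie in the minority convex hull (coordinate bounds)", {
  set.seed(15)
  Xm <- matrix(runif(30, 2, 3), 15, 2)
  XM <- matrix(runif(200, -1, 1), 100, 2)
  out <- smote_oversample(Xm, XM, k = 5, seed = 3)
  synth <- out$X[out$synthetic, , drop = FALSE]
  expect_true(all(synth >= 2 - 1e-12 & synth <= 3 + 1e-12))
})

test_that("validation folds never contain synthetic rows", {
  dat <- separable_gaussians()
  fold <- screenflow:::stratified_folds(dat$y, 5, seed = 1)
  for (f in 1:5) {
    tr <- which(fold != f)
    bal <- screenflow:::smote_fold(dat$X, dat$y, tr, k = 5, seed = f)
    n_real <- sum(!bal$synthetic)
    # every non-synthetic balanced row is an original training-fold row
    expect_equal(n_real, length(tr))
    expect_true(all(bal$synthetic[-seq_len(n_real)]))
    # validation rows are disjoint from the training fold by construction
    expect_length(intersect(tr, which(fold == f)), 0)
  }
})

test_that("CV tuning is deterministic and sensitive on separable data", {
  dat <- separable_gaussians()
  train <- training_set(dat$ids, dat$y, dat$vectors)
  spec <- classifier_spec(n_trees = 200, seed = 303)
  fit1 <- train_rf_cv(train, spec)
  fit2 <- train_rf_cv(train, spec)
  expect_identical(fit1$mtry, fit2$mtry)
  expect_identical(fit1$cv_sensitivity, fit2$cv_sensitivity)
  expect_gte(max(fit1$cv_sensitivity, na.rm = TRUE), 0.9)
  expect_true(all(fit1$cv_sensitivity >= 0 & fit1$cv_sensitivity <= 1,
                  na.rm = TRUE))
  p <- predict_probabilities(fit1, dat$vectors)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_probabilities(train_rf_cv(train, spec),
                                            dat$vectors))

  pred <- predict_eligible(fit1, dat$vectors, threshold = 0.5)
  expect_gte(length(intersect(pred, dat$ids[dat$y == 1])),
             ceiling(0.9 * sum(dat$y)))
})

test_that("single-class training data is rejected with guidance", {
  dat <- separable_gaussians()
  keep <- dat$y == 0
  train <- training_set(dat$ids[keep], dat$y[keep], dat$vectors)
  expect_error(train_rf_cv(train), "phase 1")
})

test_that("prediction is monotone in the threshold and total at zero", {
  dat <- separable_gaussians(seed = 73, d = 6)
  train <- training_set(dat$ids, dat$y, dat$vectors)
  fit <- train_rf_cv(train, classifier_spec(n_trees = 100, seed = 7))
  p0 <- predict_eligible(fit, dat$vectors, threshold = 0)
  expect_setequal(p0, dat$ids)
  thr <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sets <- lapply(thr, function(t) predict_eligible(fit, dat$vectors, t))
  for (i in seq_len(length(thr) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  expect_error(classifier_spec(threshold = 1.0), "threshold")
  small <- doc_vectors(dat$X[, 1:3], "svd")
  expect_error(predict_eligible(fit, small), "mismatch")
})
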