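test_that("LOO LDA decodes separated clusters perfectly and is at chance on null features", {
  # two tight, far-separated clusters
  set.seed(71)
  X <- rbind(
    matrix(rnorm(40, 0, 0.05), 20, 2),
    matrix(rnorm(40, 100, 0.05), 20, 2)
  )
  y <- rep(1:2, each = 20)
  expect_equal(lda_decode_loo(X, y), 1.0)

  # 1-D two-class example with a wide margin
  expect_equal(lda_decode_loo(matrix(c(0, 0.1, 10, 10.1)), c(1, 1, 2, 2)), 1.0)

  # features independent of the labels: DEC within 3 binomial SEs of 1/K
  set.seed(72)
  K <- 4
  S <- 200
  Xn <- matrix(rnorm(S * 3), S, 3)
  yn <- rep(1:K, each = S / K)
  dec <- lda_decode_loo(Xn, yn)
  se <- sqrt((1 / K) * (1 - 1 / K) / S)
  expect_lt(abs(dec - 1 / K), 3 * se)
})

test_that("LDA decoding is invariant to label bijections and matches MASS on clean data", {
  set.seed(73)
  X <- rbind(
    matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 3), 15, 2),
    matrix(rnorm(30, 6), 15, 2)
  )
  y <- rep(1:3, each = 15)
  dec1 <- lda_decode_loo(X, y)
  dec2 <- lda_decode_loo(X, c(7, 2, 5)[y]) # relabeled
  expect_equal(dec1, dec2)

  skip_if_not_installed("MASS")
  # cross-check the pooled-covariance classifier against MASS::lda fold by fold
  agree <- vapply(seq_len(nrow(X)), function(s) {
    fit <- MASS::lda(X[-s, , drop = FALSE], grouping = y[-s])
    as.integer(as.character(stats::predict(fit, X[s, , drop = FALSE])$class))
  }, integer(1))
  expect_equal(mean(agree == y), dec1)
})

test_that("singular pooled covariance triggers ridge regularization with a warning", {
  X <- cbind(c(0, 0.1, 5, 5.1), c(1, 1, 1, 1)) # constant second feature
  w <- testthat::capture_warnings(dec <- lda_decode_loo(X, c(1, 1, 2, 2)))
  expect_true(any(grepl("ridge", w)))
  expect_equal(dec, 1.0)
})

test_that("vdm multiplies, clamps negative VAF, and hits the boundary identities", {
  expect_equal(round(vdm(0.797, 0.8), 3), 0.638)
  expect_equal(vdm(0.770, 1.0), 0.770)
  expect_equal(vdm(1, 0), 0)
  expect_equal(vdm(-0.5, 0.9), 0)
  expect_equal(vdm(1, 0.3), 0.3)
  expect_error(vdm(0.5, 1.2), "\\[0, 1\\]")
})

test_that("module similarity finds the optimal pairing and respects affine invariance", {
  set.seed(81)
  a <- matrix(runif(12), 4, 3)
  self <- module_similarity(a, a)
  expect_equal(self$module_b, 1:3)
  expect_equal(self$r, rep(1, 3))

  scaled <- module_similarity(a, 2 + 3 * a)
  expect_equal(scaled$r, rep(1, 3))

  # 2 x 2 toy with a known optimal (swapped) assignment vs brute force
  b <- a[, c(2, 1, 3)]
  sw <- module_similarity(a, b)
  expect_equal(sw$module_b, c(2, 1, 3))

  expect_warning(zv <- module_similarity(cbind(a[, 1], 1), cbind(a[, 1], 1)), "zero-variance")
  expect_true(is.na(zv$r[2]))
  expect_error(module_similarity(a, a[, 1:2]), "equal")
})

test_that("SVM cross-validation scores separable data perfectly and shuffled labels at chance", {
  d <- generate_emg(toy_synergy_spec(seed = 91, noise_fraction = 0))
  fit_fn <- function(train) fit_snm3f(train, 2, 2, fit_options(n_restarts = 2, seed = 1, max_iter = 200))
  res <- svm_classify_cv(d$dataset,
    fit_fn = fit_fn, n_train_per_task = 5,
    n_splits = 4, seed = 7
  )
  expect_equal(res$cls_mean, 1.0)
  expect_equal(res$cls_sd, 0)

  again <- svm_classify_cv(d$dataset,
    fit_fn = fit_fn, n_train_per_task = 5,
    n_splits = 4, seed = 7
  )
  expect_identical(res$splits, again$splits)

  set.seed(92)
  shuffled <- sample(d$dataset$labels)
  null_res <- svm_classify_cv(d$dataset,
    labels = shuffled, fit_fn = fit_fn,
    n_train_per_task = 5, n_splits = 4, seed = 7
  )
  n_test <- 40 - 4 * 5
  se <- sqrt(0.25 * 0.75 / (n_test * 4))
  expect_lt(abs(null_res$cls_mean - 0.25), 3 * se + 0.15)

  expect_error(
    svm_classify_cv(d$dataset, fit_fn = fit_fn, n_train_per_task = 10),
    "smaller"
  )
})

test_that("model comparison of a model with itself is symmetric and round-trips as JSON", {
  d <- generate_emg(toy_synergy_spec(seed = 95))
  fit <- fit_snm3f(d$dataset, 2, 2, fit_options(n_restarts = 2, seed = 1, max_iter = 200))
  cmp <- compare_models(d$dataset, fit, fit)
  expect_equal(cmp$metrics$vaf[1], cmp$metrics$vaf[2])
  expect_equal(cmp$temporal_similarity$r, rep(1, 2))
  expect_equal(cmp$spatial_similarity$r, rep(1, 2))
  expect_equal(cmp$coef_similarity$r, rep(1, 4))
  # VDM consistency inside the report
  expect_equal(cmp$metrics$vdm, pmax(cmp$metrics$vaf, 0) * cmp$metrics$dec)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(cmp, path)
  back <- read_report(path)
  expect_equal(as.data.frame(back$metrics), as.data.frame(cmp$metrics))
  expect_equal(back$temporal_similarity$r, cmp$temporal_similarity$r)
})
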