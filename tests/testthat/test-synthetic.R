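test_that("noise-free, zero-variability generation reproduces the task means exactly", {
  spec <- toy_synergy_spec(seed = 1, noise_fraction = 0, within_task_cv = 0)
  sim <- generate_emg(spec)
  for (s in seq_along(sim$dataset$samples)) {
    k <- sim$dataset$labels[s]
    expect_equal(
      sim$dataset$samples[[s]],
      spec$temporal %*% spec$task_mean_coef[[k]] %*% spec$spatial
    )
  }
})

test_that("generation is seed-deterministic, balanced, and non-negative", {
  a <- generate_emg(toy_synergy_spec(seed = 33))
  b <- generate_emg(toy_synergy_spec(seed = 33))
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$coef, b$coef)

  expect_equal(a$dataset$dims[["S"]], 40)
  expect_equal(unname(a$dataset$dims[c("T", "M")]), c(2, 2))
  expect_true(all(vapply(a$dataset$samples, function(m) all(m >= 0), logical(1))))
  expect_equal(as.vector(table(a$dataset$labels)), rep(10, 4))
})

test_that("true coefficients of the benchmark spec decode perfectly", {
  sim <- generate_emg(toy_synergy_spec(seed = 17))
  expect_equal(lda_decode_loo(sim$coef, sim$dataset$labels), 1.0)
})

test_that("noise magnitude scales with the noise fraction", {
  dev_at <- function(f) {
    devs <- vapply(1:8, function(seed) {
      spec <- toy_synergy_spec(seed = seed, noise_fraction = f)
      sim <- generate_emg(spec)
      mean(vapply(seq_along(sim$coef), function(s) {
        clean <- spec$temporal %*% sim$coef[[s]] %*% spec$spatial
        mean(abs(sim$dataset$samples[[s]] - clean))
      }, numeric(1)))
    }, numeric(1))
    mean(devs)
  }
  d0 <- dev_at(0)
  d2 <- dev_at(0.2)
  d4 <- dev_at(0.4)
  expect_equal(d0, 0)
  expect_gt(d4, d2)
  # roughly linear scaling: doubling the fraction about doubles the deviation
  expect_equal(d4 / d2, 2, tolerance = 0.25)
})

test_that("the pointing-scale spec has experiment-sized, well-formed output", {
  spec <- pointing_synergy_spec(seed = 2)
  expect_equal(unname(spec$dims), c(50, 9, 3, 4, 640))
  sim <- generate_emg(spec)
  expect_equal(sim$dataset$dims[["S"]], 640)
  expect_true(all(vapply(sim$dataset$samples, function(m) all(is.finite(m)) && all(m >= 0), logical(1))))
})

test_that("reconstruction-only fitting of noise-free pointing-scale data is near exact", {
  sim <- generate_emg(pointing_synergy_spec(seed = 3, noise_fraction = 0))
  fit <- fit_snm3f(sim$dataset, 3, 4, fit_options(n_restarts = 3, seed = 1))
  expect_gte(vaf(sim$dataset, fit$model), 0.999)
})

test_that("recovery score is exact for the truth and invariant to permutation/rescaling", {
  sim <- generate_emg(toy_synergy_spec(seed = 41))
  spec <- sim$spec
  truth_model <- spacetime_model(spec$temporal, spec$spatial, sim$coef)
  rs <- recovery_score(truth_model, sim)
  expect_equal(rs$temporal$r, rep(1, 2))
  expect_equal(rs$spatial$r, rep(1, 2))
  expect_equal(rs$coef_r, 1)

  # permute the modules and rescale: similarity pairing must undo both
  perm_model <- spacetime_model(
    spec$temporal[, c(2, 1)] * 3,
    spec$spatial[c(2, 1), ] * 2,
    lapply(sim$coef, function(a) (a / 6)[c(2, 1), c(2, 1)])
  )
  rp <- recovery_score(perm_model, sim)
  expect_equal(rp$temporal$module_b, c(2, 1))
  expect_equal(rp$temporal$r, rep(1, 2))
  expect_equal(rp$spatial$r, rep(1, 2))
  expect_equal(rp$coef_r, 1)
})
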