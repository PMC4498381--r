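toy_noisefree <- function(seed = 1) {
  generate_emg(toy_synergy_spec(seed = seed, noise_fraction = 0))
}

test_that("sNM3F recovers a noise-free factorization nearly exactly", {
  d <- toy_noisefree(seed = 3)
  fit <- fit_snm3f(d$dataset, 2, 2, fit_options(n_restarts = 5, seed = 1))
  expect_gte(vaf(d$dataset, fit$model), 0.999)
  # unit-sum constraints and non-negativity of all factors
  expect_equal(colSums(fit$model$temporal), rep(1, 2), tolerance = 1e-8)
  expect_equal(rowSums(fit$model$spatial), rep(1, 2), tolerance = 1e-8)
  expect_true(all(fit$model$temporal >= 0) && all(fit$model$spatial >= 0))
  expect_true(all(vapply(fit$model$coef, function(a) all(a >= 0), logical(1))))
  # final cost consistent with a recomputation on the returned model
  expect_equal(fit$final_cost, e_nmf(d$dataset, fit$model), tolerance = 1e-8)
})

test_that("identical trials fit cleanly even though VAF is undefined", {
  one <- matrix(c(2, 1), 1, 2)
  d <- emg_dataset(replicate(5, one, simplify = FALSE))
  fit <- fit_snm3f(d, 1, 1, fit_options(n_restarts = 2, seed = 1))
  expect_lt(fit$e_nmf, 1e-10)
  expect_error(vaf(d, fit$model), "identical")
})

test_that("the reconstruction-error trace of sNM3F is non-increasing", {
  for (seed in 1:5) {
    d <- random_dataset(6, 3, 3, seed = seed)
    fit <- fit_snm3f(d, 2, 2, fit_options(n_restarts = 1, seed = seed, max_iter = 150))
    e <- fit$history$e_nmf
    expect_true(all(diff(e) <= 1e-9 * e[1]))
  }
})

test_that("best-of-restarts cost has the prefix property and fits are deterministic", {
  d <- generate_emg(toy_synergy_spec(seed = 5))$dataset
  fits <- lapply(1:4, function(r) {
    fit_snm3f(d, 2, 2, fit_options(n_restarts = r, seed = 9, max_iter = 120))
  })
  costs <- vapply(fits, function(f) f$final_cost, numeric(1))
  expect_true(all(diff(costs) <= 0))
  # prefix property: best over r restarts = min of the per-restart costs
  expect_equal(fits[[4]]$final_cost, min(fits[[4]]$restart_costs))
  expect_equal(fits[[3]]$restart_costs, fits[[4]]$restart_costs[1:3])

  again <- fit_snm3f(d, 2, 2, fit_options(n_restarts = 4, seed = 9, max_iter = 120))
  expect_identical(again$history, fits[[4]]$history)
  expect_identical(again$model$temporal, fits[[4]]$model$temporal)
})

test_that("DsNM3F multiplicative fit separates tasks on noise-free data", {
  d <- toy_noisefree(seed = 11)
  fit <- fit_dsnm3f(d$dataset, 2, 2,
    gamma = 0.1, delta = 0.01,
    options = fit_options(n_restarts = 5, seed = 1)
  )
  expect_equal(lda_decode_loo(fit$model, d$dataset$labels), 1.0)
  expect_true(all(fit$model$temporal >= 0))
  expect_equal(colSums(fit$model$temporal), rep(1, 2), tolerance = 1e-8)
})

test_that("ALS module updates satisfy constraints and match the equality-constrained oracle", {
  d <- generate_emg(toy_synergy_spec(seed = 21))$dataset
  fit <- fit_dsnm3f(d, 2, 2,
    gamma = 0.5, delta = 0.01, method = "als",
    options = fit_options(n_restarts = 3, seed = 2)
  )
  expect_equal(colSums(fit$model$temporal), rep(1, 2), tolerance = 1e-8)
  expect_equal(rowSums(fit$model$spatial), rep(1, 2), tolerance = 1e-8)
  expect_true(all(fit$model$temporal >= 0) && all(fit$model$spatial >= 0))

  # unclipped KKT solution vs null-space-elimination least squares
  for (seed in 1:5) {
    set.seed(seed + 300)
    T <- 4; M <- 3; P <- 2; N <- 2; S <- 5
    un <- synergizer:::data_unfolds(random_dataset(S, T, M, seed = seed + 300))
    Rh <- matrix(runif(P * M * S), P, M * S)
    kkt_sol <- synergizer:::als_update_temporal(un, Rh, T, P, clip = FALSE)
    oracle <- matrix(eqls_temporal_oracle(un$h, Rh, T, P), T, P)
    expect_equal(kkt_sol, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("projected-gradient QP module updates never increase the module cost", {
  for (seed in 1:20) {
    set.seed(seed + 400)
    T <- 4; M <- 3; P <- 2; N <- 2; S <- 5
    un <- synergizer:::data_unfolds(random_dataset(S, T, M, seed = seed + 400))
    Rh <- matrix(runif(P * M * S), P, M * S)
    Wt0 <- apply(matrix(runif(T * P), T, P), 2, synergizer:::project_simplex)
    opts <- fit_options(qp_max_iter = 25)
    f <- function(X) sum((un$h - X %*% Rh)^2)
    Wt1 <- synergizer:::qp_update_temporal(un, Rh, Wt0, opts)
    expect_lte(f(Wt1), f(Wt0) + 1e-10 * max(1, f(Wt0)))
    expect_equal(colSums(Wt1), rep(1, P), tolerance = 1e-8)
    expect_true(all(Wt1 >= 0))

    Qv <- matrix(runif(T * S * N), T * S, N)
    W0 <- t(apply(matrix(runif(N * M), N, M), 1, synergizer:::project_simplex))
    g <- function(X) sum((un$v - Qv %*% X)^2)
    W1 <- synergizer:::qp_update_spatial(list(v = un$v), Qv, W0, opts)
    expect_lte(g(W1), g(W0) + 1e-10 * max(1, g(W0)))
    expect_equal(rowSums(W1), rep(1, N), tolerance = 1e-8)
  }
})

test_that("the NLP solver respects bounds and unit-sum constraints", {
  d <- toy_noisefree(seed = 31)
  fit <- fit_dsnm3f(d$dataset, 2, 2,
    gamma = 0, delta = 0, method = "nlp",
    options = fit_options(n_restarts = 2, seed = 3)
  )
  expect_gte(vaf(d$dataset, fit$model), 0.999)
  expect_lt(fit$constraint_violation, 1e-6)
  expect_true(all(fit$model$temporal >= 0) && all(fit$model$spatial >= 0))
})

test_that("projection onto fixed modules recovers constructed and fitted coefficients", {
  set.seed(51)
  Wt <- matrix(runif(6) + 0.2, 3, 2)
  Wt <- sweep(Wt, 2, colSums(Wt), "/")
  W <- matrix(runif(6) + 0.2, 2, 3)
  W <- sweep(W, 1, rowSums(W), "/")
  A <- replicate(4, matrix(runif(4) + 0.5, 2, 2), simplify = FALSE)
  d <- emg_dataset(lapply(A, function(a) Wt %*% a %*% W))
  rec <- project_onto_modules(d, Wt, W)
  for (s in 1:4) expect_equal(rec[[s]], A[[s]], tolerance = 1e-3)

  # zero trial projects to (numerically) zero coefficients
  dz <- emg_dataset(list(matrix(0, 3, 3)))
  expect_lt(max(abs(project_onto_modules(dz, Wt, W)[[1]])), 1e-6)

  # fixed-point property on a converged reconstruction-only fit
  sim <- toy_noisefree(seed = 52)
  fit <- fit_snm3f(sim$dataset, 2, 2, fit_options(n_restarts = 3, seed = 1))
  reproj <- project_onto_modules(sim$dataset, fit)
  for (s in seq_along(reproj)) {
    expect_equal(reproj[[s]], fit$model$coef[[s]], tolerance = 1e-3)
  }

  expect_error(project_onto_modules(dz, Wt, W[, 1:2]), "match")
})

test_that("solver input validation catches bad module counts and weights", {
  d <- random_dataset(4, 2, 2, seed = 61, labels = c(1, 1, 2, 2))
  expect_error(fit_snm3f(d, 3, 2), "P")
  expect_error(fit_snm3f(d, 2, 3), "N")
  expect_error(fit_dsnm3f(d, 2, 2, gamma = -1, delta = 0), "non-negative")
  expect_error(
    fit_dsnm3f(random_dataset(4, 2, 2, seed = 62), 2, 2, gamma = 1, delta = 0),
    "labels"
  )
})
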