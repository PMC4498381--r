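test_that("reconstruct handles scalar, annihilating and identity models", {
  m1 <- spacetime_model(matrix(1), matrix(1), list(matrix(3)))
  expect_equal(reconstruct(m1, 1), matrix(3))

  m0 <- random_model(3, 2, 2, 2, 2, seed = 4)
  m0$coef[[1]][] <- 0
  expect_equal(reconstruct(m0, 1), matrix(0, 3, 2))

  a <- matrix(c(1, 3, 2, 4), 2, 2)
  mid <- spacetime_model(diag(2), diag(2), list(a))
  expect_equal(reconstruct(mid, 1), a)

  expect_error(reconstruct(mid, 2), "1\\.\\.1")
  expect_error(reconstruct(mid, 0), "1\\.\\.1")
})

test_that("reconstructions of valid models are non-negative", {
  for (seed in 1:5) {
    m <- random_model(4, 3, 2, 2, 3, seed = seed)
    expect_true(all(reconstruct(m, 1) >= 0))
    expect_true(all(reconstruct(m, 3) >= 0))
  }
})

test_that("e_nmf matches trivial cases and the elementwise oracle", {
  m <- random_model(3, 2, 2, 2, 4, seed = 2)
  exact <- emg_dataset(lapply(1:4, function(s) reconstruct(m, s)))
  expect_equal(e_nmf(exact, m), 0)

  one <- emg_dataset(list(matrix(1)))
  zero_model <- spacetime_model(matrix(1), matrix(1), list(matrix(0)))
  expect_equal(e_nmf(one, zero_model), 1)

  d <- random_dataset(3, 3, 2, seed = 11)
  m3 <- random_model(3, 2, 2, 2, 3, seed = 12)
  expect_equal(e_nmf(d, m3), brute_e_nmf(d, m3))

  expect_error(e_nmf(random_dataset(3, 4, 2, seed = 1), m3), "does not match")
})

test_that("vaf equals 1 for exact fits, 0 at the mean pattern, and the formula oracle", {
  m <- random_model(3, 2, 2, 2, 4, seed = 5)
  exact <- emg_dataset(lapply(1:4, function(s) reconstruct(m, s)))
  expect_equal(vaf(exact, m), 1)

  d <- emg_dataset(list(matrix(1), matrix(2), matrix(3)))
  mean_model <- spacetime_model(matrix(1), matrix(1), list(matrix(2), matrix(2), matrix(2)))
  expect_equal(vaf(d, mean_model), 0)

  d3 <- random_dataset(3, 3, 2, seed = 21)
  m3 <- random_model(3, 2, 2, 2, 3, seed = 22)
  expect_equal(vaf(d3, m3), brute_vaf(d3, m3))

  same <- emg_dataset(list(matrix(1:6 / 6, 3, 2), matrix(1:6 / 6, 3, 2)))
  m_same <- random_model(3, 2, 1, 1, 2, seed = 1)
  expect_error(vaf(same, m_same), "identical")
})

test_that("parameter counts reproduce the worked example and validate input", {
  pc <- parameter_counts(M = 9, T = 50, S = 640, N = 4, P = 3)
  expect_equal(pc$full, 288000)
  expect_equal(pc$coeff, 7680)
  expect_equal(pc$modules, 4 * 9 + 50 * 3)
  expect_equal(pc$total, pc$coeff + pc$modules)
  expect_error(parameter_counts(0, 50, 640, 4, 3), "positive")
  expect_error(parameter_counts(9, 50, 640, 4.5, 3), "positive")
})

test_that("compensated normalization leaves reconstructions and e_nmf unchanged", {
  m <- random_model(4, 3, 2, 2, 3, seed = 7)
  d <- random_dataset(3, 4, 3, seed = 8)
  mn <- normalize_modules(m, compensate = TRUE)
  expect_equal(colSums(mn$temporal), rep(1, 2))
  expect_equal(rowSums(mn$spatial), rep(1, 2))
  for (s in 1:3) {
    expect_equal(reconstruct(mn, s), reconstruct(m, s), tolerance = 1e-12)
  }
  expect_equal(e_nmf(d, mn), e_nmf(d, m), tolerance = 1e-10)
})

test_that("normalizing an all-zero module yields a uniform module with a warning", {
  m <- random_model(4, 3, 2, 2, 2, seed = 9)
  m$temporal[, 2] <- 0
  expect_warning(mn <- normalize_modules(m), "uniform")
  expect_equal(mn$temporal[, 2], rep(1 / 4, 4))
  # compensation zeroes the matching coefficient rows: reconstruction kept
  expect_equal(reconstruct(mn, 1), reconstruct(m, 1), tolerance = 1e-12)
})
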