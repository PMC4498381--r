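# Independent oracles used across the suite: deliberately slow, literal
# implementations of the formulas, kept free of the package's fast paths.

# sum over samples and entries of the squared residual, as a double loop
brute_e_nmf <- function(data, model) {
  total <- 0
  for (s in seq_along(data$samples)) {
    recon <- model$temporal %*% model$coef[[s]] %*% model$spatial
    for (i in seq_len(nrow(recon))) {
      for (j in seq_len(ncol(recon))) {
        total <- total + (data$samples[[s]][i, j] - recon[i, j])^2
      }
    }
  }
  total
}

brute_vaf <- function(data, model) {
  mbar <- Reduce(`+`, data$samples) / length(data$samples)
  denom <- 0
  for (s in seq_along(data$samples)) {
    denom <- denom + sum((data$samples[[s]] - mbar)^2)
  }
  1 - brute_e_nmf(data, model) / denom
}

# literal outer-product construction of the scatter matrices
brute_scatter <- function(coef, labels) {
  classes <- sort(unique(labels))
  vecs <- lapply(coef, as.vector)
  d <- length(vecs[[1]])
  gmean <- Reduce(`+`, vecs) / length(vecs)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (k in classes) {
    idx <- which(labels == k)
    cmean <- Reduce(`+`, vecs[idx]) / length(idx)
    for (s in idx) {
      dv <- vecs[[s]] - cmean
      Sw <- Sw + dv %*% t(dv)
    }
    db <- cmean - gmean
    Sb <- Sb + db %*% t(db)
  }
  list(Sw = Sw, Sb = Sb)
}

# central finite difference of f at x (scalar coordinate)
central_fd <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# generic equality-constrained least squares by null-space elimination:
# min ||vec(Mh) - (t(Rh) %x% I_T) vec(Wt)||^2 s.t. each column of Wt sums
# to 1; independent of the package's KKT solve.
eqls_temporal_oracle <- function(Mh, Rh, T, P) {
  X <- kronecker(t(Rh), diag(T))
  y <- as.vector(Mh)
  # particular solution: uniform columns
  z0 <- rep(1 / T, T * P)
  # null-space basis of the column-sum constraints (per column of Wt)
  Bcol <- rbind(diag(T - 1), -1)
  B <- kronecker(diag(P), Bcol)
  fit <- lm.fit(X %*% B, y - X %*% z0)
  z0 + B %*% fit$coefficients
}

random_dataset <- function(S, T, M, seed = 1, labels = NULL) {
  set.seed(seed)
  emg_dataset(
    replicate(S, matrix(runif(T * M), T, M), simplify = FALSE),
    labels = labels
  )
}

random_model <- function(T, M, P, N, S, seed = 1, normalize = FALSE) {
  set.seed(seed)
  spacetime_model(
    matrix(runif(T * P), T, P),
    matrix(runif(N * M), N, M),
    replicate(S, matrix(runif(P * N), P, N), simplify = FALSE),
    normalize = normalize
  )
}
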