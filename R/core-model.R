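#' Space-by-time decomposition model
#'
#' A space-by-time model represents each trial `s` of muscle activity as
#' `M^s ~ Wt A^s W`, where the columns of `Wt` (`T x P`) are temporal modules
#' shared across trials, the rows of `W` (`N x M`) are spatial modules shared
#' across trials, and `A^s` (`P x N`) holds the non-negative activation
#' coefficients that couple them in that trial. By convention each temporal
#' module (column of `Wt`) and each spatial module (row of `W`) sums to 1, so
#' amplitude lives in the coefficients.
#'
#' @param temporal `T x P` non-negative matrix of temporal modules (columns).
#' @param spatial `N x M` non-negative matrix of spatial modules (rows).
#' @param coef List of `S` non-negative `P x N` coefficient matrices, or a
#'   `P x N x S` array.
#' @param normalize Normalize modules to unit sum on construction (with
#'   compensation in `coef`, leaving reconstructions unchanged)? Default
#'   `FALSE` so handmade models are stored exactly as given.
#'
#' @return An object of class `spacetime_model` with elements `temporal`,
#'   `spatial`, `coef` and `dims` (named `T`, `M`, `P`, `N`, `S`).
#' @examples
#' m <- spacetime_model(diag(2), diag(2), list(matrix(1:4, 2, 2)))
#' reconstruct(m, 1)
#' @export
spacetime_model <- function(temporal, spatial, coef, normalize = FALSE) {
  temporal <- as.matrix(temporal)
  spatial <- as.matrix(spatial)
  if (is.array(coef) && length(dim(coef)) == 3L) {
    coef <- array_slices(coef)
  }
  if (!is.list(coef) || length(coef) == 0L) stop("`coef` must be a non-empty list or 3-D array.")
  coef <- lapply(coef, function(a) {
    a <- as.matrix(a)
    storage.mode(a) <- "double"
    a
  })
  P <- ncol(temporal); N <- nrow(spatial)
  if (!all(vapply(coef, function(a) identical(dim(a), c(P, N)), logical(1)))) {
    stop("every coefficient matrix must be P x N = ", P, " x ", N, ".")
  }
  if (any(temporal < 0) || any(spatial < 0) ||
    any(vapply(coef, function(a) any(a < 0), logical(1)))) {
    stop("all model factors must be non-negative.")
  }
  out <- structure(
    list(
      temporal = temporal, spatial = spatial, coef = coef,
      dims = c(
        T = nrow(temporal), M = ncol(spatial), P = P, N = N,
        S = length(coef)
      )
    ),
    class = "spacetime_model"
  )
  if (normalize) out <- normalize_modules(out) else out
}

#' Normalize modules to unit sum
#'
#' Rescales each temporal module (column of `Wt`) and each spatial module
#' (row of `W`) to sum to 1. With `compensate = TRUE` the coefficient
#' matrices absorb the inverse factors, so every reconstruction
#' `Wt A^s W` is unchanged (this is the renormalization used by the
#' monotone sNM3F iteration). With `compensate = FALSE` the coefficients are
#' left untouched, the convention of the discriminative multiplicative
#' update. An all-zero module is replaced by a uniform module (`1/T` or
#' `1/M` entries) with a warning; under compensation its coefficient slice
#' is zeroed so reconstructions are still unchanged.
#'
#' @param model A [spacetime_model()].
#' @param compensate Rescale coefficients to keep reconstructions identical?
#' @return A `spacetime_model` with unit-sum modules.
#' @export
normalize_modules <- function(model, compensate = TRUE) {
  ct <- colSums(model$temporal)
  cw <- rowSums(model$spatial)
  zt <- ct <= 0
  zw <- cw <= 0
  if (any(zt) || any(zw)) {
    warning("all-zero module(s) replaced by uniform module(s) during normalization.")
  }
  Tn <- nrow(model$temporal); M <- ncol(model$spatial)
  Wt <- sweep(model$temporal, 2, ifelse(zt, 1, ct), "/")
  Wt[, zt] <- 1 / Tn
  W <- sweep(model$spatial, 1, ifelse(zw, 1, cw), "/")
  W[zw, ] <- 1 / M
  coef <- model$coef
  if (compensate) {
    coef <- lapply(coef, function(a) diag(ct, nrow = length(ct)) %*% a %*% diag(cw, nrow = length(cw)))
  }
  spacetime_model(Wt, W, coef)
}

#' Reconstruct one trial from a model
#'
#' @param model A [spacetime_model()].
#' @param s Trial index in `1..S`.
#' @return The `T x M` non-negative matrix `Wt A^s W`.
#' @export
reconstruct <- function(model, s) {
  stopifnot(inherits(model, "spacetime_model"))
  S <- model$dims[["S"]]
  if (length(s) != 1L || is.na(s) || s < 1 || s > S) {
    stop("trial index must be in 1..", S, ".")
  }
  model$temporal %*% model$coef[[s]] %*% model$spatial
}

check_dims_match <- function(data, model) {
  d <- data$dims; m <- model$dims
  if (d[["T"]] != m[["T"]] || d[["M"]] != m[["M"]] || d[["S"]] != m[["S"]]) {
    stop(
      "data (S,T,M) = (", d[["S"]], ",", d[["T"]], ",", d[["M"]],
      ") does not match model (S,T,M) = (", m[["S"]], ",", m[["T"]], ",", m[["M"]], ")."
    )
  }
  invisible(TRUE)
}

#' Reconstruction error of a space-by-time model
#'
#' Sum over trials of the squared Frobenius norm of the residual
#' `M^s - Wt A^s W`. Zero if and only if the model reconstructs every trial
#' exactly.
#'
#' @param data An [emg_dataset()] (or coercible).
#' @param model A [spacetime_model()].
#' @return Non-negative scalar.
#' @export
e_nmf <- function(data, model) {
  data <- as_emg_dataset(data)
  check_dims_match(data, model)
  tot <- 0
  for (s in seq_along(data$samples)) {
    r <- data$samples[[s]] - model$temporal %*% model$coef[[s]] %*% model$spatial
    tot <- tot + sum(r * r)
  }
  tot
}

#' Variance accounted for (VAF)
#'
#' `VAF = 1 - E2_NMF / sum_s ||M^s - Mbar||^2`, where `Mbar` is the mean
#' trial pattern across the dataset. Equals 1 for an exact reconstruction and
#' can be negative for a model worse than the mean pattern.
#'
#' @inheritParams e_nmf
#' @return Scalar `<= 1`.
#' @export
vaf <- function(data, model) {
  data <- as_emg_dataset(data)
  check_dims_match(data, model)
  mbar <- Reduce(`+`, data$samples) / length(data$samples)
  denom <- sum(vapply(data$samples, function(m) sum((m - mbar)^2), numeric(1)))
  if (denom <= 0) {
    stop("VAF is undefined: all trials are identical (zero total scatter).")
  }
  1 - e_nmf(data, model) / denom
}

#' Parameter counts of the space-by-time description
#'
#' Compares the number of free values in the raw dataset (`M*T*S`) with the
#' number in the space-by-time description: `N*P*S` activation coefficients
#' plus `N*M + T*P` module entries.
#'
#' @param M,T,S,N,P Positive integers: muscles, time steps, trials, spatial
#'   modules, temporal modules.
#' @return A one-row tibble with columns `full`, `coeff`, `modules`, `total`.
#' @examples
#' parameter_counts(M = 9, T = 50, S = 640, N = 4, P = 3)
#' @export
parameter_counts <- function(M, T, S, N, P) {
  args <- c(M = M, T = T, S = S, N = N, P = P)
  if (any(args != round(args)) || any(args < 1)) {
    stop("all arguments must be positive integers.")
  }
  tibble::tibble(
    full = M * T * S,
    coeff = N * P * S,
    modules = N * M + T * P,
    total = N * P * S + N * M + T * P
  )
}

#' @export
print.spacetime_model <- function(x, ...) {
  d <- x$dims
  cat("<spacetime_model> P = ", d[["P"]], " temporal x N = ", d[["N"]],
    " spatial modules; ", d[["S"]], " trials of ", d[["T"]], " x ", d[["M"]], "\n",
    sep = ""
  )
  invisible(x)
}
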