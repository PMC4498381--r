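#' Within- and between-task scatter of activation coefficients
#'
#' Computes the Fisher scatter statistics of the vectorized (column-stacked)
#' `P x N` coefficient matrices:
#' `Sw = sum_k sum_{s in G_k} vec(A^s - Abar_k) vec(A^s - Abar_k)^T` and
#' `Sb = sum_k vec(Abar_k - Abar) vec(Abar_k - Abar)^T`,
#' where `Abar_k` is the class mean and `Abar` the mean over all trials.
#' Each class contributes once to `Sb`, unweighted by its size. Traces are
#' computed through the Frobenius identity
#' `tr(Sw) = sum_k sum_{s in G_k} ||A^s - Abar_k||^2_fro`, so the full
#' `(P*N)^2` matrices are only materialized on request.
#'
#' @param coef List of `S` `P x N` coefficient matrices (or `P x N x S`
#'   array, or a fitted [spacetime_model()]).
#' @param labels Integer task labels, one per trial; every class non-empty.
#' @param full Also return the full `Sw`, `Sb` matrices? Default `FALSE`.
#'
#' @return An object of class `scatter_summary`: list with `tr_sw`, `tr_sb`,
#'   `class_means` (list of `K` `P x N` matrices), `global_mean`, `n_k`,
#'   `K`, and (when `full = TRUE`) matrices `Sw`, `Sb`.
#' @examples
#' a <- lapply(c(1, 3, 5, 7), function(x) matrix(x, 1, 1))
#' coef_scatter(a, labels = c(1, 1, 2, 2))
#' @export
coef_scatter <- function(coef, labels, full = FALSE) {
  coef <- as_coef_list(coef)
  S <- length(coef)
  labels <- validate_labels(labels, S)
  classes <- sort(unique(labels))
  K <- length(classes)
  P <- nrow(coef[[1]]); N <- ncol(coef[[1]])
  Amat <- vapply(coef, as.vector, numeric(P * N)) # (P*N) x S
  if (is.null(dim(Amat))) Amat <- matrix(Amat, nrow = P * N)
  gmean <- rowMeans(Amat)
  tr_sw <- 0
  tr_sb <- 0
  class_means <- vector("list", K)
  n_k <- integer(K)
  Sw <- Sb <- NULL
  if (full) {
    Sw <- matrix(0, P * N, P * N)
    Sb <- matrix(0, P * N, P * N)
  }
  for (i in seq_len(K)) {
    idx <- which(labels == classes[i])
    n_k[i] <- length(idx)
    cm <- rowMeans(Amat[, idx, drop = FALSE])
    class_means[[i]] <- matrix(cm, P, N)
    dev <- Amat[, idx, drop = FALSE] - cm
    tr_sw <- tr_sw + sum(dev * dev)
    db <- cm - gmean
    tr_sb <- tr_sb + sum(db * db)
    if (full) {
      Sw <- Sw + tcrossprod(dev)
      Sb <- Sb + tcrossprod(db)
    }
  }
  structure(
    list(
      tr_sw = tr_sw, tr_sb = tr_sb,
      class_means = class_means, global_mean = matrix(gmean, P, N),
      n_k = n_k, K = K, classes = classes, Sw = Sw, Sb = Sb
    ),
    class = "scatter_summary"
  )
}

#' @export
print.scatter_summary <- function(x, ...) {
  cat("<scatter_summary> K = ", x$K, " classes; tr(Sw) = ",
    signif(x$tr_sw, 5), ", tr(Sb) = ", signif(x$tr_sb, 5), "\n",
    sep = ""
  )
  invisible(x)
}

as_coef_list <- function(coef) {
  if (inherits(coef, "spacetime_model")) {
    return(coef$coef)
  }
  if (is.array(coef) && length(dim(coef)) == 3L) {
    return(array_slices(coef))
  }
  if (!is.list(coef)) stop("`coef` must be a list of matrices, 3-D array, or spacetime_model.")
  lapply(coef, as.matrix)
}

#' Combined reconstruction + discrimination cost
#'
#' `E2 = E2_NMF + gamma * tr(Sw) - delta * tr(Sb)`. With
#' `gamma = delta = 0` this is the pure reconstruction error of sNM3F; the
#' discriminative extension weights the within-task scatter (to shrink) and
#' between-task scatter (to grow) of the activation coefficients. The value
#' can be negative when the between-task term dominates.
#'
#' @inheritParams e_nmf
#' @param labels Integer task labels (required when `gamma > 0` or
#'   `delta > 0`).
#' @param gamma,delta Non-negative discrimination weights.
#' @return Scalar cost.
#' @export
total_cost <- function(data, model, labels = NULL, gamma = 0, delta = 0) {
  if (gamma < 0 || delta < 0) stop("`gamma` and `delta` must be non-negative.")
  e <- e_nmf(data, model)
  if (gamma == 0 && delta == 0) {
    return(e)
  }
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, length(data$samples))
  sc <- coef_scatter(model$coef, labels)
  e + gamma * sc$tr_sw - delta * sc$tr_sb
}

#' Fisher discrimination ratio J
#'
#' `J = tr(Sw) / tr(Sb)`: the within-task scatter of the activation
#' coefficients relative to the between-task scatter. Smaller values mean
#' better task separation.
#'
#' @param summary A [coef_scatter()] result.
#' @return Positive scalar.
#' @export
j_ratio <- function(summary) {
  stopifnot(inherits(summary, "scatter_summary"))
  if (summary$tr_sb <= 0) {
    stop("J is undefined: tr(Sb) = 0 (single class or identical class means).")
  }
  summary$tr_sw / summary$tr_sb
}

# Analytic gradients of tr(Sw) and tr(Sb) with respect to each A^s.
# For s in class l: d tr(Sw)/dA^s = 2 (A^s - Abar_l);
# d tr(Sb)/dA^s = (2/n_l)(Abar_l - Abar) - (2/S) sum_k (Abar_k - Abar).
# Returned as lists of P x N matrices, used by the solvers and checked
# against finite differences in the tests.
scatter_gradients <- function(coef, labels) {
  coef <- as_coef_list(coef)
  S <- length(coef)
  labels <- validate_labels(labels, S)
  sc <- coef_scatter(coef, labels)
  sum_dev <- Reduce(`+`, lapply(sc$class_means, function(m) m - sc$global_mean))
  gw <- vector("list", S)
  gb <- vector("list", S)
  for (s in seq_len(S)) {
    l <- match(labels[s], sc$classes)
    gw[[s]] <- 2 * (coef[[s]] - sc$class_means[[l]])
    gb[[s]] <- (2 / sc$n_k[l]) * (sc$class_means[[l]] - sc$global_mean) -
      (2 / S) * sum_dev
  }
  list(sw = gw, sb = gb)
}
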