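# Vectorize coefficients into an S x (P*N) matrix (column-stacked vec,
# the same convention used by coef_scatter and the solvers).
coef_feature_matrix <- function(coef) {
  if (inherits(coef, "spacetime_fit")) coef <- coef$model
  coef <- as_coef_list(coef)
  matrix(
    unlist(lapply(coef, as.vector)),
    nrow = length(coef), byrow = TRUE
  )
}

# Pooled-covariance Gaussian linear discriminant. Ridge-regularizes the
# pooled covariance with lambda = 1e-6 * trace / dim when it is singular.
lda_train <- function(X, y) {
  classes <- sort(unique(y))
  K <- length(classes)
  d <- ncol(X)
  n <- nrow(X)
  means <- matrix(
    unlist(lapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]))),
    nrow = K, byrow = TRUE
  )
  pooled <- matrix(0, d, d)
  for (i in seq_len(K)) {
    dev <- sweep(X[y == classes[i], , drop = FALSE], 2, means[i, ])
    pooled <- pooled + crossprod(dev)
  }
  pooled <- pooled / max(n - K, 1)
  priors <- as.vector(table(factor(y, levels = classes))) / n
  inv <- tryCatch(
    {
      if (rcond(pooled) < 1e-12) stop("ill-conditioned")
      solve(pooled)
    },
    error = function(e) {
      warning("singular pooled covariance; applying ridge regularization.")
      lambda <- 1e-6 * sum(diag(pooled)) / d
      if (lambda <= 0) lambda <- 1e-12
      solve(pooled + lambda * diag(d))
    }
  )
  list(classes = classes, means = means, inv = inv, priors = priors)
}

lda_predict <- function(fit, X) {
  # delta_k(x) = x' inv mu_k - mu_k' inv mu_k / 2 + log pi_k
  lin <- X %*% fit$inv %*% t(fit$means)
  const <- -0.5 * rowSums((fit$means %*% fit$inv) * fit$means) + log(fit$priors)
  scores <- sweep(lin, 2, const, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Leave-one-out LDA task decoding (DEC)
#'
#' For each trial, a Gaussian linear discriminant (pooled covariance,
#' empirical class priors) is trained on the vectorized activation
#' coefficients of the remaining trials and used to classify the held-out
#' trial. DEC is the fraction of correct predictions.
#'
#' @param coef List of `P x N` coefficient matrices, a `P x N x S` array, a
#'   [spacetime_model()] or `spacetime_fit`, or an `S x d` feature matrix.
#' @param labels Integer task labels, one per trial; every class needs at
#'   least two trials.
#' @return Fraction correct in `[0, 1]`.
#' @export
lda_decode_loo <- function(coef, labels) {
  X <- if (is.matrix(coef)) coef else coef_feature_matrix(coef)
  S <- nrow(X)
  labels <- validate_labels(labels, S)
  counts <- table(labels)
  if (any(counts < 2)) stop("every task class needs at least two trials for LOO decoding.")
  if (S < length(counts) + 1) stop("need S >= K + 1 trials.")
  correct <- 0L
  for (s in seq_len(S)) {
    fit <- lda_train(X[-s, , drop = FALSE], labels[-s])
    pred <- lda_predict(fit, X[s, , drop = FALSE])
    if (pred == labels[s]) correct <- correct + 1L
  }
  correct / S
}

#' Resubstitution LDA task decoding
#'
#' Same classifier as [lda_decode_loo()] but trained and evaluated on all
#' trials ("decoding on trained data"). Reported separately from the
#' cross-validated DEC wherever both appear.
#'
#' @inheritParams lda_decode_loo
#' @return Fraction correct in `[0, 1]`.
#' @export
lda_decode_resub <- function(coef, labels) {
  X <- if (is.matrix(coef)) coef else coef_feature_matrix(coef)
  labels <- validate_labels(labels, nrow(X))
  fit <- lda_train(X, labels)
  mean(lda_predict(fit, X) == labels)
}

#' VAF-decoding metric (VDM)
#'
#' `VDM = VAF * DEC`, the single trade-off score combining data
#' approximation and task discrimination. A negative VAF is clamped to 0 so
#' that `0 <= VDM <= 1`.
#'
#' @param vaf Variance accounted for (scalar `<= 1`).
#' @param dec Decoding fraction in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' vdm(0.797, 0.8)
#' @export
vdm <- function(vaf, dec) {
  if (any(dec < 0 | dec > 1)) stop("`dec` must lie in [0, 1].")
  pmax(vaf, 0) * dec
}

#' Optimal pairing similarity between two module sets
#'
#' Computes Pearson correlations between all pairs of modules from two sets
#' and returns, for the pairing that maximizes the total similarity
#' (exhaustive search over permutations; module counts in this setting are
#' small), the matched pairs and their correlations. A zero-variance module
#' yields an `NA` correlation (with a warning) and contributes zero to the
#' pairing objective.
#'
#' @param a,b Matrices holding one module per column (for temporal modules
#'   pass `Wt`; for spatial modules pass `t(W)`), with equal module counts.
#' @return A tibble with columns `module_a`, `module_b`, `r`.
#' @export
module_similarity <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b) || nrow(a) != nrow(b)) {
    stop("module sets must have equal counts and lengths.")
  }
  n <- ncol(a)
  sd_a <- apply(a, 2, stats::sd)
  sd_b <- apply(b, 2, stats::sd)
  if (any(sd_a == 0) || any(sd_b == 0)) {
    warning("zero-variance module(s): their correlations are reported as NA.")
  }
  R <- suppressWarnings(stats::cor(a, b))
  R[!is.finite(R)] <- NA_real_
  score <- ifelse(is.na(R), 0, R)
  perms <- all_permutations(n)
  totals <- vapply(perms, function(p) sum(score[cbind(seq_len(n), p)]), numeric(1))
  best <- perms[[which.max(totals)]]
  tibble::tibble(
    module_a = seq_len(n),
    module_b = best,
    r = R[cbind(seq_len(n), best)]
  )
}

all_permutations <- function(n) {
  rec <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (p in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  rec(seq_len(n))
}

#' Generalization score by SVM over projected coefficients (CLS)
#'
#' Repeated stratified random subsampling: in each of `n_splits` splits,
#' `n_train_per_task` trials per task form the training set; modules are
#' fitted on the training trials only (via `fit_fn`), all trials are
#' projected onto those fixed modules with [project_onto_modules()] (no task
#' information used), a linear SVM (`C = 1`) is trained on the training
#' coefficients, and CLS is the fraction of test trials classified
#' correctly.
#'
#' @param data An [emg_dataset()] or coercible.
#' @param labels Integer task labels (taken from `data` if present).
#' @param fit_fn Function `(data_subset) -> spacetime_fit` (or
#'   `spacetime_model`) fitting the modules on the training trials; wrap
#'   [fit_snm3f()] or [fit_dsnm3f()] with the desired settings.
#' @param n_train_per_task Training trials per task (must be smaller than
#'   the smallest class).
#' @param n_splits Number of random splits.
#' @param seed Seed controlling the split sequence.
#' @param cost Linear-SVM cost parameter.
#' @return A list with `cls_mean`, `cls_sd`, and `splits` (tibble of
#'   per-split scores).
#' @export
svm_classify_cv <- function(data, labels = NULL, fit_fn, n_train_per_task,
                            n_splits = 20, seed = 1, cost = 1) {
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  counts <- table(labels)
  if (n_train_per_task >= min(counts)) {
    stop("`n_train_per_task` must be smaller than the smallest class (", min(counts), ").")
  }
  classes <- sort(unique(labels))
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max %/% 2, n_splits)
  scores <- numeric(n_splits)
  for (i in seq_len(n_splits)) {
    set.seed(split_seeds[i])
    train_idx <- unlist(lapply(classes, function(k) {
      sample(which(labels == k), n_train_per_task)
    }))
    if (length(unique(labels[train_idx])) < length(classes)) {
      stop("a task is absent from a training split.")
    }
    test_idx <- setdiff(seq_along(labels), train_idx)
    train_data <- emg_dataset(data$samples[train_idx], labels = labels[train_idx])
    fit <- fit_fn(train_data)
    coef_all <- project_onto_modules(data, fit)
    X <- coef_feature_matrix(coef_all)
    sv <- e1071::svm(
      x = X[train_idx, , drop = FALSE],
      y = factor(labels[train_idx], levels = classes),
      kernel = "linear", cost = cost, scale = FALSE
    )
    pred <- stats::predict(sv, X[test_idx, , drop = FALSE])
    scores[i] <- mean(as.character(pred) == as.character(labels[test_idx]))
  }
  list(
    cls_mean = mean(scores), cls_sd = stats::sd(scores),
    splits = tibble::tibble(split = seq_len(n_splits), cls = scores)
  )
}

#' Evaluate one fitted decomposition
#'
#' Computes VAF, leave-one-out decoding DEC, VDM, the scatter traces and the
#' Fisher ratio J for a fitted model on a labelled dataset.
#'
#' @param data An [emg_dataset()] or coercible.
#' @param model A [spacetime_model()] or `spacetime_fit`.
#' @param labels Integer task labels (taken from `data` if present).
#' @return One-row tibble: `vaf`, `dec`, `vdm`, `tr_sw`, `tr_sb`, `j_ratio`.
#' @export
evaluate_model <- function(data, model, labels = NULL) {
  if (inherits(model, "spacetime_fit")) model <- model$model
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  v <- vaf(data, model)
  dec <- lda_decode_loo(model, labels)
  sc <- coef_scatter(model$coef, labels)
  tibble::tibble(
    vaf = v, dec = dec, vdm = vdm(v, dec),
    tr_sw = sc$tr_sw, tr_sb = sc$tr_sb,
    j_ratio = if (sc$tr_sb > 0) sc$tr_sw / sc$tr_sb else NA_real_
  )
}

#' Side-by-side comparison of two decompositions
#'
#' Evaluates two models fitted on the same data (VAF, DEC, VDM, scatter
#' traces, J) and computes cross-model similarities of temporal modules,
#' spatial modules, and per-task mean activation coefficients. Numbers only;
#' no ranking verdict.
#'
#' @inheritParams evaluate_model
#' @param model_a,model_b Two [spacetime_model()]s or `spacetime_fit`s.
#' @param names Length-2 character vector naming the models in the report.
#' @return A list of class `model_comparison`: `metrics` (two-row tibble),
#'   `temporal_similarity`, `spatial_similarity`, `coef_similarity`
#'   (tibbles).
#' @export
compare_models <- function(data, model_a, model_b, labels = NULL,
                           names = c("model_a", "model_b")) {
  if (inherits(model_a, "spacetime_fit")) model_a <- model_a$model
  if (inherits(model_b, "spacetime_fit")) model_b <- model_b$model
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  metrics <- dplyr::bind_rows(
    dplyr::mutate(evaluate_model(data, model_a, labels), model = names[1], .before = 1),
    dplyr::mutate(evaluate_model(data, model_b, labels), model = names[2], .before = 1)
  )
  task_mean_coef <- function(model) {
    sc <- coef_scatter(model$coef, labels)
    # one column per coefficient, rows = tasks
    do.call(rbind, lapply(sc$class_means, as.vector))
  }
  ca <- task_mean_coef(model_a)
  cb <- task_mean_coef(model_b)
  coef_sim <- tibble::tibble(
    coefficient = seq_len(ncol(ca)),
    r = vapply(seq_len(ncol(ca)), function(j) {
      suppressWarnings(stats::cor(ca[, j], cb[, j]))
    }, numeric(1))
  )
  structure(
    list(
      metrics = metrics,
      temporal_similarity = module_similarity(model_a$temporal, model_b$temporal),
      spatial_similarity = module_similarity(t(model_a$spatial), t(model_b$spatial)),
      coef_similarity = coef_sim
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$metrics)
  invisible(x)
}
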