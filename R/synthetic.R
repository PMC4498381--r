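#' Specification of a ground-truthed synthetic EMG dataset
#'
#' Defines the generative model used by [generate_emg()]: known unit-sum
#' temporal and spatial modules, per-task mean coefficient matrices, a
#' within-task coefficient of variation, and additive-plus-multiplicative
#' measurement noise scaled to a fraction of the signal.
#'
#' @param temporal `T x P` matrix of true temporal modules (columns; unit
#'   sum enforced).
#' @param spatial `N x M` matrix of true spatial modules (rows; unit sum
#'   enforced).
#' @param task_mean_coef List of `K` non-negative `P x N` matrices: the
#'   task-mean activation coefficients.
#' @param n_trials_per_task Trials generated per task.
#' @param within_task_cv Coefficient of variation of the trial coefficients
#'   around the task mean (truncated-at-zero normal draws).
#' @param noise_fraction Noise level as a fraction of the signal (both the
#'   multiplicative and the additive component are scaled by it).
#' @param seed Seed used by [generate_emg()].
#' @return A list of class `synergy_spec`.
#' @export
synergy_spec <- function(temporal, spatial, task_mean_coef,
                         n_trials_per_task, within_task_cv = 0.1,
                         noise_fraction = 0.4, seed = 1L) {
  temporal <- as.matrix(temporal)
  spatial <- as.matrix(spatial)
  stopifnot(
    all(temporal >= 0), all(spatial >= 0),
    within_task_cv >= 0, noise_fraction >= 0, noise_fraction < 1,
    n_trials_per_task >= 1
  )
  temporal <- sweep(temporal, 2, colSums(temporal), "/")
  spatial <- sweep(spatial, 1, rowSums(spatial), "/")
  P <- ncol(temporal); N <- nrow(spatial)
  task_mean_coef <- lapply(task_mean_coef, as.matrix)
  ok <- vapply(task_mean_coef, function(a) {
    identical(dim(a), c(P, N)) && all(a >= 0)
  }, logical(1))
  if (!all(ok)) stop("every task-mean coefficient matrix must be non-negative P x N.")
  structure(
    list(
      temporal = temporal, spatial = spatial,
      task_mean_coef = task_mean_coef,
      K = length(task_mean_coef),
      n_trials_per_task = as.integer(n_trials_per_task),
      within_task_cv = within_task_cv,
      noise_fraction = noise_fraction,
      seed = as.integer(seed),
      dims = c(
        T = nrow(temporal), M = ncol(spatial), P = P, N = N,
        S = length(task_mean_coef) * as.integer(n_trials_per_task)
      )
    ),
    class = "synergy_spec"
  )
}

#' @export
print.synergy_spec <- function(x, ...) {
  d <- x$dims
  cat("<synergy_spec> ", x$K, " tasks x ", x$n_trials_per_task, " trials; ",
    d[["T"]], " x ", d[["M"]], " trials from P = ", d[["P"]], ", N = ", d[["N"]],
    " modules; cv = ", x$within_task_cv, ", noise = ", x$noise_fraction, "\n",
    sep = ""
  )
  invisible(x)
}

#' Small four-task benchmark specification
#'
#' A compact simulation design: two temporal modules over two time points,
#' two spatial modules over two muscles, four tasks of ten trials each, 40%
#' additive-plus-multiplicative noise. The task-mean coefficient matrices
#' are pairwise separated by at least five within-task standard deviations,
#' so the tasks are perfectly discriminable from the true coefficients by
#' construction.
#'
#' @param seed Seed stored in the spec (used by [generate_emg()]).
#' @param noise_fraction Noise level; default 0.4.
#' @param within_task_cv Within-task coefficient of variation; default 0.1.
#' @return A [synergy_spec()].
#' @examples
#' d <- generate_emg(toy_synergy_spec(seed = 7))
#' d$dataset
#' @export
toy_synergy_spec <- function(seed = 1L, noise_fraction = 0.4, within_task_cv = 0.1) {
  synergy_spec(
    temporal = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2),
    spatial = matrix(c(0.75, 0.25, 0.3, 0.7), 2, 2, byrow = TRUE),
    task_mean_coef = list(
      matrix(c(2.0, 0.5, 0.5, 1.0), 2, 2, byrow = TRUE),
      matrix(c(0.5, 2.0, 1.0, 0.5), 2, 2, byrow = TRUE),
      matrix(c(1.0, 1.0, 2.5, 0.5), 2, 2, byrow = TRUE),
      matrix(c(0.5, 1.0, 0.5, 2.5), 2, 2, byrow = TRUE)
    ),
    n_trials_per_task = 10L,
    within_task_cv = within_task_cv,
    noise_fraction = noise_fraction,
    seed = seed
  )
}

#' Realistic arm-pointing-scale specification
#'
#' A synthetic design at the scale of a typical upper-limb pointing
#' experiment: 9 muscles, 50 time steps, 16 tasks (8 movement directions at
#' 2 speeds) of 40 trials each, generated from 3 temporal modules (two
#' single-burst and one double-burst Gaussian-bump waveforms, echoing the
#' triphasic agonist-antagonist-agonist pattern) and 4 sparse spatial
#' muscle groupings. Mean coefficients for the 8 fast-speed tasks are scaled
#' above the normal-speed tasks. The EMG is statistical, not physiological:
#' no biomechanics is modelled.
#'
#' @inheritParams toy_synergy_spec
#' @return A [synergy_spec()] with `S = 640` trials of `50 x 9`.
#' @export
pointing_synergy_spec <- function(seed = 1L, noise_fraction = 0.4,
                                  within_task_cv = 0.1) {
  T <- 50L
  tt <- seq_len(T) / T
  bump <- function(center, width) exp(-(tt - center)^2 / (2 * width^2))
  temporal <- cbind(
    bump(0.2, 0.08), # early agonist burst
    bump(0.55, 0.1), # antagonist braking burst
    bump(0.15, 0.06) + bump(0.85, 0.08) # double burst: support + stabilize
  )
  spatial <- rbind(
    c(0, 0, 0, 1.0, 0.9, 0, 0, 0, 0.1), # elbow extensors
    c(0.2, 0, 0.1, 0, 0, 1.0, 0, 0.8, 0), # shoulder flexors
    c(0, 0, 0, 0.1, 0, 0, 1.0, 0, 0.9), # shoulder extensors
    c(0.3, 0.9, 1.0, 0, 0, 0, 0.1, 0, 0) # elbow flexors
  )
  dir_weight <- function(th) pmax(c(cos(th), sin(th), -cos(th), -sin(th)), 0) + 0.2
  task_mean_coef <- list()
  for (speed in c(1, 1.8)) {
    for (d in 1:8) {
      r <- dir_weight(2 * pi * (d - 1) / 8)
      task_mean_coef[[length(task_mean_coef) + 1L]] <-
        speed * outer(c(1, 0.8, 0.5), r)
    }
  }
  synergy_spec(
    temporal = temporal, spatial = spatial,
    task_mean_coef = task_mean_coef,
    n_trials_per_task = 40L,
    within_task_cv = within_task_cv,
    noise_fraction = noise_fraction,
    seed = seed
  )
}

# truncated-at-zero normal draws by inverse-CDF sampling
rtruncnorm0 <- function(n, mean, sd) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmax(out, 0)
}

#' Generate a synthetic EMG dataset from a specification
#'
#' For each trial of task `k`, coefficient entries are drawn from a
#' truncated-at-zero normal with mean `task_mean_coef[[k]]` and standard
#' deviation `within_task_cv * mean`. The clean signal `Wt A^s W` is then
#' corrupted as `observed = max(0, signal * (1 + f*u) + f * sbar * v)` with
#' `u`, `v` i.i.d. standard-normal fields, `f` the `noise_fraction`, and
#' `sbar` the trial's mean absolute signal level — a multiplicative and an
#' additive component, each scaled to the stated fraction of the signal.
#'
#' @param spec A [synergy_spec()].
#' @return A list of class `synthetic_emg`: `dataset` (labelled
#'   [emg_dataset()]), `spec`, and `coef` (the realized true per-trial
#'   coefficient matrices).
#' @export
generate_emg <- function(spec) {
  stopifnot(inherits(spec, "synergy_spec"))
  set.seed(spec$seed)
  d <- spec$dims
  P <- d[["P"]]; N <- d[["N"]]
  samples <- list()
  coefs <- list()
  labels <- integer(0)
  for (k in seq_len(spec$K)) {
    mu <- spec$task_mean_coef[[k]]
    for (r in seq_len(spec$n_trials_per_task)) {
      a <- matrix(
        rtruncnorm0(P * N, as.vector(mu), spec$within_task_cv * as.vector(mu)),
        P, N
      )
      signal <- spec$temporal %*% a %*% spec$spatial
      f <- spec$noise_fraction
      if (f > 0) {
        u <- matrix(stats::rnorm(length(signal)), nrow(signal))
        v <- matrix(stats::rnorm(length(signal)), nrow(signal))
        sbar <- mean(abs(signal))
        obs <- pmax(signal * (1 + f * u) + f * sbar * v, 0)
      } else {
        obs <- signal
      }
      samples[[length(samples) + 1L]] <- obs
      coefs[[length(coefs) + 1L]] <- a
      labels <- c(labels, k)
    }
  }
  structure(
    list(
      dataset = emg_dataset(samples, labels = labels),
      spec = spec,
      coef = coefs
    ),
    class = "synthetic_emg"
  )
}

#' @export
print.synthetic_emg <- function(x, ...) {
  cat("<synthetic_emg>\n")
  print(x$dataset)
  invisible(x)
}

#' Score recovery of the generative truth by a fitted model
#'
#' Pairs fitted with true modules by [module_similarity()] (temporal and
#' spatial separately) and, under that module pairing, correlates the
#' fitted per-task mean coefficients with the true task means.
#'
#' @param fit A `spacetime_fit` or [spacetime_model()] with the same module
#'   counts as the truth.
#' @param truth A `synthetic_emg` (from [generate_emg()]).
#' @return A list with tibbles `temporal` and `spatial` (pairing + `r` per
#'   module) and scalar `coef_r` (correlation of task-mean coefficients).
#' @export
recovery_score <- function(fit, truth) {
  if (inherits(fit, "spacetime_fit")) fit <- fit$model
  stopifnot(inherits(truth, "synthetic_emg"))
  spec <- truth$spec
  if (!identical(unname(fit$dims[c("T", "M", "P", "N")]), unname(spec$dims[c("T", "M", "P", "N")]))) {
    stop("fitted dimensions do not match the generative truth.")
  }
  tsim <- module_similarity(spec$temporal, fit$temporal)
  ssim <- module_similarity(t(spec$spatial), t(fit$spatial))
  labels <- truth$dataset$labels
  fit_means <- coef_scatter(fit$coef, labels)$class_means
  true_means <- coef_scatter(truth$coef, labels)$class_means
  # reorder fitted coefficients to the true module order
  perm_t <- tsim$module_b[order(tsim$module_a)]
  perm_s <- ssim$module_b[order(ssim$module_a)]
  fm <- unlist(lapply(fit_means, function(m) as.vector(m[perm_t, perm_s, drop = FALSE])))
  tm <- unlist(lapply(true_means, as.vector))
  list(
    temporal = tsim,
    spatial = ssim,
    coef_r = suppressWarnings(stats::cor(fm, tm))
  )
}
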