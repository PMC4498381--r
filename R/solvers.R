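#' Options controlling the decomposition solvers
#'
#' @param max_iter Maximum outer iterations per restart.
#' @param tol Relative change of the solver's own objective below which the
#'   iteration stops.
#' @param n_restarts Number of random restarts; the best restart (lowest
#'   final cost, ties broken by reconstruction error then restart index) is
#'   returned. Local minima are common in NMF-type problems, so multiple
#'   restarts are recommended for real analyses.
#' @param seed Master seed; restart `r` uses `seed + r - 1`.
#' @param epsilon_guard Small positive constant added to multiplicative-update
#'   denominators. An entry that reaches exactly zero stays zero
#'   (multiplicative absorption).
#' @param track_history Record per-iteration cost traces?
#' @param qp_max_iter Projected-gradient iterations per module update in the
#'   `als_qp` solver.
#' @param nlp_outer,nlp_inner Augmented-Lagrangian outer iterations and
#'   L-BFGS-B iterations per inner solve for the `nlp` solver.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-8, n_restarts = 10L,
                        seed = 1L, epsilon_guard = 1e-12,
                        track_history = TRUE, qp_max_iter = 100L,
                        nlp_outer = 25L, nlp_inner = 300L) {
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 1, epsilon_guard > 0)
  structure(
    list(
      max_iter = as.integer(max_iter), tol = tol,
      n_restarts = as.integer(n_restarts), seed = as.integer(seed),
      epsilon_guard = epsilon_guard, track_history = isTRUE(track_history),
      qp_max_iter = as.integer(qp_max_iter),
      nlp_outer = as.integer(nlp_outer), nlp_inner = as.integer(nlp_inner)
    ),
    class = "fit_options"
  )
}

# ---- batched matrix helpers (3-D arrays, trial index last) ----------------

# B %*% A[,,s] for every s
bmm_left <- function(B, A3) {
  d <- dim(A3)
  array(B %*% matrix(A3, d[1], d[2] * d[3]), c(nrow(B), d[2], d[3]))
}

# A[,,s] %*% B for every s
bmm_right <- function(A3, B) {
  d <- dim(A3)
  At <- aperm(A3, c(2, 1, 3))
  out <- array(t(B) %*% matrix(At, d[2], d[1] * d[3]), c(ncol(B), d[1], d[3]))
  aperm(out, c(2, 1, 3))
}

# stack trials vertically: T x M x S -> (T*S) x M
vstack <- function(A3) {
  d <- dim(A3)
  matrix(aperm(A3, c(1, 3, 2)), d[1] * d[3], d[2])
}

# data unfolds reused across iterations
data_unfolds <- function(data) {
  Marr <- emg_array(data)
  d <- dim(Marr)
  list(
    arr = Marr,
    h = matrix(Marr, d[1], d[2] * d[3]), # T x (M*S), horizontal concat
    v = vstack(Marr), # (T*S) x M, vertical concat
    T = d[1], M = d[2], S = d[3]
  )
}

recon_error <- function(un, Wt, W, A3) {
  recon <- bmm_left(Wt, bmm_right(A3, W))
  sum((un$arr - recon)^2)
}

# traces of the coefficient scatter, vectorized over a P*N x S matrix
scatter_traces <- function(Amat, lab_idx, n_k) {
  K <- length(n_k)
  gmean <- rowMeans(Amat)
  cm <- vapply(seq_len(K), function(k) {
    rowMeans(Amat[, lab_idx == k, drop = FALSE])
  }, numeric(nrow(Amat)))
  cm <- matrix(cm, nrow = nrow(Amat))
  dev <- Amat - cm[, lab_idx, drop = FALSE]
  list(
    tr_sw = sum(dev * dev),
    tr_sb = sum((cm - gmean)^2),
    class_means = cm, global_mean = gmean
  )
}

random_init <- function(un, P, N) {
  T <- un$T; M <- un$M; S <- un$S
  Wt <- matrix(stats::runif(T * P), T, P)
  W <- matrix(stats::runif(N * M), N, M)
  A3 <- array(stats::runif(P * N * S), c(P, N, S))
  Wt <- sweep(Wt, 2, colSums(Wt), "/")
  W <- sweep(W, 1, rowSums(W), "/")
  # least-squares global rescale of the coefficients so the initial
  # reconstruction matches the data scale
  recon <- bmm_left(Wt, bmm_right(A3, W))
  denom <- sum(recon * recon)
  if (denom > 0) {
    A3 <- A3 * max(sum(un$arr * recon) / denom, .Machine$double.eps)
  }
  list(Wt = Wt, W = W, A3 = A3)
}

# multiplicative update of the activation coefficients (Fisher terms
# included when gamma or delta is nonzero); Amat is P*N x S
coef_mult_update <- function(Amat, num0, den0, gamma, delta, lab_idx, n_k, eps) {
  if (gamma > 0 || delta > 0) {
    st <- scatter_traces(Amat, lab_idx, n_k)
    K <- length(n_k)
    S <- ncol(Amat)
    cm_s <- st$class_means[, lab_idx, drop = FALSE]
    n_s <- n_k[lab_idx]
    num <- num0 + sweep(cm_s, 2, gamma + delta / n_s, "*") +
      (delta * K / S) * st$global_mean
    den <- den0 + gamma * Amat +
      outer(st$global_mean, delta / n_s) +
      (delta / S) * rowSums(st$class_means)
  } else {
    num <- num0
    den <- den0
  }
  Amat * num / (den + eps)
}

# ---- the multiplicative engine (sNM3F and DsNM3F-MULT) --------------------

mult_engine <- function(un, labels, P, N, gamma, delta, opts) {
  T <- un$T; M <- un$M; S <- un$S
  discr <- gamma > 0 || delta > 0
  K <- if (discr) length(unique(labels)) else 0L
  init <- random_init(un, P, N)
  res <- mult_engine_cpp(
    un$arr, init$Wt, init$W, init$A3,
    if (discr) as.integer(labels) else integer(0), as.integer(K),
    gamma, delta, opts$max_iter, opts$tol, opts$epsilon_guard,
    opts$track_history
  )
  history <- NULL
  if (opts$track_history) {
    history <- res$history
    colnames(history) <- c("e_nmf", "tr_sw", "tr_sb", "e_total")
  }
  list(
    Wt = res$Wt, W = res$W, A3 = res$A3, e_nmf = res$e_nmf,
    objective = res$objective, converged = res$converged,
    n_iter = res$n_iter, history = history
  )
}

# ---- constrained ALS module updates ---------------------------------------

# Solve min ||Mh - Wt %*% Rh||^2 s.t. colSums(Wt) = 1 through its KKT system,
# then clip negatives and renormalize columns.
als_update_temporal <- function(un, Rh, T, P, clip = TRUE) {
  RRt <- tcrossprod(Rh)
  Num <- un$h %*% t(Rh)
  H <- 2 * kronecker(RRt, diag(T))
  C <- kronecker(diag(P), matrix(1, 1, T))
  kkt <- rbind(cbind(H, t(C)), cbind(C, matrix(0, P, P)))
  rhs <- c(2 * as.vector(Num), rep(1, P))
  sol <- solve_kkt(kkt, rhs)
  Wt <- matrix(sol[seq_len(T * P)], T, P)
  if (!clip) {
    return(Wt)
  }
  Wt[Wt < 0] <- 0
  cs <- colSums(Wt)
  cs[cs <= 0] <- 1
  sweep(Wt, 2, cs, "/")
}

# Solve min ||Mv - Qv %*% W||^2 s.t. rowSums(W) = 1 (KKT), clip, renormalize.
als_update_spatial <- function(un, Qv, N, M) {
  QtQ <- crossprod(Qv)
  Num <- crossprod(Qv, un$v) # N x M
  H <- 2 * kronecker(diag(M), QtQ)
  C <- kronecker(matrix(1, 1, M), diag(N))
  kkt <- rbind(cbind(H, t(C)), cbind(C, matrix(0, N, N)))
  rhs <- c(2 * as.vector(Num), rep(1, N))
  sol <- solve_kkt(kkt, rhs)
  W <- matrix(sol[seq_len(N * M)], N, M)
  W[W < 0] <- 0
  rs <- rowSums(W)
  rs[rs <= 0] <- 1
  sweep(W, 1, rs, "/")
}

solve_kkt <- function(kkt, rhs) {
  sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular KKT system; re-solving with ridge stabilization.")
    n <- nrow(kkt)
    sol <- solve(kkt + 1e-8 * mean(abs(diag(kkt))) * diag(n), rhs)
  }
  sol
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Monotone projected-gradient QP solve of the temporal-module subproblem:
# min ||Mh - Wt Rh||^2 with each column of Wt on the simplex.
qp_update_temporal <- function(un, Rh, Wt, opts) {
  RRt <- tcrossprod(Rh)
  Num <- un$h %*% t(Rh)
  L <- 2 * max(eigen(RRt, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  f <- function(X) sum((un$h - X %*% Rh)^2)
  fx <- f(Wt)
  for (i in seq_len(opts$qp_max_iter)) {
    G <- 2 * (Wt %*% RRt - Num)
    step <- 1 / L
    repeat {
      Xn <- apply(Wt - step * G, 2, project_simplex)
      fn <- f(Xn)
      if (fn <= fx + 1e-12 * max(1, abs(fx)) || step < 1e-16) break
      step <- step / 2
    }
    if (fn > fx) break # cannot improve further
    done <- fx - fn <= 1e-12 * max(1, abs(fx))
    Wt <- Xn
    fx <- fn
    if (done) break
  }
  Wt
}

qp_update_spatial <- function(un, Qv, W, opts) {
  QtQ <- crossprod(Qv)
  Num <- crossprod(Qv, un$v)
  L <- 2 * max(eigen(QtQ, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  f <- function(X) sum((un$v - Qv %*% X)^2)
  fx <- f(W)
  for (i in seq_len(opts$qp_max_iter)) {
    G <- 2 * (QtQ %*% W - Num)
    step <- 1 / L
    repeat {
      Xn <- t(apply(W - step * G, 1, project_simplex))
      fn <- f(Xn)
      if (fn <= fx + 1e-12 * max(1, abs(fx)) || step < 1e-16) break
      step <- step / 2
    }
    if (fn > fx) break
    done <- fx - fn <= 1e-12 * max(1, abs(fx))
    W <- Xn
    fx <- fn
    if (done) break
  }
  W
}

als_engine <- function(un, labels, P, N, gamma, delta, opts, qp = FALSE) {
  T <- un$T; M <- un$M; S <- un$S
  eps <- opts$epsilon_guard
  discr <- gamma > 0 || delta > 0
  lab_idx <- if (discr) labels else NULL
  n_k <- if (discr) as.integer(table(labels)) else NULL
  init <- random_init(un, P, N)
  Wt <- init$Wt; W <- init$W; A3 <- init$A3
  history <- if (opts$track_history) {
    matrix(NA_real_, opts$max_iter, 4,
      dimnames = list(NULL, c("e_nmf", "tr_sw", "tr_sb", "e_total"))
    )
  } else {
    NULL
  }
  objective <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    Rh <- matrix(bmm_right(A3, W), P, M * S)
    Wt <- if (qp) qp_update_temporal(un, Rh, Wt, opts) else als_update_temporal(un, Rh, T, P)
    Qv <- vstack(bmm_left(Wt, A3))
    W <- if (qp) qp_update_spatial(un, Qv, W, opts) else als_update_spatial(un, Qv, N, M)
    num0 <- bmm_right(bmm_left(t(Wt), un$arr), t(W))
    den0 <- bmm_right(bmm_left(crossprod(Wt), A3), tcrossprod(W))
    Amat <- coef_mult_update(
      matrix(A3, P * N, S), matrix(num0, P * N, S), matrix(den0, P * N, S),
      gamma, delta, lab_idx, n_k, eps
    )
    A3 <- array(Amat, c(P, N, S))
    e_rec <- recon_error(un, Wt, W, A3)
    if (discr) {
      st <- scatter_traces(matrix(A3, P * N, S), lab_idx, n_k)
      e_tot <- e_rec + gamma * st$tr_sw - delta * st$tr_sb
      if (opts$track_history) history[iter, ] <- c(e_rec, st$tr_sw, st$tr_sb, e_tot)
    } else {
      e_tot <- e_rec
      if (opts$track_history) history[iter, ] <- c(e_rec, NA, NA, e_tot)
    }
    if (is.finite(objective) &&
      abs(objective - e_tot) <= opts$tol * max(abs(objective), eps)) {
      objective <- e_tot
      converged <- TRUE
      break
    }
    objective <- e_tot
  }
  list(
    Wt = Wt, W = W, A3 = A3, e_nmf = recon_error(un, Wt, W, A3),
    objective = objective, converged = converged, n_iter = iter,
    history = if (opts$track_history) history[seq_len(iter), , drop = FALSE] else NULL
  )
}

# E^2 (reconstruction + Fisher penalty) and its analytic gradient with
# respect to every factor; used by the NLP solver and by the
# finite-difference gradient audits.
e2_value_grad <- function(un, Wt, W, A3, labels = NULL, gamma = 0, delta = 0,
                          grad = TRUE) {
  P <- ncol(Wt); N <- nrow(W); M <- un$M; S <- un$S
  discr <- gamma > 0 || delta > 0
  n_k <- if (discr) as.integer(table(labels)) else NULL
  value <- recon_error(un, Wt, W, A3)
  st <- NULL
  if (discr) {
    st <- scatter_traces(matrix(A3, P * N, S), labels, n_k)
    value <- value + gamma * st$tr_sw - delta * st$tr_sb
  }
  if (!grad) {
    return(list(value = value))
  }
  Rh <- matrix(bmm_right(A3, W), P, M * S)
  gWt <- 2 * (Wt %*% tcrossprod(Rh) - un$h %*% t(Rh))
  Qv <- vstack(bmm_left(Wt, A3))
  gW <- 2 * (crossprod(Qv) %*% W - crossprod(Qv, un$v))
  num0 <- bmm_right(bmm_left(t(Wt), un$arr), t(W))
  den0 <- bmm_right(bmm_left(crossprod(Wt), A3), tcrossprod(W))
  gA <- 2 * (den0 - num0)
  if (discr) {
    Amat <- matrix(A3, P * N, S)
    cm_s <- st$class_means[, labels, drop = FALSE]
    gw <- 2 * (Amat - cm_s)
    sum_dev <- rowSums(st$class_means - st$global_mean)
    gb <- sweep(cm_s - st$global_mean, 2, 2 / n_k[labels], "*") - (2 / S) * sum_dev
    gA <- gA + array(gamma * gw - delta * gb, c(P, N, S))
  }
  list(value = value, gWt = gWt, gA = gA, gW = gW)
}

# ---- NLP engine: augmented Lagrangian over L-BFGS-B -----------------------

nlp_engine <- function(un, labels, P, N, gamma, delta, opts) {
  T <- un$T; M <- un$M; S <- un$S
  discr <- gamma > 0 || delta > 0
  lab_idx <- if (discr) labels else NULL
  n_k <- if (discr) as.integer(table(labels)) else NULL
  nWt <- T * P; nA <- P * N * S; nW <- N * M
  unpack <- function(z) {
    list(
      Wt = matrix(z[seq_len(nWt)], T, P),
      A3 = array(z[nWt + seq_len(nA)], c(P, N, S)),
      W = matrix(z[nWt + nA + seq_len(nW)], N, M)
    )
  }
  phi <- function(z) {
    p <- unpack(z)
    c(colSums(p$Wt) - 1, rowSums(p$W) - 1)
  }
  phi_jac_t_times <- function(lam) {
    # t(Jacobian of phi) %*% lam, exploiting its block structure
    c(
      rep(lam[seq_len(P)], each = T),
      numeric(nA),
      rep(lam[P + seq_len(N)], times = M)
    )
  }
  e2 <- function(p) {
    e2_value_grad(un, p$Wt, p$W, p$A3, lab_idx, gamma, delta, grad = FALSE)$value
  }
  e2_grad <- function(p) {
    g <- e2_value_grad(un, p$Wt, p$W, p$A3, lab_idx, gamma, delta)
    c(as.vector(g$gWt), as.vector(g$gA), as.vector(g$gW))
  }
  init <- random_init(un, P, N)
  z <- c(as.vector(init$Wt), as.vector(init$A3), as.vector(init$W))
  lam <- numeric(P + N)
  mu <- 10
  prev_viol <- Inf
  for (outer in seq_len(opts$nlp_outer)) {
    fn <- function(zz) {
      p <- unpack(zz)
      ph <- phi(zz)
      e2(p) + sum(lam * ph) + (mu / 2) * sum(ph^2)
    }
    gr <- function(zz) {
      p <- unpack(zz)
      ph <- phi(zz)
      e2_grad(p) + phi_jac_t_times(lam + mu * ph)
    }
    res <- stats::optim(z, fn, gr,
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = opts$nlp_inner, factr = 1e4)
    )
    z <- res$par
    ph <- phi(z)
    viol <- max(abs(ph))
    lam <- lam + mu * ph
    if (viol < 1e-8) break
    if (viol > 0.5 * prev_viol) mu <- mu * 10
    prev_viol <- viol
  }
  p <- unpack(z)
  viol <- max(abs(phi(z)))
  list(
    Wt = p$Wt, W = p$W, A3 = p$A3,
    e_nmf = recon_error(un, p$Wt, p$W, p$A3),
    objective = e2(p), converged = viol < 1e-6, n_iter = opts$nlp_outer,
    constraint_violation = viol, history = NULL
  )
}

# ---- restart loop and public fit functions --------------------------------

run_restarts <- function(un, labels, P, N, gamma, delta, opts, engine) {
  best <- NULL
  restart_costs <- numeric(opts$n_restarts)
  for (r in seq_len(opts$n_restarts)) {
    set.seed(opts$seed + r - 1L)
    fit <- engine(un, labels, P, N, gamma, delta, opts)
    restart_costs[r] <- fit$objective
    better <- is.null(best) ||
      fit$objective < best$objective ||
      (fit$objective == best$objective && fit$e_nmf < best$e_nmf)
    if (better) {
      best <- fit
      best$restart <- r
    }
  }
  best$restart_costs <- restart_costs
  best
}

finalize_fit <- function(best, data, labels, P, N, gamma, delta, method, opts) {
  model <- spacetime_model(best$Wt, best$W, best$A3)
  history <- NULL
  if (!is.null(best$history)) {
    history <- tibble::as_tibble(as.data.frame(best$history))
    history <- dplyr::mutate(history, iter = dplyr::row_number(), .before = 1)
  }
  structure(
    list(
      model = model,
      history = history,
      converged = best$converged,
      n_iter = best$n_iter,
      restart = best$restart,
      restart_costs = best$restart_costs,
      final_cost = best$objective,
      e_nmf = best$e_nmf,
      gamma = gamma, delta = delta,
      labels = labels,
      method = method,
      options = opts,
      constraint_violation = best$constraint_violation %||% NA_real_
    ),
    class = "spacetime_fit"
  )
}

#' Fit the space-by-time decomposition (sNM3F)
#'
#' Alternates multiplicative updates of the spatial modules, temporal modules
#' and activation coefficients to minimize the reconstruction error
#' `E2_NMF = sum_s ||M^s - Wt A^s W||^2_fro`, with compensated unit-sum
#' renormalization of the modules after every iteration (so the error trace
#' is non-increasing). The best of `n_restarts` random restarts is returned.
#'
#' @param data An [emg_dataset()] or long data frame (see
#'   [as_emg_dataset()]).
#' @param P Number of temporal modules (`1 <= P <= T`).
#' @param N Number of spatial modules (`1 <= N <= M`).
#' @param options A [fit_options()] list.
#' @return A `spacetime_fit`: list with elements `model`
#'   ([spacetime_model()]), `history` (per-iteration tibble of `e_nmf`,
#'   `tr_sw`, `tr_sb`, `e_total`), `converged`, `n_iter`, `restart`,
#'   `restart_costs`, `final_cost`, `e_nmf`.
#' @examples
#' d <- generate_emg(toy_synergy_spec(seed = 1))
#' fit <- fit_snm3f(d$dataset, P = 2, N = 2, fit_options(n_restarts = 2, seed = 1))
#' vaf(d$dataset, fit$model)
#' @export
fit_snm3f <- function(data, P, N, options = fit_options()) {
  data <- as_emg_dataset(data)
  check_pn(data, P, N)
  un <- data_unfolds(data)
  best <- run_restarts(un, NULL, P, N, 0, 0, options, mult_engine)
  finalize_fit(best, data, data$labels, P, N, 0, 0, "mult", options)
}

#' Fit the task-discriminative decomposition (DsNM3F)
#'
#' Minimizes `E2 = E2_NMF + gamma * tr(Sw) - delta * tr(Sb)`: the
#' reconstruction error plus a Fisher penalty that shrinks the within-task
#' scatter and expands the between-task scatter of the activation
#' coefficients. Three interchangeable solvers are provided:
#'
#' * `"mult"` — multiplicative updates. Module updates are identical to
#'   sNM3F (the Fisher terms do not touch the modules); the coefficient
#'   update splits the gradient of `E2` into positive and negative parts.
#'   Modules are renormalized to unit sum after each iteration without
#'   compensation, which (as a known property of this scheme) forfeits the
#'   monotone-descent guarantee. With `gamma = delta = 0` the fit reduces
#'   exactly to [fit_snm3f()].
#' * `"als"` — the modules are updated by solving the equality-constrained
#'   least-squares (KKT) systems for the unit-sum constraints, with negative
#'   entries clipped to zero afterwards; coefficients use the multiplicative
#'   rule.
#' * `"als_qp"` — as `"als"` but each module update solves the
#'   non-negativity-constrained quadratic program by monotone projected
#'   gradient descent on the simplex, so module steps never increase the
#'   module-update cost.
#' * `"nlp"` — joint constrained optimization of all factors (stacked
#'   variable `z`, analytic gradients) by an augmented-Lagrangian scheme over
#'   `L-BFGS-B`; the returned iterate satisfies the bounds exactly and the
#'   unit-sum constraints to `1e-6`.
#'
#' @inheritParams fit_snm3f
#' @param gamma,delta Non-negative weights of the within-task
#'   (`tr(Sw)`, shrink) and between-task (`tr(Sb)`, expand) scatter terms.
#' @param labels Integer task labels; taken from `data` if present there.
#' @param method Solver: `"mult"` (default), `"als"`, `"als_qp"`, `"nlp"`.
#' @return A `spacetime_fit` (see [fit_snm3f()]).
#' @examples
#' d <- generate_emg(toy_synergy_spec(seed = 1))
#' fit <- fit_dsnm3f(d$dataset,
#'   P = 2, N = 2, gamma = 0.01, delta = 0.01,
#'   options = fit_options(n_restarts = 2, seed = 1)
#' )
#' fit$final_cost
#' @export
fit_dsnm3f <- function(data, P, N, gamma, delta, labels = NULL,
                       method = c("mult", "als", "als_qp", "nlp"),
                       options = fit_options()) {
  method <- match.arg(method)
  data <- as_emg_dataset(data)
  check_pn(data, P, N)
  if (gamma < 0 || delta < 0) stop("`gamma` and `delta` must be non-negative.")
  labels <- labels %||% data$labels
  if (gamma > 0 || delta > 0) {
    labels <- validate_labels(labels, data$dims[["S"]])
    labels <- match(labels, sort(unique(labels)))
  }
  un <- data_unfolds(data)
  engine <- switch(method,
    mult = mult_engine,
    als = function(...) als_engine(..., qp = FALSE),
    als_qp = function(...) als_engine(..., qp = TRUE),
    nlp = nlp_engine
  )
  best <- run_restarts(un, labels, P, N, gamma, delta, options, engine)
  finalize_fit(best, data, labels, P, N, gamma, delta, method, options)
}

check_pn <- function(data, P, N) {
  d <- data$dims
  if (P < 1 || P > d[["T"]]) stop("`P` must lie in 1..T = 1..", d[["T"]], ".")
  if (N < 1 || N > d[["M"]]) stop("`N` must lie in 1..M = 1..", d[["M"]], ".")
  invisible(TRUE)
}

#' Project data onto fixed modules
#'
#' Holds the temporal and spatial modules fixed and finds per-trial
#' activation coefficients by the pure-reconstruction multiplicative
#' coefficient update, run to convergence. No task information is used, so
#' this is the projection step used when evaluating generalization to
#' held-out trials.
#'
#' @param data An [emg_dataset()] or coercible.
#' @param temporal `T x P` temporal-module matrix (or a `spacetime_model`
#'   / `spacetime_fit`, from which both module sets are taken).
#' @param spatial `N x M` spatial-module matrix (ignored when `temporal` is
#'   a model or fit).
#' @param max_iter,tol Iteration cap and relative-change tolerance. The
#'   multiplicative iteration converges slowly near its fixed point, so the
#'   defaults are deliberately strict.
#' @param epsilon_guard Denominator guard of the multiplicative update.
#' @return List of `S` `P x N` coefficient matrices.
#' @export
project_onto_modules <- function(data, temporal, spatial = NULL,
                                 max_iter = 20000L, tol = 1e-13,
                                 epsilon_guard = 1e-12) {
  if (inherits(temporal, "spacetime_fit")) temporal <- temporal$model
  if (inherits(temporal, "spacetime_model")) {
    spatial <- temporal$spatial
    temporal <- temporal$temporal
  }
  data <- as_emg_dataset(data)
  un <- data_unfolds(data)
  Wt <- as.matrix(temporal)
  W <- as.matrix(spatial)
  if (nrow(Wt) != un$T || ncol(W) != un$M) {
    stop("module dimensions do not match the data.")
  }
  S <- un$S
  A3 <- project_coef_cpp(un$arr, Wt, W, max_iter, tol, epsilon_guard)$A3
  array_slices(A3)
}

#' @export
print.spacetime_fit <- function(x, ...) {
  d <- x$model$dims
  cat("<spacetime_fit> method = ", x$method,
    ", P = ", d[["P"]], ", N = ", d[["N"]],
    ", gamma = ", x$gamma, ", delta = ", x$delta, "\n",
    "  final cost ", signif(x$final_cost, 6),
    " (E2_NMF = ", signif(x$e_nmf, 6), ") after ", x$n_iter,
    " iterations; restart ", x$restart, "/", length(x$restart_costs),
    if (isTRUE(x$converged)) "; converged" else "; iteration cap reached", "\n",
    sep = ""
  )
  invisible(x)
}
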