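#' Grid search over the discrimination weights
#'
#' Fits the discriminative decomposition for every `(gamma, delta)` pair on
#' a coarse grid, evaluates VAF, leave-one-out decoding DEC and their
#' product VDM, and returns all records plus the VDM-maximizing cell. The
#' `(0, 0)` cell, when present, reproduces the pure-reconstruction (sNM3F)
#' result by construction. The default grid spans 0 and five log-spaced
#' decades, wide enough to bracket optima reported for typical EMG data.
#'
#' @inheritParams fit_dsnm3f
#' @param gamma_grid,delta_grid Non-negative grid values.
#' @return An object of class `vdm_grid`: list with `grid` (tibble of
#'   `gamma`, `delta`, `vaf`, `dec`, `vdm`, `e_nmf`, `ok`) and `best`
#'   (named vector `gamma`, `delta`).
#' @export
grid_search_gamma_delta <- function(data, P, N,
                                    gamma_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                                    delta_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                                    labels = NULL,
                                    method = "mult",
                                    options = fit_options()) {
  if (length(gamma_grid) == 0 || length(delta_grid) == 0 ||
    any(gamma_grid < 0) || any(delta_grid < 0)) {
    stop("grids must be non-empty and non-negative.")
  }
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  cells <- tidyr::expand_grid(gamma = gamma_grid, delta = delta_grid)
  res <- purrr::pmap(cells, function(gamma, delta) {
    out <- tryCatch(
      {
        fit <- fit_dsnm3f(data, P, N,
          gamma = gamma, delta = delta,
          labels = labels, method = method, options = options
        )
        ev <- evaluate_model(data, fit$model, labels)
        dplyr::mutate(ev, e_nmf = fit$e_nmf, ok = TRUE)
      },
      error = function(e) {
        warning(
          "fit failed at (gamma, delta) = (", gamma, ", ", delta, "): ",
          conditionMessage(e)
        )
        tibble::tibble(
          vaf = NA_real_, dec = NA_real_, vdm = NA_real_,
          tr_sw = NA_real_, tr_sb = NA_real_, j_ratio = NA_real_,
          e_nmf = NA_real_, ok = FALSE
        )
      }
    )
    out
  })
  grid <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  valid <- dplyr::filter(grid, .data$ok)
  if (nrow(valid) == 0) stop("every grid cell failed to fit.")
  top <- valid[which.max(valid$vdm), ]
  structure(
    list(
      grid = grid,
      best = c(gamma = top$gamma, delta = top$delta),
      best_vdm = top$vdm,
      P = P, N = N
    ),
    class = "vdm_grid"
  )
}

#' @export
print.vdm_grid <- function(x, ...) {
  cat("<vdm_grid> ", nrow(x$grid), " cells; best (gamma, delta) = (",
    x$best[["gamma"]], ", ", x$best[["delta"]], ") with VDM = ",
    signif(x$best_vdm, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Local refinement of the discrimination weights
#'
#' Derivative-free (Nelder-Mead) maximization of `VDM(gamma, delta)` in
#' log10 coordinates over the non-negative quadrant, started at the coarse
#' grid optimum. The fit seeds are fixed by `options`, so the objective is
#' deterministic. A zero start component is floored at `1e-8` before taking
#' logs. The returned point never scores below the start.
#'
#' @inheritParams fit_dsnm3f
#' @param start Named or unnamed numeric length-2 vector `(gamma, delta)`.
#' @param maxit Nelder-Mead iteration budget.
#' @return A list with `gamma`, `delta`, `vdm`.
#' @export
refine_gamma_delta <- function(data, P, N, start, labels = NULL,
                               method = "mult", options = fit_options(),
                               maxit = 30) {
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  start <- pmax(as.numeric(start), 0)
  if (length(start) != 2) stop("`start` must be length-2 (gamma, delta).")
  score <- function(gamma, delta) {
    fit <- fit_dsnm3f(data, P, N,
      gamma = gamma, delta = delta,
      labels = labels, method = method, options = options
    )
    ev <- evaluate_model(data, fit$model, labels)
    v <- ev$vdm
    if (!is.finite(v)) stop("non-finite VDM objective at (", gamma, ", ", delta, ").")
    v
  }
  start_vdm <- score(start[1], start[2])
  lstart <- log10(pmax(start, 1e-8))
  opt <- stats::optim(
    lstart,
    function(lp) -score(10^lp[1], 10^lp[2]),
    method = "Nelder-Mead",
    control = list(maxit = maxit, reltol = 1e-3)
  )
  if (-opt$value >= start_vdm) {
    list(gamma = 10^opt$par[1], delta = 10^opt$par[2], vdm = -opt$value)
  } else {
    list(gamma = start[1], delta = start[2], vdm = start_vdm)
  }
}

#' Select the numbers of temporal and spatial modules
#'
#' Computes leave-one-out decoding DEC for each `(P, N)` in the given
#' ranges (fitting the pure-reconstruction decomposition) and returns the
#' most compact pair whose DEC is within `tolerance` of the best: smallest
#' `P * N`, ties broken by smallest `P + N`, then smallest `P`. The default
#' tolerance is one binomial standard error of the maximal DEC at the given
#' number of trials, so extra modules are only accepted when they buy a
#' decoding gain beyond chance fluctuation.
#'
#' @inheritParams fit_snm3f
#' @param P_range,N_range Integer vectors of candidate module counts.
#' @param labels Task labels (taken from `data` if present).
#' @param tolerance DEC slack; default one binomial SE of the maximum DEC.
#' @return A list with `P`, `N`, and `grid` (tibble of all candidates with
#'   their DEC).
#' @export
select_model_order <- function(data, P_range, N_range, labels = NULL,
                               options = fit_options(), tolerance = NULL) {
  data <- as_emg_dataset(data)
  labels <- labels %||% data$labels
  labels <- validate_labels(labels, data$dims[["S"]])
  if (length(P_range) == 0 || length(N_range) == 0) stop("empty model-order range.")
  S <- data$dims[["S"]]
  cells <- tidyr::expand_grid(P = sort(unique(P_range)), N = sort(unique(N_range)))
  dec <- purrr::pmap_dbl(cells, function(P, N) {
    fit <- fit_snm3f(data, P, N, options)
    lda_decode_loo(fit$model, labels)
  })
  grid <- dplyr::mutate(cells, dec = dec)
  dec_max <- max(grid$dec)
  if (is.null(tolerance)) {
    tolerance <- sqrt(dec_max * (1 - dec_max) / S)
  }
  ok <- dplyr::filter(grid, .data$dec >= dec_max - tolerance)
  ok <- dplyr::arrange(ok, .data$P * .data$N, .data$P + .data$N, .data$P)
  list(P = ok$P[1], N = ok$N[1], grid = grid, tolerance = tolerance)
}
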