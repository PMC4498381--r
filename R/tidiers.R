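#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted space-by-time decomposition
#'
#' Returns the requested component of the fit as a long tibble:
#' `"temporal"` (columns `time`, `module`, `value`), `"spatial"`
#' (`module`, `muscle`, `value`), or `"coef"` (`trial`, `task` when known,
#' `temporal_module`, `spatial_module`, `value`).
#'
#' @param x A `spacetime_fit` or [spacetime_model()].
#' @param what One of `"temporal"`, `"spatial"`, `"coef"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spacetime_fit <- function(x, what = c("temporal", "spatial", "coef"), ...) {
  labels <- x$labels
  tidy_spacetime(x$model, match.arg(what), labels)
}

#' @rdname tidy.spacetime_fit
#' @export
tidy.spacetime_model <- function(x, what = c("temporal", "spatial", "coef"), ...) {
  tidy_spacetime(x, match.arg(what), NULL)
}

tidy_spacetime <- function(model, what, labels) {
  d <- model$dims
  switch(what,
    temporal = tibble::tibble(
      time = rep(seq_len(d[["T"]]), times = d[["P"]]),
      module = rep(seq_len(d[["P"]]), each = d[["T"]]),
      value = as.vector(model$temporal)
    ),
    spatial = tibble::tibble(
      module = rep(seq_len(d[["N"]]), times = d[["M"]]),
      muscle = rep(seq_len(d[["M"]]), each = d[["N"]]),
      value = as.vector(model$spatial)
    ),
    coef = {
      out <- tibble::tibble(
        trial = rep(seq_len(d[["S"]]), each = d[["P"]] * d[["N"]]),
        temporal_module = rep(seq_len(d[["P"]]), times = d[["N"]] * d[["S"]]),
        spatial_module = rep(rep(seq_len(d[["N"]]), each = d[["P"]]), times = d[["S"]]),
        value = unlist(lapply(model$coef, as.vector))
      )
      if (!is.null(labels)) {
        out <- dplyr::mutate(out, task = labels[.data$trial], .after = "trial")
      }
      out
    }
  )
}

#' One-row summary of a fitted decomposition
#'
#' @param x A `spacetime_fit`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `P`, `N`, `gamma`, `delta`,
#'   `e_nmf`, `final_cost`, `n_iter`, `converged`, `restart`, `n_restarts`.
#' @export
glance.spacetime_fit <- function(x, ...) {
  d <- x$model$dims
  tibble::tibble(
    method = x$method, P = d[["P"]], N = d[["N"]],
    gamma = x$gamma, delta = x$delta,
    e_nmf = x$e_nmf, final_cost = x$final_cost,
    n_iter = x$n_iter, converged = x$converged,
    restart = x$restart, n_restarts = length(x$restart_costs)
  )
}

#' @rdname glance.spacetime_fit
#' @export
tidy.vdm_grid <- function(x, ...) x$grid

#' @rdname glance.spacetime_fit
#' @export
glance.vdm_grid <- function(x, ...) {
  tibble::tibble(
    gamma = x$best[["gamma"]], delta = x$best[["delta"]],
    vdm = x$best_vdm, P = x$P, N = x$N, n_cells = nrow(x$grid)
  )
}
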