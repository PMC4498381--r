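#' Plot a fitted space-by-time decomposition
#'
#' `type = "temporal"` draws the temporal modules as waveforms over the
#' normalized movement time; `"spatial"` draws the spatial modules as
#' muscle-weighting bar charts; `"history"` draws the per-iteration cost
#' traces of the returned restart.
#'
#' @param object A `spacetime_fit` (or [spacetime_model()] for module
#'   plots).
#' @param type One of `"temporal"`, `"spatial"`, `"history"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacetime_fit <- function(object, type = c("temporal", "spatial", "history"), ...) {
  type <- match.arg(type)
  if (type == "history") {
    if (is.null(object$history)) stop("fit was run without `track_history`.")
    long <- tidyr::pivot_longer(object$history, -"iter",
      names_to = "trace", values_to = "value"
    )
    long <- dplyr::filter(long, is.finite(.data$value))
    return(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(ggplot2::vars(.data$trace), scales = "free_y") +
        ggplot2::labs(x = "iteration", y = NULL)
    )
  }
  autoplot.spacetime_model(object$model, type = type)
}

#' @rdname autoplot.spacetime_fit
#' @export
autoplot.spacetime_model <- function(object, type = c("temporal", "spatial"), ...) {
  if (inherits(object, "spacetime_fit")) object <- object$model
  type <- match.arg(type)
  if (type == "temporal") {
    ggplot2::ggplot(
      tidy_spacetime(object, "temporal", NULL),
      ggplot2::aes(x = .data$time, y = .data$value)
    ) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(ggplot2::vars(.data$module), labeller = ggplot2::label_both) +
      ggplot2::labs(x = "time step", y = "activation")
  } else {
    ggplot2::ggplot(
      tidy_spacetime(object, "spatial", NULL),
      ggplot2::aes(x = factor(.data$muscle), y = .data$value)
    ) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(ggplot2::vars(.data$module), labeller = ggplot2::label_both) +
      ggplot2::labs(x = "muscle", y = "weight")
  }
}

#' Plot a discrimination-weight tuning surface
#'
#' Tile maps of VAF, DEC and VDM over the `(gamma, delta)` grid, with the
#' VDM-maximizing cell starred.
#'
#' @param object A [grid_search_gamma_delta()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdm_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$grid, "gamma", "delta", "vaf", "dec", "vdm"),
    c("vaf", "dec", "vdm"),
    names_to = "metric", values_to = "value"
  )
  best <- tibble::tibble(
    gamma = object$best[["gamma"]], delta = object$best[["delta"]],
    metric = "vdm"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$gamma), y = factor(.data$delta),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = best, ggplot2::aes(x = factor(.data$gamma), y = factor(.data$delta)),
      inherit.aes = FALSE, shape = 8, size = 3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "gamma", y = "delta", fill = NULL)
}

#' Plot trial envelopes of an EMG dataset
#'
#' One panel per muscle, one line per trial, colored by task when labels
#' are present.
#'
#' @param object An [emg_dataset()].
#' @param max_trials Cap on the number of trials drawn (sampled evenly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_dataset <- function(object, max_trials = 50, ...) {
  tbl <- emg_tbl(object)
  keep <- unique(round(seq(1, object$dims[["S"]], length.out = min(max_trials, object$dims[["S"]]))))
  tbl <- dplyr::filter(tbl, .data$trial %in% keep)
  p <- ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$time, y = .data$activity,
    group = .data$trial
  ))
  if ("task" %in% names(tbl)) {
    p <- p + ggplot2::aes(color = factor(.data$task))
  }
  p + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$muscle)) +
    ggplot2::labs(x = "time step", y = "activity", color = "task")
}
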