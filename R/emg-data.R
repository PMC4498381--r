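#' Build a single-trial EMG dataset
#'
#' Collects `S` non-negative trial matrices (each `T` time steps by `M`
#' muscles) and optional integer task labels into the container used by all
#' decomposition and evaluation functions. Trials must share the same
#' dimensions; ragged trials should be resampled first with
#' [time_normalize()].
#'
#' @param samples A list of `S` numeric `T x M` matrices, a 3-D array with
#'   dimensions `T x M x S`, or a long data frame (see [as_emg_dataset()]).
#' @param labels Optional integer task labels, one per trial. Labels are
#'   re-coded internally to `1..K` in order of first appearance of the sorted
#'   unique values; the original values are kept as names of the recoding.
#' @param muscles Optional character vector of muscle names (length `M`).
#'
#' @return An object of class `emg_dataset`: a list with elements `samples`
#'   (list of matrices), `labels` (integer vector in `1..K` or `NULL`),
#'   `muscles`, and `dims` (named vector `S`, `T`, `M`).
#'
#' @examples
#' trials <- replicate(4, matrix(runif(6), 3, 2), simplify = FALSE)
#' d <- emg_dataset(trials, labels = c(1, 1, 2, 2))
#' d$dims
#' @export
emg_dataset <- function(samples, labels = NULL, muscles = NULL) {
  if (is.array(samples) && length(dim(samples)) == 3L) {
    arr <- samples
    samples <- array_slices(arr)
  }
  if (!is.list(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty list of matrices or a T x M x S array.")
  }
  samples <- lapply(samples, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d1 <- dim(samples[[1]])
  ok <- vapply(samples, function(m) identical(dim(m), d1), logical(1))
  if (!all(ok)) stop("all trials must share the same (T, M) dimensions.")
  if (any(vapply(samples, function(m) any(!is.finite(m)), logical(1)))) {
    stop("trial matrices must be finite.")
  }
  if (any(vapply(samples, function(m) any(m < 0), logical(1)))) {
    bad <- which(vapply(samples, function(m) any(m < 0), logical(1)))[1]
    stop("EMG data must be non-negative; trial ", bad, " has negative entries.")
  }
  S <- length(samples)
  if (is.null(muscles) && !is.null(colnames(samples[[1]]))) {
    muscles <- colnames(samples[[1]])
  }
  lab_codes <- NULL
  if (!is.null(labels)) {
    if (length(labels) != S) stop("`labels` must have one entry per trial.")
    if (any(is.na(labels))) stop("`labels` must not contain NA.")
    lev <- sort(unique(labels))
    lab_codes <- match(labels, lev)
    names(lab_codes) <- as.character(labels)
    attr(lab_codes, "levels") <- lev
  }
  structure(
    list(
      samples = samples,
      labels = lab_codes,
      muscles = muscles,
      dims = c(S = S, T = d1[1], M = d1[2])
    ),
    class = "emg_dataset"
  )
}

#' Coerce to an EMG dataset
#'
#' The data-frame method expects long ("tidy") format with one row per
#' (trial, time, muscle) observation: columns `trial`, `time`, `muscle`,
#' `activity` and optionally `task`. Time points and muscles are ordered by
#' their sorted unique values (factors keep their level order).
#'
#' @param x A long data frame, a list of matrices, a 3-D array, or an
#'   `emg_dataset` (returned unchanged).
#' @param ... Passed on to [emg_dataset()].
#' @return An `emg_dataset`.
#' @examples
#' tbl <- tidyr::expand_grid(trial = 1:2, time = 1:3, muscle = c("a", "b"))
#' tbl$activity <- runif(nrow(tbl))
#' as_emg_dataset(tbl)
#' @export
as_emg_dataset <- function(x, ...) UseMethod("as_emg_dataset")

#' @export
as_emg_dataset.emg_dataset <- function(x, ...) x

#' @export
as_emg_dataset.list <- function(x, ...) emg_dataset(x, ...)

#' @export
as_emg_dataset.array <- function(x, ...) emg_dataset(x, ...)

#' @export
as_emg_dataset.data.frame <- function(x, ...) {
  need <- c("trial", "time", "muscle", "activity")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("long EMG data frame needs columns: ", paste(miss, collapse = ", "))
  }
  ord_levels <- function(v) if (is.factor(v)) levels(v) else sort(unique(v))
  trials <- ord_levels(x$trial)
  times <- ord_levels(x$time)
  muscs <- ord_levels(x$muscle)
  ti <- match(x$trial, trials)
  rw <- match(x$time, times)
  cl <- match(x$muscle, muscs)
  arr <- array(NA_real_, c(length(times), length(muscs), length(trials)))
  arr[cbind(rw, cl, ti)] <- x$activity
  if (any(is.na(arr))) stop("long EMG data frame has missing (trial, time, muscle) cells.")
  labels <- NULL
  if ("task" %in% names(x)) {
    per_trial <- tapply(x$task, ti, function(v) {
      u <- unique(v)
      if (length(u) != 1L) stop("each trial must carry a single task label.")
      u
    })
    labels <- as.vector(per_trial)[order(as.integer(names(per_trial)))]
  }
  emg_dataset(arr, labels = labels, muscles = as.character(muscs), ...)
}

#' Long-format view of an EMG dataset
#'
#' @param data An `emg_dataset`.
#' @return A tibble with columns `trial`, `task` (if labelled), `time`
#'   (integer step), `muscle`, `activity`.
#' @examples
#' d <- emg_dataset(list(matrix(1:4 / 4, 2, 2)))
#' emg_tbl(d)
#' @export
emg_tbl <- function(data) {
  data <- as_emg_dataset(data)
  S <- data$dims[["S"]]; Tn <- data$dims[["T"]]; M <- data$dims[["M"]]
  muscs <- data$muscles %||% paste0("m", seq_len(M))
  out <- tibble::tibble(
    trial = rep(seq_len(S), each = Tn * M),
    time = rep(rep(seq_len(Tn), times = M), times = S),
    muscle = rep(rep(muscs, each = Tn), times = S),
    activity = as.vector(vapply(data$samples, as.vector, numeric(Tn * M)))
  )
  if (!is.null(data$labels)) {
    out <- dplyr::mutate(out, task = emg_task_values(data)[.data$trial], .after = "trial")
  }
  out
}

# original (pre-recoding) task values, one per trial
emg_task_values <- function(data) {
  if (is.null(data$labels)) return(NULL)
  attr(data$labels, "levels")[data$labels]
}

# number of classes
emg_n_tasks <- function(data) {
  if (is.null(data$labels)) 0L else length(attr(data$labels, "levels"))
}

# T x M x S array view (copies)
emg_array <- function(data) {
  d <- data$dims
  array(unlist(data$samples, use.names = FALSE), c(d[["T"]], d[["M"]], d[["S"]]))
}

#' @export
print.emg_dataset <- function(x, ...) {
  d <- x$dims
  cat("<emg_dataset> ", d[["S"]], " trials, ", d[["T"]], " time steps x ",
    d[["M"]], " muscles\n",
    sep = ""
  )
  if (!is.null(x$labels)) {
    k <- emg_n_tasks(x)
    cat("  tasks: ", k, " (", paste(utils::head(attr(x$labels, "levels"), 8), collapse = ", "),
      if (k > 8) ", ..." else "", ")\n",
      sep = ""
    )
  } else {
    cat("  tasks: none\n")
  }
  invisible(x)
}

validate_labels <- function(labels, S, require = TRUE) {
  if (is.null(labels)) {
    if (require) stop("task labels are required for this operation.")
    return(NULL)
  }
  if (length(labels) != S) stop("label/sample count mismatch.")
  counts <- table(labels)
  if (any(counts == 0)) stop("every task class must be non-empty.")
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a 3-D array along its last dimension into a list of matrices,
# preserving dims even when an extent equals 1
array_slices <- function(a) {
  d <- dim(a)
  lapply(seq_len(d[3]), function(s) {
    matrix(a[, , s], nrow = d[1], ncol = d[2])
  })
}
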