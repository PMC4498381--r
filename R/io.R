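#' Write / read an EMG dataset as CSV trials plus a JSON manifest
#'
#' The on-disk dialect is one CSV file per trial (`T` rows by `M` columns,
#' header row = muscle names) plus a `manifest.json` listing each trial file
#' and its task label. Round-trips losslessly up to text precision (17
#' significant digits).
#'
#' @param data An [emg_dataset()] or coercible.
#' @param dir Directory to create/write into.
#' @return `write_emg_dir()` returns `dir` invisibly; `read_emg_dir()`
#'   returns an `emg_dataset`.
#' @export
write_emg_dir <- function(data, dir) {
  data <- as_emg_dataset(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  S <- data$dims[["S"]]
  muscs <- data$muscles %||% paste0("m", seq_len(data$dims[["M"]]))
  files <- sprintf("trial_%04d.csv", seq_len(S))
  tasks <- emg_task_values(data)
  for (s in seq_len(S)) {
    m <- data$samples[[s]]
    colnames(m) <- muscs
    utils::write.csv(format(as.data.frame(m), digits = 17, trim = TRUE),
      file.path(dir, files[s]),
      row.names = FALSE, quote = FALSE
    )
  }
  manifest <- list(
    muscles = muscs,
    trials = lapply(seq_len(S), function(s) {
      entry <- list(file = files[s])
      if (!is.null(tasks)) entry$task <- tasks[s]
      entry
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_emg_dir
#' @param path Directory containing `manifest.json` (or the path to the
#'   manifest itself).
#' @export
read_emg_dir <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  if (is.null(manifest$trials) || length(manifest$trials) == 0) {
    stop("malformed manifest: no trials listed.")
  }
  samples <- list()
  labels <- c()
  has_task <- !is.null(manifest$trials[[1]]$task)
  for (i in seq_along(manifest$trials)) {
    tr <- manifest$trials[[i]]
    f <- file.path(dir, tr$file)
    if (!file.exists(f)) stop("manifest references a missing file: ", tr$file)
    m <- as.matrix(utils::read.csv(f, check.names = FALSE))
    storage.mode(m) <- "double"
    if (any(m < 0)) stop("negative entries in trial ", tr$file, ".")
    samples[[i]] <- m
    if (has_task) labels <- c(labels, tr$task)
  }
  shapes <- vapply(samples, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) {
    stop("inconsistent trial shapes across files: ", paste(unique(shapes), collapse = ", "))
  }
  emg_dataset(samples,
    labels = if (has_task) unlist(labels) else NULL,
    muscles = unlist(manifest$muscles)
  )
}

#' Save / load a space-by-time model as JSON
#'
#' All matrices are written at full double precision.
#'
#' @param model A [spacetime_model()] (or `spacetime_fit`, whose model is
#'   saved).
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `spacetime_model`.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "spacetime_fit")) model <- model$model
  stopifnot(inherits(model, "spacetime_model"))
  # matrices stored as flat column-major vectors; dims allow exact reshaping
  payload <- list(
    dims = as.list(model$dims),
    temporal = as.vector(model$temporal),
    spatial = as.vector(model$spatial),
    coef = lapply(model$coef, as.vector)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- payload$dims
  as_mat <- function(x, nr, nc) matrix(as.numeric(x), nr, nc)
  coef <- payload$coef
  if (is.matrix(coef)) coef <- lapply(seq_len(nrow(coef)), function(s) coef[s, ])
  spacetime_model(
    as_mat(payload$temporal, d$T, d$P),
    as_mat(payload$spatial, d$N, d$M),
    lapply(coef, function(a) as_mat(a, d$P, d$N))
  )
}

#' Read a run configuration file
#'
#' Reads a JSON (or, when the `yaml` package is available, YAML)
#' configuration document mapping option names to values, as used by the
#' command-line interface.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package; use JSON instead.")
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize / restore a model-comparison report as JSON
#'
#' @param report A [compare_models()] result.
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a `model_comparison`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "model_comparison"))
  jsonlite::write_json(
    lapply(unclass(report), as.data.frame),
    path,
    digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    lapply(raw, tibble::as_tibble),
    class = "model_comparison"
  )
}
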