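#' EMG envelope: rectification and zero-phase low-pass filtering
#'
#' Full-wave rectifies each channel (absolute value) and applies a low-order
#' Butterworth low-pass filter forward and backward (zero phase distortion)
#' at the given cutoff. Filter undershoot is clipped at zero so the envelope
#' stays non-negative.
#'
#' @param signal Numeric `L x M` matrix (or vector) of raw EMG, one column
#'   per muscle; may be negative.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Low-pass cutoff in Hz (must be below the Nyquist
#'   frequency `fs / 2`). The conventional envelope cutoff for movement EMG
#'   is a few Hz; default 3.
#' @param order Butterworth order of the underlying filter (applied twice
#'   by the forward-backward pass); default 4, order 2 is also customary.
#' @return Non-negative matrix of the same size.
#' @export
emg_envelope <- function(signal, fs, cutoff_hz = 3, order = 4) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) stop("need at least two samples per trial.")
  if (fs <= 0) stop("`fs` must be positive.")
  if (cutoff_hz >= fs / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency fs/2 = ", fs / 2, " Hz.")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  out <- apply(abs(signal), 2, function(x) zerophase_filter(bf, x))
  out <- matrix(out, nrow = nrow(signal))
  pmax(out, 0)
}

# Forward-backward IIR filtering with steady-state initial conditions at
# both ends (matching the boundary samples), so a constant signal passes
# exactly and edge transients of the naive double pass are avoided.
zerophase_filter <- function(bf, x) {
  b <- bf$b
  a <- bf$a
  n <- max(length(a), length(b)) - 1
  gain <- sum(b) / sum(a)
  state <- function(x0) list(x = rep(x0, n), y = rep(x0 * gain, n))
  s1 <- state(x[1])
  y <- as.numeric(signal::filter(b, a, x, init.x = s1$x, init.y = s1$y))
  s2 <- state(y[length(y)])
  rev(as.numeric(signal::filter(b, a, rev(y), init.x = s2$x, init.y = s2$y)))
}

#' Resample a trial to a fixed number of time steps
#'
#' Per-muscle linear interpolation of an `L x M` envelope onto `T` evenly
#' spaced points spanning the original duration. The first and last rows
#' are preserved exactly.
#'
#' @param env Numeric `L x M` matrix (`L >= 2`).
#' @param T Target number of time steps (default 50).
#' @return A `T x M` matrix.
#' @export
time_normalize <- function(env, T = 50) {
  env <- as.matrix(env)
  L <- nrow(env)
  if (L < 2) stop("need at least two time samples to interpolate.")
  grid <- seq(0, L - 1, length.out = T)
  out <- apply(env, 2, function(x) {
    stats::approx(x = 0:(L - 1), y = x, xout = grid)$y
  })
  matrix(out, nrow = T, dimnames = list(NULL, colnames(env)))
}

#' Per-muscle amplitude normalization across a dataset
#'
#' Divides each muscle column by that muscle's maximal value over all trials
#' and time steps, so every muscle's maximum across the experiment equals 1.
#' An identically-zero muscle is left unscaled with a warning.
#'
#' @param data An [emg_dataset()] or coercible.
#' @return An `emg_dataset` with per-muscle maxima equal to 1 (or 0 for a
#'   silent muscle).
#' @export
amplitude_normalize <- function(data) {
  data <- as_emg_dataset(data)
  maxima <- Reduce(pmax, lapply(data$samples, function(m) apply(m, 2, max)))
  if (any(maxima <= 0)) {
    warning("identically-zero muscle(s) left unscaled.")
  }
  scale <- ifelse(maxima <= 0, 1, maxima)
  samples <- lapply(data$samples, function(m) sweep(m, 2, scale, "/"))
  emg_dataset(samples,
    labels = if (is.null(data$labels)) NULL else emg_task_values(data),
    muscles = data$muscles
  )
}
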