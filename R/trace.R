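#' Convert a raw fluorescence trace to dF/F0
#'
#' Computes the relative fluorescence change `(F - F0) / F0` with `F0` the
#' mean raw fluorescence over the pre-stimulus baseline window.
#'
#' @param f Numeric vector of raw fluorescence (a.u.).
#' @param sampling_rate Sampling rate in Hz.
#' @param baseline_window Half-open interval `c(start, end)` in seconds,
#'   within the trace and preceding stimulation onset; by convention the full
#'   pre-stimulus baseline (0--10 s multi-train, 0--3 s long-train), see
#'   [baseline_window()].
#' @return A `dff_trace`: list with `values` (dF/F0), `sampling_rate`,
#'   `baseline_window` and `f0`.
#' @examples
#' d <- compute_dff(c(10, 10, 10, 12, 11), 1, c(0, 3))
#' d$values # 0 0 0 0.2 0.1
#' @export
compute_dff <- function(f, sampling_rate, baseline_window) {
  stopifnot(is.numeric(f), sampling_rate > 0, length(baseline_window) == 2)
  idx <- window_indices(baseline_window, sampling_rate, length(f))
  if (length(idx) == 0)
    stop("baseline window contains no samples", call. = FALSE)
  f0 <- mean(f[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline fluorescence F0; cannot normalise",
      call. = FALSE)
  new_dff_trace((f - f0) / f0, sampling_rate, baseline_window, f0)
}

new_dff_trace <- function(values, sampling_rate, baseline_window = NULL,
                          f0 = NA_real_) {
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
    baseline_window = baseline_window, f0 = f0), class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace: %d samples at %g Hz, F0 = %.4g>\n",
    length(x$values), x$sampling_rate, x$f0))
  invisible(x)
}

#' @export
as.numeric.dff_trace <- function(x, ...) x$values

# accept either a dff_trace or a bare numeric vector
dff_values <- function(x) {
  if (inherits(x, "dff_trace")) x$values else as.numeric(x)
}

#' Scalar Kalman smoothing of a fluorescence trace
#'
#' Causal recursive filter used for display smoothing: a constant-level
#' state-space model with unit measurement-noise variance, process-noise
#' variance `process_noise`, and initial error variance set so the first
#' update uses `gain`. Each step computes
#' `estimate_t = estimate_{t-1} + k_t (obs_t - estimate_{t-1})` with `k_t`
#' from the standard scalar Kalman recursion. The first output equals the
#' first input; `gain = 1` is an exact pass-through.
#'
#' @param x A `dff_trace` or numeric vector.
#' @param gain Initial Kalman gain, in (0, 1].
#' @param process_noise Process-noise variance (relative to unit measurement
#'   noise).
#' @return Same type as the input, smoothed.
#' @export
kalman_smooth <- function(x, gain = 0.5, process_noise = 0.05) {
  stopifnot(gain > 0, gain <= 1, process_noise >= 0)
  v <- dff_values(x)
  n <- length(v)
  if (n > 0 && gain < 1) {
    out <- numeric(n)
    out[1] <- v[1]
    p <- gain / (1 - gain) # prior error variance giving k_1 = gain
    est <- v[1]
    for (i in seq_len(n)[-1]) {
      p <- p + process_noise
      k <- p / (p + 1)
      est <- est + k * (v[i] - est)
      p <- (1 - k) * p
      out[i] <- est
    }
    v <- out
  }
  if (inherits(x, "dff_trace")) {
    x$values <- v
    x
  } else v
}

#' Pointwise trial average of dF/F0 traces
#'
#' @param traces List of `dff_trace` objects (or numeric vectors) of equal
#'   length and sampling rate, or a samples-by-trials numeric matrix.
#' @return A `dff_trace` holding the pointwise arithmetic mean.
#' @export
trial_average <- function(traces) {
  if (is.matrix(traces)) {
    if (ncol(traces) == 0) stop("no traces to average", call. = FALSE)
    return(new_dff_trace(rowMeans(traces), NA_real_))
  }
  if (length(traces) == 0) stop("no traces to average", call. = FALSE)
  lens <- vapply(traces, function(x) length(dff_values(x)), integer(1))
  if (length(unique(lens)) != 1)
    stop("traces differ in length", call. = FALSE)
  rates <- vapply(traces, function(x)
    if (inherits(x, "dff_trace")) x$sampling_rate else NA_real_, double(1))
  rate <- unique(rates[!is.na(rates)])
  if (length(rate) > 1)
    stop("traces differ in sampling rate", call. = FALSE)
  m <- vapply(traces, dff_values, numeric(lens[1]))
  if (is.null(dim(m))) m <- matrix(m, nrow = lens[1]) # single 1-sample case
  new_dff_trace(rowMeans(m), if (length(rate)) rate else NA_real_)
}

#' Trial-averaged dF/F0 responses per neuron and intensity
#'
#' Converts every raw trace of a dataset to dF/F0 (baseline = full
#' pre-stimulus window) and averages trials within each neuron-by-intensity
#' cell, the per-cell curves the correlation index and amplitude metrics are
#' computed on.
#'
#' @param dataset An `ins_dataset` (from [simulate_dataset()] or
#'   [read_trace_table()]).
#' @param smooth If `TRUE`, Kalman-smooth each averaged curve (display
#'   convention; metrics default to raw averages).
#' @param ... Passed to [kalman_smooth()].
#' @return A tibble: `neuron_id`, `cell_class`, `intensity`, `n_trials`,
#'   `dff` (list-column of numeric dF/F0 vectors).
#' @export
average_responses <- function(dataset, smooth = FALSE, ...) {
  stopifnot(inherits(dataset, "ins_dataset"))
  bw <- baseline_window(dataset$paradigm)
  idx <- window_indices(bw, dataset$sampling_rate, nrow(dataset$f))
  f0 <- colMeans(dataset$f[idx, , drop = FALSE])
  if (any(!is.finite(f0)) || any(f0 <= 0))
    stop("non-positive baseline fluorescence F0 in at least one trace",
      call. = FALSE)
  dff <- sweep(sweep(dataset$f, 2, f0, "-"), 2, f0, "/")

  grp <- interaction(dataset$trials$neuron_id, dataset$trials$intensity,
    drop = TRUE)
  sums <- rowsum(t(dff), grp)          # groups x samples
  counts <- as.vector(table(grp)[rownames(sums)])
  avg <- sums / counts

  key <- dplyr::distinct(dataset$trials, .data$neuron_id, .data$intensity)
  key$grp <- as.character(interaction(key$neuron_id, key$intensity,
    drop = TRUE))
  key <- dplyr::arrange(key, .data$neuron_id, .data$intensity)

  curves <- lapply(key$grp, function(g) avg[g, ])
  if (smooth) curves <- lapply(curves, kalman_smooth, ...)

  out <- tibble::tibble(
    neuron_id = key$neuron_id,
    intensity = key$intensity,
    n_trials = as.vector(table(grp)[key$grp]),
    dff = curves)
  out <- dplyr::left_join(out,
    dplyr::select(dataset$neurons, "neuron_id", "cell_class"),
    by = "neuron_id")
  dplyr::select(out, "neuron_id", "cell_class", "intensity", "n_trials", "dff")
}
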