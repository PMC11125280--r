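#' Classifier configuration
#'
#' Correlation-index thresholds for responder classification: a neuron-by-
#' intensity response is positive when its correlation with the reference
#' curve exceeds `threshold_pos`, negative below `threshold_neg`, otherwise
#' unclassified. Thresholds are strict inequalities (a value of exactly 0.2
#' is `"none"`).
#'
#' @param threshold_pos Positive threshold, default 0.2.
#' @param threshold_neg Negative threshold, default -0.2.
#' @param window Analysis window `c(start, end)` in seconds; `NULL` means the
#'   paradigm's stimulation window (10--28 s multi-train).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(threshold_pos = 0.2, threshold_neg = -0.2,
                              window = NULL) {
  if (!(threshold_neg < 0 && 0 < threshold_pos))
    stop("need threshold_neg < 0 < threshold_pos", call. = FALSE)
  structure(list(threshold_pos = threshold_pos,
    threshold_neg = threshold_neg, window = window),
    class = "classifier_config")
}

#' Build the reference (typical) response curve
#'
#' The reference is the pointwise mean of the trial-averaged dF/F0 curves at
#' the top radiant exposure (0.76 J/cm^2 in the standard paradigm), over all
#' contributing neurons with no pre-selection, restricted to the stimulation
#' window. The same reference is used to score both excitatory and
#' inhibitory cohorts, so anti-phase (negative-deflection) responses score
#' negative correlations.
#'
#' @param avg_tbl Trial-averaged responses from [average_responses()].
#' @param paradigm The `stim_paradigm` (supplies the default window).
#' @param intensity Reference intensity; default the maximum present.
#' @param window Analysis window in seconds; default [stim_window()].
#' @return A `reference_curve`: list with `values` (windowed mean dF/F0),
#'   `window`, `sampling_rate`, `source_intensity`, `n_contributing`.
#' @export
build_reference <- function(avg_tbl, paradigm, intensity = NULL,
                            window = NULL, sampling_rate = 30) {
  if (is.null(intensity)) intensity <- max(avg_tbl$intensity)
  if (is.null(window)) window <- stim_window(paradigm)
  rows <- avg_tbl[avg_tbl$intensity == intensity, ]
  if (nrow(rows) == 0)
    stop("no trial-averaged curves at the reference intensity", call. = FALSE)
  m <- vapply(rows$dff, identity, numeric(length(rows$dff[[1]])))
  if (is.null(dim(m))) m <- matrix(m, ncol = nrow(rows))
  idx <- window_indices(window, sampling_rate, nrow(m))
  values <- rowMeans(m)[idx]
  if (stats::sd(values) == 0)
    stop("reference curve has zero variance over the analysis window",
      call. = FALSE)
  structure(list(values = values, window = window,
    sampling_rate = sampling_rate, source_intensity = intensity,
    n_contributing = nrow(rows)), class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf(
    "<reference_curve: %d samples over [%g, %g) s, %d neurons at %g J/cm2>\n",
    length(x$values), x$window[1], x$window[2], x$n_contributing,
    x$source_intensity))
  invisible(x)
}

#' Correlation index of one response against the reference
#'
#' Pearson product-moment correlation between a neuron's trial-averaged
#' dF/F0 curve and the reference curve, both restricted to the stimulation
#' window. Invariant to offset and positive rescaling of either input. When
#' either windowed series has zero variance the index is undefined
#' (`NA`, classified `"none"`), never silently zero.
#'
#' @param cell_avg Trial-averaged dF/F0 for one neuron at one intensity: a
#'   `dff_trace` or full-trial numeric vector.
#' @param reference A `reference_curve`.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
correlation_index <- function(cell_avg, reference) {
  v <- dff_values(cell_avg)
  idx <- window_indices(reference$window, reference$sampling_rate, length(v))
  v <- v[idx]
  if (length(v) != length(reference$values))
    stop("window sample counts of cell average and reference differ",
      call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(reference$values) == 0)
    return(NA_real_)
  stats::cor(v, reference$values)
}

#' Threshold classification of a correlation index
#'
#' @param correlation_value Numeric vector of correlation indices (may
#'   contain `NA` for undefined).
#' @param config A [classifier_config()].
#' @return Character vector: `"positive"`, `"negative"` or `"none"`.
#' @examples
#' classify_correlation(c(0.35, -0.21, 0.2, NA)) # positive negative none none
#' @export
classify_correlation <- function(correlation_value,
                                 config = classifier_config()) {
  out <- rep("none", length(correlation_value))
  out[!is.na(correlation_value) &
    correlation_value > config$threshold_pos] <- "positive"
  out[!is.na(correlation_value) &
    correlation_value < config$threshold_neg] <- "negative"
  out
}

#' Six-train peak-to-peak amplitude
#'
#' Splits the stimulation epoch into one epoch per pulse train (train onset
#' to next onset; the last epoch has the same duration), takes the
#' peak-to-peak excursion (max - min) of the trial-averaged dF/F0 within
#' each epoch as p1..p6, and averages them. The amplitude carries the sign
#' of the correlation index: negative correlation means a light-evoked
#' decrease, so its amplitude is negative.
#'
#' @param cell_avg Trial-averaged dF/F0 (`dff_trace` or numeric vector over
#'   the full trial).
#' @param paradigm A six-train `stim_paradigm`.
#' @param correlation_value The neuron's correlation index at this intensity.
#' @param sampling_rate Hz (taken from `cell_avg` when it is a `dff_trace`).
#' @return List with `amplitude` (signed mean of the six peaks) and `peaks`
#'   (p1..p6).
#' @export
peak_amplitude <- function(cell_avg, paradigm, correlation_value,
                           sampling_rate = 30) {
  if (paradigm$n_trains != 6L)
    stop("peak amplitude requires a six-train paradigm", call. = FALSE)
  v <- dff_values(cell_avg)
  if (inherits(cell_avg, "dff_trace") && !is.na(cell_avg$sampling_rate))
    sampling_rate <- cell_avg$sampling_rate
  onsets <- train_onsets(paradigm)
  epoch <- paradigm$train_duration_s + paradigm$train_interval_s
  peaks <- vapply(onsets, function(on) {
    idx <- window_indices(c(on, on + epoch), sampling_rate, length(v))
    diff(range(v[idx]))
  }, double(1))
  s <- if (is.na(correlation_value)) NA_real_
    else if (correlation_value < 0) -1 else 1
  list(amplitude = s * mean(peaks), peaks = peaks)
}

#' Peak area under the curve, 3--10 s
#'
#' Quantifies the delayed response to a long pulse train as the total area
#' of above-baseline peaks of the trial-averaged dF/F0 between 3 and 10 s
#' after trial start. Following the standard peak-area rules: baseline is 0;
#' maximal contiguous above-zero segments are the candidate peaks; segments
#' whose maximum is less than 10% of the distance from the window minimum to
#' the window maximum (above the minimum) are ignored; retained segments are
#' integrated trapezoidally with interpolated zero crossings.
#'
#' @param cell_avg Trial-averaged dF/F0 (`dff_trace` or numeric vector).
#' @param sampling_rate Hz (taken from `cell_avg` when possible).
#' @param window Analysis window in seconds, default `c(3, 10)`.
#' @return Area in dF/F0 x s.
#' @export
auc_3_10 <- function(cell_avg, sampling_rate = 30, window = c(3, 10)) {
  v <- dff_values(cell_avg)
  if (inherits(cell_avg, "dff_trace") && !is.na(cell_avg$sampling_rate))
    sampling_rate <- cell_avg$sampling_rate
  n <- length(v)
  if ((n - 1) / sampling_rate < window[2])
    stop("trace too short for the analysis window", call. = FALSE)
  t <- (seq_len(n) - 1L) / sampling_rate
  keep <- t >= window[1] & t <= window[2]
  tv <- t[keep]
  y <- v[keep]
  gmin <- min(y)
  gmax <- max(y)
  height_cut <- gmin + 0.10 * (gmax - gmin)

  pos <- y > 0
  if (!any(pos)) return(0)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- 0
  for (s in seq_along(r$values)) {
    if (!r$values[s]) next
    i1 <- starts[s]; i2 <- ends[s]
    if (max(y[i1:i2]) < height_cut) next # peak too small to count
    ts <- tv[i1:i2]; ys <- y[i1:i2]
    # interpolate the zero crossings at the segment edges
    if (i1 > 1L && y[i1 - 1L] <= 0) {
      t0 <- tv[i1 - 1L] + (tv[i1] - tv[i1 - 1L]) *
        (0 - y[i1 - 1L]) / (y[i1] - y[i1 - 1L])
      ts <- c(t0, ts); ys <- c(0, ys)
    }
    if (i2 < length(y) && y[i2 + 1L] <= 0) {
      t1 <- tv[i2] + (tv[i2 + 1L] - tv[i2]) * (0 - y[i2]) / (y[i2 + 1L] - y[i2])
      ts <- c(ts, t1); ys <- c(ys, 0)
    }
    total <- total + sum(diff(ts) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  }
  total
}

#' Score every neuron-by-intensity response
#'
#' Computes, for each trial-averaged curve, the correlation index against
#' the reference, the threshold classification, and the signed six-train
#' peak-to-peak amplitude (multi-train paradigm) or the 3--10 s peak area
#' (long-train paradigm).
#'
#' @param avg_tbl Output of [average_responses()].
#' @param reference A `reference_curve` from [build_reference()].
#' @param paradigm The `stim_paradigm`.
#' @param config A [classifier_config()].
#' @return A tibble of response profiles: `neuron_id`, `cell_class`,
#'   `intensity`, `correlation_value`, `label`, `amplitude`, `p1`..`p6`
#'   (multi-train) or `auc_3_10` (long-train).
#' @export
score_responses <- function(avg_tbl, reference, paradigm,
                            config = classifier_config()) {
  fs <- reference$sampling_rate
  corr <- vapply(avg_tbl$dff, correlation_index, double(1),
    reference = reference)
  out <- tibble::tibble(
    neuron_id = avg_tbl$neuron_id,
    cell_class = avg_tbl$cell_class,
    intensity = avg_tbl$intensity,
    correlation_value = corr,
    label = classify_correlation(corr, config))
  if (paradigm$label == "multi_train") {
    pk <- purrr::map2(avg_tbl$dff, corr,
      ~peak_amplitude(.x, paradigm, .y, sampling_rate = fs))
    out$amplitude <- purrr::map_dbl(pk, "amplitude")
    pm <- do.call(rbind, purrr::map(pk, "peaks"))
    colnames(pm) <- paste0("p", 1:6)
    out <- dplyr::bind_cols(out, tibble::as_tibble(pm))
  } else {
    out$auc_3_10 <- purrr::map_dbl(avg_tbl$dff, auc_3_10,
      sampling_rate = fs)
  }
  out
}

# round half away from zero, matching how printed percentages are reported
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Classification fractions by intensity
#'
#' Counts positive and negative responders at each radiant exposure and
#' reports percentages rounded to one decimal, half away from zero.
#'
#' @param profiles Response-profile tibble from [score_responses()], or any
#'   tibble with `intensity` and `label` columns.
#' @return A tibble: `intensity`, `n_pos`, `n_neg`, `n_total`, `pct_pos`,
#'   `pct_neg`, `pct_none`.
#' @examples
#' # 104 positive of 199 neurons -> 52.3%
#' @export
classification_fractions <- function(profiles) {
  if (nrow(profiles) == 0) stop("no profiles to summarise", call. = FALSE)
  profiles |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(
      n_pos = sum(.data$label == "positive"),
      n_neg = sum(.data$label == "negative"),
      n_total = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      pct_pos = round_half_away(100 * .data$n_pos / .data$n_total),
      pct_neg = round_half_away(100 * .data$n_neg / .data$n_total),
      pct_none = round_half_away(
        100 * (.data$n_total - .data$n_pos - .data$n_neg) / .data$n_total))
}

#' Linear intensity-dependence fit
#'
#' Ordinary least squares of the mean correlation index on radiant exposure,
#' the fit summarised in the field as `Y = slope x X + intercept` with R^2
#' and a two-sided slope test.
#'
#' @param points A data frame whose first two columns are radiant exposure
#'   and mean correlation index (columns named `intensity` /
#'   `correlation_value` are used when present). At least 3 points.
#' @return An `intensity_fit` object wrapping the `lm` fit; see
#'   [tidy.intensity_fit()] and [glance.intensity_fit()].
#' @export
intensity_fit <- function(points) {
  stopifnot(is.data.frame(points))
  x <- if ("intensity" %in% names(points)) points$intensity else points[[1]]
  y <- if ("correlation_value" %in% names(points)) points$correlation_value
    else points[[2]]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2) || stats::var(y) == 0) r2 <- 0
  structure(list(
    fit = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_value = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
    data = tibble::tibble(intensity = x, correlation_value = y)),
    class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat(sprintf("<intensity_fit: Y = %.3f x X + %.3f, R2 = %.3f, p = %.4g>\n",
    x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Rank-based two-sample comparison
#'
#' Two-sided nonparametric comparison: paired Wilcoxon signed-rank test or
#' unpaired Mann-Whitney U test. Exact p-values are used for small samples
#' without ties, the normal approximation with tie/continuity correction
#' otherwise. Paired samples with all-zero differences return p = 1 (no
#' evidence of a shift); fully degenerate all-tied input is undefined and
#' returns `NA` with a warning.
#'
#' @param a,b Numeric samples; equal length required when `paired`.
#' @param paired Logical.
#' @return Two-sided p-value.
#' @export
rank_compare <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths", call. = FALSE)
  if (paired) {
    d <- a - b
    if (all(d == 0)) return(1)
    return(stats::wilcox.test(a, b, paired = TRUE, exact = NULL)$p.value)
  }
  if (length(unique(c(a, b))) == 1L) {
    warning("all observations tied; rank test undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}

#' Unique neurons in two co-labelled populations
#'
#' Inclusion-exclusion bookkeeping for dual-labelled fields of view:
#' `n_a + n_b - n_both`.
#'
#' @param n_a,n_b Neurons labelled by each reporter.
#' @param n_both Neurons labelled by both.
#' @return Unique neuron count.
#' @examples
#' unique_neuron_count(219, 189, 25) # 383
#' @export
unique_neuron_count <- function(n_a, n_b, n_both) {
  stopifnot(n_both <= n_a + n_b)
  n_a + n_b - n_both
}

#' Size of a top-fraction subset
#'
#' Number of neurons retained when selecting the top fraction of a cohort
#' (ceiling rounding), e.g. the top 10% of 335 neurons is 34.
#'
#' @param n Cohort size.
#' @param fraction Fraction retained, default 0.1.
#' @return Integer subset size.
#' @export
top_fraction_count <- function(n, fraction = 0.1) {
  as.integer(ceiling(fraction * n))
}

#' Select the top fraction of neurons by a metric
#'
#' @param profiles Tibble with one row per neuron.
#' @param metric Column name to rank by (character), e.g. `"auc_3_10"`.
#' @param fraction Fraction retained (ceiling rounding), default 0.1.
#' @return The top rows, highest metric first.
#' @export
select_top_fraction <- function(profiles, metric, fraction = 0.1) {
  k <- top_fraction_count(nrow(profiles), fraction)
  profiles[order(profiles[[metric]], decreasing = TRUE)[seq_len(k)], ]
}
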