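#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Pseudo-coloured response matrix
#'
#' Heat-map of trial-averaged dF/F0 curves, one row per neuron, faceted by
#' radiant exposure and sorted by correlation index during the stimulation
#' period (the standard population-overview layout for stimulus-locked
#' imaging data).
#'
#' @param avg_tbl Output of [average_responses()].
#' @param profiles Output of [score_responses()] (supplies the sort order);
#'   optional.
#' @param sampling_rate Hz.
#' @return A ggplot object.
#' @export
plot_response_matrix <- function(avg_tbl, profiles = NULL,
                                 sampling_rate = 30) {
  long <- avg_tbl |>
    tidyr::unnest_longer("dff", values_to = "dff", indices_to = "sample") |>
    dplyr::mutate(time_s = (.data$sample - 1) / sampling_rate)
  if (!is.null(profiles)) {
    ord <- profiles |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(sort_key = mean(.data$correlation_value, na.rm = TRUE),
        .groups = "drop")
    long <- dplyr::left_join(long, ord, by = "neuron_id") |>
      dplyr::mutate(neuron_rank = rank(.data$sort_key, ties.method = "first"))
  } else {
    long$neuron_rank <- long$neuron_id
  }
  ggplot2::ggplot(long,
    ggplot2::aes(.data$time_s, .data$neuron_rank, fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~intensity, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black", high = "yellow") +
    ggplot2::labs(x = "time (s)", y = "neuron (sorted by correlation)",
      fill = expression(Delta * F / F[0]))
}

#' @rdname autoplot.population_curve
#' @export
plot_population <- function(x, sampling_rate = NULL) {
  autoplot.population_curve(x, sampling_rate = sampling_rate)
}

#' Plot a population curve
#'
#' Three-trace layout: excitatory mean, inhibitory mean and their weighted
#' population sum.
#'
#' @param object,x A `population_curve`.
#' @param sampling_rate Hz; defaults to the curve's own rate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_curve <- function(object, sampling_rate = NULL, ...) {
  x <- object
  fs <- if (!is.null(sampling_rate)) sampling_rate
    else if (is.finite(x$sampling_rate)) x$sampling_rate else 1
  n <- length(x$values)
  df <- tibble::tibble(
    time_s = rep((seq_len(n) - 1) / fs, 3),
    dff = c(x$excitatory, x$inhibitory, x$values),
    component = rep(c("excitatory", "inhibitory", "population sum"),
      each = n))
  ggplot2::ggplot(df,
    ggplot2::aes(.data$time_s, .data$dff, colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      "excitatory" = "#7B3294", "inhibitory" = "#008837",
      "population sum" = "black")) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0]))
}

#' Plot an intensity-dependence fit
#'
#' @param object An [intensity_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
    ggplot2::aes(.data$intensity, .data$correlation_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
      colour = "red") +
    ggplot2::labs(x = expression("radiant exposure (J/cm"^2 * ")"),
      y = "mean correlation index",
      subtitle = sprintf("Y = %.2f X + %.2f, R2 = %.2f, p = %.3g",
        object$slope, object$intercept, object$r_squared, object$p_value))
}

#' Plot a fluence-map slice
#'
#' Log-scaled raster of the deposited-energy (or fluence) distribution in a
#' plane through the volume.
#'
#' @param fluence A `fluence_map`.
#' @param plane `"xz"` (side view through the beam) or `"xy"` (imaging
#'   plane).
#' @param index Slice index along the remaining axis; default mid-volume
#'   (`"xz"`) or the first cortex plane (`"xy"`).
#' @param what `"fluence"` or `"absorbed"`.
#' @return A ggplot object.
#' @export
plot_fluence <- function(fluence, plane = c("xz", "xy"), index = NULL,
                         what = c("fluence", "absorbed")) {
  plane <- match.arg(plane)
  what <- match.arg(what)
  a <- fluence[[what]]
  if (is.null(index))
    index <- if (plane == "xz") dim(a)[2] %/% 2 else dim(a)[3] %/% 2
  m <- if (plane == "xz") a[, index, ] else a[, , index]
  px <- fluence$tissue$pitch_mm
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  df$x_mm <- (df$i - 0.5) * px
  df$y_mm <- (df$j - 0.5) * px
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
    fill = log10(.data$value + max(.data$value) * 1e-6))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("log10 %s", what)) +
    ggplot2::coord_equal() +
    (if (plane == "xz") ggplot2::scale_y_reverse() else NULL) +
    ggplot2::labs(x = "x (mm)",
      y = if (plane == "xz") "depth z (mm)" else "y (mm)")
}
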