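#' Population weights
#'
#' Excitatory/inhibitory mixing weights for the population-sum model. The
#' default 0.8/0.2 is the standard excitatory:inhibitory ratio of cerebral
#' cortex.
#'
#' @param w_excitatory,w_inhibitory Non-negative weights summing to 1.
#' @return A `population_weights` list.
#' @export
population_weights <- function(w_excitatory = 0.8,
                               w_inhibitory = 1 - w_excitatory) {
  if (w_excitatory < 0 || w_inhibitory < 0 ||
      abs(w_excitatory + w_inhibitory - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  structure(list(w_excitatory = w_excitatory, w_inhibitory = w_inhibitory),
    class = "population_weights")
}

#' Weighted excitatory/inhibitory population time course
#'
#' Pointwise convex combination of the excitatory and inhibitory cohort
#' grand-mean dF/F0 curves, `w_e * excitatory + w_i * inhibitory`, modelling
#' what a non-cell-type-specific population response would look like.
#'
#' @param exc_mean,inh_mean Cohort mean curves (`dff_trace` or numeric
#'   vectors of equal length; equal sampling rates when both are
#'   `dff_trace`).
#' @param weights A [population_weights()].
#' @return A `population_curve`: list with `values`, `excitatory`,
#'   `inhibitory`, `weights`, `sampling_rate`.
#' @examples
#' population_sum(c(1, 1), c(-1, -1), population_weights(0.8))$values # 0.6 0.6
#' @export
population_sum <- function(exc_mean, inh_mean,
                           weights = population_weights()) {
  e <- dff_values(exc_mean)
  i <- dff_values(inh_mean)
  if (length(e) != length(i))
    stop("excitatory and inhibitory curves differ in length", call. = FALSE)
  rates <- c(
    if (inherits(exc_mean, "dff_trace")) exc_mean$sampling_rate else NA,
    if (inherits(inh_mean, "dff_trace")) inh_mean$sampling_rate else NA)
  rate <- unique(rates[!is.na(rates)])
  if (length(rate) > 1)
    stop("excitatory and inhibitory curves differ in sampling rate",
      call. = FALSE)
  structure(list(
    values = weights$w_excitatory * e + weights$w_inhibitory * i,
    excitatory = e, inhibitory = i, weights = weights,
    sampling_rate = if (length(rate)) rate else NA_real_),
    class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("<population_curve: %d samples, weights %.2g/%.2g exc/inh>\n",
    length(x$values), x$weights$w_excitatory, x$weights$w_inhibitory))
  invisible(x)
}
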