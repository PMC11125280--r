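#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intensity fit
#'
#' One row per model term with estimate, standard error, statistic and
#' p-value, in the usual tidier layout.
#'
#' @param x An [intensity_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.intensity_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(co[, 1]),
    std.error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p.value = unname(co[, 4]))
}

#' One-row summary of an intensity fit
#'
#' @param x An [intensity_fit()] object.
#' @param ... Unused.
#' @return A tibble with `slope`, `intercept`, `r.squared`, `p.value`,
#'   `n`.
#' @export
glance.intensity_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    p.value = x$p_value,
    n = nrow(x$data))
}

#' One-row summary of a Monte Carlo run
#'
#' Weight bookkeeping totals and their conservation residual
#' (`launched + rr_created - rr_destroyed - absorbed - escaped`, relative
#' to launched weight).
#'
#' @param x A `fluence_map`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.fluence_map <- function(x, ...) {
  t <- x$totals
  tibble::tibble(
    n_photons = x$n_photons,
    launched = t$launched,
    absorbed = t$absorbed_total,
    escaped = t$escaped_total,
    rr_created = t$rr_created,
    rr_destroyed = t$rr_destroyed,
    conservation_residual =
      (t$launched + t$rr_created - t$rr_destroyed -
        t$absorbed_total - t$escaped_total) / t$launched)
}
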