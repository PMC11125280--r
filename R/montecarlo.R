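#' Default three-layer tissue optical configuration
#'
#' Literature-typical optical properties at 1875 nm, where absorption is
#' water-dominated: ACSF (mu_a 3 mm^-1, no scattering, n 1.33), coverglass
#' (negligible absorption, n 1.52, 0.17 mm #1.5 glass) and cortex
#' (mu_a 3 mm^-1, mu_s 5 mm^-1, g 0.9, n 1.36) filling the rest of the cube.
#' All values are configuration, not measurements.
#'
#' @return A tibble with columns `name`, `thickness_mm` (`NA` = fill),
#'   `mu_a`, `mu_s`, `g`, `n`.
#' @export
default_layers <- function() {
  tibble::tibble(
    name = c("acsf", "glass", "cortex"),
    thickness_mm = c(0.5, 0.17, NA),
    mu_a = c(3.0, 1e-4, 3.0),
    mu_s = c(0, 0, 5.0),
    g = c(0, 0, 0.9),
    n = c(1.33, 1.52, 1.36))
}

#' Build a voxelised layered tissue model
#'
#' A cube of side `extent_mm` discretised at `pitch_mm` (defaults: 4 mm at
#' 10 um, i.e. 400 voxels per axis) containing horizontal layers stacked
#' along z (z = 0 at the top face, increasing into the tissue). One layer
#' may have `thickness_mm = NA` to fill the remaining depth.
#'
#' @param extent_mm Cube side length (mm).
#' @param pitch_mm Voxel pitch (mm); `extent_mm / pitch_mm` must be integer.
#' @param layers Layer table as in [default_layers()].
#' @return A `tissue_model`: list with `extent_mm`, `pitch_mm`, `n_voxels`,
#'   `layers` (with resolved thicknesses and `z_top`), `zbounds` and
#'   `layer_of_z` (layer index of each z voxel).
#' @export
build_tissue <- function(extent_mm = 4, pitch_mm = 0.010,
                         layers = default_layers()) {
  nv <- extent_mm / pitch_mm
  if (abs(nv - round(nv)) > 1e-9)
    stop("extent must be an integer multiple of the voxel pitch",
      call. = FALSE)
  nv <- as.integer(round(nv))
  stopifnot(nrow(layers) >= 1, all(layers$mu_a >= 0), all(layers$mu_s >= 0),
    all(layers$g >= -1 & layers$g <= 1), all(layers$n >= 1))
  th <- layers$thickness_mm
  if (sum(is.na(th)) > 1)
    stop("at most one layer may have NA (fill) thickness", call. = FALSE)
  fixed <- sum(th, na.rm = TRUE)
  if (fixed > extent_mm + 1e-9)
    stop("layer thicknesses exceed the cube depth", call. = FALSE)
  if (any(is.na(th))) th[is.na(th)] <- extent_mm - fixed
  if (any(th <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  layers$thickness_mm <- th
  zb <- c(0, cumsum(th))
  layers$z_top <- zb[-length(zb)]
  zc <- (seq_len(nv) - 0.5) * pitch_mm
  layer_of_z <- findInterval(zc, zb, rightmost.closed = TRUE)
  layer_of_z[layer_of_z > nrow(layers)] <- nrow(layers)
  structure(list(extent_mm = extent_mm, pitch_mm = pitch_mm, n_voxels = nv,
    layers = layers, zbounds = zb, layer_of_z = layer_of_z),
    class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model: %g mm cube, %d^3 voxels at %g um>\n",
    x$extent_mm, x$n_voxels, x$pitch_mm * 1000))
  print(as.data.frame(x$layers), row.names = FALSE)
  invisible(x)
}

#' Multimode-fiber launch specification
#'
#' Geometry of the stimulating fiber: 200 um core, NA 0.37, tilted 45
#' degrees to the horizontal plane (tilt axis in the x-z plane), tip resting
#' on the top surface of the coverglass at the cube centre by default.
#'
#' @param core_diameter_um Fiber core diameter (um).
#' @param na Numerical aperture.
#' @param tilt_deg Angle to the horizontal plane (degrees).
#' @param tip_mm Tip position `c(x, y, z)` in mm; `NULL` places it centred
#'   in x/y on the glass top surface of `tissue`.
#' @param tissue Optional `tissue_model` used to place the default tip.
#' @param wavelength_nm Wavelength (nm), metadata only.
#' @param glass_transmission Scalar transmission correction applied to the
#'   launched weight (default 1, i.e. no correction).
#' @return A `fiber_spec` list.
#' @export
fiber_spec <- function(core_diameter_um = 200, na = 0.37, tilt_deg = 45,
                       tip_mm = NULL, tissue = NULL, wavelength_nm = 1875,
                       glass_transmission = 1) {
  stopifnot(core_diameter_um > 0, na > 0, glass_transmission >= 0,
    glass_transmission <= 1)
  if (is.null(tip_mm)) {
    if (is.null(tissue))
      stop("supply tip_mm or a tissue model to place the fiber", call. = FALSE)
    glass_top <- tissue$layers$z_top[match("glass", tissue$layers$name)]
    if (is.na(glass_top)) glass_top <- 0
    tip_mm <- c(tissue$extent_mm / 2, tissue$extent_mm / 2, glass_top)
  }
  structure(list(core_diameter_um = core_diameter_um, na = na,
    tilt_deg = tilt_deg, tip_mm = tip_mm, wavelength_nm = wavelength_nm,
    glass_transmission = glass_transmission), class = "fiber_spec")
}

fiber_axis <- function(fiber) {
  a <- fiber$tilt_deg * pi / 180
  c(cos(a), 0, sin(a)) # tilted in the x-z plane, pointing into the tissue
}

#' Sample photon launch states from the fiber face
#'
#' Start positions are uniform over the tilted 200 um fiber disc; directions
#' are the fiber axis deflected by a polar angle theta with `sin(theta)`
#' uniform on `[0, NA / n_medium]` and uniform azimuth. Each photon starts
#' with weight `glass_transmission`.
#'
#' @param fiber A [fiber_spec()].
#' @param n Number of photons.
#' @param n_medium Refractive index of the launch medium (ACSF, 1.33).
#' @return List with `pos` (n x 3, mm), `dir` (n x 3 unit vectors) and
#'   `weight` (length n).
#' @export
launch_photon <- function(fiber, n = 1L, n_medium = 1.33) {
  axis <- fiber_axis(fiber)
  # orthonormal frame around the axis
  e1 <- c(-axis[3], 0, axis[1])
  e2 <- c(0, 1, 0)
  r_mm <- fiber$core_diameter_um / 2000
  rr <- r_mm * sqrt(stats::runif(n))
  ph <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(
    fiber$tip_mm[1] + rr * (cos(ph) * e1[1] + sin(ph) * e2[1]),
    fiber$tip_mm[2] + rr * (cos(ph) * e1[2] + sin(ph) * e2[2]),
    fiber$tip_mm[3] + rr * (cos(ph) * e1[3] + sin(ph) * e2[3]))
  sin_t <- stats::runif(n, 0, min(fiber$na / n_medium, 1))
  cos_t <- sqrt(1 - sin_t^2)
  ps <- stats::runif(n, 0, 2 * pi)
  dir <- cbind(
    cos_t * axis[1] + sin_t * (cos(ps) * e1[1] + sin(ps) * e2[1]),
    cos_t * axis[2] + sin_t * (cos(ps) * e1[2] + sin(ps) * e2[2]),
    cos_t * axis[3] + sin_t * (cos(ps) * e1[3] + sin(ps) * e2[3]))
  list(pos = pos, dir = dir, weight = rep(fiber$glass_transmission, n))
}

#' Run the Monte Carlo light-transport simulation
#'
#' Voxel-grid weighted-photon transport of infrared light through the
#' layered tissue: exponential step sampling on the local interaction
#' coefficient, partial-weight absorption `mu_a / (mu_a + mu_s)` deposited
#' per interaction into the enclosing voxel, Henyey-Greenstein deflection
#' with the local anisotropy, unpolarized Fresnel reflection/refraction at
#' layer interfaces, and Russian-roulette termination (threshold 1e-4,
#' survival 0.1). Deterministic given the seed. The returned totals keep an
#' exact weight ledger: `launched + rr_created - rr_destroyed =
#' absorbed_total + escaped_total` to floating-point precision.
#'
#' @param tissue A [build_tissue()] model.
#' @param fiber A [fiber_spec()].
#' @param n_photons Number of photons (>= 1).
#' @param seed Integer seed.
#' @param w_threshold Roulette weight threshold.
#' @param rr_survive Roulette survival probability.
#' @return A `fluence_map`: list with `absorbed` (3-D array of deposited
#'   weight fraction), `fluence` (absorbed / mu_a per voxel), `totals`,
#'   `tissue`, `fiber`, `n_photons`, `seed`.
#' @export
run_monte_carlo <- function(tissue, fiber, n_photons = 1e5, seed = 1L,
                            w_threshold = 1e-4, rr_survive = 0.1) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(fiber, "fiber_spec"),
    n_photons >= 1)
  n_medium <- tissue$layers$n[1] # fiber sits in the top (ACSF) layer
  res <- with_seed(seed, {
    lp <- launch_photon(fiber, as.integer(n_photons), n_medium = n_medium)
    mc_transport(rep(tissue$n_voxels, 3L), tissue$pitch_mm,
      tissue$layers$mu_a, tissue$layers$mu_s, tissue$layers$g,
      tissue$layers$n, tissue$zbounds,
      lp$pos, lp$dir, lp$weight, w_threshold, rr_survive)
  })
  nv <- tissue$n_voxels
  absorbed <- array(res$absorbed, dim = c(nv, nv, nv))
  mu_a_z <- tissue$layers$mu_a[tissue$layer_of_z]
  fl <- sweep(absorbed, 3, ifelse(mu_a_z > 0, mu_a_z, NA_real_), "/")
  fl[is.na(fl)] <- 0
  structure(list(
    absorbed = absorbed, fluence = fl,
    totals = list(launched = res$launched,
      absorbed_total = res$absorbed_total,
      escaped_total = res$escaped_total,
      rr_created = res$rr_created, rr_destroyed = res$rr_destroyed),
    tissue = tissue, fiber = fiber,
    n_photons = as.integer(n_photons), seed = seed), class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<fluence_map: %d^3 voxels, %d photons, seed %d>\n  absorbed %.4f, escaped %.4f of launched weight\n",
    dim(x$absorbed)[1], x$n_photons, x$seed,
    t$absorbed_total / t$launched, t$escaped_total / t$launched))
  invisible(x)
}

#' Illuminated-region mask at an imaging depth
#'
#' Thresholds the fluence slice at the imaging plane (a depth below the
#' cortex surface) at a fraction of the plane maximum, giving the
#' illuminated-region mask used to bin neurons. Also reports the equivalent
#' geometric light cone (apex at the fiber tip, axis refracted into the
#' cortex, half-angle `asin(NA / n_cortex)`) as a fallback definition.
#'
#' @param fluence A `fluence_map`.
#' @param depth_um Imaging depth below the cortex surface (um).
#' @param threshold_fraction Fraction of the plane maximum (default 0.1).
#' @return An `illum_mask`: list with `mask` (logical matrix), `z_index`,
#'   `depth_um`, `pitch_mm`, `threshold_fraction` and `cone`.
#' @export
illuminated_region <- function(fluence, depth_um, threshold_fraction = 0.1) {
  stopifnot(inherits(fluence, "fluence_map"))
  tis <- fluence$tissue
  cortex_row <- match("cortex", tis$layers$name)
  cortex_top <- if (!is.na(cortex_row)) tis$layers$z_top[cortex_row] else 0
  z_mm <- cortex_top + depth_um / 1000
  k <- floor(z_mm / tis$pitch_mm) + 1L
  if (k < 1L || k > tis$n_voxels)
    stop("imaging depth lies outside the simulated volume", call. = FALSE)
  slice <- fluence$fluence[, , k]
  mx <- max(slice)
  if (mx <= 0)
    stop("no fluence recorded at the imaging plane", call. = FALSE)
  mask <- slice >= threshold_fraction * mx

  # geometric cone fallback: refract the fiber axis through glass into cortex
  axis <- fiber_axis(fluence$fiber)
  n_seq <- tis$layers$n
  ax <- axis
  if (length(n_seq) > 1) {
    for (i in seq_len(length(n_seq) - 1)) {
      si <- sqrt(ax[1]^2 + ax[2]^2)
      st <- n_seq[i] / n_seq[i + 1] * si
      if (st < 1) {
        sc <- if (si > 0) st / si else 0
        ax <- c(ax[1] * sc, ax[2] * sc, sqrt(1 - st^2))
      }
    }
  }
  n_cortex <- if (!is.na(cortex_row)) tis$layers$n[cortex_row]
    else n_seq[length(n_seq)]
  cone <- list(apex_mm = fluence$fiber$tip_mm, axis = ax,
    half_angle_rad = asin(min(fluence$fiber$na / n_cortex, 1)))

  structure(list(mask = mask, z_index = k, depth_um = depth_um,
    pitch_mm = tis$pitch_mm, threshold_fraction = threshold_fraction,
    cone = cone), class = "illum_mask")
}

#' @export
print.illum_mask <- function(x, ...) {
  cat(sprintf(
    "<illum_mask: %d x %d plane at depth %g um, %d voxels >= %g x max>\n",
    nrow(x$mask), ncol(x$mask), x$depth_um, sum(x$mask),
    x$threshold_fraction))
  invisible(x)
}

#' Bin neurons into illuminated vs weakly illuminated regions
#'
#' Membership test of each neuron's (x, y) position, expressed in the
#' simulation grid frame, against the illuminated-region mask at its depth
#' plane. Neurons outside the grid are binned `weakly_illuminated` with a
#' warning.
#'
#' @param neurons Tibble with `x_um` and `y_um` columns (grid frame,
#'   micrometres from the cube corner after applying `origin_um`).
#' @param mask An `illum_mask`.
#' @param origin_um Offset `c(x, y)` in um added to neuron coordinates to
#'   map the imaging field into the grid frame (default centred is not
#'   assumed; default `c(0, 0)`).
#' @return The input tibble with a `region` column
#'   (`"illuminated"` / `"weakly_illuminated"`).
#' @export
bin_neurons <- function(neurons, mask, origin_um = c(0, 0)) {
  stopifnot(inherits(mask, "illum_mask"))
  px <- mask$pitch_mm * 1000
  ix <- floor((neurons$x_um + origin_um[1]) / px) + 1L
  iy <- floor((neurons$y_um + origin_um[2]) / px) + 1L
  inside <- ix >= 1L & ix <= nrow(mask$mask) & iy >= 1L & iy <= ncol(mask$mask)
  if (any(!inside))
    warning(sum(!inside), " neuron(s) outside the simulated grid; binned weakly_illuminated")
  lit <- logical(nrow(neurons))
  lit[inside] <- mask$mask[cbind(ix[inside], iy[inside])]
  neurons$region <- ifelse(lit, "illuminated", "weakly_illuminated")
  neurons
}
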