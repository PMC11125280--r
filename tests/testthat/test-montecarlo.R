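test_that("tissue models discretise the cube exactly", {
  tis <- build_tissue()
  expect_equal(tis$n_voxels, 400L)
  expect_equal(nrow(tis$layers), 3)
  expect_equal(sum(tis$layers$thickness_mm), 4)

  expect_equal(build_tissue(4, 0.02)$n_voxels, 200L)
  expect_error(build_tissue(4, 0.03), "integer multiple")

  homo <- build_tissue(2, 0.02, single_layer())
  expect_true(all(homo$layer_of_z == 1L))
})

test_that("photon launch respects the fiber aperture and geometry", {
  tis <- build_tissue(2, 0.02)
  fib <- fiber_spec(tissue = tis)
  set.seed(12)
  lp <- launch_photon(fib, 1e4, n_medium = 1.33)
  # unit directions
  expect_equal(rowSums(lp$dir^2), rep(1, 1e4), tolerance = 1e-12)
  # divergence bounded by asin(NA / n_medium)
  axis <- c(cos(pi / 4), 0, sin(pi / 4))
  cosang <- lp$dir %*% axis
  expect_lte(max(acos(pmin(1, cosang))), asin(0.37 / 1.33) + 1e-9)
  # collimated limit: NA -> 0 gives the bare fiber axis
  fib0 <- fiber_spec(na = 1e-9, tissue = tis)
  lp0 <- launch_photon(fib0, 100, n_medium = 1.33)
  expect_equal(max(abs(sweep(lp0$dir, 2, axis))), 0, tolerance = 1e-6)
  # mean launch position is the tip centre (disc symmetry)
  expect_equal(colMeans(lp$pos), fib$tip_mm, tolerance = 0.005)
})

test_that("weight ledger balances exactly for scattering media", {
  tis <- build_tissue(1, 0.02, single_layer(mu_a = 1, mu_s = 10, g = 0.9))
  fib <- fiber_spec(tip_mm = c(0.5, 0.5, 0), tilt_deg = 90)
  for (s in c(1, 7, 1234)) {
    fm <- run_monte_carlo(tis, fib, 3000, seed = s)
    expect_equal(generics::glance(fm)$conservation_residual, 0,
      tolerance = 1e-9)
    expect_true(all(fm$absorbed >= 0))
  }
})

test_that("a non-absorbing closed walk escapes all launched weight", {
  tis <- build_tissue(1, 0.02, single_layer(mu_a = 0, mu_s = 5, g = 0))
  fib <- fiber_spec(tip_mm = c(0.5, 0.5, 0), tilt_deg = 90)
  fm <- run_monte_carlo(tis, fib, 2000, seed = 2)
  expect_equal(fm$totals$absorbed_total, 0)
  expect_equal(fm$totals$escaped_total, fm$totals$launched)
})

test_that("pure-absorber on-axis deposition follows Beer-Lambert", {
  tis <- build_tissue(2, 0.02, single_layer(mu_a = 3, mu_s = 0))
  fib <- fiber_spec(na = 1e-9, tilt_deg = 90, tip_mm = c(1, 1, 0))
  fm <- run_monte_carlo(tis, fib, 1e5, seed = 4)
  prof <- apply(fm$absorbed, 3, sum) / fm$totals$launched
  k <- 1:25
  theo <- exp(-3 * (k - 1) * 0.02) - exp(-3 * k * 0.02)
  se <- sqrt(theo * (1 - theo) / 1e5)
  expect_true(all(abs(prof[k] - theo) <= 3 * se))
  # a collimated beam in a non-scattering medium deposits only forward
  expect_true(all(fm$absorbed[, , 1] >= 0))
})

test_that("deposition is azimuthally symmetric for isotropic scattering", {
  tis <- build_tissue(1, 0.02, single_layer(mu_a = 2, mu_s = 5, g = 0))
  fib <- fiber_spec(na = 1e-9, tilt_deg = 90, tip_mm = c(0.5, 0.5, 0))
  fm <- run_monte_carlo(tis, fib, 2e4, seed = 6)
  a <- fm$absorbed
  nv <- dim(a)[1]
  h <- nv / 2
  quads <- c(
    sum(a[1:h, 1:h, ]), sum(a[(h + 1):nv, 1:h, ]),
    sum(a[1:h, (h + 1):nv, ]), sum(a[(h + 1):nv, (h + 1):nv, ]))
  expect_lt(max(abs(quads / mean(quads) - 1)), 0.05)
})

test_that("doubling the photon count shrinks the Monte Carlo error", {
  tis <- build_tissue(0.5, 0.025, single_layer(mu_a = 2, mu_s = 2, g = 0.5))
  fib <- fiber_spec(tip_mm = c(0.25, 0.25, 0), tilt_deg = 90)
  frac <- function(n, s) {
    fm <- run_monte_carlo(tis, fib, n, seed = s)
    fm$totals$absorbed_total / fm$totals$launched
  }
  seeds <- 1:12
  sd_small <- sd(vapply(seeds, function(s) frac(500, s), double(1)))
  sd_big <- sd(vapply(seeds + 100, function(s) frac(4000, s), double(1)))
  # 8x photons: expect ~sqrt(8) = 2.8x smaller SE, allow broad stochastic slack
  expect_lt(sd_big, sd_small / 1.4)
})

test_that("the illuminated region thresholds the imaging-plane fluence", {
  tis <- build_tissue(2, 0.02)
  fib <- fiber_spec(tissue = tis)
  fm <- run_monte_carlo(tis, fib, 3e4, seed = 11)
  m <- illuminated_region(fm, depth_um = 150)
  expect_true(any(m$mask))
  sl <- fm$fluence[, , m$z_index]
  expect_equal(m$mask, sl >= 0.1 * max(sl))

  # threshold 1 keeps only the argmax voxel(s)
  m1 <- illuminated_region(fm, depth_um = 150, threshold_fraction = 1)
  expect_equal(sum(m1$mask), sum(sl == max(sl)))

  # uniform plane: every voxel is illuminated
  fm2 <- fm
  fm2$fluence[, , m$z_index] <- 1
  mu <- illuminated_region(fm2, depth_um = 150)
  expect_true(all(mu$mask))

  expect_error(illuminated_region(fm, depth_um = 5e4), "outside")
})

test_that("an angled collimated beam lands displaced by depth x tan(angle)", {
  # homogeneous non-scattering, non-refracting medium: the 45 deg beam axis
  # continues straight, so the deposition centroid at depth z sits at
  # tip_x + (z - tip_z) (tan 45 = 1); the tip is placed inside the medium so
  # the whole launch disc contributes
  tis <- build_tissue(2, 0.02, single_layer(mu_a = 2, mu_s = 0, g = 0))
  fib <- fiber_spec(na = 1e-9, tilt_deg = 45, tip_mm = c(0.5, 1, 0.2))
  fm <- run_monte_carlo(tis, fib, 2e4, seed = 9)
  nv <- dim(fm$absorbed)[1]
  v <- (seq_len(nv) - 0.5) * tis$pitch_mm
  k <- 36 # plane at z = 0.71 mm
  sl <- fm$absorbed[, , k]
  z <- (k - 0.5) * tis$pitch_mm
  xc <- sum(sl * v) / sum(sl)
  yc <- sum(t(sl) * v) / sum(sl)
  expect_equal(xc, 0.5 + (z - 0.2), tolerance = 0.03)
  expect_equal(yc, 1.0, tolerance = 0.03)
})

test_that("neurons are binned by mask membership at their plane", {
  mask <- matrix(FALSE, 50, 50)
  mask[20:30, 20:30] <- TRUE
  m <- structure(list(mask = mask, z_index = 10L, depth_um = 150,
    pitch_mm = 0.02, threshold_fraction = 0.1, cone = NULL),
    class = "illum_mask")
  neurons <- tibble::tibble(
    x_um = c(25 * 20, 1 * 20, 49 * 20),
    y_um = c(25 * 20, 1 * 20, 49 * 20))
  out <- bin_neurons(neurons, m)
  expect_equal(out$region,
    c("illuminated", "weakly_illuminated", "weakly_illuminated"))

  all_mask <- m
  all_mask$mask[] <- TRUE
  expect_true(all(bin_neurons(neurons, all_mask)$region == "illuminated"))

  expect_warning(out2 <- bin_neurons(
    tibble::tibble(x_um = -50, y_um = 10), m), "outside")
  expect_equal(out2$region, "weakly_illuminated")
})
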