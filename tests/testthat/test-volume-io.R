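test_that("make_grid builds uniformly filled volumes with correct extent", {
  g <- make_grid(c(10, 10, 10), c(1, 1, 1), fill_hu = -875)
  expect_true(all(g$values == -875))
  ax <- ctresolve:::grid_axes(g)
  expect_equal(vapply(ax, function(a) diff(range(a)), 0) + g$spacing, c(10, 10, 10))

  g2 <- make_grid(c(256, 256, 64), c(0.13, 0.13, 0.25))
  expect_equal(dim(g2$values) * g2$spacing, c(33.28, 33.28, 16))

  expect_error(make_grid(c(0, 4, 4), c(1, 1, 1)), "shape")
  expect_error(make_grid(c(4, 4, 4), c(1, -1, 1)), "spacing")
})

test_that("container validation rejects non-finite values and bad geometry", {
  arr <- array(0, c(2, 2, 2))
  expect_error(image_volume(array(c(NA, rep(0, 7)), c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(image_volume(arr, c(1, 1)), "spacing")
  expect_error(binary_mask(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "0/1")
  m <- binary_mask(array(c(1, 0, 1, 0, 0, 0, 0, 1), c(2, 2, 2)), c(1, 2, 3))
  expect_type(m$values, "logical")
  expect_equal(compute_volume(m), 3 * 6)
})

test_that("NIfTI round-trip preserves integer values, spacing and origin", {
  v <- image_volume(array(as.double(sample.int(2000, 4 * 5 * 6, TRUE) - 1000),
                          c(4, 5, 6)),
                    spacing = c(0.13, 0.13, 0.25), origin = c(1.5, -2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$values, v$values)
  expect_true(all(abs(r$spacing - v$spacing) < 1e-6))
  expect_true(all(abs(r$origin - v$origin) < 1e-4))
})

test_that("masks are stored as 8-bit 0/1 in NIfTI", {
  m <- binary_mask(array(runif(5 * 5 * 4) > 0.5, c(5, 5, 4)), c(0.5, 0.5, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  raw <- read_volume(f)
  expect_true(all(raw$values %in% c(0, 1)))
  r <- read_volume(f, mask = TRUE)
  expect_identical(r$values, m$values)
})

test_that("MetaImage round-trip is exact for integer and double data", {
  v <- image_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                    spacing = c(0.13, 0.13, 0.625), origin = c(-1, 0, 2.25))
  f <- tempfile(fileext = ".mha")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$values, v$values)
  expect_equal(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin)

  m <- binary_mask(array(runif(4 * 4 * 4) > 0.3, c(4, 4, 4)), c(1, 1, 1))
  fm <- tempfile(fileext = ".mha")
  write_volume(m, fm)
  expect_identical(read_volume(fm, mask = TRUE)$values, m$values)

  expect_error(read_volume(tempfile(fileext = ".foo")), "not found|unsupported")
})

test_that("resample is exact on identity, constants and linear ramps", {
  v <- image_volume(array(rnorm(10 * 12 * 8), c(10, 12, 8)), c(1, 1, 1))
  same <- resample(v, c(1, 1, 1))
  expect_equal(same$values, v$values)

  cv <- make_grid(c(20, 20, 10), c(0.5, 0.5, 1), fill_hu = -300)
  out <- resample(cv, c(0.7, 0.9, 1.3), method = "cubic")
  expect_true(all(abs(out$values + 300) < 1e-9))

  # linear ramp: downsample then upsample reproduces interior values
  ax <- ctresolve:::grid_axes(list(shape = c(40, 8, 8), spacing = c(0.5, 1, 1),
                                   origin = c(0, 0, 0)))
  ramp <- image_volume(array(rep(2 * ax[[1]] + 1, 8 * 8), c(40, 8, 8)),
                       c(0.5, 1, 1))
  down <- resample(ramp, c(1, 1, 1), method = "linear")
  up <- resample(down, c(0.5, 1, 1), method = "linear")
  inner <- up$values[5:36, 3:6, 3:6]
  axi <- ctresolve:::grid_axes(up)[[1]][5:36]
  expect_lt(max(abs(sweep(inner, 1, 2 * axi + 1))), 1e-6)
})

test_that("physical extent is preserved by resampling to within one voxel", {
  v <- make_grid(c(72, 30, 72), c(0.13, 0.13, 0.25))
  out <- resample(v, c(0.13, 0.13, 0.625))
  ext_in <- dim(v$values) * v$spacing
  ext_out <- dim(out$values) * out$spacing
  expect_true(all(abs(ext_in - ext_out) <= out$spacing))
})

test_that("Gaussian blur preserves constants, integrals and composes", {
  u <- make_grid(c(30, 30, 10), c(0.13, 0.13, 0.25), fill_hu = -580)
  b <- apply_psf(u, psf_model(0.3, 0.2))
  expect_equal(b$values, u$values, tolerance = 1e-12)

  imp <- make_grid(c(41, 41, 5), c(0.13, 0.13, 0.25), fill_hu = 0)
  imp$values[21, 21, 3] <- 1000
  bl <- apply_psf(imp, psf_model(0.25))
  expect_equal(sum(bl$values), 1000, tolerance = 1e-9)

  two <- apply_psf(apply_psf(imp, psf_model(0.15)), psf_model(0.2))
  one <- apply_psf(imp, psf_model(sqrt(0.15^2 + 0.2^2)))
  expect_lt(max(abs(two$values - one$values)) / max(one$values), 5e-3)
})

test_that("mean HU of a uniform region survives blur plus resampling", {
  v <- make_grid(c(80, 80, 40), c(0.13, 0.13, 0.25), fill_hu = -580)
  v$values[30:50, 30:50, 15:25] <- -110
  out <- resample(apply_psf(v, psf_model(0.28, 0.27)), c(0.13, 0.13, 0.625))
  expect_lt(abs(mean(out$values) - mean(v$values)), 0.5)
})

test_that("noise is seeded, sized correctly and off at sigma zero", {
  v <- make_grid(c(50, 50, 40), c(1, 1, 1), fill_hu = 0)
  expect_identical(add_noise(v, 0, 1)$values, v$values)
  n1 <- add_noise(v, 20, seed = 42)
  n2 <- add_noise(v, 20, seed = 42)
  expect_identical(n1$values, n2$values)
  expect_lt(abs(sd(n1$values - v$values) - 20) / 20, 0.05)
  expect_false(identical(add_noise(v, 20, seed = 43)$values, n1$values))
})

test_that("PSF width follows from a cutoff by closed-form inversion", {
  expect_equal(gaussian_psf_from_cutoff(0.5, 11.0)$sigma_mm, 0.1704, tolerance = 1e-3)
  expect_equal(gaussian_psf_from_cutoff(0.5, 6.1)$sigma_mm, 0.3072, tolerance = 1e-3)
  # round trip: the Gaussian MTF at the cutoff frequency equals the level
  for (lv in c(0.5, 0.1)) {
    s <- gaussian_psf_from_cutoff(lv, 9.8)$sigma_mm
    expect_equal(gauss_mtf(s, 9.8), lv, tolerance = 1e-12)
  }
  # sigma vanishes as the cutoff frequency grows
  expect_lt(gaussian_psf_from_cutoff(0.5, 1e5)$sigma_mm, 1e-4)
  expect_error(gaussian_psf_from_cutoff(1.2, 10), "level")
  expect_error(gaussian_psf_from_cutoff(0.5, -1), "frequency")
})

test_that("acquisition presets carry the published reconstruction spacings", {
  expect_equal(acquisition_preset("spcct")$recon_spacing_mm, c(0.13, 0.13, 0.25))
  expect_equal(acquisition_preset("ct")$recon_spacing_mm, c(0.13, 0.13, 0.625))
  expect_equal(acquisition_preset("hrct")$recon_spacing_mm, c(0.13, 0.13, 0.625))
  ph <- make_grid(c(40, 40, 20), c(0.13, 0.13, 0.25), fill_hu = -580)
  sim <- simulate_acquisition(ph, acquisition_preset("spcct", noise_sigma_hu_preset = 0))
  expect_equal(sim$spacing, c(0.13, 0.13, 0.25))
  expect_lt(max(abs(sim$values + 580)), 1e-9)
  coarse <- make_grid(c(10, 10, 5), c(0.5, 0.5, 1))
  expect_error(simulate_acquisition(coarse, acquisition_preset("ct")), "fine")
})
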