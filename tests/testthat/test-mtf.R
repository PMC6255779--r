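# analytic circularly symmetric Gaussian image, point-sampled
gaussian_plane <- function(n = 161, px = 0.13, sigma = 0.3, amp = 100,
                           center_off = c(0.2, -0.3)) {
  ctr <- (n - 1) / 2 * px + center_off * px
  xs <- (seq_len(n) - 1) * px
  vals <- amp * exp(-outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+") / (2 * sigma^2))
  structure(list(values = vals, spacing = c(px, px), origin = c(0, 0)),
            class = "plane_image")
}

test_that("slice averaging reduces noise like the mean of n slices", {
  v <- make_grid(c(40, 40, 1), c(0.13, 0.13, 0.25), fill_hu = 7)
  expect_equal(average_slices(v)$values, v$values[, , 1])

  base <- make_grid(c(60, 60, 16), c(0.13, 0.13, 0.25), fill_hu = 0)
  noisy <- add_noise(base, 20, seed = 2)
  avg <- average_slices(noisy)
  expect_lt(abs(sd(avg$values) - 20 / sqrt(16)) / (20 / sqrt(16)), 0.1)

  multi <- image_volume(array(rep(1:9, 4), c(3, 3, 4)), c(1, 1, 1))
  expect_equal(average_slices(multi)$values, matrix(1:9, 3, 3))
})

test_that("wire centres are found to sub-pixel accuracy", {
  for (off in list(c(0.3, 0.1), c(-0.4, 0.25))) {
    g <- list(shape = c(101L, 101L, 1L), spacing = c(0.13, 0.13, 1))
    ctr <- 50 * 0.13 + off * 0.13
    img <- generate_wire_image(wire_phantom_spec(0.2, grid = g, center_mm = ctr))
    est <- estimate_wire_center(average_slices(img))
    expect_lt(max(abs(est - ctr)), 0.1 * 0.13)
    # invariant to a constant background offset
    shifted <- average_slices(img)
    shifted$values <- shifted$values + 500
    expect_equal(estimate_wire_center(shifted), est)
  }
  flat <- average_slices(make_grid(c(20, 20, 1), c(0.13, 0.13, 1), fill_hu = 0))
  expect_error(estimate_wire_center(flat), "no wire")
})

test_that("background subtraction zeroes the far field exactly", {
  u <- average_slices(make_grid(c(30, 30, 1), c(0.13, 0.13, 1), fill_hu = -875))
  out <- subtract_background(u, c(1.9, 1.9), 0.5)
  expect_true(all(out$values == 0))

  img <- average_slices(generate_wire_image(wire_phantom_spec(0.1)))
  ctr <- estimate_wire_center(img)
  sub <- subtract_background(img, ctr, 1)
  r <- ctresolve:::pixel_radii(sub, ctr)
  expect_equal(mean(sub$values[r > 1]), 0, tolerance = 1e-12)
  expect_error(subtract_background(img, ctr, 1e3), "whole image")
})

test_that("radial profiles reproduce an analytic Gaussian", {
  pl <- gaussian_plane(sigma = 0.3)
  ctr <- c(80.2 * 0.13, 79.7 * 0.13)
  for (ab in c("mean_radius", "bin_center")) {
    prof <- radial_profile(pl, ctr, abscissa = ab)
    truth <- 100 * exp(-prof$radii_mm^2 / (2 * 0.3^2))
    expect_lt(max(abs(prof$values_hu - truth)), 0.02 * 100)
    expect_true(all(diff(prof$radii_mm) > 0))
  }
  # quadrature consistency: profile mass equals pixel mass
  prof <- radial_profile(pl, ctr, abscissa = "bin_center")
  lhs <- sum(prof$values_hu * 2 * pi * prof$radii_mm * prof$bin_width_mm)
  r <- ctresolve:::pixel_radii(pl, ctr)
  rhs <- sum(pl$values[r <= max(prof$radii_mm)]) * 0.13^2
  expect_lt(abs(lhs - rhs) / rhs, 0.03)

  zero <- gaussian_plane(amp = 0)
  expect_true(all(radial_profile(zero, ctr)$values_hu == 0))
})

test_that("the Hankel transform matches closed forms for disk and Gaussian", {
  # uniform disk of diameter d: MTF proportional to 2 J1(pi d f)/(pi d f)
  d <- 1.2
  rr <- seq(0.005, 4, by = 0.01)
  disk <- structure(list(radii_mm = rr, values_hu = as.numeric(rr <= d / 2),
                         bin_width_mm = 0.01), class = "radial_profile")
  cv <- normalize_mtf(hankel_mtf(disk, freq_grid_lp_cm = seq(0, 7, 0.05)))
  f <- cv$frequencies_lp_cm / 10
  u <- pi * d * f
  airy <- abs(ifelse(u == 0, 1, 2 * besselJ(u, 1) / u))
  first_null <- 3.8317 / (pi * d)
  sel <- f < 0.95 * first_null & f > 0
  expect_lt(max(abs(cv$modulation[sel] - airy[sel]) / airy[sel]), 0.01)

  sg <- 0.35
  gauss <- structure(list(radii_mm = rr, values_hu = exp(-rr^2 / (2 * sg^2)),
                          bin_width_mm = 0.01), class = "radial_profile")
  cg <- normalize_mtf(hankel_mtf(gauss))
  truth <- gauss_mtf(sg, cg$frequencies_lp_cm)
  expect_lt(max(abs(cg$modulation - truth)), 0.005)

  # all mass at the origin: flat transform
  imp <- structure(list(radii_mm = c(0.005, rr), values_hu = c(1, 0 * rr),
                        bin_width_mm = 0.01), class = "radial_profile")
  ci <- normalize_mtf(suppressWarnings(hankel_mtf(imp)))
  expect_gt(min(ci$modulation), 0.995)
})

test_that("the finite-wire correction divides out the wire disk transform", {
  cv <- structure(list(frequencies_lp_cm = seq(0, 30, 0.1),
                       modulation = gauss_mtf(0.2, seq(0, 30, 0.1))),
                  class = "mtf_curve")
  tiny <- wire_correction(cv, 1e-6)
  expect_equal(tiny$modulation, cv$modulation, tolerance = 1e-9)

  w <- wire_correction(cv, 0.1)
  u0 <- pi * 0.1 * 2.17
  i217 <- which.min(abs(cv$frequencies_lp_cm - 21.7))
  expect_equal(cv$modulation[i217] / w$modulation[i217],
               2 * besselJ(u0, 1) / u0)
  expect_equal(2 * besselJ(u0, 1) / u0, 0.943, tolerance = 1e-3)
  expect_true(all(w$modulation[-1] > cv$modulation[-1]))

  # frequencies beyond the disk transform's first null are dropped
  wide <- structure(list(frequencies_lp_cm = seq(0, 150, 1),
                         modulation = rep(1, 151)), class = "mtf_curve")
  expect_warning(cut <- wire_correction(wide, 0.1), "null")
  expect_lt(max(cut$frequencies_lp_cm), 10 * 3.8317 / (pi * 0.1))
})

test_that("normalisation and cutoff extraction behave at the boundaries", {
  cv <- structure(list(frequencies_lp_cm = c(0, 10, 12),
                       modulation = c(2, 1.2, 0.8)), class = "mtf_curve")
  n1 <- normalize_mtf(cv)
  expect_equal(n1$modulation[1], 1)
  scaled <- cv
  scaled$modulation <- cv$modulation * 7
  expect_equal(normalize_mtf(scaled), n1)
  degenerate <- cv
  degenerate$modulation[1] <- 0
  expect_error(normalize_mtf(degenerate), "degenerate")

  lin <- structure(list(frequencies_lp_cm = c(0, 10, 12),
                        modulation = c(1, 0.6, 0.4)), class = "mtf_curve")
  expect_equal(mtf_cutoff(lin, 0.5), 11.0)
  expect_equal(mtf_cutoff(lin, 1), 0)
  expect_error(mtf_cutoff(lin, 0.1), "no cutoff")

  g <- structure(list(frequencies_lp_cm = seq(0, 40, 0.1),
                      modulation = gauss_mtf(0.1704, seq(0, 40, 0.1))),
                 class = "mtf_curve")
  expect_equal(mtf_cutoff(g, 0.5), 11.0, tolerance = 1e-3)
})

test_that("the full estimation chain recovers analytic blur cutoffs", {
  img100 <- simulate_wire_acquisition(wire_phantom_spec(0.1), psf_model(0.1704))
  est100 <- estimate_mtf(img100, 0.1)
  expect_lt(abs(est100$cutoff_50_lp_cm - 11.0) / 11.0, 0.02)

  img200 <- simulate_wire_acquisition(wire_phantom_spec(0.2), psf_model(0.3072))
  est200 <- estimate_mtf(img200, 0.2)
  expect_lt(abs(est200$cutoff_50_lp_cm - 6.1) / 6.1, 0.02)

  # an unblurred wire stays flat out to 20 LP/cm once its own transform is
  # divided out (200 um wire; a 100 um wire on a 130 um grid aliases at
  # sampling time, which no correction can undo)
  es <- estimate_mtf(generate_wire_image(wire_phantom_spec(0.2)), 0.2)
  sel <- es$curve$frequencies_lp_cm <= 20
  expect_gt(min(es$curve$modulation[sel]), 0.9)
})

test_that("estimated curves track the analytic Gaussian MTF closely", {
  for (sg in c(0.16, 0.25, 0.35)) for (d in c(0.1, 0.2)) {
    img <- simulate_wire_acquisition(wire_phantom_spec(d), psf_model(sg))
    est <- estimate_mtf(img, d)
    f10 <- gauss_cutoff_lp_cm(sg, 0.1)
    sel <- est$curve$frequencies_lp_cm <= f10
    err <- max(abs(est$curve$modulation[sel] -
                   gauss_mtf(sg, est$curve$frequencies_lp_cm[sel])))
    expect_lt(err, 0.03)
  }
})

test_that("stronger blur strictly lowers the 50% cutoff", {
  cuts <- vapply(c(0.15, 0.25, 0.35), function(sg) {
    img <- simulate_wire_acquisition(wire_phantom_spec(0.2), psf_model(sg))
    estimate_mtf(img, 0.2)$cutoff_50_lp_cm
  }, 0)
  expect_true(all(diff(cuts) < 0))
})

test_that("the estimate is invariant to wire contrast", {
  lo <- wire_phantom_spec(0.2, wire_hu = 500, background_hu = -875)
  hi <- wire_phantom_spec(0.2, wire_hu = 12875, background_hu = -875)  # x10
  e_lo <- estimate_mtf(simulate_wire_acquisition(lo, psf_model(0.28)), 0.2)
  e_hi <- estimate_mtf(simulate_wire_acquisition(hi, psf_model(0.28)), 0.2)
  expect_lt(abs(e_lo$cutoff_50_lp_cm - e_hi$cutoff_50_lp_cm) /
              e_lo$cutoff_50_lp_cm, 0.005)
  expect_lt(abs(e_lo$cutoff_10_lp_cm - e_hi$cutoff_10_lp_cm) /
              e_lo$cutoff_10_lp_cm, 0.005)
})
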