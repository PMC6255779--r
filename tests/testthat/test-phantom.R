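test_that("voxelised sphere volume converges to the closed form", {
  truth <- 4 / 3 * pi * 4.5^3
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    n <- ceiling(10 / h)
    spec <- nodule_spec("sphere", 9, rep((n - 1) * h / 2, 3))
    m <- generate_sphere_mask(spec, list(shape = rep(n, 3), spacing = rep(h, 3)))
    abs(compute_volume(m) - truth) / truth
  }, 0)
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))
})

test_that("sub-voxel centre shifts barely move the voxelised volume", {
  h <- 0.05
  n <- 141
  grid <- list(shape = rep(n, 3), spacing = rep(h, 3))
  c0 <- rep((n - 1) * h / 2, 3)
  v1 <- compute_volume(generate_sphere_mask(nodule_spec("sphere", 6, c0), grid))
  v2 <- compute_volume(generate_sphere_mask(
    nodule_spec("sphere", 6, c0 + c(h / 2, 0, 0)), grid))
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("degenerate and out-of-bounds spheres are handled", {
  grid <- list(shape = c(21, 21, 21), spacing = c(1, 1, 1))
  tiny <- generate_sphere_mask(nodule_spec("sphere", 0.4, c(10, 10, 10)), grid)
  expect_lte(sum(tiny$values), 1)
  expect_error(generate_sphere_mask(nodule_spec("sphere", 30, c(10, 10, 10)), grid),
               "bounds")
})

test_that("spiked nodules extend the sphere and fit their VOI", {
  grid <- list(shape = c(120, 120, 120), spacing = c(0.13, 0.13, 0.13))
  c0 <- rep(59 * 0.13, 3)
  sph <- generate_sphere_mask(nodule_spec("sphere", 6, c0), grid)
  lim <- nodule_spec("spiked_sphere", 6, c0, n_spikes = 6, spike_length_mm = 0)
  expect_identical(generate_spiked_sphere_mask(lim, grid)$values, sph$values)

  spk <- nodule_spec("spiked_sphere", 6, c0, n_spikes = 6, spike_length_mm = 2.5)
  m <- generate_spiked_sphere_mask(spk, grid)
  expect_true(all(m$values | !sph$values))    # superset of the sphere
  expect_gt(sum(m$values), sum(sph$values))   # strictly, for positive length
  idx <- which(m$values, arr.ind = TRUE)
  span <- apply(idx, 2, function(i) diff(range(i))) * 0.13
  expect_true(all(span <= 6 + 6.5))           # inside the d + 6.5 mm VOI
  expect_true(all(span >= 10.8))              # ~11 mm tip-to-tip
})

test_that("nodule specs validate spike parameters", {
  expect_error(nodule_spec("spiked_sphere", 6, c(0, 0, 0), n_spikes = 0), "n_spikes")
  expect_error(nodule_spec("spiked_sphere", 6, c(0, 0, 0), spike_length_mm = 4), "VOI")
  expect_error(nodule_spec("sphere", -3, c(0, 0, 0)), "positive")
})

test_that("vessel trees are reproducible with the prescribed radius decay", {
  grid <- list(shape = c(120, 80, 40), spacing = c(0.25, 0.25, 0.5))
  p <- list(depth = 4, root_radius_mm = 1, radius_decay = 0.7,
            segment_length_mm = 6, root_start_mm = c(0, 10, 10))
  t1 <- generate_vessel_tree(5, p, grid)
  t2 <- generate_vessel_tree(5, p, grid)
  expect_identical(t1$values, t2$values)
  segs <- attr(t1, "segments")
  expect_equal(max(segs$depth), 4)
  expect_equal(unique(segs$radius_mm[segs$depth == 4]), 1 * 0.7^3)

  single <- generate_vessel_tree(5, list(depth = 1, root_start_mm = c(0, 10, 10)),
                                 grid)
  comp <- keep_connected_to_center(single, c(3, 10, 10))
  expect_identical(comp$values, single$values)  # one connected tube
  expect_error(generate_vessel_tree(1, list(depth = 0), grid), "depth")
  expect_error(generate_vessel_tree(1, list(radius_decay = 1.5), grid), "decay")
})

test_that("assembled phantoms have two HU modes and exact reference masks", {
  sc <- small_scene(print_undersize_mm = 0)
  ph <- assemble_phantom(sc)
  expect_setequal(unique(as.numeric(ph$volume$values)), c(-580, -110))
  expect_length(ph$reference_masks, 2)
  for (i in 1:2) {
    ref <- ph$reference_masks[[i]]
    expect_gt(sum(ref$values), 0)
    # single 26-connected component containing the nodule centre
    comp <- keep_connected_to_center(ref, sc$nodules[[i]]$center_mm)
    expect_identical(comp$values, ref$values)
  }
  # vessels only when no nodules are present
  sc0 <- sc
  sc0$nodules <- list()
  ph0 <- assemble_phantom(sc0)
  expect_length(ph0$reference_masks, 0)
  expect_identical(ph0$volume$values == -110, ph0$structure_mask$values)
})

test_that("manufacturing undersize shrinks the imaged object, not the reference", {
  sc_exact <- small_scene(print_undersize_mm = 0)
  sc_small <- small_scene(print_undersize_mm = 0.05)
  ph_exact <- assemble_phantom(sc_exact)
  ph_small <- assemble_phantom(sc_small)
  expect_lt(sum(ph_small$volume$values == -110),
            sum(ph_exact$volume$values == -110))
  expect_identical(ph_small$reference_masks[[1]]$values,
                   ph_exact$reference_masks[[1]]$values)
})

test_that("overlapping nodules warn and take the union", {
  grid <- list(shape = c(80, 60, 60), spacing = c(0.25, 0.25, 0.25))
  sc <- phantom_scene(grid, nodules = list(
    nodule_spec("sphere", 6, c(9, 7, 7)),
    nodule_spec("sphere", 6, c(12, 7, 7))),
    feeder_radius_mm = 0, print_undersize_mm = 0,
    vessel_params = list(depth = 1, root_start_mm = c(0, 2, 2)))
  expect_warning(assemble_phantom(sc), "overlap")
})

test_that("wire rendering conserves the analytic disk signal at any offset", {
  for (off in list(c(0.35, -0.25), c(0.11, 0.47))) {
    g <- list(shape = c(101L, 101L, 2L), spacing = c(0.13, 0.13, 0.25))
    ctr <- 50 * 0.13 + off * 0.13
    ws <- wire_phantom_spec(0.1, wire_hu = 2000, background_hu = -875,
                            grid = g, center_mm = ctr)
    img <- generate_wire_image(ws)
    excess <- sum(img$values[, , 1] + 875) * 0.13^2
    expect_equal(excess, (2000 + 875) * pi * 0.05^2, tolerance = 1e-9)
  }
  flat <- wire_phantom_spec(0.1, wire_hu = -875, background_hu = -875,
                            grid = list(shape = c(41L, 41L, 1L),
                                        spacing = c(0.13, 0.13, 1)))
  expect_true(all(generate_wire_image(flat)$values == -875))
  expect_error(wire_phantom_spec(10, grid = list(shape = c(41L, 41L, 1L),
                                                 spacing = c(0.13, 0.13, 1))),
               "extent")
})
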