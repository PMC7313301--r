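test_that("grid size, spatial, intensity, and combined distances match closed forms", {
  expect_equal(grid_size(65536, 200), sqrt(65536 / 200), tolerance = 1e-12)
  expect_equal(grid_size(65536, 200), 18.1019336, tolerance = 1e-6)
  expect_equal(grid_size(256, 200), 1.13137085, tolerance = 1e-6)
  expect_equal(grid_size(50, 50), 1)
  expect_error(grid_size(10, 0), class = "ccparcel_validation_error")
  expect_error(grid_size(10, 20), class = "ccparcel_validation_error")

  expect_equal(spatial_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(spatial_distance(c(2, 2), c(2, 2)), 0)
  expect_equal(spatial_distance(c(1, 1), c(2, 3)), sqrt(5))

  expect_equal(intensity_distance(0, 0, mode = "root_sum"), 0)
  expect_equal(intensity_distance(0.25, 0.75, mode = "root_sum"), 1)
  expect_equal(intensity_distance(0.5, 0.5), 0)
  expect_equal(intensity_distance(0.2, 0.9), 0.7)
  expect_error(intensity_distance(-0.1, 0.5), class = "ccparcel_validation_error")

  expect_equal(combined_distance(0, 0, 10, 0.3), 0.3)
  expect_equal(combined_distance(1, 18, 18, 0), 1)
  expect_equal(combined_distance(2, 9, 18, 0.5), sqrt(1.25))
  expect_error(combined_distance(1, 1, 0, 0.5), class = "ccparcel_validation_error")
})

test_that("a flat image tiles into near-square superpixels of equal area", {
  img <- matrix(0, 64, 64)
  sp <- slic_segment(img, slic_params(K = 16, compactness = 0.5))
  expect_identical(nrow(sp$centers), 16L)
  areas <- sp$centers$area
  expect_true(all(abs(areas - 256) <= 0.4 * 256))
})

test_that("superpixels respect a step edge (boundary recall)", {
  img <- cbind(matrix(0.2, 64, 32), matrix(0.8, 64, 32))
  sp <- slic_segment(img, slic_params(K = 8))
  expect_lte(nrow(sp$centers), 8L)
  expect_gte(boundary_recall_vertical(sp$labels, 32), 0.95)
})

test_that("requesting more superpixels than pixels is rejected", {
  img <- matrix(runif(256), 16, 16)
  expect_error(slic_segment(img, slic_params(K = 300)),
               class = "ccparcel_validation_error")
})

test_that("partition, connectivity, locality, and determinism hold on phantoms", {
  for (s in c(1, 2, 3)) {
    b <- make_phantom(phantom_spec(size = c(64, 64), seed = s))
    img <- normalize_intensity(b$image)
    sp <- slic_segment(img, slic_params(K = 16))
    check_slic_invariants(sp, matrix(TRUE, 64, 64))
    sp2 <- slic_segment(img, slic_params(K = 16))
    expect_identical(sp$labels, sp2$labels)
  }
})

test_that("ROI mode labels exactly the mask and seeds densely enough", {
  b <- make_phantom(phantom_spec(size = c(96, 96), seed = 1, noise_sigma = 0))
  img <- normalize_intensity(b$image)
  sp <- slic_segment(img, slic_params(K = 40), roi = b$cc_mask)
  check_slic_invariants(sp, b$cc_mask$mask)
  expect_error(slic_segment(img, slic_params(K = 10000), roi = b$cc_mask),
               class = "ccparcel_validation_error")
})

test_that("mean superpixel compactness is non-decreasing in the coefficient", {
  b <- make_phantom(phantom_spec(size = c(64, 64), seed = 4))
  img <- normalize_intensity(b$image)
  comp <- vapply(c(0.1, 0.5, 0.9), function(e)
    mean_compactness(slic_segment(img, slic_params(K = 16, compactness = e))$labels),
    numeric(1))
  expect_true(all(diff(comp) >= -1e-12))
})
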