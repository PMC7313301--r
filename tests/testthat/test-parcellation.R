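test_that("the anterior-posterior axis aligns with elongation and rotates", {
  rect <- matrix(TRUE, 10, 40)
  ax <- anterior_posterior_axis(rect)
  expect_equal(abs(ax$axis), c(row = 0, col = 1), tolerance = 1e-9)
  expect_gt(ax$axis[["col"]], 0)  # anterior = smaller columns by default
  axv <- anterior_posterior_axis(matrix(TRUE, 40, 10))
  expect_equal(abs(axv$axis), c(row = 1, col = 0), tolerance = 1e-9)
  flipped <- anterior_posterior_axis(rect, flip = TRUE)
  expect_equal(flipped$axis, -ax$axis)
})

test_that("a near-isotropic mask falls back to the column axis with a warning", {
  sq <- matrix(TRUE, 10, 10)
  expect_warning(ax <- anterior_posterior_axis(sq), "isotropic")
  expect_equal(ax$axis, c(row = 0, col = 1))
})

test_that("the phantom arch axis is within 10 degrees of horizontal", {
  b <- make_phantom(phantom_spec(seed = 1))
  ax <- anterior_posterior_axis(b$cc_mask)
  expect_lte(abs(ax$axis[["row"]]), sin(10 * pi / 180))
})

test_that("geometric cut columns are integer-exact on rectangles", {
  # expected first (1-based) column of each successive parcel, from the
  # scheme fractions: floor(fraction * width) in 0-based columns
  cases <- list(
    list(w = 60, scheme = "witelson", cuts0 = c(20L, 30L, 40L, 48L)),
    list(w = 60, scheme = "hofer",    cuts0 = c(10L, 30L, 40L, 45L)),
    list(w = 120, scheme = "witelson", cuts0 = c(40L, 60L, 80L, 96L)),
    list(w = 120, scheme = "hofer",    cuts0 = c(20L, 60L, 80L, 90L))
  )
  for (cs in cases) {
    pm <- geometric_parcellate(matrix(TRUE, 10, cs$w), cs$scheme)
    first_col <- vapply(1:5, function(p) min(which(pm$labels[1, ] == p)), 0L) - 1L
    expect_identical(first_col, c(0L, cs$cuts0))
    expect_identical(sort(unique(as.vector(pm$labels))), 1:5)
  }
})

test_that("a position exactly on a boundary joins the posterior parcel", {
  pm <- geometric_parcellate(matrix(TRUE, 10, 60), "witelson")
  # 0-based column 30 has normalized position exactly 1/2
  expect_identical(unique(pm$labels[, 31]), 3L)
  expect_identical(unique(pm$labels[, 30]), 2L)
})

test_that("Witelson and Hofer share parcel 3 pixel-for-pixel", {
  rect <- matrix(TRUE, 10, 60)
  w <- geometric_parcellate(rect, "witelson")
  h <- geometric_parcellate(rect, "hofer")
  expect_identical(w$labels == 3L, h$labels == 3L)
})

test_that("masks too short along the axis are rejected", {
  m <- matrix(FALSE, 8, 8); m[4, 3:6] <- TRUE
  expect_error(suppressWarnings(geometric_parcellate(m, "witelson")),
               class = "ccparcel_validation_error")
})

test_that("superpixel parcels of a uniform rectangle are five equal bands", {
  img <- matrix(0.5, 24, 104)
  mask <- matrix(FALSE, 24, 104); mask[3:22, 3:102] <- TRUE
  sp <- slic_segment(img, slic_params(K = 40), roi = mask)
  pm <- slic_parcellate(sp, mask)
  expect_identical(sort(unique(pm$labels[mask])), 1:5)
  expect_true(all(pm$labels[!mask] == 0L))
  for (p in 1:5) {
    extent <- diff(range(which(colSums(pm$labels == p) > 0))) + 1
    expect_lte(abs(extent - 20), 1.5 * sp$S)
  }
  # parcel order follows the axis
  proj <- vapply(1:5, function(p) mean(col(pm$labels)[pm$labels == p]), 0)
  expect_true(all(diff(proj) > 0))
})

test_that("distinct-intensity ground-truth bands are recovered with Dice >= 0.7", {
  img <- matrix(0, 24, 104)
  mask <- matrix(FALSE, 24, 104); mask[3:22, 3:102] <- TRUE
  gt <- matrix(0L, 24, 104)
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (p in 1:5) {
    cols <- (3 + (p - 1) * 20):(2 + p * 20)
    img[3:22, cols] <- levels[p]
    gt[3:22, cols] <- p
  }
  sp <- slic_segment(img, slic_params(K = 40), roi = mask)
  pm <- slic_parcellate(sp, mask)
  for (p in 1:5)
    expect_gte(suppressMessages(dice(confusion(pm, gt, p))), 0.7)
})

test_that("fewer than five superpixels cannot be parcellated", {
  img <- matrix(0.5, 24, 104)
  mask <- matrix(FALSE, 24, 104); mask[3:22, 3:102] <- TRUE
  sp <- slic_segment(img, slic_params(K = 4), roi = mask)
  expect_error(slic_parcellate(sp, mask), class = "ccparcel_validation_error")
})
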