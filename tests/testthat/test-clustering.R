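test_that("K-means recovers exactly separated binary intensities", {
  img <- matrix(rep(c(0, 1), each = 32), 8, 8)
  model <- kmeans_centers(img, 2, seed = 1)
  expect_equal(model$centers, c(0, 1), tolerance = 1e-12)
  expect_s3_class(model, "cc_class_model")
  expect_gt(model$sigma, 0)
})

test_that("K-means rejects k below 2 and k above the distinct-value count", {
  img <- matrix(rep(c(0, 1), each = 32), 8, 8)
  expect_error(kmeans_centers(img, 1, seed = 1), class = "ccparcel_validation_error")
  expect_error(kmeans_centers(img, 3, seed = 1), class = "ccparcel_validation_error")
})

test_that("K-means estimates two Gaussian component means within 0.03", {
  set.seed(5)
  x <- c(rnorm(100, 0.2, 0.05), rnorm(100, 0.8, 0.05))
  img <- matrix(pmin(pmax(x, 0), 1), 10, 20)
  model <- kmeans_centers(img, 2, seed = 1)
  expect_lt(abs(model$centers[1] - 0.2), 0.03)
  expect_lt(abs(model$centers[2] - 0.8), 0.03)
})

test_that("K-means is deterministic given the seed", {
  img <- make_plateau_image(c(0.2, 0.5, 0.8), size = c(16, 16), seed = 3)
  m1 <- kmeans_centers(img, 3, seed = 9)
  m2 <- kmeans_centers(img, 3, seed = 9)
  expect_identical(m1, m2)
})

test_that("PNN assigns centroid-valued pixels to their class and breaks ties low", {
  model <- class_model(centers = c(0.25, 0.75), sigma = 0.1)
  img <- matrix(0.75, 8, 8); img[1, 1] <- 0.25; img[2, 2] <- 0.5  # 0.5 equidistant
  map <- pnn_classify(img, model)
  expect_identical(map$labels[1, 1], 1L)
  expect_identical(map$labels[3, 3], 2L)
  expect_identical(map$labels[2, 2], 1L)  # exact tie -> lower class index
})

test_that("PNN density ranking follows direct kernel summation", {
  model <- class_model(centers = c(0.1, 0.45, 0.9), sigma = 0.1)
  img <- matrix(0.5, 8, 8)
  map <- pnn_classify(img, model)
  dens <- sapply(c(0.1, 0.45, 0.9), function(u) exp(-(0.5 - u)^2 / (2 * 0.1^2)))
  expect_identical(unique(as.vector(map$labels)), as.integer(which.max(dens)))
  expect_identical(unique(as.vector(map$labels)), 2L)
})

test_that("PNN map matches a direct-summation oracle with multi-unit classes", {
  set.seed(8)
  img <- matrix(runif(64), 8, 8)
  units <- list(sort(runif(5, 0, 0.4)), sort(runif(7, 0.5, 1)))
  model <- ccparcel:::new_class_model(2, c(0.2, 0.75), sigma = 0.07, units = units)
  map <- pnn_classify(img, model)
  oracle <- apply(matrix(as.vector(img)), 1, function(x) {
    d <- vapply(units, function(u) mean(exp(-(x - u)^2 / (2 * 0.07^2))), numeric(1))
    which.max(d)
  })
  expect_identical(as.vector(map$labels), as.integer(oracle))
})

test_that("PNN classification is permutation-equivariant", {
  set.seed(4)
  img <- matrix(runif(100), 10, 10)
  model <- kmeans_centers(img, 3, seed = 2)
  perm <- c(3L, 1L, 2L)
  permuted <- ccparcel:::new_class_model(3, model$centers[perm], model$sigma,
                                         model$units[perm])
  m1 <- pnn_classify(img, model)
  m2 <- pnn_classify(img, permuted)
  expect_identical(match(m1$labels, perm), as.vector(m2$labels))
})

test_that("every pixel receives exactly one class", {
  img <- make_plateau_image(c(0.1, 0.9), size = c(12, 12), seed = 1)
  map <- pnn_classify(img, kmeans_centers(img, 2, seed = 1))
  expect_true(all(map$labels %in% 1:2))
  expect_identical(dim(map$labels), dim(img))
})

test_that("validity score prefers two classes over a spatial split of flat regions", {
  img <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  lab2 <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  lab3 <- lab2; lab3[5:8, 1:4] <- 3L  # split the left flat region spatially
  s2 <- vmep_score(ccparcel:::new_cluster_map(lab2, 2L), img)
  s3 <- vmep_score(ccparcel:::new_cluster_map(lab3, 3L), img)
  expect_gt(s2, s3)
})

test_that("validity score is deterministic and finite", {
  img <- make_plateau_image(c(0.2, 0.8), size = c(16, 16), seed = 2)
  map <- pnn_classify(img, kmeans_centers(img, 2, seed = 2))
  s1 <- vmep_score(map, img)
  expect_true(is.finite(s1))
  expect_identical(s1, vmep_score(map, img))
})

test_that("validity score rejects degenerate maps", {
  img <- matrix(runif(64), 8, 8)
  lab <- matrix(1L, 8, 8)
  expect_error(vmep_score(ccparcel:::new_cluster_map(lab, 1L), img),
               class = "ccparcel_validation_error")
  lab[1, 1] <- 2L  # declare k = 3 but class 3 is empty
  expect_error(vmep_score(ccparcel:::new_cluster_map(lab, 3L), img),
               class = "ccparcel_validation_error")
})

test_that("class-count selection validates its range and recovers plateaus", {
  img <- make_plateau_image(c(0.1, 0.5, 0.9), seed = 1)
  expect_error(select_num_classes(img, c(4, 3)), class = "ccparcel_validation_error")
  expect_error(select_num_classes(img, c(1, 3)), class = "ccparcel_validation_error")
  map <- select_num_classes(img, c(2, 6), seed = 1)
  expect_identical(map$k, 3L)
  expect_true(is.finite(map$vmep))
})
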