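# Unsupervised pixel classification: K-means defines candidate classes on
# normalized intensity, a probabilistic neural network (Parzen-kernel
# classifier) assigns every pixel, and an entropy-based validity index picks
# the number of classes.

#' K-means class model on normalized intensity
#'
#' Runs Lloyd's algorithm on the scalar normalized intensities of an image
#' (kmeans++ seeding, 4 deterministic restarts, iterated to an unchanged
#' assignment or 300 iterations), returning a class model usable by
#' [pnn_classify()]. Each class carries a subsample of its member intensities
#' as PNN pattern units, and a shared Gaussian kernel width `sigma`
#' defaulting to half the mean nearest-centroid gap.
#'
#' @param img normalized image matrix (values in `[0, 1]`).
#' @param k number of classes, `>= 2` and at most the number of distinct
#'   intensities.
#' @param seed integer seed; results are deterministic given the seed.
#' @param max_units maximum pattern units retained per class (default 256).
#' @param sigma optional kernel width override (normalized-intensity scale).
#' @return an object of class `cc_class_model` with fields `k`, `centers`
#'   (ascending), `sigma`, and `units` (list of per-class pattern units).
#' @export
kmeans_centers <- function(img, k, seed = 0L, max_units = 256L, sigma = NULL) {
  check_normalized(img)
  k <- check_count(k, "k", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  x <- as.vector(img)
  ux <- unique(x)
  if (length(ux) < k)
    abort_validation(sprintf(
      "k = %d exceeds the number of distinct intensities (%d)", k, length(ux)))
  set.seed(seed)
  best <- NULL
  best_wss <- Inf
  for (restart in 1:4) {
    cen <- kmeanspp_init(x, k)
    assign <- integer(length(x))
    for (it in 1:300) {
      a <- max.col(-abs(outer(x, cen, "-")), ties.method = "first")
      newc <- vapply(seq_len(k), function(c) {
        m <- x[a == c]
        if (length(m)) mean(m) else x[which.max(abs(x - cen[c]))]  # revive empty class
      }, numeric(1))
      if (identical(a, assign)) { cen <- newc; break }
      assign <- a
      cen <- newc
    }
    wss <- sum((x - cen[assign])^2)
    if (wss < best_wss) { best_wss <- wss; best <- list(centers = cen, assign = assign) }
  }
  ord <- order(best$centers)
  centers <- best$centers[ord]
  assign <- match(best$assign, ord)
  units <- lapply(seq_len(k), function(c) {
    m <- x[assign == c]
    if (length(m) > max_units) m <- sort(m)[round(seq(1, length(m), length.out = max_units))]
    if (!length(m)) m <- centers[c]
    m
  })
  if (is.null(sigma)) {
    gaps <- vapply(seq_len(k), function(i) min(abs(centers[i] - centers[-i])), numeric(1))
    sigma <- 0.5 * mean(gaps)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 0.05
  }
  if (sigma <= 0) abort_validation("`sigma` must be positive")
  new_class_model(k, centers, sigma, units)
}

kmeanspp_init <- function(x, k) {
  cen <- numeric(k)
  cen[1] <- x[sample.int(length(x), 1L)]
  d2 <- (x - cen[1])^2
  for (i in seq_len(k)[-1]) {
    cen[i] <- x[sample.int(length(x), 1L, prob = d2 + 1e-300)]
    d2 <- pmin(d2, (x - cen[i])^2)
  }
  cen
}

new_class_model <- function(k, centers, sigma, units = NULL) {
  if (any(duplicated(centers)))
    abort_validation("class centers must be pairwise distinct")
  if (is.null(units)) units <- as.list(centers)
  structure(list(k = as.integer(k), centers = as.numeric(centers),
                 sigma = as.numeric(sigma), units = units),
            class = "cc_class_model")
}

#' Build a class model from explicit centers
#'
#' Convenience constructor for a `cc_class_model` whose pattern units are the
#' centers themselves (a one-unit-per-class PNN).
#'
#' @param centers numeric vector of distinct class centroids in `[0, 1]`.
#' @param sigma Gaussian kernel width.
#' @export
class_model <- function(centers, sigma) {
  if (length(centers) < 2L) abort_validation("at least 2 class centers required")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    abort_validation("`sigma` must be a single positive number")
  new_class_model(length(centers), centers, sigma)
}

#' Probabilistic neural network classification
#'
#' Assigns every pixel to the class with maximal Parzen (Gaussian-kernel)
#' density, the kernel being centred on each class's pattern units:
#' `f_c(x) = mean_u exp(-(x - u)^2 / (2 sigma^2))`. Ties break toward the
#' smaller class index. Deterministic.
#'
#' @param img normalized image matrix.
#' @param model a `cc_class_model`.
#' @return an object of class `cc_cluster_map`: list with `labels` (integer
#'   matrix in `1..k`), `k`, and `vmep` (NA until scored).
#' @export
pnn_classify <- function(img, model) {
  check_normalized(img)
  if (!inherits(model, "cc_class_model"))
    abort_validation("`model` must be a cc_class_model")
  x <- as.vector(img)
  n <- length(x)
  k <- model$k
  inv2s2 <- 1 / (2 * model$sigma^2)
  lab <- integer(n)
  chunk <- 8192L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dens <- matrix(0, length(idx), k)
    for (c in seq_len(k)) {
      u <- model$units[[c]]
      d <- exp(-(outer(x[idx], u, "-"))^2 * inv2s2)
      dens[, c] <- if (is.matrix(d)) rowMeans(d) else d
    }
    lab[idx] <- max.col(dens, ties.method = "first")
  }
  new_cluster_map(matrix(lab, nrow(img)), k)
}

new_cluster_map <- function(labels, k, vmep = NA_real_) {
  structure(list(labels = labels, k = as.integer(k), vmep = vmep),
            class = "cc_cluster_map")
}

#' @export
print.cc_cluster_map <- function(x, ...) {
  cat(sprintf("<cc_cluster_map> %dx%d, k = %d, vmep = %s\n",
              nrow(x$labels), ncol(x$labels), x$k,
              ifelse(is.na(x$vmep), "unscored", format(x$vmep, digits = 4))))
  invisible(x)
}

#' Entropy-based cluster validity score
#'
#' Scores how well a class partition is supported by the image's intensity
#' distribution. Each class is summarized by the maximum-entropy density for
#' its observed mean and variance — a Gaussian — and the partition is scored
#' by the per-pixel penalized log-likelihood of the resulting mixture
#' (a minimum-description-length criterion):
#' `V(k) = [2 L(k) - (3k - 1) log(n)] / n`,
#' where `L(k)` is the mixture log-likelihood of the image intensities and
#' `3k - 1` the parameter count (per-class mean, spread, and proportion).
#' Merging distinct intensity modes into one class costs likelihood heavily;
#' splitting one mode into two classes gains almost none and pays the
#' complexity penalty — so the score peaks at the best-supported class
#' count. Class spreads are floored at `1e-4` so zero-variance (flat) classes
#' remain finite.
#'
#' @param map a `cc_cluster_map` covering `img`.
#' @param img the normalized image the map was computed from.
#' @return a finite scalar; larger is better.
#' @export
vmep_score <- function(map, img) {
  check_normalized(img)
  if (!inherits(map, "cc_cluster_map"))
    abort_validation("`map` must be a cc_cluster_map")
  lab <- as.vector(map$labels)
  if (length(lab) != length(img))
    abort_validation("cluster map and image shapes differ")
  if (any(lab < 1L))
    abort_validation("cluster map must assign every pixel a class >= 1")
  k <- map$k
  if (k < 2L) abort_validation("validity is undefined for a single-class map")
  counts <- tabulate(lab, nbins = k)
  if (any(counts == 0L))
    abort_validation("cluster map contains an empty class")
  x <- as.vector(img)
  n <- length(x)
  p <- counts / n
  mu <- vapply(seq_len(k), function(c) mean(x[lab == c]), numeric(1))
  sg <- vapply(seq_len(k), function(c) {
    s <- stats::sd(x[lab == c])
    if (!is.finite(s)) s <- 0
    max(s, 1e-4)
  }, numeric(1))
  dens <- rowSums(vapply(seq_len(k),
                         function(c) p[c] * stats::dnorm(x, mu[c], sg[c]),
                         numeric(n)))
  L <- sum(log(pmax(dens, 1e-300)))
  (2 * L - (3 * k - 1) * log(n)) / n
}

#' Select the number of classes by validity maximization
#'
#' For each `k` in `k_range`, fits [kmeans_centers()], classifies with
#' [pnn_classify()], and scores with [vmep_score()]; returns the cluster map
#' whose `k` maximizes the score (ties go to the smaller `k`).
#'
#' @param img normalized image matrix.
#' @param k_range integer vector `c(k_min, k_max)`, within `[2, 10]`.
#' @param seed integer seed driving all K-means restarts.
#' @param ... passed on to [kmeans_centers()].
#' @return the winning `cc_cluster_map`, with its `vmep` field set.
#' @export
select_num_classes <- function(img, k_range = c(2L, 6L), seed = 0L, ...) {
  check_normalized(img)
  if (length(k_range) != 2L || any(!is.finite(k_range)))
    abort_validation("`k_range` must be c(k_min, k_max)")
  k_min <- as.integer(k_range[1]); k_max <- as.integer(k_range[2])
  if (k_min > k_max)
    abort_validation(sprintf("empty k range [%d, %d]", k_min, k_max))
  if (k_min < 2L || k_max > 10L)
    abort_validation("`k_range` must lie within [2, 10]")
  seed <- check_count(seed, "seed", min = 0L)
  best <- NULL
  for (k in k_min:k_max) {
    model <- tryCatch(kmeans_centers(img, k, seed = seed + 1000L * k, ...),
                      ccparcel_validation_error = function(e) NULL)
    if (is.null(model)) next  # k exceeds distinct intensities
    map <- pnn_classify(img, model)
    score <- tryCatch(vmep_score(map, img),
                      ccparcel_validation_error = function(e) -Inf)
    if (is.null(best) || score > best$vmep + 1e-12) {
      map$vmep <- score
      best <- map
    }
  }
  if (is.null(best))
    abort_validation("no k in the range produced a valid clustering")
  best
}
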