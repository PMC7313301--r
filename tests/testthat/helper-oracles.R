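# Independent brute-force oracles and fixture builders shared across tests.
# Every oracle is written as plainly as possible (explicit loops, no shared
# code with the implementation) so agreement is meaningful.

# explicit-scheme Perona-Malik iteration, pixel by pixel, replicated edges
pm_diffuse_oracle <- function(img, iterations, kappa, lambda,
                              conductance = "exponential") {
  g <- if (conductance == "exponential") function(d) exp(-(d / kappa)^2)
       else function(d) 1 / (1 + (d / kappa)^2)
  h <- nrow(img); w <- ncol(img)
  u <- img
  for (it in seq_len(iterations)) {
    v <- u
    for (r in 1:h) for (c in 1:w) {
      dN <- u[max(r - 1, 1), c] - u[r, c]
      dS <- u[min(r + 1, h), c] - u[r, c]
      dW <- u[r, max(c - 1, 1)] - u[r, c]
      dE <- u[r, min(c + 1, w)] - u[r, c]
      v[r, c] <- u[r, c] + lambda * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
    }
    u <- v
  }
  u
}

# border pixels = foreground with at least one (4-neighbour) background side,
# image boundary counting as background; returns 0-based (row, col)
border_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m); out <- NULL
  for (r in 1:h) for (c in 1:w) if (m[r, c]) {
    nb <- c(if (r > 1) m[r - 1, c] else FALSE,
            if (r < h) m[r + 1, c] else FALSE,
            if (c > 1) m[r, c - 1] else FALSE,
            if (c < w) m[r, c + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(r - 1, c - 1))
  }
  out
}

# exhaustive pixel-by-pixel confusion tally for one parcel label
tally_oracle <- function(pred, truth, parcel) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == parcel; t <- truth[i] == parcel
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# random connected hole-free blob for contour tests
random_blob <- function(seed, h = 12L, w = 12L) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  r <- sample(3:(h - 2), 1); c <- sample(3:(w - 2), 1); m[r, c] <- TRUE
  for (i in 1:40) {
    r <- min(max(r + sample(-1:1, 1), 1), h)
    c <- min(max(c + sample(-1:1, 1), 1), w)
    m[r, c] <- TRUE
  }
  lab <- ccparcel:::label_components(m, 8L)
  m <- lab == which.max(tabulate(lab[lab > 0]))
  bg <- ccparcel:::label_components(!m, 4L)
  edge_labs <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  matrix(m | !(matrix(bg %in% edge_labs, h)), h)
}

mask_dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# fraction of true vertical-edge pixels with a superpixel label change
# within +/- 1 column
boundary_recall_vertical <- function(labels, edge_col) {
  hit <- 0L
  for (r in seq_len(nrow(labels))) {
    cols <- max(1, edge_col - 1):min(ncol(labels) - 1, edge_col + 1)
    if (any(labels[r, cols] != labels[r, cols + 1L])) hit <- hit + 1L
  }
  hit / nrow(labels)
}

# per-superpixel isoperimetric compactness 4*pi*A/P^2, perimeter = count of
# pixel sides facing a different label or the image edge
mean_compactness <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  vapply(ids, function(i) {
    m <- labels == i
    A <- sum(m)
    P <- 0L
    h <- nrow(m); w <- ncol(m)
    for (r in 1:h) for (c in 1:w) if (m[r, c]) {
      P <- P + (r == 1 || !m[r - 1, c]) + (r == h || !m[r + 1, c]) +
           (c == 1 || !m[r, c - 1]) + (c == w || !m[r, c + 1])
    }
    4 * pi * A / P^2
  }, numeric(1)) |> mean()
}

# SLIC structural invariants shared by unit and acceptance tests
check_slic_invariants <- function(sp, scope) {
  labels <- sp$labels
  # partition of the scope
  expect_true(all(labels[scope] > 0L))
  expect_true(all(labels[!scope] == 0L))
  expect_lte(nrow(sp$centers), length(labels))
  # 4-connectivity of every superpixel
  for (i in seq_len(nrow(sp$centers))) {
    comp <- ccparcel:::label_components(labels == i, 4L)
    expect_identical(max(comp), 1L)
  }
  # 2S locality (Chebyshev) from each centre
  for (i in seq_len(nrow(sp$centers))) {
    px <- which(labels == i, arr.ind = TRUE) - 1L
    cheb <- pmax(abs(px[, 1] - sp$centers$row[i]), abs(px[, 2] - sp$centers$col[i]))
    expect_lte(max(cheb), 2 * sp$S + 1e-9)
  }
}
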