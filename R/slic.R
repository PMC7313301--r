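# SLIC superpixel generation on grayscale slices: localized K-means over a
# joint spatial-intensity distance, with seeds on a regular grid of spacing
# S = sqrt(N / K) and the search restricted to a 2S x 2S window per centre.

#' SLIC initial grid spacing
#'
#' `S = sqrt(N / K)` where `N` is the number of in-scope pixels and `K` the
#' requested superpixel count.
#'
#' @param N pixel count (`>= K`).
#' @param K superpixel count (`>= 1`).
#' @export
grid_size <- function(N, K) {
  N <- check_count(N, "N"); K <- check_count(K, "K")
  if (N < K) abort_validation("`N` must be at least `K`")
  sqrt(N / K)
}

#' Euclidean spatial distance between two pixels
#'
#' @param pi,pj numeric `(row, col)` pairs.
#' @export
spatial_distance <- function(pi, pj) {
  if (length(pi) != 2L || length(pj) != 2L)
    abort_validation("points must be (row, col) pairs")
  sqrt(sum((pj - pi)^2))
}

#' Intensity distance between two normalized intensities
#'
#' The default `"difference"` mode is the standard SLIC intensity term
#' `|Nj - Ni|`. The `"root_sum"` mode computes `sqrt(Nj + Ni)`, a variant
#' printed in part of the CC-parcellation literature; it is not a metric
#' (it does not vanish for identical intensities) and is provided for
#' comparability only.
#'
#' @param Ni,Nj normalized intensities in `[0, 1]` (vectorized).
#' @param mode `"difference"` (default) or `"root_sum"`.
#' @export
intensity_distance <- function(Ni, Nj, mode = c("difference", "root_sum")) {
  mode <- match.arg(mode)
  if (any(Ni < 0 | Ni > 1) || any(Nj < 0 | Nj > 1))
    abort_validation("intensities must lie in [0, 1]")
  if (mode == "difference") abs(Nj - Ni) else sqrt(Nj + Ni)
}

#' SLIC combined spatial-intensity distance
#'
#' `C_d = sqrt(Id^2 * (Sd / S)^2 + e^2)`: the intensity term is weighted by
#' the spatial separation relative to the grid spacing `S`, plus the
#' compactness coefficient `e`. Note that `e` enters as an additive constant
#' under the square root, identically for every candidate centre, so it
#' cannot change which centre attains the minimum; assignment ties are
#' resolved by spatial distance (see [slic_segment()]).
#'
#' @param Id intensity distance.
#' @param Sd spatial distance.
#' @param S grid spacing (`> 0`).
#' @param e compactness coefficient in `[0, 1]`.
#' @export
combined_distance <- function(Id, Sd, S, e) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0)
    abort_validation("`S` must be a single positive length")
  sqrt(Id^2 * (Sd / S)^2 + e^2)
}

#' SLIC parameters
#'
#' @param K number of superpixels (default 200, the setting used for
#'   256 x 256 slices).
#' @param compactness compactness coefficient `e` in `[0, 1]` (default 0.5).
#' @param max_iters assignment/update iterations (default 10).
#' @param intensity_mode see [intensity_distance()].
#' @export
slic_params <- function(K = 200L, compactness = 0.5, max_iters = 10L,
                        intensity_mode = c("difference", "root_sum")) {
  K <- check_count(K, "K", min = 2L)
  if (!is.numeric(compactness) || length(compactness) != 1L ||
      compactness < 0 || compactness > 1)
    abort_validation("`compactness` must lie in [0, 1]")
  max_iters <- check_count(max_iters, "max_iters")
  structure(list(K = K, compactness = compactness, max_iters = max_iters,
                 intensity_mode = match.arg(intensity_mode)),
            class = "slic_params")
}

#' SLIC superpixel segmentation
#'
#' Seeds `K` centres on a regular grid of spacing `S = sqrt(N / K)` (each
#' perturbed to the lowest-gradient position in its 3 x 3 neighbourhood),
#' then alternates (a) assigning every pixel to the centre of minimal
#' [combined_distance()] among centres within a `2S x 2S` search window —
#' ties broken by smaller spatial distance, then smaller label — and (b)
#' recomputing each centre as the mean (row, col, intensity) of its members,
#' stopping after `max_iters` iterations or when no centre moves by 0.5 px.
#' A post-pass enforces 4-connectivity by relabelling orphan fragments to
#' the dominant adjacent superpixel. Fully deterministic.
#'
#' When `roi` is given, seeding and clustering are restricted to the mask
#' (label 0 outside), which is how the CC parcellation uses it.
#'
#' @param img normalized image matrix.
#' @param params a [slic_params()] object.
#' @param roi optional `cc_mask` or binary matrix restricting the scope.
#' @return an object of class `superpixel_map`: list with `labels` (integer
#'   matrix, `1..K'` in scope and 0 outside), `centers` (data.frame with
#'   0-based `row`, `col`, mean `intensity`, `area`), and grid spacing `S`.
#' @export
slic_segment <- function(img, params = slic_params(), roi = NULL) {
  check_normalized(img)
  if (!inherits(params, "slic_params"))
    abort_validation("`params` must come from slic_params()")
  h <- nrow(img); w <- ncol(img)
  scope <- if (is.null(roi)) matrix(TRUE, h, w) else {
    rm <- as_cc_mask(roi)$mask
    if (!all(dim(rm) == dim(img)))
      abort_validation("`roi` and image shapes differ")
    rm
  }
  N <- sum(scope)
  K <- params$K
  if (N < K)
    abort_validation(sprintf(
      "scope has %d pixels, fewer than K = %d superpixels: reduce K", N, K))
  S <- sqrt(N / K)

  # --- seeding: S-spaced grid, kept in scope, gradient-perturbed ---
  gr <- (shift_mat(img, 0L, 1L) - shift_mat(img, 0L, -1L))^2 +
        (shift_mat(img, 1L, 0L) - shift_mat(img, -1L, 0L))^2
  rows <- seq(1 + S / 2, h, by = S)
  cols <- seq(1 + S / 2, w, by = S)
  seeds <- expand.grid(row = round(rows), col = round(cols))
  seeds <- seeds[seeds$row >= 1 & seeds$row <= h & seeds$col >= 1 & seeds$col <= w, ]
  seeds <- seeds[scope[cbind(seeds$row, seeds$col)], , drop = FALSE]
  if (!nrow(seeds))
    abort_validation("no seed of the S-grid falls inside the scope: reduce K")
  perturb <- function(r, c) {
    rr <- max(1L, r - 1L):min(h, r + 1L)
    cc <- max(1L, c - 1L):min(w, c + 1L)
    cand <- expand.grid(row = rr, col = cc)
    cand <- cand[scope[cbind(cand$row, cand$col)], , drop = FALSE]
    if (!nrow(cand)) return(c(r, c))
    g <- gr[cbind(cand$row, cand$col)]
    unlist(cand[which.min(g), ])
  }
  pos <- t(mapply(perturb, seeds$row, seeds$col))
  cen <- data.frame(row = pos[, 1], col = pos[, 2],
                    intensity = img[cbind(pos[, 1], pos[, 2])])
  cen <- unique(cen)
  if (nrow(cen) > K) {
    # grid rounding can overshoot K; keep an evenly spaced subset so the
    # superpixel count never exceeds the request
    cen <- cen[round(seq(1, nrow(cen), length.out = K)), ]
  }
  nk <- nrow(cen)

  # --- iterative assignment / update ---
  ridx <- row(img); cidx <- col(img)
  win <- ceiling(S)
  labels <- matrix(0L, h, w)
  for (iter in seq_len(params$max_iters)) {
    best_d <- matrix(Inf, h, w)
    best_sd <- matrix(Inf, h, w)
    labels <- matrix(0L, h, w)
    for (ci in seq_len(nk)) {
      r0 <- max(1L, floor(cen$row[ci] - win)); r1 <- min(h, ceiling(cen$row[ci] + win))
      c0 <- max(1L, floor(cen$col[ci] - win)); c1 <- min(w, ceiling(cen$col[ci] + win))
      sub_scope <- scope[r0:r1, c0:c1]
      if (!any(sub_scope)) next
      dr <- ridx[r0:r1, c0:c1] - cen$row[ci]
      dc <- cidx[r0:r1, c0:c1] - cen$col[ci]
      sd2 <- dr * dr + dc * dc
      Id <- intensity_distance(cen$intensity[ci], img[r0:r1, c0:c1],
                               mode = params$intensity_mode)
      cd <- sqrt(Id^2 * sd2 / S^2 + params$compactness^2)
      bd <- best_d[r0:r1, c0:c1]; bs <- best_sd[r0:r1, c0:c1]
      lb <- labels[r0:r1, c0:c1]
      upd <- sub_scope & (cd < bd - 1e-12 |
                          (abs(cd - bd) <= 1e-12 & sd2 < bs - 1e-12))
      bd[upd] <- cd[upd]; bs[upd] <- sd2[upd]; lb[upd] <- ci
      best_d[r0:r1, c0:c1] <- bd; best_sd[r0:r1, c0:c1] <- bs
      labels[r0:r1, c0:c1] <- lb
    }
    # pixels no window reached: nearest centre spatially
    miss <- which(scope & labels == 0L)
    if (length(miss)) {
      mr <- ridx[miss]; mc <- cidx[miss]
      d2 <- outer(mr, cen$row, "-")^2 + outer(mc, cen$col, "-")^2
      labels[miss] <- max.col(-d2, ties.method = "first")
    }
    newc <- cen
    for (ci in seq_len(nk)) {
      member <- labels == ci
      if (any(member)) {
        newc$row[ci] <- mean(ridx[member])
        newc$col[ci] <- mean(cidx[member])
        newc$intensity[ci] <- mean(img[member])
      }
    }
    motion <- max(sqrt((newc$row - cen$row)^2 + (newc$col - cen$col)^2))
    cen <- newc
    if (motion < 0.5) break
  }

  labels <- enforce_connectivity(labels, scope)
  finalize_superpixels(labels, img, S)
}

# Split every superpixel into its 4-connected fragments (computed per label
# within its bounding box), keep each superpixel's largest fragment, and
# reassign every orphan fragment to the adjacent superpixel sharing the
# longest border.
label_fragments <- function(labels, connectivity = 4L) {
  fid <- matrix(0L, nrow(labels), ncol(labels))
  nfrag <- 0L
  for (l in sort(unique(labels[labels > 0L]))) {
    px <- which(labels == l, arr.ind = TRUE)
    r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
    sub <- label_components(labels[r0:r1, c0:c1, drop = FALSE] == l, connectivity)
    sel <- sub > 0L
    fid[r0:r1, c0:c1][sel] <- sub[sel] + nfrag
    nfrag <- nfrag + max(sub)
  }
  fid
}

enforce_connectivity <- function(labels, scope) {
  fid <- label_fragments(labels, connectivity = 4L)
  nfrag <- max(fid)
  if (nfrag == 0L) return(labels)
  frag_area <- tabulate(fid[fid > 0L], nbins = nfrag)
  first_px <- match(seq_len(nfrag), as.vector(fid))
  frag_label <- labels[first_px]
  # main fragment per superpixel = largest (ties: smaller fragment id)
  main <- tapply(seq_len(nfrag),
                 frag_label,
                 function(ix) ix[order(-frag_area[ix], ix)][1])
  orphan <- setdiff(seq_len(nfrag), unlist(main))
  if (length(orphan)) {
    orphan_set <- rep(FALSE, nfrag + 1L)
    orphan_set[orphan + 1L] <- TRUE
    guard <- 0L
    while (length(orphan) && guard < 1000L) {
      guard <- guard + 1L
      progressed <- FALSE
      for (fi in orphan) {
        px <- which(fid == fi)
        if (!length(px)) next
        nb_labels <- integer(0)
        for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          nb <- shift_px(px, sh, nrow(labels), ncol(labels))
          ok <- !is.na(nb)
          nl <- labels[nb[ok]]
          nf <- fid[nb[ok]]
          good <- nl > 0L & !orphan_set[nf + 1L]
          nb_labels <- c(nb_labels, nl[good])
        }
        if (length(nb_labels)) {
          tt <- sort(table(nb_labels), decreasing = TRUE)
          new_lab <- as.integer(names(tt)[1])
          labels[px] <- new_lab
          fid[px] <- 0L
          orphan_set[fi + 1L] <- FALSE
          progressed <- TRUE
        }
      }
      orphan <- which(orphan_set) - 1L
      if (!progressed) break
    }
    # anything still orphaned (enclosed by orphans only) keeps its label
  }
  labels
}

shift_px <- function(px, sh, h, w) {
  r <- ((px - 1L) %% h) + 1L + sh[1]
  c <- ((px - 1L) %/% h) + 1L + sh[2]
  out <- ifelse(r >= 1L & r <= h & c >= 1L & c <= w, (c - 1L) * h + r, NA_integer_)
  out
}

finalize_superpixels <- function(labels, img, S) {
  present <- sort(unique(labels[labels > 0L]))
  dense <- match(labels, present)
  dense[is.na(dense)] <- 0L
  labels <- matrix(as.integer(dense), nrow(labels))
  nk <- length(present)
  ridx <- row(img); cidx <- col(img)
  centers <- data.frame(
    label = seq_len(nk),
    row = vapply(seq_len(nk), function(i) mean(ridx[labels == i]) - 1, numeric(1)),
    col = vapply(seq_len(nk), function(i) mean(cidx[labels == i]) - 1, numeric(1)),
    intensity = vapply(seq_len(nk), function(i) mean(img[labels == i]), numeric(1)),
    area = vapply(seq_len(nk), function(i) sum(labels == i), numeric(1))
  )
  structure(list(labels = labels, centers = centers, S = S),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %dx%d, %d superpixels, S = %.2f\n",
              nrow(x$labels), ncol(x$labels), nrow(x$centers), x$S))
  invisible(x)
}
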