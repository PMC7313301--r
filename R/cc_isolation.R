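# Isolating the corpus callosum from the cluster map and tracing its contour.
#
# The CC is the brightest white-matter structure in a T1 midsagittal slice,
# so the brightest cluster class is taken as the CC candidate class. A
# radius-1 morphological opening severs thin bright bridges (the fornix is a
# thin similar-intensity appendage), and a spatial prior — area discounted by
# distance from the central-upper part of the slice, where the CC sits —
# picks the winning 8-connected component.

#' Isolate the corpus callosum
#'
#' @param map a `cc_cluster_map` of the slice.
#' @param img the normalized image the map was computed from.
#' @param min_area_frac minimum component area as a fraction of the image
#'   (default 0.001); below this the CC is declared not found.
#' @param target fractional (row, col) position of the spatial prior's
#'   centre, default `c(0.4, 0.5)` (centre-upper).
#' @param tau_frac prior length scale as a fraction of the image diagonal
#'   (default 0.25).
#' @return an object of class `cc_mask`: list with logical `mask`, `area`,
#'   `centroid` (0-based row, col), and `bbox` (0-based half-open
#'   `(row0, col0, row1, col1)`).
#' @export
isolate_cc <- function(map, img, min_area_frac = 0.001,
                       target = c(0.4, 0.5), tau_frac = 0.25) {
  check_normalized(img)
  if (!inherits(map, "cc_cluster_map"))
    abort_validation("`map` must be a cc_cluster_map")
  lab <- map$labels
  if (!all(dim(lab) == dim(img)))
    abort_validation("cluster map and image shapes differ")
  mean_int <- vapply(seq_len(map$k), function(c) mean(img[lab == c]), numeric(1))
  cc_class <- which.max(mean_int)
  cand <- lab == cc_class
  opened <- binary_open(cand, radius = 1L)
  comp <- label_components(opened, connectivity = 8L)
  areas <- component_areas(comp)
  min_area <- min_area_frac * length(img)
  keep <- which(areas >= min_area)
  if (!length(keep))
    abort_not_found(sprintf(
      "CC not found: no bright component reaches the minimal area (%.0f px)", min_area))
  h <- nrow(img); w <- ncol(img)
  tau <- tau_frac * sqrt(h^2 + w^2)
  tr <- target[1] * h; tc <- target[2] * w
  score <- vapply(keep, function(i) {
    px <- which(comp == i, arr.ind = TRUE)
    d2 <- (mean(px[, 1]) - tr)^2 + (mean(px[, 2]) - tc)^2
    areas[i] * exp(-d2 / (2 * tau^2))
  }, numeric(1))
  best <- keep[which.max(score)]
  new_cc_mask(comp == best)
}

new_cc_mask <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) abort_validation("empty CC mask")
  structure(list(
    mask = mask,
    area = nrow(px),
    centroid = c(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1),
    bbox = c(row0 = min(px[, 1]) - 1L, col0 = min(px[, 2]) - 1L,
             row1 = max(px[, 1]), col1 = max(px[, 2]))
  ), class = "cc_mask")
}

#' @export
print.cc_mask <- function(x, ...) {
  cat(sprintf("<cc_mask> %dx%d, area %d px, centroid (%.1f, %.1f)\n",
              nrow(x$mask), ncol(x$mask), x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

as_cc_mask <- function(x) {
  if (inherits(x, "cc_mask")) return(x)
  if (is.matrix(x)) return(new_cc_mask(x != 0))
  abort_validation("expected a cc_mask or a binary matrix")
}

#' Trace the boundary contour of a mask
#'
#' Moore-neighbour boundary tracing with Jacob's stopping criterion: the
#' walk starts at the uppermost-leftmost foreground pixel, scans the 8
#' neighbours clockwise from the backtrack position, and stops when the
#' start pixel is re-entered from the starting direction. On a binary mask
#' every border pixel is a spatial-gradient maximum, so the traced chain is
#' the maximal-gradient border. The chain is closed and 8-connected; on
#' single-pixel-wide necks and spurs a border pixel is necessarily traversed
#' once per side.
#'
#' @param mask a `cc_mask` (single 8-connected component) or binary matrix.
#' @return an object of class `cc_contour`: an n x 2 integer matrix of
#'   0-based (row, col) boundary points in traversal order.
#' @export
trace_contour <- function(mask) {
  m <- as_cc_mask(mask)$mask
  if (!any(m)) abort_validation("cannot trace an empty mask")
  # pad with background ring so neighbour scans never leave the array
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  start <- which(p, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # clockwise neighbour offsets (row down): N NE E SE S SW W NW
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  if (sum(p) == 1L)
    return(new_contour(matrix(start - 2L, 1L)))
  pts <- list()
  cur <- start
  back_dir <- 7L  # treat the start as entered from the west (background)
  first_move <- NA_integer_
  repeat {
    pts[[length(pts) + 1L]] <- cur
    found <- FALSE
    for (step in 1:8) {
      dir <- ((back_dir - 1L + step) %% 8L) + 1L
      nb <- cur + offs[dir, ]
      if (p[nb[1], nb[2]]) { found <- TRUE; break }
    }
    if (!found) break  # isolated pixel (handled above), defensive
    # stop when the walk is back at the start about to repeat its first move:
    # the (pixel, outgoing direction) state determines the whole future
    if (all(cur == start) && !is.na(first_move) && dir == first_move) break
    if (is.na(first_move)) first_move <- dir
    # new backtrack: the last background neighbour scanned before the move
    prev_dir <- ((dir - 2L) %% 8L) + 1L
    back_off <- cur + offs[prev_dir, ] - nb
    back_dir <- which(offs[, 1] == back_off[1] & offs[, 2] == back_off[2])
    cur <- nb
    if (length(pts) > 8L * length(p)) break  # defensive bound
  }
  out <- do.call(rbind, pts)
  if (nrow(out) > 1L && all(out[1, ] == out[nrow(out), ]))
    out <- out[-nrow(out), , drop = FALSE]
  new_contour(sweep(out, 2L, c(2L, 2L)))
}

new_contour <- function(points) {
  colnames(points) <- c("row", "col")
  structure(points, class = c("cc_contour", class(points)))
}

#' @export
print.cc_contour <- function(x, ...) {
  cat(sprintf("<cc_contour> %d boundary points\n", nrow(x)))
  invisible(x)
}

#' Write a contour as CSV of 0-based (row, col) pairs
#' @param contour a `cc_contour`.
#' @param path output path.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(unclass(contour)), path, row.names = FALSE)
  invisible(path)
}
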