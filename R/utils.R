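# Shared validation helpers, classed conditions, and small raster utilities.

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("ccparcel_validation_error",
                                     "ccparcel_error", "error", "condition")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("ccparcel_io_error",
                                     "ccparcel_error", "error", "condition")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("ccparcel_config_error",
                                     "ccparcel_error", "error", "condition")))
}

abort_not_found <- function(msg) {
  stop(errorCondition(msg, class = c("ccparcel_cc_not_found",
                                     "ccparcel_error", "error", "condition")))
}

# Minimum slice size: anything smaller cannot hold structure worth segmenting.
check_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    abort_validation(sprintf("`%s` must be a numeric matrix", arg))
  if (nrow(img) < 8L || ncol(img) < 8L)
    abort_validation(sprintf("`%s` must be at least 8x8 (got %dx%d)",
                             arg, nrow(img), ncol(img)))
  if (!all(is.finite(img)))
    abort_validation(sprintf("`%s` contains non-finite intensities", arg))
  invisible(img)
}

check_normalized <- function(img, arg = "img") {
  check_gray_image(img, arg)
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    abort_validation(sprintf(
      "`%s` must be normalized to [0, 1] (range %.4g..%.4g); see normalize_intensity()",
      arg, rng[1], rng[2]))
  invisible(img)
}

check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    abort_validation(sprintf("`%s` must be a single integer >= %d", arg, min))
  as.integer(x)
}

# Shift a matrix by (dr, dc) with edge replication, so boundary differences
# vanish (Neumann / reflecting boundary for diffusion).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) > 2L) x <- x[, , 1L]
  as.matrix(x)
}

# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, diagonally adjacent 4-components are merged by union-find.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- as_mat(EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask))))
  lab <- matrix(as.integer(round(lab)), nrow(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(lab, sh[1], sh[2])
    sel <- which(lab > 0L & nb > 0L & lab != nb)
    if (length(sel)) {
      pairs <- unique(cbind(lab[sel], nb[sel]))
      for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

component_areas <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

# Binary morphology on plain matrices via EBImage, radius-1 box (3x3).
binary_open <- function(mask, radius = 1L) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  out <- as_mat(EBImage::opening(matrix(as.numeric(mask != 0), nrow(mask)), brush))
  out > 0.5
}

binary_erode <- function(mask, radius = 1L) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  out <- as_mat(EBImage::erode(matrix(as.numeric(mask != 0), nrow(mask)), brush))
  out > 0.5
}
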