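# Deterministic synthetic phantoms: a bright downward-opening arch standing
# in for the CC, an enclosing elliptical "brain" at tissue intensity, an
# optional thin bright fornix-like appendage attached under the arch's
# posterior end, and additive Gaussian noise — with exact ground-truth masks
# and five equal-arc-length parcels.

#' Phantom specification
#'
#' The default spec is the "easy" study condition: 256 x 256 slice,
#' intensity levels 0.05 / 0.45 / 0.85 (background / tissue / CC) and noise
#' sigma 0.03, so adjacent levels are separated by more than 5 sigma; the
#' fornix surrogate is on and shares the CC intensity.
#'
#' @param size `(height, width)` in pixels.
#' @param cc_intensity,tissue_intensity,background_intensity normalized
#'   intensity levels.
#' @param noise_sigma additive Gaussian noise sigma (normalized scale).
#' @param fornix include the fornix surrogate?
#' @param centre arch centre `(row, col)`; default centre-upper region.
#' @param radii `(inner, outer)` arch radii in pixels; thickness
#'   (`outer - inner`) must be at least 3.
#' @param seed integer seed; bundles are bit-identical given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L),
                         cc_intensity = 0.85,
                         tissue_intensity = 0.45,
                         background_intensity = 0.05,
                         noise_sigma = 0.03,
                         fornix = TRUE,
                         centre = NULL,
                         radii = NULL,
                         seed = 0L) {
  if (length(size) != 2L) abort_validation("`size` must be (height, width)")
  h <- check_count(size[1], "height", min = 8L)
  w <- check_count(size[2], "width", min = 8L)
  if (is.null(centre)) centre <- c(0.52 * h, 0.50 * w)
  if (is.null(radii)) {
    R <- 0.30 * min(h, w)
    radii <- c(R - 0.10 * min(h, w), R)
  }
  if (length(radii) != 2L || radii[1] <= 0 || radii[2] <= radii[1])
    abort_validation("`radii` must be (inner, outer) with 0 < inner < outer")
  if (radii[2] - radii[1] < 3)
    abort_validation("arch thickness must be at least 3 px")
  if (centre[1] - radii[2] < 1 || centre[2] - radii[2] < 1 ||
      centre[2] + radii[2] > w || centre[1] > h)
    abort_validation("arch does not fit inside the image")
  for (v in c(cc_intensity, tissue_intensity, background_intensity))
    if (v < 0 || v > 1) abort_validation("intensity levels must lie in [0, 1]")
  if (noise_sigma < 0) abort_validation("`noise_sigma` must be non-negative")
  structure(list(size = c(h, w), cc_intensity = cc_intensity,
                 tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, fornix = isTRUE(fornix),
                 centre = centre, radii = radii,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "phantom_spec")
}

#' Generate a phantom bundle
#'
#' Renders the arch (CC surrogate), the enclosing tissue ellipse, the
#' optional fornix appendage (2 px wide, descending from the arch's
#' posterior underside, 8-adjacent to but disjoint from the CC mask), adds
#' clipped Gaussian noise, and returns exact ground truth: the CC mask, a
#' five-parcel map of equal-arc-length bands anterior to posterior, and the
#' fornix mask.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle`: list with `image`, `cc_mask`
#'   (a `cc_mask`), `parcels_gt` (a `parcel_map`), `fornix_mask` (logical
#'   matrix), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    abort_validation("`spec` must come from phantom_spec()")
  h <- spec$size[1]; w <- spec$size[2]
  cy <- spec$centre[1]; cx <- spec$centre[2]
  rr <- row(matrix(0, h, w)); cc <- col(matrix(0, h, w))
  dy <- cy - rr  # y grows upward
  dx <- cc - cx
  rad <- sqrt(dx^2 + dy^2)
  upper <- dy >= 0
  arch <- upper & rad >= spec$radii[1] & rad <= spec$radii[2]

  # tissue ellipse comfortably containing the arch
  ea <- min(spec$radii[2] * 1.45, (min(cy - 1, h - cy)) * 0.98)
  eb <- min(spec$radii[2] * 1.45, (min(cx - 1, w - cx)) * 0.98)
  tissue <- (dy / ea)^2 + (dx / eb)^2 <= 1

  fornix <- matrix(FALSE, h, w)
  if (spec$fornix) {
    # thin (2 px wide) appendage descending from directly under the arch's
    # inner boundary near the posterior (large-column) end, starting in the
    # row just below the lowest arch pixel of its attachment column so it is
    # 8-adjacent to, but disjoint from, the CC mask
    theta0 <- pi / 10
    ax0 <- round(cx + spec$radii[1] * cos(theta0))
    ax0 <- min(max(ax0, 2L), w - 1L)
    arch_rows <- which(arch[, ax0])
    ay <- if (length(arch_rows)) max(arch_rows) else round(cy - spec$radii[1] * sin(theta0))
    len <- max(6, round(0.12 * h))
    fr <- seq(ay + 1L, min(ay + len, h - 1L))
    fc <- round(ax0 - 0.15 * (fr - ay))  # slight anterior lean
    keep <- fr >= 1 & fr <= h & fc >= 2 & fc <= w - 1
    fr <- fr[keep]; fc <- fc[keep]
    fornix[cbind(fr, fc)] <- TRUE
    fornix[cbind(fr, fc + 1L)] <- TRUE
    fornix <- fornix & !arch
  }

  img <- matrix(spec$background_intensity, h, w)
  img[tissue] <- spec$tissue_intensity
  img[arch] <- spec$cc_intensity
  img[fornix] <- spec$cc_intensity
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    img <- pmin(pmax(img, 0), 1)
  }

  # ground-truth parcels: 5 equal-angle (= equal arc-length) bands,
  # anterior (theta = pi, small columns) to posterior (theta = 0)
  theta <- atan2(pmax(dy, 0), dx)
  band <- pmin(pmax(as.integer(ceiling((pi - theta) / (pi / 5))), 1L), 5L)
  parcels <- matrix(0L, h, w)
  parcels[arch] <- band[arch]
  ax_obj <- suppressWarnings(anterior_posterior_axis(arch))
  structure(list(image = img,
                 cc_mask = new_cc_mask(arch),
                 parcels_gt = new_parcel_map(parcels, "phantom_gt", ax_obj),
                 fornix_mask = fornix,
                 spec = spec),
            class = "phantom_bundle")
}

binary_dilate1 <- function(mask) {
  out <- mask
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                  c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
    out <- out | shift_mat(mask, sh[1], sh[2])
  out
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %dx%d, CC area %d px, fornix %s, sigma %.3f, seed %d\n",
              x$spec$size[1], x$spec$size[2], x$cc_mask$area,
              ifelse(any(x$fornix_mask), "on", "off"),
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

#' Plateau test image
#'
#' Vertical equal-width bands at the given intensity levels plus clipped
#' Gaussian noise; the fixture for clustering model-selection studies.
#'
#' @param levels intensity levels in `[0, 1]`, at least two.
#' @param size `(height, width)`.
#' @param noise_sigma Gaussian noise sigma.
#' @param seed integer seed.
#' @return numeric image matrix.
#' @export
make_plateau_image <- function(levels, size = c(96L, 96L),
                               noise_sigma = 0.02, seed = 0L) {
  if (length(levels) < 2L) abort_validation("at least 2 levels required")
  h <- check_count(size[1], "height", min = 8L)
  w <- check_count(size[2], "width", min = 8L)
  if (length(levels) > w)
    abort_validation("more levels than image columns")
  if (any(levels < 0 | levels > 1))
    abort_validation("levels must lie in [0, 1]")
  seed <- check_count(seed, "seed", min = 0L)
  img <- matrix(0, h, w)
  edges <- round(seq(0, w, length.out = length(levels) + 1L))
  for (i in seq_along(levels))
    img[, (edges[i] + 1L):edges[i + 1L]] <- levels[i]
  if (noise_sigma > 0) {
    set.seed(seed)
    img <- pmin(pmax(img + matrix(rnorm(h * w, 0, noise_sigma), h, w), 0), 1)
  }
  img
}
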