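# Five-parcel subdivision of the CC: geometric baselines (Witelson, Hofer)
# cutting the anterior-posterior extent at fixed fractions, and the
# data-driven grouping of SLIC superpixels along the same axis.

#' Anterior-posterior axis of a CC mask
#'
#' The first principal axis of the mask's pixel coordinates, oriented so that
#' the configured anterior convention holds (anterior = smaller columns by
#' default; `flip` inverts). Near-isotropic masks (principal-axis variance
#' ratio below 1.05) fall back to the image column axis with a warning.
#'
#' @param mask a `cc_mask` or binary matrix.
#' @param flip logical; flip the anterior direction.
#' @return object of class `cc_axis`: list with unit `axis` (row, col)
#'   pointing anterior -> posterior, 0-based `anterior` and `posterior`
#'   extreme points, and `extent` (pixel count along the axis).
#' @export
anterior_posterior_axis <- function(mask, flip = FALSE) {
  m <- as_cc_mask(mask)
  px <- which(m$mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  cov <- stats::cov(px)
  if (!all(is.finite(cov))) cov <- diag(2)
  eg <- eigen(cov, symmetric = TRUE)
  ratio <- eg$values[1] / max(eg$values[2], 1e-12)
  if (nrow(px) < 3L || ratio < 1.05) {
    warning("near-isotropic mask: falling back to the image column axis")
    v <- c(0, 1)
  } else {
    v <- eg$vectors[, 1]
  }
  # orient: posterior = larger columns (or rows if the axis is vertical)
  if (abs(v[2]) > 1e-12) { if (v[2] < 0) v <- -v } else if (v[1] < 0) v <- -v
  if (flip) v <- -v
  proj <- px %*% v
  structure(list(axis = c(row = v[1], col = v[2]),
                 anterior = px[which.min(proj), ] - 1L,
                 posterior = px[which.max(proj), ] - 1L,
                 extent = diff(range(proj)) + 1),
            class = "cc_axis")
}

#' Geometric parcellation scheme
#'
#' The Witelson scheme cuts the anterior-posterior extent at 1/3, 1/2, 2/3
#' and 4/5 (anterior third; anterior and posterior midbody halves; posterior
#' third; posterior one-fifth). The Hofer scheme cuts at 1/6, 1/2, 2/3 and
#' 3/4 (first sixth; remainder of the anterior half; posterior half minus
#' the posterior third; third minus the posterior quarter; posterior
#' quarter). Both schemes share the 1/2 and 2/3 cuts, so their third parcels
#' coincide on any mask.
#'
#' @param name `"witelson"` or `"hofer"`.
#' @return object of class `geometric_scheme` with `name` and 4 strictly
#'   increasing `boundaries` in (0, 1).
#' @export
geometric_scheme <- function(name = c("witelson", "hofer")) {
  name <- match.arg(name)
  boundaries <- switch(name,
    witelson = c(1 / 3, 1 / 2, 2 / 3, 4 / 5),
    hofer = c(1 / 6, 1 / 2, 2 / 3, 3 / 4))
  structure(list(name = name, boundaries = boundaries),
            class = "geometric_scheme")
}

new_parcel_map <- function(labels, scheme, axis) {
  structure(list(labels = labels, scheme = scheme, axis = axis),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  areas <- tabulate(x$labels[x$labels > 0L], nbins = 5L)
  cat(sprintf("<parcel_map> %s scheme, parcel areas: %s px\n",
              x$scheme, paste(areas, collapse = ", ")))
  invisible(x)
}

#' Geometric parcellation (Witelson / Hofer)
#'
#' Projects every CC pixel onto the anterior-posterior axis, normalizes the
#' position to `t` in `[0, 1)` over the axis extent, and assigns parcel
#' `1 + #(boundaries <= t)` — a position exactly on a boundary goes to the
#' posterior side. On an axis-aligned rectangle of extent `n` this cuts at
#' columns `floor(fraction * n)` exactly.
#'
#' @param mask a `cc_mask` or binary matrix.
#' @param scheme a [geometric_scheme()] or its name.
#' @param flip flip the anterior direction.
#' @return a `parcel_map` (labels 0 outside the mask, 1..5 anterior to
#'   posterior inside).
#' @export
geometric_parcellate <- function(mask, scheme = "witelson", flip = FALSE) {
  m <- as_cc_mask(mask)
  if (is.character(scheme)) scheme <- geometric_scheme(scheme)
  if (!inherits(scheme, "geometric_scheme"))
    abort_validation("`scheme` must be a geometric_scheme or its name")
  ax <- suppressWarnings(anterior_posterior_axis(m, flip = flip))
  px <- which(m$mask, arr.ind = TRUE)
  proj <- px %*% ax$axis
  n <- diff(range(proj)) + 1
  if (n < 5) abort_validation("mask extent along the axis is below 5 px")
  t <- (proj - min(proj)) / n
  parcel <- 1L + rowSums(outer(as.vector(t), scheme$boundaries, ">="))
  labels <- matrix(0L, nrow(m$mask), ncol(m$mask))
  labels[px] <- as.integer(parcel)
  new_parcel_map(labels, scheme$name, ax)
}

#' Superpixel-based (non-geometric) parcellation
#'
#' Groups the superpixels inside the CC mask into five parcels: superpixel
#' centroids are projected onto the anterior-posterior axis and clustered by
#' 1-D K-means (k = 5, deterministic farthest-point initialization, sample
#' weights = superpixel area x mean intensity), groups are relabelled 1..5
#' by ascending mean projection, and every pixel inherits its superpixel's
#' parcel. A contiguity repair pass reassigns any parcel fragment
#' disconnected from its parcel's main body to the adjacent parcel with the
#' longest shared border.
#'
#' @param sp a `superpixel_map` computed inside the mask.
#' @param mask the `cc_mask` the superpixels cover.
#' @param flip flip the anterior direction.
#' @return a `parcel_map` with scheme `"slic"`.
#' @export
slic_parcellate <- function(sp, mask, flip = FALSE) {
  if (!inherits(sp, "superpixel_map"))
    abort_validation("`sp` must be a superpixel_map")
  m <- as_cc_mask(mask)
  if (!all(dim(sp$labels) == dim(m$mask)))
    abort_validation("superpixel map and mask shapes differ")
  inside <- sp$labels > 0L & m$mask
  sp_ids <- sort(unique(sp$labels[inside]))
  if (length(sp_ids) < 5L)
    abort_validation(sprintf(
      "only %d superpixels intersect the mask; at least 5 are needed: increase K",
      length(sp_ids)))
  ax <- suppressWarnings(anterior_posterior_axis(m, flip = flip))
  cen <- sp$centers[sp$centers$label %in% sp_ids, ]
  z <- as.vector(cbind(cen$row + 1, cen$col + 1) %*% ax$axis)
  wts <- cen$area * pmax(cen$intensity, 1e-6)
  grp <- weighted_kmeans_1d(z, k = 5L, w = wts)
  # order groups anterior -> posterior
  mean_proj <- vapply(1:5, function(g) mean(z[grp == g]), numeric(1))
  grp <- match(grp, order(mean_proj))
  parcel_of_sp <- integer(max(sp_ids))
  parcel_of_sp[cen$label] <- grp
  labels <- matrix(0L, nrow(m$mask), ncol(m$mask))
  labels[inside] <- parcel_of_sp[sp$labels[inside]]
  # CC pixels not covered by any superpixel: inherit from projection bands
  stray <- m$mask & labels == 0L
  if (any(stray)) {
    px <- which(stray, arr.ind = TRUE)
    proj <- px %*% ax$axis
    cuts <- vapply(1:5, function(g) mean(z[grp == g]), numeric(1))
    labels[stray] <- max.col(-abs(outer(as.vector(proj), cuts, "-")),
                             ties.method = "first")
  }
  labels <- repair_contiguity(labels)
  new_parcel_map(labels, "slic", ax)
}

# deterministic 1-D weighted K-means: farthest-point init from the smallest
# projection, Lloyd to convergence; degenerate inputs fall back to a rank
# split into k near-equal groups
weighted_kmeans_1d <- function(z, k, w) {
  rank_split <- function() as.integer(ceiling(rank(z, ties.method = "first") * k / length(z)))
  if (length(unique(z)) < k) return(rank_split())
  cen <- numeric(k)
  cen[1] <- z[which.min(z)]
  for (i in seq_len(k)[-1]) {
    dmin <- vapply(z, function(v) min(abs(v - cen[seq_len(i - 1)])), numeric(1))
    cen[i] <- z[which.max(dmin)]
  }
  assign <- integer(length(z))
  for (it in 1:300) {
    a <- max.col(-abs(outer(z, cen, "-")), ties.method = "first")
    if (identical(a, assign)) break
    assign <- a
    for (c in seq_len(k)) {
      sel <- a == c
      if (any(sel)) cen[c] <- sum(w[sel] * z[sel]) / sum(w[sel])
    }
  }
  if (any(tabulate(assign, k) == 0L)) return(rank_split())
  assign
}

# Reassign parcel fragments disconnected from their parcel's main body to
# the 4-adjacent parcel with the longest shared border.
repair_contiguity <- function(labels) {
  for (pass in 1:100) {
    fid <- label_fragments(labels, connectivity = 8L)
    nfrag <- max(fid)
    if (nfrag == 0L) break
    frag_area <- tabulate(fid[fid > 0L], nbins = nfrag)
    frag_label <- labels[match(seq_len(nfrag), as.vector(fid))]
    main <- tapply(seq_len(nfrag), frag_label,
                   function(ix) ix[order(-frag_area[ix], ix)][1])
    orphan <- setdiff(seq_len(nfrag), unlist(main))
    if (!length(orphan)) break
    changed <- FALSE
    h <- nrow(labels); w <- ncol(labels)
    for (fi in orphan) {
      px <- which(fid == fi)
      nb_labels <- integer(0)
      for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nb <- shift_px(px, sh, h, w)
        ok <- !is.na(nb)
        nl <- labels[nb[ok]]
        nf <- fid[nb[ok]]
        nb_labels <- c(nb_labels, nl[nl > 0L & nf != fi & !(nf %in% orphan)])
      }
      if (length(nb_labels)) {
        tt <- sort(table(nb_labels), decreasing = TRUE)
        top <- as.integer(names(tt)[tt == tt[1]])
        labels[px] <- min(top)  # ties: smaller parcel label
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}
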