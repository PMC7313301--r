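# Per-parcel evaluation against ground truth: one-vs-rest confusion counts
# and the five standard metrics (Dice, accuracy, sensitivity, specificity,
# precision), plus pairwise inter-method Dice tables.

parcel_labels_of <- function(x, arg = "map") {
  if (inherits(x, "parcel_map")) return(x$labels)
  if (is.matrix(x)) return(x)
  abort_validation(sprintf("`%s` must be a parcel_map or a label matrix", arg))
}

#' One-vs-rest confusion counts for a parcel
#'
#' Binarizes both maps at the given parcel label and tallies pixelwise
#' TP / TN / FP / FN over the full image (background included, so TN counts
#' background agreement).
#'
#' @param pred,truth `parcel_map`s or label matrices of identical shape.
#' @param parcel parcel label in `1..5`.
#' @param roi_only if `TRUE`, restrict the tally to the union of the two
#'   maps' foregrounds instead of the full image.
#' @return object of class `confusion_counts`: named numeric
#'   `(TP, TN, FP, FN)`.
#' @export
confusion <- function(pred, truth, parcel, roi_only = FALSE) {
  p <- parcel_labels_of(pred, "pred")
  t <- parcel_labels_of(truth, "truth")
  if (!all(dim(p) == dim(t)))
    abort_validation("`pred` and `truth` shapes differ")
  parcel <- check_count(parcel, "parcel")
  keep <- if (roi_only) p > 0L | t > 0L else rep(TRUE, length(p))
  pp <- p[keep] == parcel
  tt <- t[keep] == parcel
  structure(c(TP = sum(pp & tt), TN = sum(!pp & !tt),
              FP = sum(pp & !tt), FN = sum(!pp & tt)),
            class = "confusion_counts")
}

check_confusion <- function(c) {
  if (!is.numeric(c) || !all(c("TP", "TN", "FP", "FN") %in% names(c)))
    abort_validation("expected confusion counts with names TP, TN, FP, FN")
  if (any(c < 0)) abort_validation("confusion counts must be non-negative")
  c
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (2 TP + FN + FP)`. When prediction and truth are both empty for
#' the parcel (TP = FN = FP = 0) the Dice is defined as 1: the maps agree on
#' the parcel's absence.
#'
#' @param c a `confusion_counts`.
#' @export
dice <- function(c) {
  c <- check_confusion(c)
  denom <- 2 * c[["TP"]] + c[["FN"]] + c[["FP"]]
  if (denom == 0) {
    message("dice: both maps empty for this parcel; returning 1 (agreement on absence)")
    return(1)
  }
  2 * c[["TP"]] / denom
}

#' Confusion-count rate metrics
#'
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `precision = TP / (TP + FP)`. A zero denominator yields `NA` (an
#' undefined marker), not an error.
#'
#' @param c a `confusion_counts`.
#' @name rate_metrics
NULL

ratio_or_na <- function(num, denom) if (denom == 0) NA_real_ else num / denom

#' @rdname rate_metrics
#' @export
accuracy <- function(c) {
  c <- check_confusion(c)
  ratio_or_na(c[["TP"]] + c[["TN"]], sum(c))
}

#' @rdname rate_metrics
#' @export
sensitivity <- function(c) {
  c <- check_confusion(c)
  ratio_or_na(c[["TP"]], c[["TP"]] + c[["FN"]])
}

#' @rdname rate_metrics
#' @export
specificity <- function(c) {
  c <- check_confusion(c)
  ratio_or_na(c[["TN"]], c[["TN"]] + c[["FP"]])
}

#' @rdname rate_metrics
#' @export
precision <- function(c) {
  c <- check_confusion(c)
  ratio_or_na(c[["TP"]], c[["TP"]] + c[["FP"]])
}

#' Per-parcel metric report
#'
#' Computes the five metrics for every parcel of a prediction against a
#' ground truth, with mean and standard-deviation summary rows.
#'
#' @inheritParams confusion
#' @param parcels parcel labels to evaluate (default `1:5`).
#' @return data.frame with columns `parcel, dice, accuracy, sensitivity,
#'   specificity, precision`; the last two rows are `"mean"` and `"sd"`.
#' @export
metric_report <- function(pred, truth, parcels = 1:5, roi_only = FALSE) {
  rows <- lapply(parcels, function(pl) {
    c <- confusion(pred, truth, pl, roi_only = roi_only)
    data.frame(parcel = as.character(pl),
               dice = suppressMessages(dice(c)),
               accuracy = accuracy(c),
               sensitivity = sensitivity(c),
               specificity = specificity(c),
               precision = precision(c))
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1, drop = FALSE]
  tab <- rbind(tab,
               cbind(data.frame(parcel = "mean"), as.data.frame(t(colMeans(num)))),
               cbind(data.frame(parcel = "sd"), as.data.frame(t(apply(num, 2, stats::sd)))))
  rownames(tab) <- NULL
  tab
}

#' Pairwise per-parcel Dice between methods
#'
#' For each unordered pair of maps and each parcel, the Dice of the
#' one-vs-rest masks. Rows are parcels; columns are pairs.
#'
#' @param maps named list of at least two `parcel_map`s or label matrices
#'   of identical shape.
#' @param parcels parcel labels (default `1:5`).
#' @export
pairwise_dice_table <- function(maps, parcels = 1:5) {
  if (!is.list(maps) || length(maps) < 2L)
    abort_validation("`maps` must be a named list of at least two maps")
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    names(maps) <- paste0("map", seq_along(maps))
  labs <- lapply(maps, parcel_labels_of)
  d0 <- dim(labs[[1]])
  for (l in labs) if (!all(dim(l) == d0))
    abort_validation("all maps must share the same shape")
  pairs <- utils::combn(names(maps), 2L)
  out <- data.frame(parcel = parcels)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    out[[paste(a, "vs", b)]] <- vapply(parcels, function(pl)
      suppressMessages(dice(confusion(labs[[a]], labs[[b]], pl))), numeric(1))
  }
  out
}
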