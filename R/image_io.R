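# Reading/writing slices and label maps, and intensity normalization.
#
# Conventions shared by every module: an image is a numeric matrix [row, col],
# row 1 at the top of the rendered image; exported point sets use 0-based
# (row, col) coordinates.

#' Read a grayscale midsagittal slice
#'
#' Reads a 2-D grayscale image from PNG, TIFF, or NIfTI-1. Multi-channel
#' rasters are reduced to luminance (Rec. 601 weights); intensities are
#' returned exactly as decoded, without rescaling. For 3-D NIfTI volumes one
#' sagittal slice must be selected with `slice` (indexing the first voxel
#' dimension, 1-based).
#'
#' @param path path to a `.png`, `.tif(f)`, `.nii` or `.nii.gz` file.
#' @param slice for 3-D NIfTI input, the sagittal slice index; ignored
#'   otherwise.
#' @return a numeric matrix (rows x cols).
#' @export
read_gray <- function(path, slice = NULL) {
  if (!is.character(path) || length(path) != 1L)
    abort_io("`path` must be a single file path")
  if (!file.exists(path))
    abort_io(sprintf("cannot read '%s': file does not exist", path))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) abort_io(sprintf("cannot decode '%s' as PNG: %s",
                                                        path, conditionMessage(e)))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) abort_io(sprintf("cannot decode '%s' as TIFF: %s",
                                                         path, conditionMessage(e)))),
    nii = {
      vol <- tryCatch(RNifti::readNifti(path),
                      error = function(e) abort_io(sprintf("cannot decode '%s' as NIfTI: %s",
                                                           path, conditionMessage(e))))
      arr <- as.array(vol)
      if (length(dim(arr)) == 2L) arr
      else if (length(dim(arr)) == 3L) {
        if (is.null(slice))
          abort_config(sprintf("'%s' is a 3-D volume: a sagittal `slice` index is required", path))
        slice <- check_count(slice, "slice")
        if (slice > dim(arr)[1])
          abort_config(sprintf("slice %d out of range (volume has %d sagittal slices)",
                               slice, dim(arr)[1]))
        arr[slice, , ]
      } else abort_io(sprintf("'%s': unsupported NIfTI dimensionality %d",
                              path, length(dim(arr))))
    },
    abort_io(sprintf("unsupported image format '.%s' for '%s'", ext, path))
  )
  if (length(dim(img)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    nch <- min(dim(img)[3], 3L)
    img <- Reduce(`+`, lapply(seq_len(nch), function(i) img[, , i] * w[i] / sum(w[seq_len(nch)])))
  }
  img <- as.matrix(img)
  storage.mode(img) <- "double"
  check_gray_image(img, "decoded image")
  img
}

#' Write / read an integer label map
#'
#' Label maps (cluster maps, superpixel maps, parcel maps) are stored as
#' 16-bit grayscale TIFF, losslessly: `read_label_map(write_label_map(x))`
#' is pixel-identical for any labels in `0..65535`.
#'
#' @param map integer matrix of labels (0 = background).
#' @param path output path (`.tif`).
#' @export
write_label_map <- function(map, path) {
  if (!is.matrix(map) || any(!is.finite(map)))
    abort_validation("`map` must be a finite numeric/integer matrix")
  if (any(map != round(map)) || any(map < 0))
    abort_validation("labels must be non-negative integers")
  if (any(map > 65535))
    abort_validation("labels must fit in the 16-bit unsigned range (max 65535)")
  ok <- tryCatch({
    tiff::writeTIFF(map / 65535, path, bits.per.sample = 16L)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    abort_io(sprintf("cannot write label map to '%s'", path))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read '%s': file does not exist", path))
  m <- tryCatch(tiff::readTIFF(path),
                error = function(e) abort_io(sprintf("cannot decode '%s': %s",
                                                     path, conditionMessage(e))))
  matrix(as.integer(round(as_mat(m) * 65535)), nrow(as_mat(m)))
}

#' Min-max intensity normalization
#'
#' Affinely rescales an image so its minimum maps to 0 and maximum to 1; a
#' constant image maps to all zeros. Idempotent on its own output. All later
#' stages (clustering, SLIC intensity distances) operate on normalized
#' intensities.
#'
#' @param img numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  check_gray_image(img)
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}
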