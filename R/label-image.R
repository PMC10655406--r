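#' Label images
#'
#' A label image is a 2D or 3D integer array in which all voxels of one
#' segmented cell share one strictly positive label and 0 marks the
#' background. Labelings may be discontinuous (missing labels), as commonly
#' produced by segmentation post-processing. Each image carries a per-axis
#' voxel spacing (physical size of one voxel along each array dimension,
#' default 1), used to convert voxel counts to volumes.
#'
#' @param voxels A 2D or 3D array (or matrix) of non-negative integers.
#' @param spacing Numeric vector of per-axis voxel sizes, one per array
#'   dimension; defaults to 1 per axis.
#' @return An object of class `label_image` with fields `voxels` (integer
#'   array) and `spacing`.
#' @export
label_image <- function(voxels, spacing = NULL) {
  if (is.null(dim(voxels))) stop_lineage("invalid label image: not an array")
  nd <- length(dim(voxels))
  if (nd < 2L || nd > 3L) {
    stop_lineage("invalid label image: expected 2 or 3 dimensions, got %d", nd)
  }
  v <- voxels
  if (!is.integer(v)) {
    if (any(v != round(v), na.rm = TRUE)) {
      stop_lineage("invalid label image: non-integer values")
    }
    storage.mode(v) <- "integer"
  }
  if (anyNA(v) || any(v < 0L)) {
    stop_lineage("invalid label image: labels must be non-negative integers")
  }
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_lineage("invalid spacing: need %d positive values", nd)
  }
  structure(list(voxels = v, spacing = as.numeric(spacing)),
            class = "label_image")
}

as_label_image <- function(x) {
  if (inherits(x, "label_image")) x else label_image(x)
}

#' Labels present in a label image
#' @param image A `label_image`.
#' @return Sorted strictly positive labels (background 0 excluded).
#' @export
image_labels <- function(image) {
  image <- as_label_image(image)
  v <- image$voxels
  sort(unique(v[v > 0L]))
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Label image %s, spacing (%s): %d labels, %d foreground voxels\n",
              paste(d, collapse = " x "),
              paste(format(x$spacing), collapse = ", "),
              length(image_labels(x)), sum(x$voxels > 0L)))
  invisible(x)
}

# Smallest of the 8/16/32-bit unsigned precisions holding `maxval`.
tiff_bits_for <- function(maxval) {
  if (maxval < 2^8) 8L else if (maxval < 2^16) 16L else 32L
}

#' Read and write label images as TIFF
#'
#' `write_label_tiff()` stores a label image as a single- (2D) or multi-page
#' (3D, one page per slice along the third dimension) grayscale TIFF at the
#' smallest of 8/16/32-bit precision that holds the maximum label; 8/16-bit
#' files hold integer samples exactly, the 32-bit path uses float samples and
#' is exact for labels below 2^23. `read_label_tiff()` reads such files back
#' (and any unsigned-integer label TIFF); voxel spacing is taken from the
#' `spacing` argument when given, else from TIFF x/y resolution tags when the
#' file carries them, else defaults to 1 per axis (our own writer cannot
#' embed resolution tags, so spacing normally travels alongside the file).
#'
#' @param image A `label_image` (or bare array).
#' @param path TIFF file path.
#' @param spacing Optional per-axis voxel spacing overriding file metadata.
#' @return `read_label_tiff()`: a `label_image` (2D when the file has a
#'   single page). `write_label_tiff()`: invisibly, `path`.
#' @export
write_label_tiff <- function(image, path) {
  image <- as_label_image(image)
  v <- image$voxels
  bits <- tiff_bits_for(max(v, 0L))
  scale <- 2^bits - 1
  if (length(dim(v)) == 2L) {
    pages <- list(v / scale)
  } else {
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / scale)
  }
  if (length(pages) == 1L) pages <- pages[[1]]
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "LZW")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path, spacing = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      stop_parse("cannot read TIFF %s: %s", path,
                                 conditionMessage(e))
                    })
  if (!length(pages)) stop_parse("cannot read TIFF %s: no pages", path)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- 16L
  to_int <- function(p) {
    m <- as.integer(round(p * (2^bits - 1)))
    dim(m) <- dim(p)  # drop the TIFF tag attributes readTIFF attaches
    m
  }
  mats <- lapply(pages, to_int)
  d <- dim(mats[[1]])
  if (any(vapply(mats, function(m) !identical(dim(m), d), logical(1)))) {
    stop_parse("cannot read TIFF %s: pages differ in size", path)
  }
  v <- if (length(mats) == 1L) {
    mats[[1]]
  } else {
    array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
  }
  if (is.null(spacing)) {
    xres <- info$x.resolution
    yres <- info$y.resolution
    if (!is.null(xres) && !is.null(yres) && xres > 0 && yres > 0) {
      spacing <- c(1 / yres, 1 / xres, if (length(dim(v)) == 3L) 1)
    }
  }
  label_image(v, spacing = spacing)
}
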