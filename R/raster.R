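#' Read a fin micrograph as an 8-bit RGB array
#'
#' Reads a TIFF or PNG micrograph and returns an integer array of dimension
#' `nrow x ncol x 3` with values in 0--255, row 1 at the top of the image.
#' Greyscale images are replicated across the three channels; an alpha
#' channel, if present, is dropped.  16-bit inputs are linearly rescaled to
#' 8-bit with a warning, because all colour-threshold bands in this package
#' are expressed on the 8-bit scale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer array `c(rows, cols, 3)`, values 0--255.
#' @export
read_fin_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image not found: ", path), class = "finregen_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    img <- img * 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (max(img) > 255) {
      warn("16-bit image rescaled to 8-bit (thresholds are 8-bit values)")
      img <- img / 65535 * 255
    }
  } else {
    abort(paste0("unsupported image format: .", ext), class = "finregen_io_error")
  }
  as_rgb255(img)
}

#' Coerce a numeric raster to the package's 8-bit RGB convention
#'
#' @param img Numeric matrix (greyscale) or array with 3 (RGB) or 4 (RGBA)
#'   channels, values on the 0--255 scale.
#' @return Integer array `c(rows, cols, 3)`.
#' @export
as_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (length(dim(img)) != 3) abort("raster must be a matrix or a rows x cols x channels array")
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3) abort("raster must have 1, 3 or 4 channels")
  storage.mode(img) <- "integer"
  img[img < 0L] <- 0L
  img[img > 255L] <- 255L
  img
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param img Integer array `c(rows, cols, 3)`, values 0--255.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_fin_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Label connected components of a binary mask
#'
#' 8-connected labelling (the package convention for bony-ray components).
#' Built on [EBImage::bwlabel()], which is 4-connected, plus a union-find
#' merge of diagonally touching labels.  Components smaller than `min_px`
#' pixels are discarded as speckle.
#'
#' @param mask Logical matrix.
#' @param min_px Minimum component size in pixels; smaller components get
#'   label 0.  Default 1 (keep everything).
#' @return Integer matrix of the same dimension; 0 is background, components
#'   are numbered 1..k in row-major order of first appearance.
#' @export
label_components <- function(mask, min_px = 1L) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax > 1L) {
    # merge labels that touch diagonally -> 8-connectivity
    parent <- seq_len(nmax)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (i in seq_len(nrow(pairs))) {
        a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(nmax), find, integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes > 0L & sizes < min_px)
    if (length(small)) lab[lab %in% small] <- 0L
    kept <- as.vector(t(lab))  # row-major order of appearance
    first <- unique(kept[kept > 0L])
    if (length(first)) {
      remap <- integer(max(lab)); remap[first] <- seq_along(first)
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  lab
}

#' Fill interior holes in a binary mask
#'
#' @param mask Logical matrix.
#' @return Logical matrix with enclosed background regions filled.
#' @export
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(EBImage::Image(mask * 1L))
  matrix(as.integer(EBImage::imageData(filled)) > 0L, nrow(mask), ncol(mask))
}

#' Construct a region mask
#'
#' A plain container for a binary raster region, carrying its pixel count.
#'
#' @param mask Logical matrix.
#' @return An object of class `region_mask`: list with `mask` and `n_pixels`.
#' @export
region_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, n_pixels = sum(mask)), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", nrow(x$mask), "x", ncol(x$mask), ", ",
      x$n_pixels, " pixels\n", sep = "")
  invisible(x)
}

as_mask_matrix <- function(x, what = "mask") {
  if (inherits(x, c("region_mask", "mineral_mask"))) return(x$mask)
  if (is.matrix(x) && is.logical(x)) return(x)
  abort(paste0(what, " must be a logical matrix or a region/mineral mask"))
}

#' Spatial calibration from a ruled calibrator image
#'
#' Converts a pixel count measured across a known physical span on a
#' calibrator micrograph (e.g. a stage micrometer) into the `mm_per_px`
#' scale used by all area and length measurements.
#'
#' @param px_span Number of pixels spanned by the ruled interval.
#' @param mm_span Physical length of that interval in mm.
#' @return mm per pixel (positive scalar).
#' @export
calibrate_mm_per_px <- function(px_span, mm_span) {
  stopifnot(px_span > 0, mm_span > 0)
  mm_span / px_span
}
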