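#' RGB colour-threshold specification for alizarin red S signal
#'
#' Mineralized bone stained with alizarin red S fluoresces red; the real
#' mineralized area (RMA) is selected by a conjunctive RGB band test.  The
#' standard protocol keeps green and blue between 0 and 30 and red up to
#' 255, with the red minimum determined per treatment (expected within
#' 20--60 for typical acquisitions).
#'
#' @param red_min,red_max,green_min,green_max,blue_min,blue_max Integer
#'   channel bounds in 0--255, each `min <= max`.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(red_min = 40L, red_max = 255L,
                           green_min = 0L, green_max = 30L,
                           blue_min = 0L, blue_max = 30L) {
  v <- vapply(list(red_min, red_max, green_min, green_max, blue_min, blue_max),
              as.integer, integer(1))
  if (any(v < 0L | v > 255L)) abort("threshold bounds must lie in 0..255")
  if (v[1] > v[2] || v[3] > v[4] || v[5] > v[6]) {
    abort("each channel minimum must not exceed its maximum")
  }
  structure(list(red_min = v[1], red_max = v[2], green_min = v[3],
                 green_max = v[4], blue_min = v[5], blue_max = v[6]),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec> R [", x$red_min, ",", x$red_max, "] G [",
      x$green_min, ",", x$green_max, "] B [", x$blue_min, ",", x$blue_max, "]\n",
      sep = "")
  invisible(x)
}

#' Select alizarin-red-positive pixels by RGB colour threshold
#'
#' A pixel enters the mineral mask iff all three channels fall inside their
#' bands and, when `restrict_to` is given, the pixel lies inside that
#' region (e.g. the regenerate, so RMA is measured within REG).
#'
#' @param fluorescence 8-bit RGB array (`rows x cols x 3`).
#' @param spec A [threshold_spec()].
#' @param restrict_to Optional region mask (logical matrix or
#'   [region_mask()]).
#' @return A `mineral_mask` object: `mask` (logical matrix),
#'   `threshold_used`, `n_pixels`.
#' @export
apply_rgb_threshold <- function(fluorescence, spec = threshold_spec(), restrict_to = NULL) {
  img <- as_rgb255(fluorescence)
  nr <- dim(img)[1]; nc <- dim(img)[2]
  r <- matrix(img[, , 1], nr, nc)
  g <- matrix(img[, , 2], nr, nc)
  b <- matrix(img[, , 3], nr, nc)
  m <- r >= spec$red_min & r <= spec$red_max &
       g >= spec$green_min & g <= spec$green_max &
       b >= spec$blue_min & b <= spec$blue_max
  if (!is.null(restrict_to)) {
    rm_ <- as_mask_matrix(restrict_to, "restrict_to")
    if (!identical(dim(rm_), dim(m))) abort("restrict_to dimensions differ from image")
    m <- m & rm_
  }
  structure(list(mask = m, threshold_used = spec, n_pixels = sum(m)),
            class = "mineral_mask")
}

#' @export
print.mineral_mask <- function(x, ...) {
  cat("<mineral_mask> ", nrow(x$mask), "x", ncol(x$mask), ", ",
      x$n_pixels, " pixels, red_min = ", x$threshold_used$red_min,
      if (isTRUE(x$empty_signal)) ", EMPTY SIGNAL" else "", "\n", sep = "")
  invisible(x)
}

#' Automatically tune the red minimum of the colour threshold
#'
#' The protocol calls for adjusting the red minimum methodically and
#' consistently per treatment so the mask hugs the lateral edges of the
#' rays and the distal mineralized summit.  The automatic rule is Otsu's
#' threshold on the red-channel histogram within the distal half-plane,
#' clamped to the `search` range; it is deterministic for a fixed image and
#' removes the analyst from the loop.  A manual `threshold_spec` always
#' takes precedence downstream.
#'
#' If no distal pixel reaches the bottom of the search range the returned
#' spec carries `red_min = max(search)` and an `empty_signal` attribute
#' (RMA will be 0).
#'
#' @param fluorescence 8-bit RGB array.
#' @param distal Distal region mask (logical matrix or [region_mask()]).
#' @param search Integer candidate range for `red_min` (default 20:60).
#' @return A [threshold_spec()] with attribute `empty_signal` (logical).
#' @export
autotune_red_min <- function(fluorescence, distal, search = 20:60) {
  img <- as_rgb255(fluorescence)
  dm <- as_mask_matrix(distal, "distal")
  red <- img[, , 1][dm]
  lo <- min(search); hi <- max(search)
  if (!length(red) || max(red) < lo) {
    spec <- threshold_spec(red_min = hi)
    attr(spec, "empty_signal") <- TRUE
    return(spec)
  }
  # Otsu on the 8-bit red histogram within the distal region
  th <- EBImage::otsu(EBImage::Image(red / 255), range = c(0, 1), levels = 256)
  red_min <- as.integer(round(th * 255)) + 1L   # first level counted as signal
  red_min <- min(max(red_min, lo), hi)
  spec <- threshold_spec(red_min = red_min)
  attr(spec, "empty_signal") <- FALSE
  spec
}
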