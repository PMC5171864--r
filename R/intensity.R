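#' Convert an RGB raster to 8-bit luma (YUV Y channel)
#'
#' Per-pixel `Y = round(cr*R + cg*G + cb*B)` with BT.601 coefficients by
#' default (0.299, 0.587, 0.114) -- the YUV convention of common image
#' software.  Coefficients are configurable.
#'
#' @param raster 8-bit RGB array.
#' @param coefs Length-3 numeric luma weights for R, G, B.
#' @return Integer matrix of luma values 0--255.
#' @export
rgb_to_luma <- function(raster, coefs = c(0.299, 0.587, 0.114)) {
  img <- as_rgb255(raster)
  stopifnot(length(coefs) == 3)
  y <- round(coefs[1] * img[, , 1] + coefs[2] * img[, , 2] + coefs[3] * img[, , 3])
  storage.mode(y) <- "integer"
  y
}

#' Pixel-intensity histogram within the mineralized area
#'
#' Tallies the luma values of mineral-mask pixels falling inside the
#' intensity spectrum (15--254 by default; value 255 and the near-black
#' values below 15 are excluded, which together with controlled acquisition
#' settings removes non-mineralized background).  Relative frequencies are
#' normalized by the number of pixels inside the spectrum (default) or by
#' all mask pixels (`denominator = "mask"`).
#'
#' @param luma Integer luma matrix from [rgb_to_luma()].
#' @param mineral `mineral_mask` or logical matrix.
#' @param spectrum Inclusive intensity bounds, default `c(15, 254)`.
#' @param denominator `"spectrum"` (default) or `"mask"`.
#' @param source_id Optional identifier attached to the result.
#' @return A tibble (class `intensity_histogram`) with one row per luma
#'   value in the spectrum: `luma`, `count`, `freq`.  Attributes:
#'   `n_pixels_in_spectrum`, `n_mask`, `denominator`, `source_id`, `empty`.
#'   An empty spectrum yields all-zero counts, `empty = TRUE` and a
#'   warning.
#' @export
intensity_histogram <- function(luma, mineral, spectrum = c(15, 254),
                                denominator = c("spectrum", "mask"),
                                source_id = NULL) {
  denominator <- match.arg(denominator)
  m <- as_mask_matrix(mineral, "mineral")
  if (!identical(dim(luma), dim(m))) abort("luma and mask dimensions differ")
  vals <- luma[m]
  lo <- spectrum[1]; hi <- spectrum[2]
  inside <- vals[vals >= lo & vals <= hi]
  counts <- tabulate(inside - lo + 1L, nbins = hi - lo + 1L)
  denom <- if (denominator == "spectrum") length(inside) else length(vals)
  empty <- length(inside) == 0L
  if (empty) warn("no mask pixels inside the intensity spectrum; empty histogram")
  out <- tibble(luma = lo:hi, count = counts,
                freq = if (denom > 0) counts / denom else rep(0, length(counts)))
  structure(out, class = c("intensity_histogram", class(out)),
            n_pixels_in_spectrum = length(inside), n_mask = length(vals),
            denominator = denominator, source_id = source_id, empty = empty)
}

#' Low- and high-intensity class frequencies
#'
#' Sums the histogram's relative frequencies over the low (15--29) and
#' high (30--44) intensity classes used to compare mineral staining
#' intensity between groups.
#'
#' @param hist An [intensity_histogram()].
#' @param low,high Inclusive class bounds.
#' @return One-row tibble: `low_15_29`, `high_30_44` (column names follow
#'   the supplied bounds).
#' @export
class_frequencies <- function(hist, low = c(15, 29), high = c(30, 44)) {
  stopifnot(inherits(hist, "intensity_histogram") || all(c("luma", "freq") %in% names(hist)))
  f_low <- sum(hist$freq[hist$luma >= low[1] & hist$luma <= low[2]])
  f_high <- sum(hist$freq[hist$luma >= high[1] & hist$luma <= high[2]])
  out <- tibble(f_low, f_high)
  names(out) <- c(paste0("low_", low[1], "_", low[2]),
                  paste0("high_", high[1], "_", high[2]))
  out
}

#' Refuse to pool intensity data acquired under different exposures
#'
#' Intensity comparisons are only meaningful between images acquired with
#' identical settings (exposure time, magnification, gamma 1.0).  Given the
#' recorded exposure times of the records entering a comparison, this stops
#' with an error when they differ, unless `force = TRUE`.
#'
#' @param exposure_ms Numeric vector of exposure times (NA allowed; NAs are
#'   ignored with a warning).
#' @param force Set `TRUE` to pool anyway.
#' @return `TRUE`, invisibly, when pooling is acceptable.
#' @export
check_exposure_pooling <- function(exposure_ms, force = FALSE) {
  known <- exposure_ms[!is.na(exposure_ms)]
  if (length(known) < length(exposure_ms)) {
    warn("some records carry no exposure metadata; they are assumed comparable")
  }
  if (length(unique(known)) > 1 && !force) {
    abort(paste0("records were acquired at different exposures (",
                 paste(sort(unique(known)), collapse = ", "),
                 " ms); refusing to pool intensity data (use force = TRUE to override)"),
          class = "finregen_exposure_mismatch")
  }
  invisible(TRUE)
}

#' Compare intensity-class frequencies between groups
#'
#' Given per-specimen class frequencies, runs an unpaired t test of each
#' class for every treatment group against the control group and reports
#' the direction of significant changes.
#'
#' @param data Data frame with one row per specimen: a `group` column plus
#'   one column per intensity class (e.g. `low_15_29`, `high_30_44`).
#' @param group Name of the grouping column (default `"group_label"`).
#' @param control Label of the control group (default `"control"`).
#' @param classes Class column names; defaults to the low/high pair.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per (group, class): mean difference vs
#'   control, `p_value`, and `direction` (`"decrease"`, `"none"`,
#'   `"increase"`).
#' @export
compare_intensity_classes <- function(data, group = "group_label",
                                      control = "control",
                                      classes = c("low_15_29", "high_30_44"),
                                      alpha = 0.05) {
  data <- as_tibble(data)
  stopifnot(group %in% names(data), all(classes %in% names(data)))
  g <- data[[group]]
  if (!control %in% g) abort(paste0("no rows with control label '", control, "'"))
  others <- setdiff(unique(g), control)
  purrr::map_dfr(others, function(trt) {
    purrr::map_dfr(classes, function(cl) {
      a <- data[[cl]][g == trt]; b <- data[[cl]][g == control]
      tt <- t_test_unpaired(a, b)
      dir <- if (tt$p_value < alpha) (if (tt$mean_diff > 0) "increase" else "decrease") else "none"
      tibble(group = trt, class = cl, mean_diff = tt$mean_diff,
             p_value = tt$p_value, direction = dir)
    })
  })
}
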