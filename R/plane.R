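#' Annotate the amputation plane
#'
#' The amputation plane is a straight line traced by the analyst through two
#' endpoints on the micrograph (dorsal and ventral edge of the cut).  All
#' coordinates are R-native: 1-based `(row, col)`, row 1 at the top.
#' `distal_side` states which side of the line holds the regenerate.
#'
#' @param p_dorsal,p_ventral Numeric `(row, col)` endpoints; must differ.
#' @param distal_side One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return An `amputation_plane` object.
#' @examples
#' amputation_plane(c(100, 10), c(100, 390), distal_side = "up")
#' @export
amputation_plane <- function(p_dorsal, p_ventral, distal_side = c("up", "down", "left", "right")) {
  distal_side <- match.arg(distal_side)
  p_dorsal <- as.numeric(p_dorsal); p_ventral <- as.numeric(p_ventral)
  stopifnot(length(p_dorsal) == 2, length(p_ventral) == 2)
  if (all(p_dorsal == p_ventral)) {
    abort("degenerate amputation plane: coincident endpoints",
          class = "finregen_invalid_annotation")
  }
  obj <- structure(list(p_dorsal = p_dorsal, p_ventral = p_ventral,
                        distal_side = distal_side),
                   class = "amputation_plane")
  # the distal direction must not be parallel to the plane itself
  if (plane_probe_sign(obj) == 0) {
    abort("distal_side is parallel to the amputation plane",
          class = "finregen_invalid_annotation")
  }
  obj
}

#' @export
print.amputation_plane <- function(x, ...) {
  cat("<amputation_plane> (", x$p_dorsal[1], ",", x$p_dorsal[2], ") - (",
      x$p_ventral[1], ",", x$p_ventral[2], "), distal: ", x$distal_side,
      ", length ", round(plane_length_px(x), 2), " px\n", sep = "")
  invisible(x)
}

#' Stump width in pixels
#'
#' Euclidean distance between the two plane endpoints: the raw STU
#' measurement before calibration.
#'
#' @param plane An [amputation_plane()].
#' @return Length in pixels.
#' @export
plane_length_px <- function(plane) {
  sqrt(sum((plane$p_ventral - plane$p_dorsal)^2))
}

# raw cross-product sign of a probe point nudged toward the distal side
plane_probe_sign <- function(plane) {
  dir <- switch(plane$distal_side,
                up = c(-1, 0), down = c(1, 0), left = c(0, -1), right = c(0, 1))
  probe <- plane$p_dorsal + dir
  sign(plane_cross(plane, probe[1], probe[2]))
}

# cross product (p2-p1) x (p - p1); vectorized over row/col
plane_cross <- function(plane, row, col) {
  p1 <- plane$p_dorsal; p2 <- plane$p_ventral
  (p2[2] - p1[2]) * (row - p1[1]) - (p2[1] - p1[1]) * (col - p1[2])
}

#' Signed distance of every pixel from the amputation plane
#'
#' Distances are in pixels, positive on the distal (regenerate) side,
#' negative on the proximal (stump) side, zero on the line.
#'
#' @param plane An [amputation_plane()].
#' @param dim Raster dimension `c(rows, cols)`.
#' @return Numeric `rows x cols` matrix.
#' @export
plane_signed_distance <- function(plane, dim) {
  nr <- dim[1]; nc <- dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- plane_cross(plane, rows, cols) / plane_length_px(plane)
  d * plane_probe_sign(plane)
}

#' Coordinate of every pixel along the plane axis
#'
#' Projection (in pixels) of each pixel onto the unit vector running from
#' `p_dorsal` to `p_ventral`; used to order ray tips and group ray segments.
#'
#' @inheritParams plane_signed_distance
#' @return Numeric `rows x cols` matrix.
#' @export
plane_axis_coord <- function(plane, dim) {
  nr <- dim[1]; nc <- dim[2]
  p1 <- plane$p_dorsal
  u <- (plane$p_ventral - p1) / plane_length_px(plane)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - p1[1]) * u[1] + (cols - p1[2]) * u[2]
}

#' Partition a raster into distal and proximal half-planes
#'
#' Every pixel is assigned to exactly one side by the sign of its distance
#' to the infinite line through the plane endpoints; pixels exactly on the
#' line are assigned to the distal side (fixed convention).
#'
#' @param dim Raster dimension `c(rows, cols)`.
#' @param plane An [amputation_plane()].
#' @return List with `distal` and `proximal` [region_mask()] objects.
#' @examples
#' pl <- amputation_plane(c(1, 6), c(10, 6), distal_side = "right")
#' sp <- split_by_plane(c(10, 10), pl)
#' sp$distal$n_pixels  # cols 6..10 -> 50
#' @export
split_by_plane <- function(dim, plane) {
  stopifnot(length(dim) == 2, all(dim >= 1))
  for (p in list(plane$p_dorsal, plane$p_ventral)) {
    if (p[1] < 1 || p[1] > dim[1] || p[2] < 1 || p[2] > dim[2]) {
      abort("plane endpoint outside raster bounds", class = "finregen_invalid_annotation")
    }
  }
  d <- plane_signed_distance(plane, dim)
  distal <- d >= 0
  list(distal = region_mask(distal), proximal = region_mask(!distal))
}
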