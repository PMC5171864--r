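#' Segment the regenerate in a bright-field image
#'
#' REG is the full regenerated area from the amputation plane to the distal
#' extremity of the regenerate.  The automatic rule mirrors what an analyst
#' traces: within the distal half-plane, tissue is darker than the clear
#' background (estimated as the modal luminance of the brightest decile),
#' so pixels whose luminance falls below `frac` times that background level
#' are tissue; the largest 8-connected component, with holes filled, is the
#' regenerate.  A manually traced outline (polygon of
#' `(row, col)` vertices) always takes precedence.
#'
#' @param brightfield 8-bit RGB array.
#' @param distal Distal region mask from [split_by_plane()].
#' @param outline Optional manual outline: numeric matrix of polygon
#'   vertices `(row, col)`; when supplied it is rasterized and returned
#'   as-is.
#' @param frac Fraction of the modal background luminance below which a
#'   pixel counts as tissue (default 0.9).
#' @return A [region_mask()] of the regenerate.
#' @export
segment_regenerate <- function(brightfield, distal, outline = NULL, frac = 0.9) {
  dm <- as_mask_matrix(distal, "distal")
  if (!is.null(outline)) {
    return(region_mask(rasterize_polygon(outline, dim(dm))))
  }
  img <- as_rgb255(brightfield)
  if (!identical(dim(img)[1:2], dim(dm))) abort("brightfield dimensions differ from distal mask")
  y <- rgb_to_luma(img)
  yv <- y[dm]
  # background = modal luminance of the brightest decile (the clear field is
  # always the bright end; the tissue itself may dominate the half-plane)
  bright <- yv[yv >= quantile(yv, 0.9)]
  mode_bg <- as.integer(names(which.max(table(bright))))
  tissue <- (y < frac * mode_bg) & dm
  lab <- label_components(tissue)
  if (max(lab) == 0L) {
    abort("no tissue component found distal to the amputation plane",
          class = "finregen_empty_regenerate")
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  region_mask(fill_holes(lab == keep))
}

#' Rasterize a polygon outline into a binary mask
#'
#' Even-odd scanline fill over pixel centres; vertices are `(row, col)`
#' coordinates.  Used for manual regenerate outlines.
#'
#' @param vertices Numeric matrix with two columns `(row, col)`.
#' @param dim Raster dimension `c(rows, cols)`.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, dim) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3)
  nr <- dim[1]; nc <- dim[2]
  out <- matrix(FALSE, nr, nc)
  y1 <- v[, 1]; x1 <- v[, 2]
  y2 <- c(y1[-1], y1[1]); x2 <- c(x1[-1], x1[1])
  for (row in seq_len(nr)) {
    crosses <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(crosses)) next
    xs <- x1[crosses] + (row - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1])
      if (b >= a) out[row, max(1, a):min(nc, b)] <- TRUE
    }
  }
  out
}

# per-component summaries in plane-aligned coordinates (u along plane,
# v signed distance, positive distal)
component_stats <- function(lab, u, v) {
  ids <- sort(unique(lab[lab > 0L]))
  purrr::map_dfr(ids, function(i) {
    sel <- lab == i
    tibble(component = i, n_px = sum(sel),
           u_lo = min(u[sel]), u_hi = max(u[sel]),
           v_lo = min(v[sel]), v_hi = max(v[sel]))
  })
}

# sweep-line grouping: components whose u-intervals overlap belong to the
# same ray (intersegment joints split one ray into several components)
group_rays <- function(stats) {
  stats <- dplyr::arrange(stats, .data$u_lo)
  ray_id <- integer(nrow(stats)); cur <- 0L; cur_hi <- -Inf
  for (i in seq_len(nrow(stats))) {
    if (stats$u_lo[i] > cur_hi) { cur <- cur + 1L; cur_hi <- stats$u_hi[i] }
    else cur_hi <- max(cur_hi, stats$u_hi[i])
    ray_id[i] <- cur
  }
  stats$ray <- ray_id
  stats
}

#' Estimated mineralized area (EMA) polygon from ray tips
#'
#' EMA is delimited by joining the most distal mineralized tip of each ray
#' and closing the outline along the amputation plane, so it includes the
#' non-mineralized inter-ray tissue.  8-connected mineral components distal
#' to the plane (speckle below `min_px` discarded) are grouped into rays by
#' overlapping extent along the plane axis (intersegment joints split a ray
#' into several components); each ray contributes the pixel with maximal
#' signed distance from the plane as its tip, and tips are ordered along
#' the plane axis between the two plane endpoints.
#'
#' @param mineral A `mineral_mask` (or logical matrix) of alizarin-red
#'   positive pixels.
#' @param plane An [amputation_plane()].
#' @param min_px Minimum component size counted as a ray (default 20).
#' @return A `tip_polygon` object: `vertices` (matrix of `(row, col)`),
#'   `area_px2` (shoelace area), `n_rays`, `empty`.  When no mineral
#'   component exists, `empty = TRUE` and `area_px2 = 0` (EMA = 0).
#' @export
distal_tip_polygon <- function(mineral, plane, min_px = 20L) {
  m <- as_mask_matrix(mineral, "mineral")
  d <- plane_signed_distance(plane, dim(m))
  u <- plane_axis_coord(plane, dim(m))
  lab <- label_components(m & d >= 0, min_px = min_px)
  if (max(lab) == 0L) {
    return(structure(list(vertices = NULL, area_px2 = 0, n_rays = 0L, empty = TRUE),
                     class = "tip_polygon"))
  }
  stats <- group_rays(component_stats(lab, u, d))
  tips <- purrr::map_dfr(split(stats, stats$ray), function(seg) {
    sel <- which(matrix(lab %in% seg$component, nrow(lab), ncol(lab)))
    dmax <- max(d[sel])
    cand <- sel[d[sel] == dmax]
    best <- cand[which.min(u[cand])]   # deterministic tie-break along plane axis
    rc <- arrayInd(best, dim(m))
    tibble(row = rc[1], col = rc[2], u = u[best])
  })
  tips <- dplyr::arrange(tips, .data$u)
  verts <- rbind(plane$p_dorsal,
                 as.matrix(tips[, c("row", "col")]),
                 plane$p_ventral)
  structure(list(vertices = unname(verts),
                 area_px2 = shoelace_area(verts),
                 n_rays = max(stats$ray), empty = FALSE),
            class = "tip_polygon")
}

#' @export
print.tip_polygon <- function(x, ...) {
  cat("<tip_polygon> ", x$n_rays, " ray tips, area ", round(x$area_px2, 1),
      " px^2\n", sep = "")
  invisible(x)
}

#' Shoelace area of a closed polygon
#'
#' @param vertices Numeric matrix `(row, col)`; the polygon is closed
#'   implicitly.
#' @return Absolute area in squared pixel units.
#' @export
shoelace_area <- function(vertices) {
  v <- as.matrix(vertices)
  y <- v[, 1]; x <- v[, 2]
  yn <- c(y[-1], y[1]); xn <- c(x[-1], x[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Mineralized ray widths at the first intersegment joint below the plane
#'
#' RAY is the mean width of the mineralized rays at the first intersegment
#' joint proximal to the amputation plane.  Joints are the non-mineralized
#' gaps that split each ray into 8-connected mineral segments, so for each
#' ray (segments grouped by overlapping extent along the plane axis) the
#' first joint is the gap between the two segments nearest the plane, and
#' the width is the across-ray extent of the plane-adjacent segment at the
#' distal border of that gap.  A ray whose stump shows no joint within the
#' image is skipped with a warning.
#'
#' @param mineral_proximal Mineral mask on the stump side (a full-image
#'   mask is restricted to the proximal half-plane internally).
#' @param plane An [amputation_plane()].
#' @param min_px Minimum segment size in pixels (default 20).
#' @return Tibble with one row per measurable ray: `ray`, `width_px`,
#'   `u_center` (position along the plane axis).
#' @export
ray_widths_at_first_joint <- function(mineral_proximal, plane, min_px = 20L) {
  m <- as_mask_matrix(mineral_proximal, "mineral_proximal")
  d <- plane_signed_distance(plane, dim(m))
  u <- plane_axis_coord(plane, dim(m))
  lab <- label_components(m & d < 0, min_px = min_px)
  stats <- component_stats(lab, u, d)
  if (!nrow(stats)) {
    abort("no mineralized ray segments proximal to the plane",
          class = "finregen_missing_ray")
  }
  stats <- group_rays(stats)
  out <- purrr::map_dfr(split(stats, stats$ray), function(seg) {
    seg <- dplyr::arrange(seg, dplyr::desc(.data$v_hi))  # nearest plane first
    if (nrow(seg) < 2) {
      warn(paste0("ray at u ~ ", round(mean(c(seg$u_lo, seg$u_hi))),
                  ": no intersegment joint within the imaged stump; skipped"))
      return(NULL)
    }
    first <- seg[1, ]   # segment between the plane and the first joint
    sel <- lab == first$component & d <= first$v_lo + 1  # distal border of joint
    tibble(ray = first$ray,
           width_px = max(u[sel]) - min(u[sel]) + 1,
           u_center = (first$u_lo + first$u_hi) / 2)
  })
  if (is.null(out) || !nrow(out)) {
    abort("no ray presented a measurable first intersegment joint",
          class = "finregen_missing_ray")
  }
  dplyr::arrange(out, .data$u_center)
}
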