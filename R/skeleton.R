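#' Medial axis of a binary mask by Zhang-Suen thinning
#'
#' Iterative two-subpass thinning down to a 1-pixel-wide 8-connected
#' skeleton.  Written in vectorized R (no installed package provides binary
#' thinning); adequate for micrograph-sized masks.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask & !is.na(mask)
  pad <- function(x) rbind(FALSE, cbind(FALSE, x, FALSE), FALSE)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(p); nc <- ncol(p)
      ctr <- p[2:(nr - 1), 2:(nc - 1)]
      # neighbours clockwise from north (image rows increase downward)
      p2 <- p[1:(nr - 2), 2:(nc - 1)]; p3 <- p[1:(nr - 2), 3:nc]
      p4 <- p[2:(nr - 1), 3:nc];       p5 <- p[3:nr, 3:nc]
      p6 <- p[3:nr, 2:(nc - 1)];       p7 <- p[3:nr, 1:(nc - 2)]
      p8 <- p[2:(nr - 1), 1:(nc - 2)]; p9 <- p[1:(nr - 2), 1:(nc - 2)]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- ctr & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- ctr & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# count of 8-neighbours that are TRUE, per pixel
neighbour_count <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  nr <- nrow(p); nc <- ncol(p)
  p[1:(nr - 2), 2:(nc - 1)] + p[1:(nr - 2), 3:nc] + p[2:(nr - 1), 3:nc] +
    p[3:nr, 3:nc] + p[3:nr, 2:(nc - 1)] + p[3:nr, 1:(nc - 2)] +
    p[2:(nr - 1), 1:(nc - 2)] + p[1:(nr - 2), 1:(nc - 2)]
}

#' Count intersegment joints and bifurcations of a single mineralized ray
#'
#' The mask of one ray is morphologically closed with an anisotropic brush
#' that bridges the non-mineralized joint gaps along the ray axis without
#' merging the two sister branches of a bifurcation, then skeletonized.
#' Joints are counted as connected runs of at least `min_gap_px` skeleton
#' pixels lying outside the original mineral mask, and bifurcations as
#' clusters of skeleton branch points (pixels with three or more skeleton
#' neighbours).  The ray axis is assumed roughly aligned with the matrix
#' rows (the rendering convention of this package).
#'
#' @param ray_mask Logical matrix holding a single ray (possibly split into
#'   segments by joints, possibly bifurcated).
#' @param bridge_px Along-ray extent of the closing brush (default 9; must
#'   exceed the widest joint gap).
#' @param bridge_across_px Across-ray extent of the brush (default 3; must
#'   stay below the inter-branch separation).
#' @param min_gap_px Minimum skeleton run length counted as a joint
#'   (default 2, so single-pixel notches are ignored).
#' @return Named list `joints`, `bifurcations` (non-negative integers);
#'   `(0, 0)` for an empty mask.
#' @export
count_joints_bifurcations <- function(ray_mask, bridge_px = 9L,
                                      bridge_across_px = 3L, min_gap_px = 2L) {
  m <- as_mask_matrix(ray_mask, "ray_mask")
  if (!any(m)) return(list(joints = 0L, bifurcations = 0L))
  brush <- matrix(1L, as.integer(bridge_px), as.integer(bridge_across_px))
  closed <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1L), brush)) > 0
  closed <- matrix(closed, nrow(m), ncol(m))
  skel <- skeletonize(closed)
  gaps <- label_components(skel & !m, min_px = min_gap_px)
  branch <- skel & neighbour_count(skel) >= 3
  if (any(branch)) {
    # a Y-junction thinned from a wide bar can leave two triple-points a
    # few pixels apart; cluster them before counting
    blob <- EBImage::imageData(EBImage::dilate(EBImage::Image(branch * 1L),
                                               EBImage::makeBrush(7L, "box"))) > 0
    bif <- max(label_components(matrix(blob, nrow(m), ncol(m))))
  } else bif <- 0L
  list(joints = max(gaps), bifurcations = bif)
}
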