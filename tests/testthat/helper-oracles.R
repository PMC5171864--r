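# fixture builders and independent brute-force oracles used across tests

make_rgb <- function(nr, nc, r = 0, g = 0, b = 0) {
  img <- array(0L, dim = c(nr, nc, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  finregen::as_rgb255(img)
}

random_rgb <- function(nr, nc) {
  array(sample(0:255, nr * nc * 3, replace = TRUE), dim = c(nr, nc, 3))
}

# per-pixel signed-distance side assignment, straight from the definition
brute_split <- function(dim, plane) {
  p1 <- plane$p_dorsal; p2 <- plane$p_ventral
  dir <- switch(plane$distal_side,
                up = c(-1, 0), down = c(1, 0), left = c(0, -1), right = c(0, 1))
  probe <- p1 + dir
  cross <- function(r, c) (p2[2] - p1[2]) * (r - p1[1]) - (p2[1] - p1[1]) * (c - p1[2])
  sgn <- sign(cross(probe[1], probe[2]))
  distal <- matrix(FALSE, dim[1], dim[2])
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
    distal[r, c] <- sgn * cross(r, c) >= 0
  }
  distal
}

# per-pixel conjunctive band test, straight from the definition
brute_threshold <- function(img, spec, restrict = NULL) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    px <- img[r, c, ]
    out[r, c] <- px[1] >= spec$red_min && px[1] <= spec$red_max &&
      px[2] >= spec$green_min && px[2] <= spec$green_max &&
      px[3] >= spec$blue_min && px[3] <= spec$blue_max
    if (!is.null(restrict)) out[r, c] <- out[r, c] && restrict[r, c]
  }
  out
}

# even-odd point-in-polygon test, vectorized over query points
polygon_contains <- function(verts, ry, cx) {
  n <- nrow(verts)
  crossings <- integer(length(ry))
  for (k in seq_len(n)) {
    y1 <- verts[k, 1]; x1 <- verts[k, 2]
    k2 <- if (k == n) 1L else k + 1L
    y2 <- verts[k2, 1]; x2 <- verts[k2, 2]
    hit <- (y1 <= ry & y2 > ry) | (y2 <= ry & y1 > ry)
    if (any(hit)) {
      xc <- x1 + (ry[hit] - y1) / (y2 - y1) * (x2 - x1)
      crossings[hit] <- crossings[hit] + (xc > cx[hit])
    }
  }
  crossings %% 2L == 1L
}

# Monte-Carlo polygon area: unbiased, independent of the shoelace formula
mc_polygon_area <- function(verts, n_pts = 2e5) {
  ylim <- range(verts[, 1]); xlim <- range(verts[, 2])
  ry <- runif(n_pts, ylim[1], ylim[2])
  cx <- runif(n_pts, xlim[1], xlim[2])
  mean(polygon_contains(verts, ry, cx)) * diff(ylim) * diff(xlim)
}

# small fin geometry for fast rendered tests (dots override the defaults)
small_fin_spec <- function(seed, ...) {
  args <- list(n_rays = 8L, stump_width_px = 200L, regenerate_height_px = 110,
               stump_depth_px = 80L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(finregen::synthetic_fin_spec, args)
}

# hand-built proximal ray mask: horizontal plane at row r0, one vertical ray
# of given width with joint gaps at stated depths below the plane
proximal_ray_mask <- function(nr, nc, r0, col_lo, width, gap_depths, gap = 4L,
                              depth = NULL) {
  depth <- depth %||% (nr - r0 - 2L)
  m <- matrix(FALSE, nr, nc)
  for (dv in seq_len(depth)) {
    in_gap <- any(dv >= gap_depths & dv <= gap_depths + gap - 1L)
    if (!in_gap) m[r0 + dv, col_lo:(col_lo + width - 1L)] <- TRUE
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
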