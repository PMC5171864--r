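test_that("regenerate segmentation recovers the rendered tissue dome", {
  rf <- render_fin(small_fin_spec(seed = 3))
  rec <- rf$record
  halves <- split_by_plane(dim(rec$brightfield)[1:2], rec$plane)
  regen <- segment_regenerate(rec$brightfield, halves$distal)
  truth_px <- sum(rf$truth$regenerate)
  expect_lt(abs(regen$n_pixels - truth_px) / truth_px, 0.02)
})

test_that("an all-white distal half-plane raises an empty-regenerate error", {
  img <- make_rgb(30, 30, r = 255L, g = 255L, b = 255L)
  expect_error(segment_regenerate(img, matrix(TRUE, 30, 30)),
               class = "finregen_empty_regenerate")
})

test_that("a manual outline takes precedence and is rasterized exactly", {
  img <- make_rgb(30, 30, r = 255L, g = 255L, b = 255L)   # nothing segmentable
  poly <- rbind(c(5, 5), c(5, 20), c(15, 20), c(15, 5))
  regen <- segment_regenerate(img, matrix(TRUE, 30, 30), outline = poly)
  expect_identical(regen$mask, rasterize_polygon(poly, c(30, 30)))
  expect_gt(regen$n_pixels, 0)
})

test_that("polygon rasterization fills an axis-aligned rectangle", {
  poly <- rbind(c(2.5, 2.5), c(2.5, 10.5), c(8.5, 10.5), c(8.5, 2.5))
  m <- rasterize_polygon(poly, c(12, 12))
  expect_true(all(m[3:8, 3:10]))
  expect_equal(sum(m), 6 * 8)
})

test_that("a single rectangular ray yields the analytic tip triangle", {
  # horizontal plane (row 30, cols 5..25), one ray of height 10 at cols 10..15
  m <- matrix(FALSE, 40, 30)
  m[20:30, 10:15] <- TRUE
  pl <- amputation_plane(c(30, 5), c(30, 25), distal_side = "up")
  tp <- distal_tip_polygon(m, pl)
  expect_equal(tp$n_rays, 1)
  # triangle: (30,5) -> tip(20, u-min of tip row) -> (30,25)
  expect_equal(tp$area_px2, 0.5 * 20 * 10)
})

test_that("two rays of equal height spanning the plane give the rectangle area", {
  m <- matrix(FALSE, 40, 40)
  m[18:30, 5:8] <- TRUE     # tips at row 18, height 12
  m[18:30, 32:35] <- TRUE
  pl <- amputation_plane(c(30, 5), c(30, 35), distal_side = "up")
  tp <- distal_tip_polygon(m, pl)
  expect_equal(tp$n_rays, 2)
  # trapezoid between tips at u = 0 and u = 27 over a 30-px plane
  h <- 12; L <- 30; u1 <- 0; u2 <- 27
  expect_equal(tp$area_px2, h * ((u2 - u1) + L) / 2)
})

test_that("no mineral components give the empty-polygon signal (EMA = 0)", {
  pl <- amputation_plane(c(30, 5), c(30, 25), distal_side = "up")
  tp <- distal_tip_polygon(matrix(FALSE, 40, 30), pl)
  expect_true(tp$empty)
  expect_equal(tp$area_px2, 0)
})

test_that("shoelace area of random tip polygons matches the rasterization oracle", {
  set.seed(91)
  for (rep in 1:3) {
    m <- matrix(FALSE, 80, 120)
    heights <- sample(30:60, 5)
    for (k in 1:5) {
      lo <- 10 + (k - 1) * 22
      m[(70 - heights[k]):70, lo:(lo + 11)] <- TRUE
    }
    pl <- amputation_plane(c(70, 5), c(70, 115), distal_side = "up")
    tp <- distal_tip_polygon(m, pl)
    mc <- mc_polygon_area(tp$vertices)
    expect_lt(abs(tp$area_px2 - mc) / tp$area_px2, 0.01)
  }
})

test_that("ray width is read at the distal border of the first proximal joint", {
  # constant width 12, joints every 40 px starting 10 px below the plane
  m <- proximal_ray_mask(120, 80, r0 = 20, col_lo = 30, width = 12,
                         gap_depths = c(10, 50, 90))
  pl <- amputation_plane(c(20, 5), c(20, 75), distal_side = "up")
  w <- ray_widths_at_first_joint(m, pl)
  expect_equal(nrow(w), 1)
  expect_equal(w$width_px, 12)
})

test_that("a tapering ray is measured at the joint within one pixel", {
  m <- matrix(FALSE, 120, 80)
  r0 <- 20
  for (dv in 1:80) {
    w <- round(14 - dv * 0.05)            # slow taper with depth
    if (dv >= 30 && dv <= 33) next        # joint at depth 30
    lo <- 40 - floor(w / 2)
    m[r0 + dv, lo:(lo + w - 1)] <- TRUE
  }
  pl <- amputation_plane(c(20, 5), c(20, 75), distal_side = "up")
  w <- ray_widths_at_first_joint(m, pl)
  expect_equal(nrow(w), 1)
  expect_lte(abs(w$width_px - round(14 - 29 * 0.05)), 1)
})

test_that("a gapless stump raises the missing-RAY error", {
  m <- proximal_ray_mask(120, 80, r0 = 20, col_lo = 30, width = 12,
                         gap_depths = numeric(0))
  pl <- amputation_plane(c(20, 5), c(20, 75), distal_side = "up")
  expect_error(expect_warning(ray_widths_at_first_joint(m, pl)),
               class = "finregen_missing_ray")
})

test_that("RMA is bounded by REG and by EMA on rendered fins", {
  for (s in 1:3) {
    rf <- render_fin(small_fin_spec(seed = s))
    an <- analyze_fin(rf$record)
    m <- an$measurements
    expect_lte(m$rma_mm2, m$reg_mm2)
    expect_lte(m$rma_mm2, m$ema_mm2)
  }
})
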