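test_that("luma follows the BT.601 weights", {
  img <- make_rgb(1, 3)
  img[1, 1, ] <- c(0L, 0L, 0L)
  img[1, 2, ] <- c(255L, 255L, 255L)
  img[1, 3, ] <- c(255L, 0L, 0L)
  y <- rgb_to_luma(img)
  expect_equal(as.vector(y), c(0L, 255L, 76L))
})

test_that("luma of a random raster equals the per-pixel formula", {
  set.seed(2)
  img <- as_rgb255(random_rgb(20, 20))
  y <- rgb_to_luma(img)
  expected <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  expect_equal(as.vector(y), as.vector(expected))
})

test_that("histogram counts masked pixels inside the spectrum only", {
  y <- matrix(100L, 10, 10)
  m <- matrix(TRUE, 10, 10)
  h <- intensity_histogram(y, m)
  expect_equal(h$freq[h$luma == 100], 1)
  expect_equal(sum(h$freq), 1)

  y2 <- matrix(c(rep(20L, 50), rep(10L, 50)), 10, 10)
  h2 <- intensity_histogram(y2, m)
  expect_equal(attr(h2, "n_pixels_in_spectrum"), 50)   # Y = 10 below floor
  expect_equal(h2$freq[h2$luma == 20], 1)
})

test_that("random histograms equal a brute-force tally", {
  set.seed(3)
  y <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  m <- matrix(runif(400) < 0.6, 20, 20)
  h <- intensity_histogram(y, m)
  vals <- y[m]; vals <- vals[vals >= 15 & vals <= 254]
  for (lv in c(15, 40, 100, 254)) {
    expect_equal(h$count[h$luma == lv], sum(vals == lv))
  }
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
})

test_that("pixels outside the mask or spectrum never influence the histogram", {
  y <- matrix(30L, 10, 10)
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  h1 <- intensity_histogram(y, m)
  y2 <- y; y2[!m] <- 200L                      # outside mask
  y2[1, 1:3] <- 5L; y2[2, 1:3] <- 255L          # masked but out of spectrum
  m2 <- m
  h2 <- intensity_histogram(y2, m2)
  expect_equal(h1$freq[h1$luma == 30], h2$freq[h2$luma == 30], tolerance = 1e-12)
})

test_that("class frequencies sum the low and high bands", {
  y <- matrix(c(rep(20L, 50), rep(40L, 50)), 10, 10)
  cls <- class_frequencies(intensity_histogram(y, matrix(TRUE, 10, 10)))
  expect_equal(cls$low_15_29, 0.5)
  expect_equal(cls$high_30_44, 0.5)
  y2 <- matrix(200L, 10, 10)
  cls2 <- class_frequencies(intensity_histogram(y2, matrix(TRUE, 10, 10)))
  expect_equal(cls2$low_15_29, 0)
  expect_equal(cls2$high_30_44, 0)
})

test_that("a stated luma mixture is recovered within 0.02", {
  set.seed(19)
  n <- 1e4
  vals <- c(sample(15:29, round(0.60 * n), replace = TRUE),
            sample(30:44, round(0.25 * n), replace = TRUE),
            sample(45:254, round(0.15 * n), replace = TRUE))
  y <- matrix(vals[1:n], 100, 100)
  cls <- class_frequencies(intensity_histogram(y, matrix(TRUE, 100, 100)))
  expect_lt(abs(cls$low_15_29 - 0.60), 0.02)
  expect_lt(abs(cls$high_30_44 - 0.25), 0.02)
})

test_that("a +15 saturating luma shift never increases the low class", {
  set.seed(23)
  for (i in 1:10) {
    y <- matrix(sample(15:120, 400, replace = TRUE), 20, 20)
    m <- matrix(TRUE, 20, 20)
    base <- class_frequencies(intensity_histogram(y, m))
    shifted <- pmin(y + 15L, 254L)
    up <- class_frequencies(intensity_histogram(shifted, m))
    expect_lte(up$low_15_29, base$low_15_29 + 1e-12)
  }
})

test_that("an empty spectrum warns and flags the histogram", {
  y <- matrix(5L, 4, 4)
  expect_warning(h <- intensity_histogram(y, matrix(TRUE, 4, 4)))
  expect_true(attr(h, "empty"))
  expect_equal(attr(h, "n_pixels_in_spectrum"), 0)
})

test_that("differing exposures refuse to pool unless forced", {
  expect_error(check_exposure_pooling(c(200, 200, 500)),
               class = "finregen_exposure_mismatch")
  expect_true(check_exposure_pooling(c(200, 200, 500), force = TRUE))
  expect_true(check_exposure_pooling(c(200, 200, 200)))
})

test_that("dimming the luma moves mass from high to low class almost surely", {
  set.seed(31)
  hits <- 0L
  for (i in 1:40) {
    base <- pmin(pmax(round(rnorm(2000, 28, 5)), 0), 255)
    dim_ <- pmin(pmax(round(rnorm(2000, 28 * 0.7, 5)), 0), 255)
    cl_b <- class_frequencies(intensity_histogram(matrix(base, 40, 50),
                                                  matrix(TRUE, 40, 50)))
    cl_d <- class_frequencies(intensity_histogram(matrix(dim_, 40, 50),
                                                  matrix(TRUE, 40, 50)))
    hits <- hits + (cl_d$low_15_29 > cl_b$low_15_29 &&
                      cl_d$high_30_44 < cl_b$high_30_44)
  }
  expect_gte(hits / 40, 0.95)
})
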