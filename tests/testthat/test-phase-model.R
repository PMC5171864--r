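test_that("poly2 interpolates three points and flattens constant data", {
  d <- tibble::tibble(t = c(0, 1, 2), y = c(0, 1, 4))
  f <- fit_poly2(d, "t", "y")
  expect_equal(c(f$c0, f$c1, f$c2), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(f$sse, 0, tolerance = 1e-12)

  d2 <- tibble::tibble(t = 1:10, y = rep(3, 10))
  f2 <- fit_poly2(d2, "t", "y")
  expect_equal(c(f2$c1, f2$c2), c(0, 0), tolerance = 1e-10)
})

test_that("poly2 equals the normal-equations oracle on random data", {
  set.seed(6)
  t <- runif(60, 0, 240); y <- 0.3 + 0.01 * t - 2e-5 * t^2 + rnorm(60, 0, 0.05)
  f <- fit_poly2(tibble::tibble(t = t, y = y), "t", "y")
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f$c0, f$c1, f$c2), as.vector(beta), tolerance = 1e-8)
})

test_that("poly2 rejects degenerate time designs", {
  expect_error(fit_poly2(tibble::tibble(t = c(1, 1, 1), y = 1:3), "t", "y"),
               class = "finregen_singular_fit")
  expect_error(fit_poly2(tibble::tibble(t = 1:2, y = 1:2), "t", "y"))
})

test_that("segmental fit recovers a noiseless broken stick exactly", {
  x <- seq(0.1, 1.1, length.out = 30)
  y <- pmax(0, 1.2 * (x - 0.6))
  f <- fit_segmental(tibble::tibble(x = x, y = y), "x", "y")
  expect_equal(f$x0, 0.6, tolerance = 1e-3)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(f$c, 1.2, tolerance = 1e-3)
  expect_lt(f$sse, 1e-10)
  expect_true(all(f$data$phase[f$data$x <= f$x0] == "P1"))
})

test_that("single-line data flag the breakpoint as unidentifiable", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * x + 1
  expect_warning(f <- fit_segmental(tibble::tibble(x = x, y = y), "x", "y"))
  expect_false(f$x0_identifiable)
  lin_sse <- sum(residuals(lm(y ~ x))^2)
  expect_equal(f$sse, lin_sse, tolerance = 1e-8)
})

test_that("segmental SSE never exceeds the nested single-line SSE", {
  set.seed(14)
  for (i in 1:8) {
    x <- runif(25)
    y <- rnorm(25)
    f <- suppressWarnings(fit_segmental(tibble::tibble(x = x, y = y), "x", "y"))
    expect_lte(f$sse, f$sse_linear + 1e-10)
    expect_true(all(f$data$phase %in% c("P1", "P2")))
    expect_true(all(f$data$x[f$data$phase == "P1"] <= f$x0))
  }
})

test_that("profile search matches an exhaustive fine-grid oracle", {
  set.seed(25)
  for (i in 1:4) {
    coh <- simulate_cohort(cohort_spec(seed = 300 + i))
    f <- fit_segmental(coh)
    x <- coh$reg_over_stu; y <- coh$rma_over_ray
    xs <- sort(unique(x))
    feas <- vapply(xs, function(v) sum(x <= v) >= 3 && sum(x > v) >= 3, TRUE)
    grid <- seq(min(xs[feas]), max(xs[feas]), length.out = 3000)
    sse_grid <- vapply(grid, function(x0) {
      sum(stats::lm.fit(cbind(1, x, pmax(x - x0, 0)), y)$residuals^2)
    }, 0)
    expect_lte(f$sse, min(sse_grid) + 1e-8)
    expect_lt(abs(f$x0 - grid[which.min(sse_grid)]), 2 * diff(grid[1:2]) + 0.001)
  }
})

test_that("breakpoint is recovered near truth on simulated cohorts", {
  errs <- vapply(1:10, function(s) {
    abs(fit_segmental(simulate_cohort(cohort_spec(seed = 500 + s)))$x0 - 0.586)
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("the flat-P1 constraint pins the first slope at zero", {
  coh <- simulate_cohort(cohort_spec(seed = 9))
  f <- fit_segmental(coh, constrain_b0 = TRUE)
  expect_equal(f$b, 0)
  expect_gt(f$c, 0)
})

test_that("degenerate segmental inputs raise the documented errors", {
  expect_error(fit_segmental(tibble::tibble(x = 1:5, y = 1:5), "x", "y"))
  d <- tibble::tibble(x = rep(1, 10), y = rnorm(10))
  expect_error(fit_segmental(d, "x", "y"), class = "finregen_no_breakpoint")
})

test_that("standard curve uses only the screening window", {
  coh <- simulate_cohort(cohort_spec(seed = 21))
  sc <- build_standard_curve(coh)
  extra <- dplyr::bind_rows(coh, dplyr::mutate(coh[1:8, ], time_hpa = 24,
                                               rma_over_ray = 99))
  sc2 <- build_standard_curve(extra)
  expect_equal(sc2$slope, sc$slope)
  expect_equal(sc2$intercept, sc$intercept)
  expect_equal(sc2$n, sc$n)
})

test_that("collinear control points give a perfect standard curve", {
  d <- tibble::tibble(time_hpa = seq(90, 230, length.out = 12),
                      reg_over_stu = seq(0.6, 1.2, length.out = 12))
  d$rma_over_ray <- 1.1 * d$reg_over_stu - 0.5
  sc <- build_standard_curve(d)
  expect_equal(sc$r, 1, tolerance = 1e-12)
  expect_equal(sc$slope, 1.1, tolerance = 1e-10)
  expect_lt(sc$sigma, 1e-10)
})

test_that("curve slope approximates the generator's P2 slope", {
  sc <- build_standard_curve(simulate_cohort(cohort_spec(seed = 33)))
  expect_lt(abs(sc$slope - 1.2) / 1.2, 0.10)
})

test_that("a sparse window is refused", {
  d <- tibble::tibble(time_hpa = rep(100, 5), reg_over_stu = runif(5),
                      rma_over_ray = runif(5))
  expect_error(build_standard_curve(d), class = "finregen_window_sparse")
})

test_that("identical treated and control groups are called neutral", {
  set.seed(3)
  ctl <- tibble::tibble(reg_over_stu = rnorm(10, 0.7, 0.03),
                        rma_over_ray = rnorm(10, 0.13, 0.02))
  call <- classify_effect(ctl, ctl)
  expect_equal(call$regen_shift, "none")
  expect_equal(call$mineral_shift, "none")
  expect_equal(call$dx, 0)
  expect_equal(call$dy, 0)
})

test_that("classification is antisymmetric under group swap", {
  set.seed(4)
  ctl <- tibble::tibble(reg_over_stu = rnorm(12, 0.7, 0.03),
                        rma_over_ray = rnorm(12, 0.13, 0.02))
  trt <- tibble::tibble(reg_over_stu = rnorm(12, 0.5, 0.03),
                        rma_over_ray = rnorm(12, 0.2, 0.02))
  curve <- classify_effect(trt, ctl)$curve
  a <- classify_effect(trt, ctl, curve)
  b <- classify_effect(ctl, trt, curve)
  expect_equal(a$dx, -b$dx)
  expect_equal(a$dy, -b$dy)
  expect_equal(a$p_dx, b$p_dx)
  swap <- c(under = "over", over = "under", none = "none")
  expect_equal(unname(swap[a$regen_shift]), b$regen_shift)
  expect_equal(unname(swap[a$mineral_shift]), b$mineral_shift)
})

test_that("small groups are refused as underpowered", {
  d <- tibble::tibble(reg_over_stu = 1:2 / 2, rma_over_ray = 1:2 / 2)
  expect_error(classify_effect(d, d), class = "finregen_underpowered")
})

test_that("an RA-like cohort is called under-regenerated and over-mineralized", {
  curve <- build_standard_curve(simulate_cohort(cohort_spec(seed = 61)))
  ctl <- simulate_cohort(cohort_spec(n_fish = 10, time_points_hpa = 120, seed = 62))
  ra <- simulate_cohort(cohort_spec(n_fish = 10, time_points_hpa = 120, seed = 63,
                                    treatment_effects = ra_like_effects,
                                    group_label = "ra"))
  call <- classify_effect(ra, ctl, curve)
  expect_equal(call$regen_shift, "under")
  expect_equal(call$mineral_shift, "over")
})
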