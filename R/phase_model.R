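#' Reference breakpoint between the pre-mineralization and linear phases
#'
#' REG/STU value at which a 60-specimen fixed-stained reference time course
#' switched from the pre-mineralization phase (P1) to linear co-growth of
#' mineralization with regeneration (P2).  Provided as an overlay/reference
#' value for plots; every analysis estimates its own breakpoint from data.
#'
#' @format Numeric scalar, REG/STU units (mm).
#' @export
fin_reference_x0 <- 0.5860

#' Degree-2 polynomial fit of a metric over time
#'
#' Least-squares fit of `y = c0 + c1 t + c2 t^2`, the standard description
#' of the saturating time course of regeneration metrics.
#'
#' @param data Data frame.
#' @param t,y Column names (strings) of time (hours post-amputation) and
#'   the response.
#' @return A `poly2_fit` object with `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
fit_poly2 <- function(data, t = "time_hpa", y = "reg_over_stu") {
  data <- as_tibble(data)
  stopifnot(t %in% names(data), y %in% names(data))
  tt <- data[[t]]; yy <- data[[y]]
  ok <- is.finite(tt) & is.finite(yy)
  tt <- tt[ok]; yy <- yy[ok]
  if (length(tt) < 3) abort("fit_poly2 needs n >= 3")
  if (length(unique(tt)) < 3) {
    abort("singular fit: fewer than 3 distinct time values",
          class = "finregen_singular_fit")
  }
  fit <- lm(yy ~ tt + I(tt^2))
  cf <- unname(coef(fit))
  structure(list(c0 = cf[1], c1 = cf[2], c2 = cf[3],
                 sse = sum(residuals(fit)^2), n = length(tt),
                 data = tibble(t = tt, y = yy),
                 t_name = t, y_name = y),
            class = "poly2_fit")
}

#' @export
print.poly2_fit <- function(x, ...) {
  cat("<poly2_fit> y = ", signif(x$c0, 4), " + ", signif(x$c1, 4), " t + ",
      signif(x$c2, 4), " t^2   (n = ", x$n, ", SSE = ", signif(x$sse, 4), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy poly2_fit
#' @export
tidy.poly2_fit <- function(x, ...) {
  tibble(term = c("c0", "c1", "c2"), estimate = c(x$c0, x$c1, x$c2))
}

#' @method glance poly2_fit
#' @export
glance.poly2_fit <- function(x, ...) {
  tibble(sse = x$sse, n = x$n)
}

#' @export
predict.poly2_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata
  object$c0 + object$c1 * t + object$c2 * t^2
}

# continuous two-segment design at breakpoint x0; returns sse and coefs
segmental_profile <- function(x, y, x0, constrain_b0) {
  X <- if (constrain_b0) cbind(1, pmax(x - x0, 0)) else cbind(1, x, pmax(x - x0, 0))
  f <- stats::lm.fit(X, y)
  cf <- f$coefficients
  sse <- sum(f$residuals^2)
  if (constrain_b0) list(sse = sse, a = cf[1], b = 0, c = cf[2])
  else list(sse = sse, a = cf[1], b = cf[2], c = cf[2] + cf[3])
}

#' Continuous segmental (broken-stick) linear regression
#'
#' Fits the two-phase model of mineralization versus regeneration:
#' `y = a + b x` for `x <= x0` (P1) and `y = a + b x0 + c (x - x0)` for
#' `x > x0` (P2), continuous at the breakpoint.  The breakpoint is found
#' by profiling the least-squares SSE over every interior data value and
#' midpoint, followed by numerical refinement within the bracketing
#' inter-datapoint intervals, so the result matches an exhaustive fine-grid
#' search; SSE ties are broken toward the smaller `x0`.  Each segment must
#' be supported by at least 3 points.
#'
#' When the data are fit equally well by a single line the breakpoint is
#' not identifiable; the fit is returned with `x0_identifiable = FALSE`.
#'
#' @param data Data frame.
#' @param x,y Column names (strings); defaults `reg_over_stu`,
#'   `rma_over_ray`.
#' @param constrain_b0 Force the first segment's slope to zero (the
#'   pre-mineralization phase is flat); default `FALSE` (slope free).
#' @return A `segmental_fit` object: `x0`, `a`, `b`, `c`, `sse`,
#'   `sse_linear`, `n`, `x0_identifiable`, per-point `phase` labels
#'   (`"P1"`/`"P2"`); with `tidy()`, `glance()`, `predict()`, `autoplot()`.
#' @export
fit_segmental <- function(data, x = "reg_over_stu", y = "rma_over_ray",
                          constrain_b0 = FALSE) {
  data <- as_tibble(data)
  stopifnot(x %in% names(data), y %in% names(data))
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 6) abort("fit_segmental needs n >= 6")
  xs <- sort(unique(xv))
  n_le <- vapply(xs, function(v) sum(xv <= v), 0L)
  feas <- n_le >= 3 & (n - n_le) >= 3
  if (!any(feas)) {
    abort("no candidate breakpoint leaves >= 3 points on both sides",
          class = "finregen_no_breakpoint")
  }
  prof <- function(x0) segmental_profile(xv, yv, x0, constrain_b0)$sse
  # candidate values: feasible data points and midpoints
  cand <- xs[feas]
  mids <- (head(xs, -1) + tail(xs, -1)) / 2
  mids <- mids[feas[-length(xs)]]
  cand <- sort(unique(c(cand, mids)))
  sse_cand <- vapply(cand, prof, 0)
  best <- list(x0 = cand[which.min(sse_cand)], sse = min(sse_cand))
  # refine inside every feasible inter-datapoint interval
  for (i in which(feas[-length(xs)])) {
    if (xs[i + 1] - xs[i] < 1e-12) next
    op <- optimize(prof, c(xs[i], xs[i + 1]), tol = 1e-9)
    if (op$objective < best$sse - 1e-12) best <- list(x0 = op$minimum, sse = op$objective)
    else if (op$objective <= best$sse + 1e-12 * (1 + best$sse) && op$minimum < best$x0) {
      best <- list(x0 = op$minimum, sse = op$objective)
    }
  }
  # ties toward the smaller breakpoint
  tol <- 1e-10 * (1 + best$sse)
  tie <- cand[sse_cand <= best$sse + tol]
  if (length(tie) && min(tie) < best$x0) best$x0 <- min(tie)
  fit <- segmental_profile(xv, yv, best$x0, constrain_b0)
  lin <- lm(yv ~ xv)
  sse_lin <- sum(residuals(lin)^2)
  identifiable <- fit$sse < sse_lin - 1e-10 * (1 + sse_lin) && abs(fit$b - fit$c) > 1e-8
  if (!identifiable) {
    warn("breakpoint not identifiable: data are fit as well by a single line")
  }
  phase <- ifelse(xv <= best$x0, "P1", "P2")
  structure(list(x0 = unname(best$x0), a = unname(fit$a), b = unname(fit$b),
                 c = unname(fit$c), sse = fit$sse, sse_linear = sse_lin,
                 n = n, x0_identifiable = identifiable,
                 constrain_b0 = constrain_b0,
                 data = tibble(x = xv, y = yv, phase = phase),
                 x_name = x, y_name = y),
            class = "segmental_fit")
}

#' @export
print.segmental_fit <- function(x, ...) {
  cat("<segmental_fit> x0 = ", signif(x$x0, 4),
      if (!x$x0_identifiable) " (not identifiable)" else "",
      ", P1 slope b = ", signif(x$b, 4), ", P2 slope c = ", signif(x$c, 4),
      "\n  n = ", x$n, " (P1: ", sum(x$data$phase == "P1"), ", P2: ",
      sum(x$data$phase == "P2"), "), SSE = ", signif(x$sse, 4),
      " (single line: ", signif(x$sse_linear, 4), ")\n", sep = "")
  invisible(x)
}

#' @method tidy segmental_fit
#' @export
tidy.segmental_fit <- function(x, ...) {
  tibble(term = c("x0", "a", "b", "c"),
         estimate = c(x$x0, x$a, x$b, x$c))
}

#' @method glance segmental_fit
#' @export
glance.segmental_fit <- function(x, ...) {
  tibble(x0 = x$x0, sse = x$sse, sse_linear = x$sse_linear, n = x$n,
         x0_identifiable = x$x0_identifiable)
}

#' @export
predict.segmental_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x else newdata
  object$a + object$b * pmin(xv, object$x0) + object$c * pmax(xv - object$x0, 0)
}

#' @method augment segmental_fit
#' @export
augment.segmental_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = predict(x), .resid = .data$y - .data$.fitted)
}

#' Standard curve of mineralization versus regeneration in the linear phase
#'
#' Ordinary least squares of RMA/RAY on REG/STU restricted to the
#' screening window (84--240 hours post-amputation by default, the span of
#' the linear co-growth phase P2).  Treated groups are later compared to
#' this curve: displacement along it reflects a regenerative effect,
#' displacement off it a mineralogenic effect.  95% prediction-band
#' parameters are stored for single-specimen flagging.
#'
#' @param data Data frame of control specimens with time and corrected
#'   metrics.
#' @param x,y,time Column names; defaults `reg_over_stu`, `rma_over_ray`,
#'   `time_hpa`.
#' @param window Inclusive time window in hpa (default `c(84, 240)`).
#' @return A `standard_curve` object with `tidy()`, `glance()`,
#'   `predict()` and `autoplot()` methods.
#' @export
build_standard_curve <- function(data, x = "reg_over_stu", y = "rma_over_ray",
                                 time = "time_hpa", window = c(84, 240)) {
  data <- as_tibble(data)
  stopifnot(x %in% names(data), y %in% names(data), time %in% names(data))
  keep <- is.finite(data[[time]]) & data[[time]] >= window[1] & data[[time]] <= window[2]
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 10) {
    abort(paste0("only ", n, " control points inside the ", window[1], "-",
                 window[2], " hpa window (>= 10 required)"),
          class = "finregen_window_sparse")
  }
  fit <- lm(yv ~ xv)
  res <- residuals(fit)
  sigma <- if (n > 2) sqrt(sum(res^2) / (n - 2)) else 0
  r <- if (sd(xv) > 0 && sd(yv) > 0) cor(xv, yv) else NA_real_
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = r, n = n, window = window, sigma = sigma,
                 x_mean = mean(xv), sxx = sum((xv - mean(xv))^2),
                 data = tibble(x = xv, y = yv),
                 x_name = x, y_name = y),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> y = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " x, r = ", signif(x$r, 4), ", n = ", x$n,
      ", window ", x$window[1], "-", x$window[2], " hpa\n", sep = "")
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r^2, n = x$n, sigma = x$sigma,
         window_min = x$window[1], window_max = x$window[2])
}

#' @export
predict.standard_curve <- function(object, newdata = NULL, interval = c("none", "prediction"),
                                   level = 0.95, ...) {
  interval <- match.arg(interval)
  xv <- if (is.null(newdata)) object$data$x else newdata
  fit <- object$intercept + object$slope * xv
  if (interval == "none") return(fit)
  tq <- qt(1 - (1 - level) / 2, df = object$n - 2)
  half <- tq * object$sigma * sqrt(1 + 1 / object$n + (xv - object$x_mean)^2 / object$sxx)
  tibble(fit = fit, lwr = fit - half, upr = fit + half)
}

#' Classify a treated group against the control standard curve
#'
#' Decomposes the displacement of a treated group relative to controls
#' measured at the same nominal time into a shift along the regeneration
#' axis (`dx`, difference in mean REG/STU: a regenerative effect) and a
#' shift off the standard curve (`dy`, difference in mean residual from
#' the curve: a mineralogenic effect).  Each shift is called `under`/
#' `over` only when the corresponding unpaired t test is significant at
#' `alpha`; otherwise `none`.
#'
#' @param treated,control Data frames of corrected metrics (columns
#'   `reg_over_stu`, `rma_over_ray`), n >= 3 each.
#' @param curve A [build_standard_curve()] result; when `NULL`, an
#'   ordinary least-squares line is fitted to the control points supplied
#'   here.
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch t tests (default `FALSE`, pooled variance).
#' @return An `effect_call` object: `regen_shift`, `mineral_shift`
#'   (factors `under`/`none`/`over`), `dx`, `dy`, `p_dx`, `p_dy`; with
#'   `tidy()` and `autoplot()` methods.
#' @export
classify_effect <- function(treated, control, curve = NULL, alpha = 0.05,
                            welch = FALSE) {
  treated <- as_tibble(treated); control <- as_tibble(control)
  for (df in list(treated, control)) {
    stopifnot(all(c("reg_over_stu", "rma_over_ray") %in% names(df)))
  }
  if (nrow(treated) < 3 || nrow(control) < 3) {
    abort("classify_effect needs n >= 3 per group",
          class = "finregen_underpowered")
  }
  if (is.null(curve)) {
    fit <- lm(rma_over_ray ~ reg_over_stu, data = control)
    curve <- structure(list(slope = unname(coef(fit)[2]),
                            intercept = unname(coef(fit)[1]),
                            r = cor(control$reg_over_stu, control$rma_over_ray),
                            n = nrow(control), window = c(NA_real_, NA_real_),
                            sigma = sqrt(sum(residuals(fit)^2) / max(1, nrow(control) - 2)),
                            x_mean = mean(control$reg_over_stu),
                            sxx = sum((control$reg_over_stu - mean(control$reg_over_stu))^2),
                            data = tibble(x = control$reg_over_stu,
                                          y = control$rma_over_ray),
                            x_name = "reg_over_stu", y_name = "rma_over_ray"),
                       class = "standard_curve")
  }
  res_t <- treated$rma_over_ray - predict(curve, treated$reg_over_stu)
  res_c <- control$rma_over_ray - predict(curve, control$reg_over_stu)
  t_dx <- t_test_unpaired(treated$reg_over_stu, control$reg_over_stu, welch = welch)
  t_dy <- t_test_unpaired(res_t, res_c, welch = welch)
  shift <- function(d, p) {
    if (p < alpha) (if (d > 0) "over" else "under") else "none"
  }
  structure(list(regen_shift = shift(t_dx$mean_diff, t_dx$p_value),
                 mineral_shift = shift(t_dy$mean_diff, t_dy$p_value),
                 dx = t_dx$mean_diff, dy = t_dy$mean_diff,
                 p_dx = t_dx$p_value, p_dy = t_dy$p_value,
                 alpha = alpha, curve = curve,
                 treated = treated, control = control),
            class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat("<effect_call> regeneration: ", x$regen_shift,
      " (dx = ", signif(x$dx, 3), ", p = ", signif(x$p_dx, 3), ")",
      "\n              mineralization: ", x$mineral_shift,
      " (dy = ", signif(x$dy, 3), ", p = ", signif(x$p_dy, 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy effect_call
#' @export
tidy.effect_call <- function(x, ...) {
  tibble(axis = c("regeneration", "mineralization"),
         shift = c(x$regen_shift, x$mineral_shift),
         estimate = c(x$dx, x$dy),
         p_value = c(x$p_dx, x$p_dy))
}
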