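#' @method autoplot poly2_fit
#' @export
autoplot.poly2_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t), length.out = 200))
  grid$y <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = object$t_name, y = object$y_name,
                  title = "Degree-2 polynomial time course") +
    ggplot2::theme_minimal()
}

#' @method autoplot segmental_fit
#' @export
autoplot.segmental_fit <- function(object, reference_x0 = NULL, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x), length.out = 200))
  grid$y <- predict(object, grid$x)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), alpha = 0.8) +
    ggplot2::geom_line(data = grid, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$x0, linetype = "dashed") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  colour = "phase",
                  title = sprintf("Segmental fit, x0 = %.3f", object$x0)) +
    ggplot2::theme_minimal()
  if (!is.null(reference_x0)) {
    p <- p + ggplot2::geom_vline(xintercept = reference_x0,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x), length.out = 100))
  band <- predict(object, grid$x, interval = "prediction")
  grid <- dplyr::bind_cols(grid, band)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = grid, inherit.aes = FALSE,
                         ggplot2::aes(x = .data$x, ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey85") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$fit), colour = "firebrick") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  title = sprintf("Standard curve (%g-%g hpa), r = %.3f",
                                  object$window[1], object$window[2], object$r)) +
    ggplot2::theme_minimal()
}

#' @method autoplot intensity_histogram
#' @export
autoplot.intensity_histogram <- function(object, low = c(15, 29), high = c(30, 44), ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$luma, y = .data$freq)) +
    ggplot2::annotate("rect", xmin = low[1], xmax = low[2], ymin = -Inf, ymax = Inf,
                      fill = "grey88") +
    ggplot2::annotate("rect", xmin = high[1], xmax = high[2], ymin = -Inf, ymax = Inf,
                      fill = "grey94") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pixel intensity (luma)", y = "relative frequency",
                  title = "Mineral staining intensity spectrum") +
    ggplot2::theme_minimal()
}

#' @method autoplot effect_call
#' @export
autoplot.effect_call <- function(object, ...) {
  curve <- object$curve
  both <- dplyr::bind_rows(
    dplyr::mutate(object$control, group = "control"),
    dplyr::mutate(object$treated, group = "treated"))
  xr <- range(both$reg_over_stu)
  grid <- tibble(x = seq(xr[1], xr[2], length.out = 100))
  grid$y <- predict(curve, grid$x)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$reg_over_stu, y = .data$rma_over_ray,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = grid, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "REG/STU (mm)", y = "RMA/RAY (mm)",
                  title = sprintf("regeneration: %s (p = %.3g); mineralization: %s (p = %.3g)",
                                  object$regen_shift, object$p_dx,
                                  object$mineral_shift, object$p_dy)) +
    ggplot2::theme_minimal()
}
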