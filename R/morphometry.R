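#' One specimen at one time point
#'
#' Bundles the paired micrographs, the amputation-plane annotation, the
#' spatial calibration and the specimen metadata used throughout the
#' pipeline.
#'
#' @param specimen_id Specimen identifier (text).
#' @param time_hpa Hours post-amputation (non-negative).
#' @param brightfield,fluorescence 8-bit RGB arrays of identical dimension.
#' @param plane An [amputation_plane()].
#' @param mm_per_px Spatial calibration, mm per pixel (> 0); see
#'   [calibrate_mm_per_px()].
#' @param wei_mg Optional total fish weight in mg.
#' @param len_mm Optional snout-to-amputation-plane length in mm.
#' @param group_label Treatment group (default `"control"`).
#' @param exposure_ms Optional fluorescence exposure time in ms (typically
#'   200 for fixed specimens, 500 for live ones); used to refuse pooling of
#'   non-comparable intensity data.
#' @param manual_outline Optional manual regenerate outline, a matrix of
#'   `(row, col)` polygon vertices; takes precedence over automatic
#'   segmentation.
#' @param manual_ray_widths_px Optional numeric vector of manually measured
#'   ray widths (pixels) at the first proximal joint; takes precedence over
#'   automatic width extraction.
#' @return A `fin_record` object.
#' @export
fin_record <- function(specimen_id, time_hpa, brightfield, fluorescence, plane,
                       mm_per_px, wei_mg = NA_real_, len_mm = NA_real_,
                       group_label = "control", exposure_ms = NA_real_,
                       manual_outline = NULL, manual_ray_widths_px = NULL) {
  brightfield <- as_rgb255(brightfield)
  fluorescence <- as_rgb255(fluorescence)
  if (!identical(dim(brightfield), dim(fluorescence))) {
    abort("brightfield and fluorescence rasters must share dimensions")
  }
  stopifnot(inherits(plane, "amputation_plane"))
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) abort("mm_per_px must be > 0")
  if (time_hpa < 0) abort("time_hpa must be non-negative")
  structure(list(specimen_id = as.character(specimen_id), time_hpa = time_hpa,
                 brightfield = brightfield, fluorescence = fluorescence,
                 plane = plane, mm_per_px = mm_per_px, wei_mg = wei_mg,
                 len_mm = len_mm, group_label = group_label,
                 exposure_ms = exposure_ms, manual_outline = manual_outline,
                 manual_ray_widths_px = manual_ray_widths_px),
            class = "fin_record")
}

#' @export
print.fin_record <- function(x, ...) {
  cat("<fin_record> ", x$specimen_id, " @ ", x$time_hpa, " hpa (",
      x$group_label, "), ", nrow(x$brightfield), "x", ncol(x$brightfield),
      " px, ", x$mm_per_px, " mm/px\n", sep = "")
  invisible(x)
}

#' Histomorphometric quantities from masks and annotation
#'
#' Converts pixel-level measurements into the calibrated quantities:
#' REG (regenerate area, mm^2), RMA (real mineralized area, mm^2), EMA
#' (estimated mineralized area from the tip polygon, mm^2), STU (stump
#' width = Euclidean distance between the plane endpoints, mm) and RAY
#' (mean ray width at the first proximal joint, mm).
#'
#' @param record A [fin_record()] (supplies calibration, plane, metadata).
#' @param regenerate [region_mask()] of the regenerate.
#' @param mineral_distal `mineral_mask` of alizarin-red pixels within the
#'   regenerate.
#' @param ema_polygon `tip_polygon` from [distal_tip_polygon()], or `NULL`
#'   (EMA reported as 0 when no mineral is present).
#' @param ray_widths Tibble from [ray_widths_at_first_joint()], a bare
#'   numeric vector of widths in px, or `NULL` when no ray was measurable
#'   (RAY reported as `NA`).
#' @return One-row tibble: `specimen_id`, `time_hpa`, `group_label`,
#'   `reg_mm2`, `ema_mm2`, `rma_mm2`, `ray_mm`, `stu_mm`, `wei_mg`,
#'   `len_mm`.
#' @export
measure_fin <- function(record, regenerate, mineral_distal, ema_polygon = NULL,
                        ray_widths = NULL) {
  stopifnot(inherits(record, "fin_record"))
  s <- record$mm_per_px
  if (!is.numeric(s) || !is.finite(s) || s <= 0) {
    abort("missing or invalid calibration (mm_per_px)", class = "finregen_missing_calibration")
  }
  reg_px <- if (inherits(regenerate, "region_mask")) regenerate$n_pixels else sum(as_mask_matrix(regenerate))
  rma_px <- if (inherits(mineral_distal, "mineral_mask")) mineral_distal$n_pixels else sum(as_mask_matrix(mineral_distal))
  ema_px2 <- if (is.null(ema_polygon)) 0 else ema_polygon$area_px2
  widths <- if (is.null(ray_widths)) numeric(0)
            else if (is.data.frame(ray_widths)) ray_widths$width_px
            else as.numeric(ray_widths)
  tibble(specimen_id = record$specimen_id,
         time_hpa = record$time_hpa,
         group_label = record$group_label,
         reg_mm2 = reg_px * s^2,
         ema_mm2 = ema_px2 * s^2,
         rma_mm2 = rma_px * s^2,
         ray_mm = if (length(widths)) mean(widths) * s else NA_real_,
         stu_mm = plane_length_px(record$plane) * s,
         wei_mg = record$wei_mg,
         len_mm = record$len_mm)
}

#' Inter-specimen correction factors
#'
#' Adds the corrected metrics to a morphometrics table: `reg_over_stu`
#' (REG/STU, mm) as the standard measure of overall regeneration,
#' `rma_over_ray` (RMA/RAY, mm) as the measure of mineral deposition, and
#' `mineral_fraction` ((RMA/RAY)/(REG/STU), dimensionless) as the
#' mineralogenic performance within the regenerate.  When weight or length
#' metadata are present, the alternate corrections `reg_over_wei` and
#' `reg_over_len` are added for comparison; REG/STU remains the standard.
#'
#' A specimen with `rma_mm2 = 0` is in the pre-mineralization phase:
#' `rma_over_ray` and `mineral_fraction` are 0 regardless of RAY.
#'
#' @param data Data frame with at least `reg_mm2`, `stu_mm`, `rma_mm2`,
#'   `ray_mm` (optionally `wei_mg`, `len_mm`).
#' @return The input as a tibble with correction columns appended.
#' @export
correct_metrics <- function(data) {
  data <- as_tibble(data)
  req <- c("reg_mm2", "stu_mm", "rma_mm2", "ray_mm")
  if (!all(req %in% names(data))) {
    abort(paste0("correct_metrics needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(!is.finite(data$stu_mm) | data$stu_mm <= 0)) {
    abort("STU must be positive for every specimen", class = "finregen_invalid_specimen")
  }
  bad_ray <- data$rma_mm2 > 0 & (!is.finite(data$ray_mm) | data$ray_mm <= 0)
  if (any(bad_ray)) {
    abort("RAY missing for specimens with non-zero RMA; cannot correct",
          class = "finregen_missing_correction")
  }
  out <- dplyr::mutate(
    data,
    reg_over_stu = .data$reg_mm2 / .data$stu_mm,
    rma_over_ray = dplyr::if_else(.data$rma_mm2 > 0, .data$rma_mm2 / .data$ray_mm, 0),
    mineral_fraction = dplyr::if_else(.data$reg_over_stu > 0,
                                      .data$rma_over_ray / .data$reg_over_stu, 0)
  )
  if ("wei_mg" %in% names(out)) out$reg_over_wei <- out$reg_mm2 / out$wei_mg
  if ("len_mm" %in% names(out)) out$reg_over_len <- out$reg_mm2 / out$len_mm
  out
}
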