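#' Analyse one fin record end to end
#'
#' Runs the full per-specimen chain: half-plane split, regenerate
#' segmentation (manual outline wins when present), colour-threshold
#' tuning (a supplied `threshold` wins over [autotune_red_min()]), RMA
#' within REG, EMA tip polygon, ray widths at the first proximal joint
#' (manual widths win), calibrated morphometrics, and the
#' staining-intensity histogram and classes.
#'
#' @param record A [fin_record()].
#' @param threshold Optional manual [threshold_spec()].
#' @return List: `measurements` (one-row tibble joining morphometrics and
#'   intensity classes), `histogram`, `masks` (regenerate, mineral,
#'   distal/proximal regions), `threshold` (the spec actually applied).
#' @export
analyze_fin <- function(record, threshold = NULL) {
  stopifnot(inherits(record, "fin_record"))
  halves <- split_by_plane(dim(record$brightfield)[1:2], record$plane)
  regen <- segment_regenerate(record$brightfield, halves$distal,
                              outline = record$manual_outline)
  spec <- threshold %||% autotune_red_min(record$fluorescence, halves$distal)
  mineral_distal <- apply_rgb_threshold(record$fluorescence, spec,
                                        restrict_to = regen)
  mineral_all <- apply_rgb_threshold(record$fluorescence, spec)
  ema <- if (mineral_distal$n_pixels > 0) {
    distal_tip_polygon(mineral_distal, record$plane)
  } else NULL
  widths <- if (!is.null(record$manual_ray_widths_px)) {
    tibble(ray = seq_along(record$manual_ray_widths_px),
           width_px = record$manual_ray_widths_px,
           u_center = NA_real_)
  } else {
    tryCatch(
      ray_widths_at_first_joint(region_mask(mineral_all$mask & halves$proximal$mask),
                                record$plane),
      finregen_missing_ray = function(e) NULL)
  }
  morpho <- measure_fin(record, regen, mineral_distal, ema, widths)
  luma <- rgb_to_luma(record$fluorescence)
  hist <- suppressWarnings(
    intensity_histogram(luma, mineral_distal, source_id = record$specimen_id))
  classes <- class_frequencies(hist)
  list(measurements = dplyr::bind_cols(morpho, classes,
                                       tibble(exposure_ms = record$exposure_ms,
                                              red_min_used = spec$red_min)),
       histogram = hist,
       masks = list(regenerate = regen, mineral_distal = mineral_distal,
                    distal = halves$distal, proximal = halves$proximal),
       threshold = spec)
}

#' Read a batch manifest
#'
#' One row per record.  Required columns: `specimen_id`, `group_label`,
#' `time_hpa`, `brightfield`, `fluorescence` (image paths, absolute or
#' relative to the manifest), `plane_r1`, `plane_c1`, `plane_r2`,
#' `plane_c2`, `distal_side`, `mm_per_px`.  Optional: `exposure_ms`,
#' `wei_mg`, `len_mm`.
#'
#' @param path Manifest CSV path.
#' @return Tibble with an attribute `dir` (the manifest's directory, used
#'   to resolve relative image paths).
#' @export
read_manifest <- function(path) {
  req <- c("specimen_id", "group_label", "time_hpa", "brightfield",
           "fluorescence", "plane_r1", "plane_c1", "plane_r2", "plane_c2",
           "distal_side", "mm_per_px")
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(req, names(m))
  if (length(missing)) {
    abort(paste0("manifest lacks columns: ", paste(missing, collapse = ", ")),
          class = "finregen_config_error")
  }
  if (!nrow(m)) abort("empty manifest", class = "finregen_config_error")
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

load_record <- function(row, dir) {
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  fin_record(
    specimen_id = row$specimen_id, time_hpa = row$time_hpa,
    brightfield = read_fin_image(resolve(row$brightfield)),
    fluorescence = read_fin_image(resolve(row$fluorescence)),
    plane = amputation_plane(c(row$plane_r1, row$plane_c1),
                             c(row$plane_r2, row$plane_c2),
                             distal_side = row$distal_side),
    mm_per_px = row$mm_per_px,
    wei_mg = row$wei_mg %||% NA_real_,
    len_mm = row$len_mm %||% NA_real_,
    group_label = row$group_label,
    exposure_ms = row$exposure_ms %||% NA_real_)
}

#' Run the batch analysis pipeline
#'
#' Measures every manifest record, derives corrected metrics, builds the
#' control standard curve inside the screening window, classifies each
#' treated group against it at the shared time points, and compares
#' intensity classes.  Records that fail to load or measure become entries
#' in the `errors` table and the run continues; an empty run is fatal.
#' The result is deterministic for a fixed manifest and configuration.
#'
#' @param manifest Path to a manifest CSV (see [read_manifest()]) or an
#'   already-read manifest tibble.
#' @param control Control group label (default `"control"`).
#' @param window Screening window in hpa (default `c(84, 240)`); records
#'   beyond the upper bound are excluded from model fits with a warning
#'   (the late mineralization-only phase is never fitted).
#' @param threshold Optional manual [threshold_spec()] applied to every
#'   record.
#' @param alpha Significance level (default 0.05).
#' @param force_pool_exposures Pool intensity data across differing
#'   exposure times (default `FALSE`).
#' @param out_dir Optional directory; when given, `morphometrics.csv`,
#'   `effect_calls.csv`, `intensity_comparison.csv`, `model_summary.csv`
#'   and `run_log.txt` are written there.
#' @return List: `measurements` (tibble with corrected metrics and
#'   intensity classes), `curve` (standard curve or NULL), `effects`
#'   (tibble of per-group effect calls), `intensity` (class-comparison
#'   tibble), `errors` (tibble), `log` (character).
#' @export
run_pipeline <- function(manifest, control = "control", window = c(84, 240),
                         threshold = NULL, alpha = 0.05,
                         force_pool_exposures = FALSE, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  log <- c(paste0("finregen pipeline, ", nrow(manifest), " records"),
           paste0("window: ", window[1], "-", window[2], " hpa; alpha = ", alpha),
           paste0("threshold: ", if (is.null(threshold)) "auto (Otsu in 20-60)"
                  else paste0("manual red_min = ", threshold$red_min)))
  rows <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- as.list(manifest[i, ])
    res <- tryCatch({
      rec <- load_record(row, dir)
      an <- analyze_fin(rec, threshold = threshold)
      log <- c(log, paste0(row$specimen_id, ": red_min = ",
                           an$threshold$red_min))
      an$measurements
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1]] <- tibble(specimen_id = as.character(row$specimen_id),
                                         error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) abort("no record could be analysed", class = "finregen_config_error")
  meas <- correct_metrics(dplyr::bind_rows(rows))
  late <- meas$time_hpa > window[2]
  if (any(late)) {
    warn(paste0(sum(late), " record(s) beyond ", window[2],
                " hpa excluded from model fits"))
  }
  model_data <- meas[!late, ]
  ctl <- model_data[model_data$group_label == control, ]
  curve <- tryCatch(build_standard_curve(ctl, window = window),
                    error = function(e) { log <<- c(log, paste0("standard curve: ", conditionMessage(e))); NULL })
  groups <- setdiff(unique(model_data$group_label), control)
  effects <- purrr::map_dfr(groups, function(g) {
    trt <- model_data[model_data$group_label == g, ]
    shared_t <- intersect(unique(trt$time_hpa), unique(ctl$time_hpa))
    shared_t <- shared_t[shared_t >= window[1] & shared_t <= window[2]]
    if (!length(shared_t)) return(NULL)
    tryCatch({
      check_exposure_pooling(c(trt$exposure_ms, ctl$exposure_ms),
                             force = force_pool_exposures)
      call <- classify_effect(trt[trt$time_hpa %in% shared_t, ],
                              ctl[ctl$time_hpa %in% shared_t, ],
                              curve = curve, alpha = alpha)
      dplyr::bind_cols(tibble(group = g), tidy(call) |>
                         tidyr::pivot_wider(names_from = "axis",
                                            values_from = c("shift", "estimate", "p_value")))
    }, error = function(e) {
      errs[[length(errs) + 1]] <<- tibble(specimen_id = paste0("group:", g),
                                          error = conditionMessage(e))
      NULL
    })
  })
  intensity <- tryCatch({
    check_exposure_pooling(meas$exposure_ms, force = force_pool_exposures)
    compare_intensity_classes(model_data, control = control, alpha = alpha)
  }, error = function(e) { log <<- c(log, paste0("intensity: ", conditionMessage(e))); NULL })
  errors <- if (length(errs)) dplyr::bind_rows(errs) else tibble(specimen_id = character(), error = character())
  out <- list(measurements = meas, curve = curve, effects = effects,
              intensity = intensity, errors = errors, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$measurements, file.path(out_dir, "morphometrics.csv"), row.names = FALSE)
  if (!is.null(out$effects) && nrow(out$effects)) {
    write.csv(out$effects, file.path(out_dir, "effect_calls.csv"), row.names = FALSE)
  }
  if (!is.null(out$intensity) && nrow(out$intensity)) {
    write.csv(out$intensity, file.path(out_dir, "intensity_comparison.csv"), row.names = FALSE)
  }
  if (!is.null(out$curve)) {
    write.csv(glance(out$curve) |>
                dplyr::mutate(slope = out$curve$slope, intercept = out$curve$intercept),
              file.path(out_dir, "model_summary.csv"), row.names = FALSE)
  }
  if (nrow(out$errors)) {
    write.csv(out$errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  }
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
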