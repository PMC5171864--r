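#' @section Reproducibility:
#' All generator randomness flows from a single integer seed through a
#' counter-based substream per record, so cohorts are reproducible
#' record-by-record and the caller's RNG state is never disturbed.
#' @name synthfin-reproducibility
#' @keywords internal
NULL

# run code under a derived seed, restoring the caller's RNG state
with_substream <- function(seed, counter, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 7919L * as.integer(counter)) %% 2147483629L)
  force(code)
}

#' Parameters of a synthetic fin image pair
#'
#' Describes the geometry and signal of one rendered specimen: a fan of
#' quasi-parallel bony rays with intersegment joints and optional
#' bifurcations, red-fluorescent mineral over a dark background, and a
#' bright-field view of the regenerate tissue dome over the stump.  The
#' defaults emulate a fin at roughly mm scale imaged at 0.005 mm/px
#' (16 rays across a 2 mm stump, 12 px ~ 60 um ray width, segments every
#' 40 px ~ 200 um).
#'
#' @param n_rays Number of rays across the stump (default 16).
#' @param ray_width_px Mean ray width in px (default 12).
#' @param ray_width_cv Coefficient of variation of ray width (default 0.1).
#' @param segment_length_px Distance between intersegment joints (default 40).
#' @param joint_gap_px Width of the non-mineralized joint gap (default 4).
#' @param bifurcation_fraction Fraction of rays that bifurcate distally
#'   (default 0.5).
#' @param regenerate_height_px Maximal outgrowth extent above the
#'   amputation plane (default 160).
#' @param mineral_height_fraction Fraction of the local regenerate height
#'   that is mineralized, per ray (default 0.7).
#' @param mineral_height_cv Per-ray CV of the mineral height (default 0.08).
#' @param luma_mean,luma_sd Mean and SD of the mineral signal's luma; the
#'   red channel is rendered so that pixel luma matches this distribution
#'   (defaults 28 and 5, centred on the low/high intensity classes).
#' @param background_noise_sd Gaussian noise SD added to every channel
#'   (default 3).
#' @param stump_width_px Width of the amputation plane in px (default 400).
#' @param stump_depth_px Imaged stump depth below the plane (default 100).
#' @param mm_per_px Spatial calibration (default 0.005).
#' @param seed Integer seed (default 1).
#' @param canvas_px Optional `c(rows, cols)` canvas override; an error is
#'   raised if the fin does not fit.
#' @return A `synthetic_fin_spec` object (validated list).
#' @export
synthetic_fin_spec <- function(n_rays = 16L, ray_width_px = 12, ray_width_cv = 0.1,
                               segment_length_px = 40, joint_gap_px = 4,
                               bifurcation_fraction = 0.5,
                               regenerate_height_px = 160,
                               mineral_height_fraction = 0.7,
                               mineral_height_cv = 0.08,
                               luma_mean = 28, luma_sd = 5,
                               background_noise_sd = 3,
                               stump_width_px = 400, stump_depth_px = 100,
                               mm_per_px = 0.005, seed = 1L,
                               canvas_px = NULL) {
  spec <- list(n_rays = as.integer(n_rays), ray_width_px = ray_width_px,
               ray_width_cv = ray_width_cv, segment_length_px = segment_length_px,
               joint_gap_px = joint_gap_px,
               bifurcation_fraction = bifurcation_fraction,
               regenerate_height_px = regenerate_height_px,
               mineral_height_fraction = mineral_height_fraction,
               mineral_height_cv = mineral_height_cv,
               luma_mean = luma_mean, luma_sd = luma_sd,
               background_noise_sd = background_noise_sd,
               stump_width_px = as.integer(stump_width_px),
               stump_depth_px = as.integer(stump_depth_px),
               mm_per_px = mm_per_px, seed = as.integer(seed),
               canvas_px = canvas_px)
  with(spec, {
    stopifnot(n_rays >= 1, ray_width_px >= 3, segment_length_px > joint_gap_px,
              joint_gap_px >= 1, stump_width_px >= n_rays * 6,
              stump_depth_px > segment_length_px + joint_gap_px + 10,
              regenerate_height_px >= 20, mm_per_px > 0)
    if (bifurcation_fraction < 0 || bifurcation_fraction > 1 ||
        mineral_height_fraction < 0 || mineral_height_fraction > 1) {
      abort("fractions must lie in [0, 1]", class = "finregen_spec_error")
    }
  })
  structure(spec, class = "synthetic_fin_spec")
}

#' Render a synthetic fin image pair with full ground truth
#'
#' Deterministic for a fixed spec (same seed gives bit-identical images).
#' The bright-field image shows the regenerate tissue dome and stump on a
#' light background; the fluorescence image shows red mineral (high R, G
#' and B near 0) over black, split into segments by intersegment joints
#' both distal and proximal to the plane.  Ground truth is recorded from
#' the noise-free masks, so measuring the ground-truth masks directly
#' reproduces the recorded morphometrics exactly.
#'
#' @param spec A [synthetic_fin_spec()].
#' @param specimen_id,time_hpa,group_label Metadata for the returned
#'   record.
#' @return List with `record` (a [fin_record()]) and `truth`: noise-free
#'   masks (`regenerate`, `mineral`, `mineral_distal`, `mineral_proximal`),
#'   a one-row `morphometrics` tibble, per-ray `ray_widths_px`, tip
#'   coordinates, per-ray distal joint and bifurcation counts, and the
#'   luma parameters.
#' @export
render_fin <- function(spec, specimen_id = "synth", time_hpa = 120,
                       group_label = "control") {
  stopifnot(inherits(spec, "synthetic_fin_spec"))
  margin <- 20L
  r0 <- 12L + as.integer(ceiling(spec$regenerate_height_px))
  H <- r0 + spec$stump_depth_px + 8L
  W <- spec$stump_width_px + 2L * margin
  if (!is.null(spec$canvas_px)) {
    if (spec$canvas_px[1] < H || spec$canvas_px[2] < W) {
      abort("fin geometry does not fit the requested canvas",
            class = "finregen_spec_error")
    }
    H <- as.integer(spec$canvas_px[1]); W <- as.integer(spec$canvas_px[2])
  }
  c1 <- margin + 1L; c2 <- margin + spec$stump_width_px
  plane <- amputation_plane(c(r0, c1), c(r0, c2), distal_side = "up")

  # tissue dome height per column (slow parabolic taper toward the lobes)
  cols <- seq_len(W)
  cmid <- (c1 + c2) / 2
  rel <- (cols - cmid) / ((c2 - c1) / 2)
  h_col <- ifelse(cols >= c1 & cols <= c2,
                  round(spec$regenerate_height_px * (1 - 0.25 * rel^2)), -1)
  vmat <- matrix(r0 - seq_len(H), H, W)              # signed distance, + distal
  hmat <- matrix(h_col, H, W, byrow = TRUE)
  tissue_distal <- vmat >= 0 & vmat <= hmat

  gen <- with_substream(spec$seed, 0L, {
    n <- spec$n_rays
    spacing <- spec$stump_width_px / n
    centers <- margin + (seq_len(n) - 0.5) * spacing
    widths <- round(spec$ray_width_px * exp(rnorm(n, 0, spec$ray_width_cv)))
    widths <- pmin(pmax(widths, 4L), floor(spacing) - 2L)
    offs <- round(runif(n, 8, spec$segment_length_px - 8))   # first proximal joint
    phase <- round(runif(n, spec$segment_length_px * 0.5, spec$segment_length_px))
    bif <- runif(n) < spec$bifurcation_fraction
    mh <- exp(rnorm(n, 0, spec$mineral_height_cv))
    list(centers = centers, widths = widths, offs = offs, phase = phase,
         bif = bif, mh = mh)
  })

  mineral <- matrix(FALSE, H, W)
  L <- spec$segment_length_px; gp <- spec$joint_gap_px
  tips <- matrix(NA_real_, spec$n_rays, 2)
  joints_distal <- integer(spec$n_rays)
  bifurcated <- logical(spec$n_rays)
  stump_floor <- spec$stump_depth_px - 6L
  for (i in seq_len(spec$n_rays)) {
    w <- gen$widths[i]
    lo <- as.integer(floor(gen$centers[i] - w / 2)) + 1L
    hi <- lo + as.integer(w) - 1L
    hmin <- min(h_col[lo:hi])
    m_i <- min(round(spec$mineral_height_fraction * hmin * gen$mh[i]), hmin - 3L)
    # distal: v = 0..m_i, joint gaps every L starting at the per-ray phase;
    # bifurcated rays keep their distal branches unsegmented (joints are
    # rendered only below the branching point)
    if (m_i > 0) {
      v_bif <- round(0.55 * m_i)
      do_bif <- gen$bif[i] && (m_i - v_bif) > L / 2 && w >= 10
      bifurcated[i] <- do_bif
      gap_ceiling <- if (do_bif) v_bif else m_i
      ks <- 0:ceiling(m_i / L)
      gap_start <- gen$phase[i] + ks * L
      gap_ok <- gap_start + gp + 3 <= gap_ceiling   # keep a mineral cap above

      joints_distal[i] <- sum(gap_ok)
      v <- 0:m_i
      in_gap <- rep(FALSE, length(v))
      for (g0 in gap_start[gap_ok]) in_gap[v >= g0 & v <= g0 + gp - 1] <- TRUE
      v_on <- v[!in_gap]
      wb <- as.integer(floor((w - 4) / 2))
      spacing_px <- spec$stump_width_px / spec$n_rays
      max_off <- max(0L, as.integer(floor((spacing_px - w) / 2)) - 2L)
      for (v_k in v_on) {
        row <- r0 - v_k
        if (do_bif && v_k > v_bif + 3) {
          off <- min(max_off, v_k - v_bif - 3L)
          mineral[row, (lo - off):(lo - off + wb - 1L)] <- TRUE
          mineral[row, (hi + off - wb + 1L):(hi + off)] <- TRUE
        } else {
          mineral[row, lo:hi] <- TRUE
        }
      }
      tip_v <- max(v_on)
      tips[i, ] <- c(r0 - tip_v, (lo + hi) / 2)
    }
    # proximal stump: v = -1..-stump_floor minus joints at offs + k*L
    dv <- 1:stump_floor
    in_gap_p <- ((dv - gen$offs[i]) %% L) < gp & dv >= gen$offs[i]
    for (v_k in dv[!in_gap_p]) mineral[r0 + v_k, lo:hi] <- TRUE
  }
  mineral_distal <- mineral & vmat >= 0 & tissue_distal
  mineral_proximal <- mineral & vmat < 0

  # ground truth recorded from the noise-free masks
  ema_true <- distal_tip_polygon(mineral_distal, plane)
  s <- spec$mm_per_px
  truth_morpho <- tibble(
    specimen_id = specimen_id, time_hpa = time_hpa, group_label = group_label,
    reg_mm2 = sum(tissue_distal) * s^2,
    ema_mm2 = ema_true$area_px2 * s^2,
    rma_mm2 = sum(mineral_distal) * s^2,
    ray_mm = mean(gen$widths) * s,
    stu_mm = plane_length_px(plane) * s,
    wei_mg = NA_real_, len_mm = NA_real_)

  imgs <- with_substream(spec$seed, 1L, {
    fluo <- array(0, dim = c(H, W, 3))
    n_min <- sum(mineral)
    if (n_min > 0) {
      luma_px <- rnorm(n_min, spec$luma_mean, spec$luma_sd)
      red <- fluo[, , 1]
      red[mineral] <- pmin(pmax(round(luma_px / 0.299), 0), 255)
      fluo[, , 1] <- red
    }
    fluo <- fluo + array(rnorm(H * W * 3, 0, spec$background_noise_sd), dim = c(H, W, 3))
    bf_tissue <- tissue_distal |
      (vmat < 0 & vmat >= -spec$stump_depth_px &
         matrix(cols >= c1 & cols <= c2, H, W, byrow = TRUE))
    bf_base <- matrix(235, H, W)
    bf_base[bf_tissue] <- 200
    bf_base[mineral] <- 180
    bf <- array(rep(bf_base, 3), dim = c(H, W, 3)) +
      array(rnorm(H * W * 3, 0, 2), dim = c(H, W, 3))
    list(fluo = as_rgb255(round(fluo)), bf = as_rgb255(round(bf)))
  })

  record <- fin_record(specimen_id, time_hpa, imgs$bf, imgs$fluo, plane,
                       spec$mm_per_px, group_label = group_label,
                       exposure_ms = 200)
  truth <- list(regenerate = tissue_distal, mineral = mineral,
                mineral_distal = mineral_distal,
                mineral_proximal = mineral_proximal,
                morphometrics = truth_morpho,
                ray_widths_px = gen$widths,
                first_joint_offset_px = gen$offs,
                tips = tips, joints_distal = joints_distal,
                bifurcations = as.integer(bifurcated),
                luma_mean = spec$luma_mean, luma_sd = spec$luma_sd)
  list(record = record, truth = truth)
}

#' Treatment-effect multiplier presets
#'
#' Named multipliers on the regeneration trajectory, the mineral fraction
#' and the staining luma used by [simulate_cohort()].  `ra_like_effects`
#' emulates a retinoic-acid-like phenotype (stunted regeneration, enriched
#' mineral fraction); `warf_like_effects` a warfarin-like one (areas
#' untouched, staining intensity reduced).
#'
#' @format Named numeric vectors with entries `regen`, `mineral`, `luma`.
#' @export
ra_like_effects <- c(regen = 0.6, mineral = 1.3, luma = 1)

#' @rdname ra_like_effects
#' @format NULL
#' @export
warf_like_effects <- c(regen = 1, mineral = 1, luma = 0.7)

#' Parameters of a simulated longitudinal cohort
#'
#' Defines the study conditions of a simulated regeneration trial: the
#' sampling schedule (default: 4 fish sampled at each of 24--144 hpa every
#' 12 h and 168--240 hpa every 24 h, i.e. 60 fish), the saturating
#' regeneration trajectory, the mineralization onset (between 24 and 48
#' hpa), the P1/P2 breakpoint and P2 slope, inter-specimen size
#' variability and measurement noise, and treatment-effect multipliers.
#'
#' @param n_fish Number of fish (default 60).
#' @param time_points_hpa Sampling times; fish are assigned cyclically
#'   (cross-sectional design, one time per fish).
#' @param onset_hpa Mineralization onset (default 36).
#' @param x0_true True P1/P2 breakpoint on the REG/STU axis (default 0.586).
#' @param r_max REG/STU reached at 240 hpa on the noise-free trajectory
#'   (default 1.25 mm).
#' @param fraction_slope True P2 slope of RMA/RAY versus REG/STU
#'   (default 1.2).
#' @param size_cv Inter-specimen size CV; scales STU strongly and RAY
#'   weakly (default 0.1).
#' @param noise_cv Measurement noise CV (default 0.05).
#' @param stu_mean_mm,ray_mean_mm Mean stump width and ray width
#'   (defaults 2.0 and 0.06 mm).
#' @param luma_mean,luma_sd,n_luma_px Staining-intensity distribution and
#'   pixels sampled per fish for the intensity classes (defaults 28, 5,
#'   2000).
#' @param treatment_effects Named multipliers `regen`, `mineral`, `luma`
#'   (see [ra_like_effects]).
#' @param group_label Group label stamped on every record.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_fish = 60L,
                        time_points_hpa = c(seq(24, 144, by = 12), seq(168, 240, by = 24)),
                        onset_hpa = 36, x0_true = 0.586, r_max = 1.25,
                        fraction_slope = 1.2, size_cv = 0.1, noise_cv = 0.05,
                        stu_mean_mm = 2.0, ray_mean_mm = 0.06,
                        luma_mean = 28, luma_sd = 5, n_luma_px = 2000L,
                        treatment_effects = c(regen = 1, mineral = 1, luma = 1),
                        group_label = "control", seed = 1L) {
  stopifnot(n_fish >= 1, length(time_points_hpa) >= 1, size_cv >= 0,
            noise_cv >= 0, r_max > x0_true, onset_hpa >= 24, onset_hpa <= 48)
  eff <- c(regen = 1, mineral = 1, luma = 1)
  eff[names(treatment_effects)] <- treatment_effects
  structure(list(n_fish = as.integer(n_fish), time_points_hpa = time_points_hpa,
                 onset_hpa = onset_hpa, x0_true = x0_true, r_max = r_max,
                 fraction_slope = fraction_slope, size_cv = size_cv,
                 noise_cv = noise_cv, stu_mean_mm = stu_mean_mm,
                 ray_mean_mm = ray_mean_mm, luma_mean = luma_mean,
                 luma_sd = luma_sd, n_luma_px = as.integer(n_luma_px),
                 treatment_effects = eff, group_label = group_label,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# noise-free control trajectory of REG/STU over time
cohort_trajectory <- function(t, r_max, t_on = 24, t_end = 240) {
  u <- pmin(pmax((t - t_on) / (t_end - t_on), 0), 1)
  r_max * (2 * u - u^2)
}

#' Simulate a longitudinal cohort of corrected metrics
#'
#' Draws one record per fish: REG/STU follows a saturating quadratic-like
#' trajectory starting at 24 hpa; RMA/RAY is zero before the
#' mineralization onset, then tracks `fraction_slope * (REG/STU - x0)`
#' along the control schedule, so plotting RMA/RAY against REG/STU shows a
#' flat pre-mineralization phase P1 and a linear co-growth phase P2
#' breaking at `x0_true`.  Inter-specimen size variability scales STU
#' strongly and RAY weakly (RAY--STU coupling is deliberately loose), so
#' raw areas REG and RMA are noisier in time than their corrected ratios.
#' Treatment multipliers rescale the trajectory (`regen`), the mineral
#' fraction (`mineral`) and the staining luma (`luma`).  Per-fish
#' intensity classes come from `n_luma_px` simulated mineral pixels.
#'
#' @param cspec A [cohort_spec()].
#' @return Tibble, one row per fish: identifiers, `time_hpa`, raw
#'   (`stu_mm`, `ray_mm`, `reg_mm2`, `rma_mm2`, `wei_mg`, `len_mm`) and
#'   corrected (`reg_over_stu`, `rma_over_ray`, `mineral_fraction`)
#'   metrics, plus `low_15_29` and `high_30_44` intensity-class
#'   frequencies.
#' @export
simulate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  k <- length(cspec$time_points_hpa)
  eff <- cspec$treatment_effects
  y_scale <- cspec$fraction_slope * (cspec$r_max - cspec$x0_true)
  purrr::map_dfr(seq_len(cspec$n_fish), function(i) {
    t <- cspec$time_points_hpa[((i - 1) %% k) + 1]
    with_substream(cspec$seed, i, {
      g <- cohort_trajectory(t, cspec$r_max)
      frac <- if (t >= cspec$onset_hpa && g > 0) {
        max(0, cspec$fraction_slope * (g - cspec$x0_true)) / g
      } else 0
      x <- g * eff[["regen"]] * exp(rnorm(1, 0, cspec$noise_cv))
      y <- eff[["mineral"]] * frac * x
      if (y > 0) y <- max(0, y + rnorm(1, 0, cspec$noise_cv * y_scale))
      size <- exp(rnorm(1, 0, cspec$size_cv))
      stu <- cspec$stu_mean_mm * size
      ray <- cspec$ray_mean_mm * size^0.3 * exp(rnorm(1, 0, cspec$size_cv / 2))
      wei <- 100 * size^2.5 * exp(rnorm(1, 0, cspec$size_cv / 2))
      len <- 19 * size * exp(rnorm(1, 0, cspec$size_cv / 2))
      luma_i <- cspec$luma_mean * eff[["luma"]] + rnorm(1, 0, 1.5)
      px <- pmin(pmax(round(rnorm(cspec$n_luma_px, luma_i, cspec$luma_sd)), 0), 255)
      in_spec <- px[px >= 15 & px <= 254]
      n_sp <- length(in_spec)
      tibble(specimen_id = sprintf("%s_f%03d", cspec$group_label, i),
             group_label = cspec$group_label, time_hpa = t,
             stu_mm = stu, ray_mm = ray,
             reg_mm2 = x * stu, rma_mm2 = y * ray,
             wei_mg = wei, len_mm = len,
             reg_over_stu = x, rma_over_ray = y,
             mineral_fraction = ifelse(x > 0, y / x, 0),
             low_15_29 = if (n_sp) sum(in_spec >= 15 & in_spec <= 29) / n_sp else 0,
             high_30_44 = if (n_sp) sum(in_spec >= 30 & in_spec <= 44) / n_sp else 0)
    })
  })
}

#' Write a rendered synthetic cohort to disk
#'
#' Renders one image pair per fish per time point and writes PNGs, a
#' manifest CSV consumable by [run_pipeline()], and a ground-truth CSV.
#' Geometry follows the same trajectory as [simulate_cohort()]: the
#' regenerate height tracks the saturating time course (scaled by the
#' `regen` multiplier), the mineral height fraction follows the
#' mineralization schedule (scaled by `mineral`), and the staining luma is
#' scaled by `luma`.
#'
#' @param dir Output directory (created if needed).
#' @param cspec A [cohort_spec()]; `n_fish` fins are rendered at their
#'   assigned time points.
#' @param base_spec A [synthetic_fin_spec()] giving the base geometry at
#'   full regeneration.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_synthetic_cohort <- function(dir, cspec, base_spec = synthetic_fin_spec()) {
  stopifnot(inherits(cspec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- length(cspec$time_points_hpa)
  eff <- cspec$treatment_effects
  rows <- list(); truths <- list()
  for (i in seq_len(cspec$n_fish)) {
    t <- cspec$time_points_hpa[((i - 1) %% k) + 1]
    g_rel <- cohort_trajectory(t, 1) * eff[["regen"]]
    g_ctl <- cohort_trajectory(t, cspec$r_max)
    frac_rel <- if (t >= cspec$onset_hpa && g_ctl > cspec$x0_true) {
      min(1, eff[["mineral"]] * (g_ctl - cspec$x0_true) / (cspec$r_max - cspec$x0_true))
    } else 0
    jitter <- with_substream(cspec$seed, 10000L + i, exp(rnorm(2, 0, c(cspec$noise_cv, cspec$size_cv))))
    spec_i <- synthetic_fin_spec(
      n_rays = base_spec$n_rays,
      ray_width_px = base_spec$ray_width_px * jitter[2]^0.3,
      ray_width_cv = base_spec$ray_width_cv,
      segment_length_px = base_spec$segment_length_px,
      joint_gap_px = base_spec$joint_gap_px,
      bifurcation_fraction = if (t >= 96) base_spec$bifurcation_fraction else 0,
      regenerate_height_px = max(24, round(base_spec$regenerate_height_px * g_rel * jitter[1])),
      mineral_height_fraction = min(0.95, base_spec$mineral_height_fraction * frac_rel),
      mineral_height_cv = base_spec$mineral_height_cv,
      luma_mean = base_spec$luma_mean * eff[["luma"]],
      luma_sd = base_spec$luma_sd,
      background_noise_sd = base_spec$background_noise_sd,
      stump_width_px = max(base_spec$n_rays * 6L,
                           as.integer(round(base_spec$stump_width_px * jitter[2]))),
      stump_depth_px = base_spec$stump_depth_px,
      mm_per_px = base_spec$mm_per_px,
      seed = cspec$seed + 100L * i)
    id <- sprintf("%s_f%03d_t%03d", cspec$group_label, i, t)
    rf <- render_fin(spec_i, specimen_id = id, time_hpa = t,
                     group_label = cspec$group_label)
    bf_path <- file.path(dir, paste0(id, "_bf.png"))
    fl_path <- file.path(dir, paste0(id, "_fl.png"))
    write_fin_image(rf$record$brightfield, bf_path)
    write_fin_image(rf$record$fluorescence, fl_path)
    pl <- rf$record$plane
    rows[[i]] <- tibble(specimen_id = id, group_label = cspec$group_label,
                        time_hpa = t,
                        brightfield = basename(bf_path),
                        fluorescence = basename(fl_path),
                        plane_r1 = pl$p_dorsal[1], plane_c1 = pl$p_dorsal[2],
                        plane_r2 = pl$p_ventral[1], plane_c2 = pl$p_ventral[2],
                        distal_side = pl$distal_side,
                        mm_per_px = spec_i$mm_per_px,
                        exposure_ms = 200, wei_mg = NA_real_, len_mm = NA_real_)
    truths[[i]] <- rf$truth$morphometrics
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(dplyr::bind_rows(truths), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
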