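## ---- mask geometry helpers ------------------------------------------------

ellipse_mask <- function(nrow, ncol, center_row, center_col,
                         semi_row, semi_col) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((r - center_row) / semi_row)^2 + ((c - center_col) / semi_col)^2 <= 1
}

## planar projection of a homogeneous ellipsoid: per-pixel weight equals the
## chord length sqrt(1 - rho^2), so kidney edges are dim and small ROI
## disagreements cost little signal (as in real renograms); normalized to
## sum to 1 over the kidney
ellipse_profile <- function(nrow, ncol, center_row, center_col,
                            semi_row, semi_col) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  rho2 <- ((r - center_row) / semi_row)^2 + ((c - center_col) / semi_col)^2
  w <- sqrt(pmax(0, 1 - rho2))
  w / sum(w)
}

shift_mask <- function(mask, dr, dc) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  src_r <- seq_len(nrow(mask)) - dr
  src_c <- seq_len(ncol(mask)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(mask)
  ok_c <- src_c >= 1 & src_c <= ncol(mask)
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

## dilate (amount > 0) or erode (amount < 0) a binary mask with a disc brush
morph_mask <- function(mask, amount) {
  if (amount == 0) return(mask)
  size <- 2L * abs(amount) + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  m <- if (amount > 0) EBImage::dilate(mask * 1, kern)
       else EBImage::erode(mask * 1, kern)
  m > 0.5
}

## perirenal background ring: `gap` px outside the kidney edge, `width` px
background_ring <- function(kidney, gap = 2L, width = 3L) {
  outer_m <- morph_mask(kidney, gap + width)
  inner_m <- morph_mask(kidney, gap)
  outer_m & !inner_m
}

## ---- simulation settings --------------------------------------------------

#' Acquisition schedule of the phantom
#'
#' Default emulates the study protocol: 30 frames of 2 s immediately
#' after injection followed by 20 frames of 60 s, on a 64 x 64 matrix.
#'
#' @param n_fast,fast_s number and duration (s) of early frames.
#' @param n_slow,slow_s number and duration (s) of late frames.
#' @param matrix_px image matrix side length, pixels.
#' @return A list of class `gates_acquisition` including the derived
#'   `frame_start_s` / `frame_duration_s` vectors.
#' @export
gates_acquisition <- function(n_fast = 30L, fast_s = 2, n_slow = 20L,
                              slow_s = 60, matrix_px = 64L) {
  stopifnot(n_fast >= 1, n_slow >= 0, fast_s > 0, slow_s > 0,
            matrix_px >= 16)
  starts <- c(seq(0, by = fast_s, length.out = n_fast),
              seq(n_fast * fast_s, by = slow_s, length.out = n_slow))
  durs <- c(rep(fast_s, n_fast), rep(slow_s, n_slow))
  structure(list(n_fast = n_fast, fast_s = fast_s, n_slow = n_slow,
                 slow_s = slow_s, matrix_px = matrix_px,
                 frame_start_s = starts, frame_duration_s = durs),
            class = "gates_acquisition")
}

#' Rater variability model
#'
#' Emulates independent ROI delineation by several blinded physicians.
#' Each rater's kidney outline is the true ellipse dilated or eroded by
#' up to `roi_dilation_px` and shifted by up to `roi_shift_px` (integer
#' pixels, uniform); the background ring is additionally displaced by up
#' to `background_placement_jitter_px`. Background placement is the
#' dominant variability channel: it perturbs only the conventional
#' (background-subtracted) variant, which is what degrades its
#' between-rater concordance relative to blank-background processing.
#' The jitter magnitudes are synthetic choices, not measured values.
#'
#' @param n_raters number of raters (>= 2).
#' @param roi_dilation_px,roi_shift_px,background_placement_jitter_px
#'   non-negative integer jitter half-ranges, pixels.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(n_raters = 5L, roi_dilation_px = 1L,
                        roi_shift_px = 1L,
                        background_placement_jitter_px = 3L) {
  stopifnot(n_raters >= 2, roi_dilation_px >= 0, roi_shift_px >= 0,
            background_placement_jitter_px >= 0)
  structure(list(n_raters = as.integer(n_raters),
                 roi_dilation_px = as.integer(roi_dilation_px),
                 roi_shift_px = as.integer(roi_shift_px),
                 background_placement_jitter_px =
                   as.integer(background_placement_jitter_px)),
            class = "rater_model")
}

#' Cohort truth distribution
#'
#' Population the phantom draws subjects from. Total GFR is a truncated
#' normal with mean 89.62 and SD 46.57 mL/min (the cohort moments of the
#' hydronephrosis population this method targets), truncated above
#' 5 mL/min; the left split fraction is uniform on (0.2, 0.8) to span
#' markedly asymmetric function; adult heights and weights.
#'
#' @param tgfr_mean,tgfr_sd,tgfr_min truncated-normal parameters of true
#'   total GFR, mL/min.
#' @param split_range range of the uniform left split fraction.
#' @param height_mean,height_sd,weight_mean,weight_kg_sd adult biometrics
#'   (cm, kg), truncated to plausible ranges.
#' @return A list of class `truth_distribution`.
#' @export
truth_distribution <- function(tgfr_mean = 89.62, tgfr_sd = 46.57,
                               tgfr_min = 5, split_range = c(0.2, 0.8),
                               height_mean = 165, height_sd = 8,
                               weight_mean = 70, weight_kg_sd = 12) {
  stopifnot(tgfr_sd > 0, tgfr_min > 0,
            split_range[1] > 0, split_range[2] < 1,
            split_range[1] < split_range[2])
  structure(list(tgfr_mean = tgfr_mean, tgfr_sd = tgfr_sd,
                 tgfr_min = tgfr_min, split_range = split_range,
                 height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_kg_sd = weight_kg_sd),
            class = "truth_distribution")
}

#' Phantom physiology constants
#'
#' Compartmental constants of the generative model. Plasma tracer
#' concentration is `c(t) = (D/Vp - D/V) e^(-alpha t) + (D/V) e^(-k t)`
#' with a fast distribution phase (plasma volume `Vp`, rate `alpha`)
#' fully decayed by the 2 h / 4 h plasma draws, so late samples follow
#' the mono-exponential with `k = tGFR / V` (extracellular volume `V`).
#' Each kidney accumulates tracer at `split * tGFR * c(t)` while also
#' carrying a small vascular (blood-pool) component; a spatially
#' structured soft-tissue background (uniform tissue plus a bright
#' para-aortic blood-pool stripe between the kidneys) follows the blood
#' curve.
#'
#' The central-volume and mixing constants are calibrated so that the
#' simulated renal uptake tracks the Gates regression's own empirical
#' calibration (total uptake of roughly (GFR + 6.8)/9.8 percent in the
#' 2--3 min window): `plasma_volume_ml_per_kg = 32` is the effective
#' central distribution volume during the uptake window, below the
#' anatomic plasma volume because mixing is still incomplete.
#'
#' @param plasma_volume_ml_per_kg,ecf_volume_ml_per_kg effective central
#'   and extracellular distribution volumes per kg body weight.
#' @param alpha_fast_per_min fast-mixing rate constant, min^-1.
#' @param vascular_fraction fraction of the injected dose apparent in
#'   each kidney ROI through its blood pool at t = 0.
#' @param tissue_bg_cps_px,aorta_cps_px tissue and para-aortic background
#'   count rates per pixel at t = 0, counts/s.
#' @param dose_rate_cps full-syringe count rate under the camera,
#'   counts/s.
#' @param residual_fraction fraction of the dose left in the syringe.
#' @param counter_dose_counts injected dose in gamma-counter calibration
#'   (counts, same calibration as plasma samples).
#' @param plasma_t_min plasma draw times, minutes.
#' @return A list of class `phantom_physiology`.
#' @export
phantom_physiology <- function(plasma_volume_ml_per_kg = 32,
                               ecf_volume_ml_per_kg = 200,
                               alpha_fast_per_min = 0.05,
                               vascular_fraction = 0.003,
                               tissue_bg_cps_px = 0.5,
                               aorta_cps_px = 4,
                               dose_rate_cps = 30000,
                               residual_fraction = 0.01,
                               counter_dose_counts = 5e8,
                               plasma_t_min = c(120, 240)) {
  structure(as.list(environment()), class = "phantom_physiology")
}

## ---- subject-level generation --------------------------------------------

rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
}

simulate_subject <- function(id, truth_dist, acquisition, physiology,
                             config, noise, background) {
  px <- acquisition$matrix_px
  tgfr <- rtruncnorm1(truth_dist$tgfr_mean, truth_dist$tgfr_sd,
                      lower = truth_dist$tgfr_min)
  split_l <- stats::runif(1, truth_dist$split_range[1],
                          truth_dist$split_range[2])
  height <- round(rtruncnorm1(truth_dist$height_mean, truth_dist$height_sd,
                              150, 200), 1)
  weight <- round(rtruncnorm1(truth_dist$weight_mean, truth_dist$weight_kg_sd,
                              45, 120), 1)
  bio <- patient_biometrics(height, weight)
  depths <- kidney_depth(bio, config)
  att <- exp(-config$mu_per_cm * depths)

  ## plasma kinetics
  vp <- physiology$plasma_volume_ml_per_kg * weight
  v <- physiology$ecf_volume_ml_per_kg * weight
  k <- tgfr / v
  alpha <- physiology$alpha_fast_per_min
  d_counter <- physiology$counter_dose_counts
  p0 <- d_counter / v

  ## masks (scaled to the matrix)
  s <- px / 64
  kid_l <- ellipse_mask(px, px, 30 * s, 21 * s, 8 * s, 5.5 * s)
  kid_r <- ellipse_mask(px, px, 30 * s, 43 * s, 8 * s, 5.5 * s)
  prof_l <- ellipse_profile(px, px, 30 * s, 21 * s, 8 * s, 5.5 * s)
  prof_r <- ellipse_profile(px, px, 30 * s, 43 * s, 8 * s, 5.5 * s)
  aorta <- matrix(FALSE, px, px)
  aorta[round(16 * s):round(48 * s), round(31 * s):round(33 * s)] <- TRUE

  ## time courses at frame mid-times (minutes)
  t_min <- (acquisition$frame_start_s + acquisition$frame_duration_s / 2) / 60
  dur <- acquisition$frame_duration_s
  cum_conc <- (1 / vp - 1 / v) * (1 - exp(-alpha * t_min)) / alpha +
    (1 / v) * (1 - exp(-k * t_min))  # integral of c(t)/D, min/mL
  blood <- vp * ((1 / vp - 1 / v) * exp(-alpha * t_min) +
                   (1 / v) * exp(-k * t_min))  # c(t)/c(0), dimensionless

  injected_cps <- physiology$dose_rate_cps * (1 - physiology$residual_fraction)
  uptake_l <- split_l * tgfr * cum_conc        # fraction of dose
  uptake_r <- (1 - split_l) * tgfr * cum_conc
  kv <- if (background) physiology$vascular_fraction else 0

  counts_l <- injected_cps * (uptake_l + kv * blood) * att[["left"]] * dur
  counts_r <- injected_cps * (uptake_r + kv * blood) * att[["right"]] * dur

  nf <- length(t_min)
  flat <- matrix(0, nf, px * px)
  flat <- flat + counts_l %o% as.numeric(prof_l)
  flat <- flat + counts_r %o% as.numeric(prof_r)
  if (background) {
    tissue <- physiology$tissue_bg_cps_px * blood * dur
    flat <- flat + tissue %o% rep(1, px * px)
    flat <- flat + (physiology$aorta_cps_px * blood * dur) %o%
      as.numeric(aorta)
  }
  if (noise) {
    flat <- matrix(stats::rpois(length(flat), flat), nf)
  }
  frames <- array(flat, dim = c(nf, px, px))
  reno <- dynamic_renogram(frames, acquisition$frame_start_s,
                           acquisition$frame_duration_s, "posterior")

  ## syringe records
  full_expect <- physiology$dose_rate_cps * 60
  empty_expect <- physiology$residual_fraction * physiology$dose_rate_cps * 6
  inj <- injection_record(
    full_syringe_counts = if (noise) stats::rpois(1, full_expect) else full_expect,
    full_count_duration_s = 60,
    empty_syringe_counts = if (noise) stats::rpois(1, empty_expect) else empty_expect,
    empty_count_duration_s = 6,
    full_count_time_offset_s = 120,
    empty_count_time_offset_s = 300
  )

  ## plasma samples from the slow (mono-exponential) phase
  t12 <- physiology$plasma_t_min
  p1_true <- p0 * exp(-k * t12[1])
  p2_true <- p0 * exp(-k * t12[2])
  if (noise) {
    for (i in 1:100) {
      p1 <- stats::rpois(1, p1_true)
      p2 <- stats::rpois(1, p2_true)
      if (p1 > p2 && p2 > 0) break
    }
  } else {
    p1 <- p1_true; p2 <- p2_true
  }
  plasma <- plasma_study(d_counter, p1, p2, t12[1], t12[2])

  rois_true <- roi_set(list(left_kidney = kid_l, right_kidney = kid_r,
                            left_background = background_ring(kid_l) & !kid_r,
                            right_background = background_ring(kid_r) & !kid_l))

  truth <- structure(
    list(tgfr_true = tgfr, split_fraction_left_true = split_l,
         depth_left_cm = depths[["left"]], depth_right_cm = depths[["right"]],
         plasma_k = k, plasma_P0 = p0, injected_dose = d_counter),
    class = "phantom_truth")

  list(id = id, renogram = reno, rois_true = rois_true, biometrics = bio,
       injection = inj, plasma = plasma, truth = truth)
}

rater_rois_for_subject <- function(subject, model) {
  kid_true <- list(left = subject$rois_true$masks$left_kidney,
                   right = subject$rois_true$masks$right_kidney)
  lapply(seq_len(model$n_raters), function(r) {
    kid <- list()
    ## outlining style (tight vs generous) is a per-physician trait and is
    ## applied to both kidneys alike; placement error is per kidney
    dil <- if (model$roi_dilation_px > 0) {
      sample(-model$roi_dilation_px:model$roi_dilation_px, 1)
    } else 0L
    for (side in c("left", "right")) {
      dr <- if (model$roi_shift_px > 0) {
        sample(-model$roi_shift_px:model$roi_shift_px, 1)
      } else 0L
      dc <- if (model$roi_shift_px > 0) {
        sample(-model$roi_shift_px:model$roi_shift_px, 1)
      } else 0L
      m <- shift_mask(morph_mask(kid_true[[side]], dil), dr, dc)
      if (!any(m)) m <- kid_true[[side]]
      kid[[side]] <- m
    }
    if (any(kid$left & kid$right)) kid <- kid_true
    bg <- list()
    for (side in c("left", "right")) {
      ring <- background_ring(kid[[side]])
      j <- model$background_placement_jitter_px
      if (j > 0) {
        ring <- shift_mask(ring, sample(-j:j, 1), sample(-j:j, 1))
      }
      ring <- ring & !kid$left & !kid$right
      if (!any(ring)) {
        ring <- background_ring(kid[[side]]) & !kid$left & !kid$right
      }
      bg[[side]] <- ring
    }
    roi_set(list(left_kidney = kid$left, right_kidney = kid$right,
                 left_background = bg$left, right_background = bg$right))
  })
}

#' Simulate a phantom cohort
#'
#' Generates a cohort of synthetic subjects with known ground truth:
#' dynamic renograms from the two-compartment phantom (Poisson counting
#' noise optional), syringe counting records, dual-sample plasma studies
#' consistent with the same clearance, and one jittered ROI set per
#' simulated rater. Everything downstream of the generator — Gates
#' processing in both variants, dual-plasma tGFR, the per-kidney
#' apportioning, and the rater-concordance comparison — can be validated
#' against the recorded truth.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param truth a [truth_distribution()].
#' @param acquisition a [gates_acquisition()].
#' @param raters a [rater_model()].
#' @param physiology a [phantom_physiology()].
#' @param config a [splitgfr_config()]; its depth coefficients and
#'   attenuation coefficient are used by the generator, so processing
#'   with the same config inverts the geometry exactly.
#' @param seed integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @param noise Poisson counting noise on frames, syringe and plasma
#'   counts (`TRUE`) or exact expectations (`FALSE`).
#' @param background include tissue/vascular background activity.
#' @return A list of class `phantom_cohort`: `subjects` (each with
#'   `renogram`, `rois_true`, `rater_rois`, `biometrics`, `injection`,
#'   `plasma`, `truth`) plus the generating settings.
#' @examples
#' coh <- simulate_cohort(2, seed = 7,
#'                        acquisition = gates_acquisition(matrix_px = 32))
#' coh$subjects[[1]]$truth$split_fraction_left_true
#' @export
simulate_cohort <- function(n_subjects = 30L,
                            truth = truth_distribution(),
                            acquisition = gates_acquisition(),
                            raters = rater_model(),
                            physiology = phantom_physiology(),
                            config = splitgfr_config(),
                            seed = 1L,
                            noise = TRUE,
                            background = TRUE) {
  stopifnot(n_subjects >= 1)
  subjects <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      s <- simulate_subject(sprintf("P%02d", i), truth, acquisition,
                            physiology, config, noise, background)
      s$rater_rois <- rater_rois_for_subject(s, raters)
      s
    })
  })
  structure(list(subjects = subjects, truth_distribution = truth,
                 acquisition = acquisition, rater_model = raters,
                 physiology = physiology, config = config, seed = seed,
                 noise = noise, background = background),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d subjects, %d raters, seed %d (%s, %s)\n",
              length(x$subjects), x$rater_model$n_raters, x$seed,
              if (x$noise) "Poisson noise" else "noiseless",
              if (x$background) "with background" else "background off"))
  invisible(x)
}
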