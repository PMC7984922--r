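#' Time-activity curve over a region of interest
#'
#' Sums counts under a binary mask in every frame of a dynamic renogram.
#'
#' @param renogram a [dynamic_renogram()].
#' @param mask logical matrix of the frame's row/col shape, non-empty.
#' @return A list of class `time_activity_curve` with `times_s` (frame
#'   mid-times), `counts` (summed ROI counts per frame) and `count_rates`
#'   (counts per second).
#' @export
extract_tac <- function(renogram, mask) {
  d <- dim(renogram$frames)
  if (!is.matrix(mask) || !all(dim(mask) == d[2:3])) {
    stop("mask shape does not match the frame grid")
  }
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  nf <- d[1]
  flat <- matrix(renogram$frames, nrow = nf)  # frames x pixels
  counts <- as.numeric(flat %*% as.numeric(mask))
  structure(
    list(times_s = renogram$frame_start_s + renogram$frame_duration_s / 2,
         counts = counts,
         count_rates = counts / renogram$frame_duration_s),
    class = "time_activity_curve"
  )
}

#' Kidney depth from biometrics (Tonnesen estimate)
#'
#' Empirical posterior kidney depth used for attenuation correction:
#' `depth_cm = a * (weight_kg / height_cm) + b`, with side-specific
#' coefficients from the configuration (defaults a = 13.2 / 13.3,
#' b = 0.7 for left / right).
#'
#' @param biometrics a [patient_biometrics()].
#' @param config a [splitgfr_config()].
#' @return Named numeric vector `c(left = , right = )`, cm.
#' @export
kidney_depth <- function(biometrics, config = splitgfr_config()) {
  r <- biometrics$weight_kg / biometrics$height_cm
  c(left = unname(config$depth_left[["slope"]] * r +
                    config$depth_left[["intercept"]]),
    right = unname(config$depth_right[["slope"]] * r +
                     config$depth_right[["intercept"]]))
}

#' Depth / attenuation correction factors
#'
#' Bundles per-kidney depths with the linear attenuation coefficient and
#' the resulting attenuation factors `exp(-mu * depth)`.
#'
#' @param depth_left_cm,depth_right_cm kidney depths, cm.
#' @param mu_per_cm linear attenuation coefficient, cm^-1.
#' @return A list of class `depth_correction`.
#' @export
depth_correction <- function(depth_left_cm, depth_right_cm,
                             mu_per_cm = 0.153) {
  if (depth_left_cm <= 0 || depth_right_cm <= 0 || mu_per_cm <= 0) {
    stop("depths and mu must be positive")
  }
  structure(
    list(depth_left_cm = depth_left_cm,
         depth_right_cm = depth_right_cm,
         mu_per_cm = mu_per_cm,
         attenuation_factor_left = exp(-mu_per_cm * depth_left_cm),
         attenuation_factor_right = exp(-mu_per_cm * depth_right_cm)),
    class = "depth_correction"
  )
}

#' Net injected count rate from syringe records
#'
#' Full-syringe count rate minus residual (empty-syringe) rate, each
#' optionally decay-corrected to the injection time with the Tc-99m
#' half-life. This is the dose term of the Gates uptake calculation, in
#' camera counts per second.
#'
#' @param injection an [injection_record()].
#' @param decay_correct correct both rates to injection time.
#' @param half_life_h isotope half-life, hours.
#' @return Net injected count rate, counts/s.
#' @export
net_injected_counts <- function(injection, decay_correct = FALSE,
                                half_life_h = 6.0058) {
  full_rate <- injection$full_syringe_counts / injection$full_count_duration_s
  empty_rate <- injection$empty_syringe_counts / injection$empty_count_duration_s
  if (decay_correct) {
    ## full counted before injection: it decays *towards* injection time
    full_rate <- decay_correct_rate(full_rate,
                                    injection$full_count_time_offset_s / 3600,
                                    half_life_h)
    ## residual counted after injection: correct back up to injection time
    empty_rate <- decay_correct_rate(empty_rate,
                                     -injection$empty_count_time_offset_s / 3600,
                                     half_life_h)
  }
  net <- full_rate - empty_rate
  if (!is.finite(net) || net <= 0) stop("residual exceeds full syringe")
  net
}

#' Frame weights for a time window
#'
#' For a half-open window `[start, end)` in seconds post-injection,
#' returns one weight per frame equal to the fraction of that frame's
#' duration overlapping the window. Summing `weight * frame_counts`
#' yields the counts accumulated during the window, with partial frames
#' weighted by overlap.
#'
#' @param frame_start_s,frame_duration_s frame timing vectors.
#' @param window_s numeric length-2, `c(start, end)` seconds.
#' @return Numeric weight vector, one per frame.
#' @export
frame_window_weights <- function(frame_start_s, frame_duration_s, window_s) {
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2])
  ends <- frame_start_s + frame_duration_s
  overlap <- pmin(ends, window_s[2]) - pmax(frame_start_s, window_s[1])
  pmax(overlap, 0) / frame_duration_s
}

#' Renal uptake fractions
#'
#' The heart of the Gates computation: the fraction of the injected dose
#' accumulated by each kidney during the uptake window. For each kidney,
#' counts in frames overlapping the window are summed (partial frames
#' weighted by overlap); the `conventional` variant subtracts a
#' background prediction (mean background-ROI counts per pixel times the
#' kidney ROI pixel count, from that side's background ROI), while
#' `blank_background` subtracts nothing. Net counts are divided by the
#' attenuation factor `exp(-mu * depth)` and by
#' `dose_rate * window length` to give a fraction of injected dose.
#' Background-subtracted counts that come out negative are clamped to
#' zero with a warning.
#'
#' @param renogram a [dynamic_renogram()].
#' @param rois a [roi_set()]; the conventional variant requires
#'   `left_background` and `right_background` masks.
#' @param depth a [depth_correction()].
#' @param dose_rate net injected count rate, counts/s
#'   (see [net_injected_counts()]).
#' @param variant `"conventional"` or `"blank_background"`.
#' @param window_s uptake window `c(start, end)`, seconds post-injection;
#'   must lie within the acquisition span.
#' @return Named numeric `c(left = , right = )` uptake fractions, with the
#'   attenuation-corrected window counts attached as attribute
#'   `corrected_counts`.
#' @export
renal_uptake_fractions <- function(renogram, rois, depth, dose_rate,
                                   variant = c("conventional",
                                               "blank_background"),
                                   window_s = c(120, 180)) {
  variant <- match.arg(variant)
  stopifnot(inherits(depth, "depth_correction"), dose_rate > 0)
  span <- c(renogram$frame_start_s[1],
            max(renogram$frame_start_s + renogram$frame_duration_s))
  if (window_s[1] < span[1] || window_s[2] > span[2]) {
    stop(sprintf("uptake window [%g, %g) outside acquisition span [%g, %g]",
                 window_s[1], window_s[2], span[1], span[2]))
  }
  w <- frame_window_weights(renogram$frame_start_s,
                            renogram$frame_duration_s, window_s)

  window_counts <- function(mask) {
    sum(w * extract_tac(renogram, mask)$counts)
  }

  att <- c(left = depth$attenuation_factor_left,
           right = depth$attenuation_factor_right)
  out <- c(left = NA_real_, right = NA_real_)
  corrected <- c(left = NA_real_, right = NA_real_)
  for (side in c("left", "right")) {
    kmask <- rois$masks[[paste0(side, "_kidney")]]
    if (is.null(kmask)) stop("missing ", side, "_kidney mask")
    kc <- window_counts(kmask)
    if (variant == "conventional") {
      bmask <- rois$masks[[paste0(side, "_background")]]
      if (is.null(bmask) || !any(bmask)) {
        stop("conventional variant requires a non-empty ", side,
             "_background mask")
      }
      bg_pred <- window_counts(bmask) / sum(bmask) * sum(kmask)
      net <- kc - bg_pred
      if (net < 0) {
        warning(sprintf("%s kidney: background prediction (%.0f) exceeds ROI counts (%.0f); clamped to 0",
                        side, bg_pred, kc))
        net <- 0
      }
    } else {
      net <- kc
    }
    corrected[side] <- net / att[side]
    out[side] <- corrected[side] / (dose_rate * diff(window_s))
  }
  attr(out, "corrected_counts") <- corrected
  out
}

#' Gates regression: uptake fraction to GFR
#'
#' Maps total renal uptake (fraction of injected dose in the uptake
#' window) to GFR via the published linear regression
#' `GFR = slope * uptake_percent - intercept`, clamped at zero.
#'
#' @param uptake_total total (left + right) uptake as a fraction in
#'   `[0, 1]`.
#' @param config a [splitgfr_config()] supplying slope and intercept.
#' @return GFR in mL/min.
#' @export
gates_gfr_from_uptake <- function(uptake_total, config = splitgfr_config()) {
  if (!is.finite(uptake_total) || uptake_total < 0 || uptake_total > 1) {
    stop("uptake must be a fraction in [0, 1]")
  }
  max(0, config$gates_slope * (uptake_total * 100) - config$gates_intercept)
}

#' Full Gates pipeline
#'
#' Composes depth estimation, dose-rate extraction, uptake computation,
#' the Gates regression, the proportional left/right split and optional
#' BSA normalization into one call.
#'
#' @param renogram a [dynamic_renogram()].
#' @param rois a [roi_set()].
#' @param biometrics a [patient_biometrics()].
#' @param injection an [injection_record()].
#' @param variant `"conventional"` (background-subtracted gGFR) or
#'   `"blank_background"` (gGFR', kidney outline only).
#' @param config a [splitgfr_config()].
#' @param normalize report GFRs per 1.73 m^2 BSA instead of raw mL/min.
#' @return A list of class `gates_result` with `gfr_left`, `gfr_right`
#'   (mL/min, or mL.min^-1.(1.73 m^2)^-1 when normalized), `uptake_left`,
#'   `uptake_right` (fractions of injected dose), `variant` and
#'   `normalized`.
#' @export
gates_pipeline <- function(renogram, rois, biometrics, injection,
                           variant = c("conventional", "blank_background"),
                           config = splitgfr_config(), normalize = FALSE) {
  variant <- match.arg(variant)
  bad <- validate_study(renogram, rois, biometrics, injection)
  if (length(bad)) {
    stop("invalid study: ", paste(bad, collapse = "; "))
  }
  depths <- kidney_depth(biometrics, config)
  dc <- depth_correction(depths[["left"]], depths[["right"]],
                         config$mu_per_cm)
  dose_rate <- net_injected_counts(injection, config$decay_correct_syringe,
                                   config$half_life_h)
  uptake <- renal_uptake_fractions(renogram, rois, dc, dose_rate,
                                   variant, config$uptake_window_s)
  total_uptake <- sum(uptake)
  gfr_total <- gates_gfr_from_uptake(total_uptake, config)
  shares <- if (total_uptake > 0) uptake / total_uptake else c(left = 0.5,
                                                               right = 0.5)
  gfr <- gfr_total * shares
  if (normalize) {
    bsa <- body_surface_area(biometrics, config = config)
    gfr <- normalize_to_bsa(gfr, bsa)
  }
  structure(
    list(gfr_left = unname(gfr["left"]),
         gfr_right = unname(gfr["right"]),
         uptake_left = unname(uptake["left"]),
         uptake_right = unname(uptake["right"]),
         variant = variant,
         normalized = normalize),
    class = "gates_result"
  )
}

#' @export
print.gates_result <- function(x, ...) {
  unit <- if (x$normalized) "mL/min/1.73m^2" else "mL/min"
  cat(sprintf("Gates %s: left %.2f + right %.2f = %.2f %s (uptake %.2f%% + %.2f%%)\n",
              x$variant, x$gfr_left, x$gfr_right, x$gfr_left + x$gfr_right,
              unit, 100 * x$uptake_left, 100 * x$uptake_right))
  invisible(x)
}
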