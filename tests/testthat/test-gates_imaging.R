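test_that("time-activity curves are plain masked sums", {
  reno <- tiny_renogram()
  col0 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)  # first column
  expect_equal(extract_tac(reno, col0)$counts, c(4, 12))
  expect_equal(extract_tac(reno, matrix(TRUE, 2, 2))$counts, c(10, 26))
  px <- matrix(FALSE, 2, 2); px[1, 2] <- TRUE
  tac <- extract_tac(reno, px)
  expect_equal(tac$counts, c(2, 6))
  expect_equal(tac$count_rates, c(1, 3))
  expect_equal(tac$times_s, c(1, 3))
  expect_error(extract_tac(reno, matrix(FALSE, 2, 2)), "empty mask")
  expect_error(extract_tac(reno, matrix(TRUE, 3, 3)), "shape")
})

test_that("kidney depth follows the configured weight/height formula", {
  d <- kidney_depth(patient_biometrics(170, 70))
  expect_equal(d[["left"]], 13.2 * 70 / 170 + 0.7, tolerance = 1e-12)
  expect_equal(d[["right"]], 13.3 * 70 / 170 + 0.7, tolerance = 1e-12)
  expect_equal(unname(d), c(6.1353, 6.1765), tolerance = 1e-4)
  ## intercept limit as weight/height -> 0
  d0 <- kidney_depth(patient_biometrics(250, 2))
  expect_equal(unname(d0), 0.7 + c(13.2, 13.3) * 2 / 250, tolerance = 1e-12)
  ## coefficients are pure config passthrough
  cfg <- splitgfr_config(depth_left = c(slope = 0, intercept = 1),
                         depth_right = c(slope = 0, intercept = 1))
  expect_equal(unname(kidney_depth(patient_biometrics(170, 70), cfg)),
               c(1, 1))
})

test_that("net injected counts is rate arithmetic with optional decay", {
  inj <- injection_record(600000, 60, 600, 6)
  expect_equal(net_injected_counts(inj), 9900)
  expect_equal(net_injected_counts(injection_record(600000, 60, 0, 6)),
               10000)
  ## full syringe counted half a half-life before injection
  inj2 <- injection_record(600000, 60, 0, 6,
                           full_count_time_offset_s = 3.0029 * 3600)
  expect_equal(net_injected_counts(inj2, decay_correct = TRUE),
               10000 * 2^-0.5, tolerance = 1e-9)
  expect_error(net_injected_counts(injection_record(100, 60, 600, 6)),
               "residual exceeds")
})

test_that("window weights match brute-force frame-interval enumeration", {
  acq <- gates_acquisition()  # 30 x 2 s + 20 x 60 s
  brute <- function(window) {
    vapply(seq_along(acq$frame_start_s), function(i) {
      a <- acq$frame_start_s[i]
      b <- a + acq$frame_duration_s[i]
      max(0, min(b, window[2]) - max(a, window[1])) /
        acq$frame_duration_s[i]
    }, numeric(1))
  }
  ## the 2-3 min window selects exactly the single 60 s frame covering it
  w <- frame_window_weights(acq$frame_start_s, acq$frame_duration_s,
                            c(120, 180))
  expect_equal(w, brute(c(120, 180)))
  expect_equal(sum(w > 0), 1)
  expect_equal(w[32], 1)  # frames 1-30 end at 60 s; frame 32 is [120,180)
  ## partial overlaps agree with the oracle too
  for (win in list(c(119, 181), c(50, 130), c(0, 2), c(59, 61))) {
    expect_equal(frame_window_weights(acq$frame_start_s,
                                      acq$frame_duration_s, win),
                 brute(win))
  }
})

test_that("uptake fractions follow the documented correction chain", {
  ## two frames: [0,120) empty, [120,180) carrying all counts
  nr <- 8; nc <- 8
  kid <- matrix(FALSE, nr, nc); kid[2:5, 2:3] <- TRUE      # 8 px
  bg <- matrix(FALSE, nr, nc); bg[7:8, 1:4] <- TRUE        # 8 px
  f2 <- matrix(0, nr, nc)
  f2[kid] <- 5000 / sum(kid)
  frames <- array(0, c(2, nr, nc)); frames[2, , ] <- f2
  reno <- dynamic_renogram(frames, c(0, 120), c(120, 60))
  rois <- roi_set(list(left_kidney = kid, right_kidney = kid,
                       left_background = bg, right_background = bg))
  dc <- depth_correction(log(2) / 0.153, log(2) / 0.153)  # factors = 0.5
  dose_rate <- 100000 / 60                                # in-window dose

  blank <- renal_uptake_fractions(reno, rois, dc, dose_rate,
                                  "blank_background", c(120, 180))
  expect_equal(as.numeric(blank), c(0.10, 0.10), tolerance = 1e-12)

  ## background ROI holding 1000 counts predicts 1000 over the kidney's
  ## 8 px (equal pixel counts), so conventional subtracts exactly 1000
  f2[bg] <- 1000 / sum(bg)
  frames[2, , ] <- f2
  reno <- dynamic_renogram(frames, c(0, 120), c(120, 60))
  conv <- renal_uptake_fractions(reno, rois, dc, dose_rate,
                                 "conventional", c(120, 180))
  expect_equal(as.numeric(conv), c(0.08, 0.08), tolerance = 1e-12)

  ## background exceeding the kidney counts clamps to zero with a warning
  f2[bg] <- 6000 / sum(bg)
  frames[2, , ] <- f2
  reno <- dynamic_renogram(frames, c(0, 120), c(120, 60))
  expect_warning(expect_warning(
    clamped <- renal_uptake_fractions(reno, rois, dc, dose_rate,
                                      "conventional", c(120, 180)),
    "left kidney.*clamped"), "right kidney.*clamped")
  expect_equal(as.numeric(suppressWarnings(clamped)), c(0, 0))

  ## guard rails
  expect_error(renal_uptake_fractions(reno, rois, dc, dose_rate,
                                      "conventional", c(120, 500)),
               "outside acquisition")
  rois_nobg <- roi_set(list(left_kidney = kid, right_kidney = kid))
  expect_error(renal_uptake_fractions(reno, rois_nobg, dc, dose_rate,
                                      "conventional", c(120, 180)),
               "background mask")
})

test_that("the Gates regression maps uptake to GFR with a zero clamp", {
  expect_equal(gates_gfr_from_uptake(0.10), 9.8127 * 10 - 6.82519,
               tolerance = 1e-12)
  expect_equal(gates_gfr_from_uptake(0.10), 91.302, tolerance = 1e-3)
  expect_equal(gates_gfr_from_uptake(0), 0)
  expect_error(gates_gfr_from_uptake(1.2), "fraction")
  expect_error(gates_gfr_from_uptake(-0.1), "fraction")
})

test_that("gates_pipeline equals the hand-composed stage chain", {
  s <- quick_cohort(1, seed = 21)$subjects[[1]]
  cfg <- splitgfr_config()
  res <- gates_pipeline(s$renogram, s$rois_true, s$biometrics, s$injection,
                        "blank_background", cfg)

  depths <- kidney_depth(s$biometrics, cfg)
  dc <- depth_correction(depths[["left"]], depths[["right"]], cfg$mu_per_cm)
  dose <- net_injected_counts(s$injection)
  up <- renal_uptake_fractions(s$renogram, s$rois_true, dc, dose,
                               "blank_background", cfg$uptake_window_s)
  total <- gates_gfr_from_uptake(sum(up), cfg)
  expect_equal(res$gfr_left, total * up[["left"]] / sum(up),
               tolerance = 1e-12)
  expect_equal(res$gfr_right, total * up[["right"]] / sum(up),
               tolerance = 1e-12)
  expect_equal(res$uptake_left, up[["left"]])

  ## per-kidney GFRs split the regression total proportionally and exactly
  expect_equal(res$gfr_left + res$gfr_right, total, tolerance = 1e-12)

  ## determinism
  res2 <- gates_pipeline(s$renogram, s$rois_true, s$biometrics,
                         s$injection, "blank_background", cfg)
  expect_identical(res, res2)

  ## BSA normalization scales both kidneys by 1.73/bsa
  resn <- gates_pipeline(s$renogram, s$rois_true, s$biometrics,
                         s$injection, "blank_background", cfg,
                         normalize = TRUE)
  bsa <- body_surface_area(s$biometrics, config = cfg)
  expect_equal(resn$gfr_left, res$gfr_left * 1.73 / bsa, tolerance = 1e-12)
  expect_true(resn$normalized)
})

test_that("variant switch changes uptake by exactly the background term", {
  s <- quick_cohort(1, seed = 22)$subjects[[1]]
  cfg <- splitgfr_config()
  depths <- kidney_depth(s$biometrics, cfg)
  dc <- depth_correction(depths[["left"]], depths[["right"]], cfg$mu_per_cm)
  dose <- net_injected_counts(s$injection)
  blank <- renal_uptake_fractions(s$renogram, s$rois_true, dc, dose,
                                  "blank_background", cfg$uptake_window_s)
  conv <- renal_uptake_fractions(s$renogram, s$rois_true, dc, dose,
                                 "conventional", cfg$uptake_window_s)
  w <- frame_window_weights(s$renogram$frame_start_s,
                            s$renogram$frame_duration_s,
                            cfg$uptake_window_s)
  for (side in c("left", "right")) {
    kmask <- s$rois_true$masks[[paste0(side, "_kidney")]]
    bmask <- s$rois_true$masks[[paste0(side, "_background")]]
    bg_pred <- sum(w * extract_tac(s$renogram, bmask)$counts) /
      sum(bmask) * sum(kmask)
    att <- if (side == "left") dc$attenuation_factor_left else
      dc$attenuation_factor_right
    expected_drop <- bg_pred / att / (dose * diff(cfg$uptake_window_s))
    expect_equal(blank[[side]] - conv[[side]], expected_drop,
                 tolerance = 1e-9)
  }
  ## blank-background dominance: subtraction only removes counts
  expect_true(all(blank >= conv))
})

test_that("adding kidney counts never decreases that kidney's uptake or GFR", {
  s <- quick_cohort(1, seed = 23)$subjects[[1]]
  cfg <- splitgfr_config()
  base <- gates_pipeline(s$renogram, s$rois_true, s$biometrics,
                         s$injection, "blank_background", cfg)
  boosted <- s$renogram
  kmask <- s$rois_true$masks$left_kidney
  for (f in which(boosted$frame_start_s >= 120 &
                    boosted$frame_start_s < 180)) {
    fr <- boosted$frames[f, , ]
    fr[kmask] <- fr[kmask] + 50
    boosted$frames[f, , ] <- fr
  }
  more <- gates_pipeline(boosted, s$rois_true, s$biometrics, s$injection,
                         "blank_background", cfg)
  expect_gt(more$uptake_left, base$uptake_left)
  expect_gte(more$gfr_left, base$gfr_left)
})
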