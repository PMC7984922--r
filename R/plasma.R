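#' Two-sample (slope-intercept) plasma clearance GFR
#'
#' Total GFR from an injected dose and two timed plasma counts, assuming
#' mono-exponential late plasma disappearance `P(t) = P0 * exp(-k t)`:
#'
#' \deqn{GFR = \frac{D\,\ln(P_1/P_2)}{T_2-T_1}\;
#'   \exp\!\left[\frac{T_1\ln P_2 - T_2\ln P_1}{T_2-T_1}\right]}
#'
#' which is algebraically `D * k / P0` for the mono-exponential through the
#' two samples. Times are minutes, so the result is mL/min provided `D`
#' (counts) and `P1`, `P2` (counts/mL) share one counting calibration.
#'
#' No single-compartment overestimation correction is applied by default;
#' the uncorrected slope-intercept value is what this method calls tGFR.
#' Setting `brochner_mortensen = TRUE` in the config applies the adult
#' Brochner-Mortensen polynomial as an optional hook.
#'
#' @param study a [plasma_study()].
#' @param config a [splitgfr_config()]; only the `brochner_mortensen`
#'   switch is consulted here.
#' @return GFR in mL/min (a single number).
#' @examples
#' s <- plasma_study(D = 10000, P1 = 50 * exp(-0.01 * 120),
#'                   P2 = 50 * exp(-0.01 * 240), T1_min = 120, T2_min = 240)
#' dual_plasma_gfr(s)  # 10000 * 0.01 / 50 = 2 mL/min
#' @export
dual_plasma_gfr <- function(study, config = splitgfr_config()) {
  stopifnot(inherits(study, "plasma_study"))
  if (study$D <= 0) stop("injected dose D must be positive")
  if (study$P1 <= 0 || study$P2 <= 0) stop("plasma counts must be positive")
  if (study$T1_min <= 0 || study$T2_min <= study$T1_min) {
    stop("draw times must satisfy T2 > T1 > 0")
  }
  if (study$P2 > study$P1) {
    stop("non-decreasing plasma activity: P2 >= P1 implies non-positive clearance")
  }
  gfr <- dual_plasma_formula(study$D, study$P1, study$P2,
                             study$T1_min, study$T2_min)
  if (isTRUE(config$brochner_mortensen)) {
    gfr <- 0.990778 * gfr - 0.001218 * gfr^2
  }
  gfr
}

## The bare slope-intercept formula, no precondition checks. Kept separate
## so degenerate limits (e.g. P1 == P2) can be probed directly.
##
## Evaluated as D*k/P0 with k = ln(P1/P2)/(T2-T1) and P0 = P1*exp(k*T1),
## which is algebraically identical to the textbook form
## D*ln(P1/P2)/(T2-T1) * exp[(T1*lnP2 - T2*lnP1)/(T2-T1)] but avoids the
## cancellation of the large T*lnP products in the exponent.
dual_plasma_formula <- function(D, P1, P2, T1, T2) {
  k <- log(P1 / P2) / (T2 - T1)
  D * k / (P1 * exp(k * T1))
}

#' Body surface area
#'
#' DuBois (`0.007184 * W^0.425 * H^0.725`, default) or Haycock
#' (`0.024265 * W^0.5378 * H^0.3964`) estimate, weight in kg and height
#' in cm, result in m^2.
#'
#' @param biometrics a [patient_biometrics()].
#' @param formula `"dubois"` or `"haycock"`; defaults to the config choice.
#' @param config a [splitgfr_config()].
#' @return BSA in m^2.
#' @export
body_surface_area <- function(biometrics, formula = config$bsa_formula,
                              config = splitgfr_config()) {
  h <- biometrics$height_cm
  w <- biometrics$weight_kg
  if (!is.finite(h) || h <= 0 || !is.finite(w) || w <= 0) {
    stop("height and weight must be positive")
  }
  switch(match.arg(formula, c("dubois", "haycock")),
         dubois  = 0.007184 * w^0.425 * h^0.725,
         haycock = 0.024265 * w^0.5378 * h^0.3964)
}

#' Normalize a GFR to 1.73 m^2 body surface area
#'
#' @param gfr_raw GFR in mL/min.
#' @param bsa body surface area in m^2.
#' @return GFR in mL.min^-1.(1.73 m^2)^-1.
#' @export
normalize_to_bsa <- function(gfr_raw, bsa) {
  if (!is.finite(bsa) || bsa <= 0) stop("BSA must be positive")
  gfr_raw * 1.73 / bsa
}

#' Physical decay correction of a count rate
#'
#' Corrects a measured count rate to a reference time `dt_h` hours away;
#' positive `dt_h` means the measurement was taken *before* the reference
#' (counts decayed since, so the rate is scaled down to the reference),
#' negative means after (scaled up).
#'
#' @param rate measured count rate.
#' @param dt_h signed hours from measurement to reference time.
#' @param half_life_h isotope half-life in hours (Tc-99m: 6.0058).
#' @return Decay-corrected rate.
#' @export
decay_correct_rate <- function(rate, dt_h, half_life_h = 6.0058) {
  rate * 2^(-dt_h / half_life_h)
}

#' Total GFR with BSA normalization
#'
#' Convenience wrapper combining [dual_plasma_gfr()] and BSA
#' normalization.
#'
#' @inheritParams dual_plasma_gfr
#' @param biometrics a [patient_biometrics()].
#' @return A list of class `plasma_gfr` with `gfr_raw` (mL/min),
#'   `bsa_m2`, and `gfr_bsa` (mL.min^-1.(1.73 m^2)^-1).
#' @export
plasma_gfr <- function(study, biometrics, config = splitgfr_config()) {
  raw <- dual_plasma_gfr(study, config)
  bsa <- body_surface_area(biometrics, config = config)
  structure(list(gfr_raw = raw, bsa_m2 = bsa,
                 gfr_bsa = normalize_to_bsa(raw, bsa)),
            class = "plasma_gfr")
}

#' @export
print.plasma_gfr <- function(x, ...) {
  cat(sprintf("dual-plasma GFR: %.2f mL/min (%.2f mL/min/1.73m^2, BSA %.3f m^2)\n",
              x$gfr_raw, x$gfr_bsa, x$bsa_m2))
  invisible(x)
}

#' Batch plasma clearance from a CSV table
#'
#' Reads one study per row with columns `D, P1, P2, T1_min, T2_min,
#' height_cm, weight_kg` and appends `gfr_raw`, `bsa_m2`, `gfr_bsa`.
#'
#' @param path input CSV path.
#' @param out optional output CSV path; written when non-`NULL`.
#' @param config a [splitgfr_config()].
#' @return The augmented data frame, invisibly when `out` is given.
#' @export
process_plasma_csv <- function(path, out = NULL, config = splitgfr_config()) {
  df <- utils::read.csv(path)
  need <- c("D", "P1", "P2", "T1_min", "T2_min", "height_cm", "weight_kg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("plasma CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    st <- plasma_study(df$D[i], df$P1[i], df$P2[i], df$T1_min[i], df$T2_min[i])
    bio <- patient_biometrics(df$height_cm[i], df$weight_kg[i])
    plasma_gfr(st, bio, config)
  })
  df$gfr_raw <- vapply(res, `[[`, numeric(1), "gfr_raw")
  df$bsa_m2 <- vapply(res, `[[`, numeric(1), "bsa_m2")
  df$gfr_bsa <- vapply(res, `[[`, numeric(1), "gfr_bsa")
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    return(invisible(df))
  }
  df
}
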