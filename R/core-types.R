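#' Dynamic renogram frame stack
#'
#' The raw imaging object: a time-stamped stack of planar gamma-camera
#' frames acquired after tracer injection. Frames are indexed
#' `(frame, row, col)`; time origin is the injection (`t = 0`) and
#' `frame_start_s` is the leading edge of each frame.
#'
#' @param frames 3-D numeric array `(frame, row, col)` of counts.
#' @param frame_start_s numeric vector, frame start times in seconds
#'   post-injection, strictly increasing; one per frame.
#' @param frame_duration_s numeric vector (or scalar, recycled) of frame
#'   durations in seconds.
#' @param detector `"posterior"` (default analysis view) or `"anterior"`.
#' @return An object of class `dynamic_renogram`.
#' @seealso [validate_study()] for invariant checking, [extract_tac()].
#' @export
dynamic_renogram <- function(frames, frame_start_s, frame_duration_s,
                             detector = c("posterior", "anterior")) {
  detector <- match.arg(detector)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (frame, row, col)")
  }
  n <- dim(frames)[1]
  if (length(frame_duration_s) == 1L) {
    frame_duration_s <- rep(frame_duration_s, n)
  }
  if (length(frame_start_s) != n || length(frame_duration_s) != n) {
    stop("time arrays must have one entry per frame")
  }
  storage.mode(frames) <- "double"
  structure(
    list(frames = frames,
         frame_start_s = as.numeric(frame_start_s),
         frame_duration_s = as.numeric(frame_duration_s),
         detector = detector),
    class = "dynamic_renogram"
  )
}

#' @export
print.dynamic_renogram <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("dynamic_renogram: %d frames of %dx%d (%s view), %g-%g s\n",
              d[1], d[2], d[3], x$detector,
              x$frame_start_s[1],
              x$frame_start_s[d[1]] + x$frame_duration_s[d[1]]))
  invisible(x)
}

#' Named set of regions of interest
#'
#' Binary masks on the frame grid. Recognised roles are `left_kidney`,
#' `right_kidney` and the optional `left_background`, `right_background`
#' used by conventional Gates background subtraction.
#'
#' @param masks named list of logical matrices, all of the frame's
#'   row/col shape.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  roles <- c("left_kidney", "right_kidney",
             "left_background", "right_background")
  if (is.null(names(masks)) || !all(names(masks) %in% roles)) {
    stop("mask roles must be among: ", paste(roles, collapse = ", "))
  }
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be a matrix")
    storage.mode(m) <- "logical"
    m
  })
  structure(list(masks = masks), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  px <- vapply(x$masks, sum, numeric(1))
  cat("roi_set:", paste(sprintf("%s (%d px)", names(px), px),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Patient biometrics
#'
#' Height and weight as recorded before the scan; inputs to body-surface
#' area and kidney-depth estimation.
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return An object of class `patient_biometrics`.
#' @export
patient_biometrics <- function(height_cm, weight_kg) {
  structure(list(height_cm = as.numeric(height_cm),
                 weight_kg = as.numeric(weight_kg)),
            class = "patient_biometrics")
}

#' Syringe counting record
#'
#' Pre-injection full-syringe and post-injection residual (empty-syringe)
#' counts under the camera, from which the net injected count rate is
#' derived. Time offsets allow optional physical decay correction to the
#' injection time.
#'
#' @param full_syringe_counts,full_count_duration_s counts and counting
#'   duration (s) of the full syringe.
#' @param empty_syringe_counts,empty_count_duration_s counts and counting
#'   duration (s) of the emptied syringe (residual activity).
#' @param full_count_time_offset_s seconds the full count was taken
#'   *before* injection (default 0).
#' @param empty_count_time_offset_s seconds the residual count was taken
#'   *after* injection (default 0).
#' @return An object of class `injection_record`.
#' @seealso [net_injected_counts()]
#' @export
injection_record <- function(full_syringe_counts, full_count_duration_s,
                             empty_syringe_counts, empty_count_duration_s,
                             full_count_time_offset_s = 0,
                             empty_count_time_offset_s = 0) {
  structure(
    list(full_syringe_counts = as.numeric(full_syringe_counts),
         full_count_duration_s = as.numeric(full_count_duration_s),
         empty_syringe_counts = as.numeric(empty_syringe_counts),
         empty_count_duration_s = as.numeric(empty_count_duration_s),
         full_count_time_offset_s = as.numeric(full_count_time_offset_s),
         empty_count_time_offset_s = as.numeric(empty_count_time_offset_s)),
    class = "injection_record"
  )
}

#' Dual-sample plasma study
#'
#' Injected dose and two timed plasma counts for the slope-intercept
#' clearance calculation. The dose `D` and the plasma counts must share
#' one counting calibration (same counter geometry and counting time); the
#' draw times are in minutes post-injection.
#'
#' @param D injected dose, counts.
#' @param P1,P2 plasma radioactivity, counts per mL, at `T1_min` and
#'   `T2_min`.
#' @param T1_min,T2_min draw times, minutes post-injection, `T2 > T1 > 0`.
#' @param validate error on invariant violations (default). Disable only
#'   in tests probing degenerate inputs.
#' @return An object of class `plasma_study`.
#' @export
plasma_study <- function(D, P1, P2, T1_min, T2_min, validate = TRUE) {
  obj <- structure(
    list(D = as.numeric(D), P1 = as.numeric(P1), P2 = as.numeric(P2),
         T1_min = as.numeric(T1_min), T2_min = as.numeric(T2_min)),
    class = "plasma_study"
  )
  if (validate) {
    if (obj$D <= 0) stop("injected dose D must be positive")
    if (obj$P2 <= 0 || obj$P1 <= obj$P2) {
      stop("non-decreasing plasma activity: need P1 > P2 > 0")
    }
    if (obj$T1_min <= 0 || obj$T2_min <= obj$T1_min) {
      stop("draw times must satisfy T2 > T1 > 0")
    }
  }
  obj
}

#' Subjects-by-raters measurement table
#'
#' Matrix of one scalar measure (for example a per-kidney GFR) scored by
#' several raters on the same subjects; the input to Kendall's W.
#'
#' @param values numeric matrix, rows = subjects, columns = raters; no
#'   missing cells.
#' @param subject_ids,rater_ids optional identifiers; defaults derived
#'   from dimnames or generated.
#' @return An object of class `rater_table`.
#' @export
rater_table <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 subjects and 2 raters")
  }
  if (anyNA(values)) stop("rater table has missing cells")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(rater_ids)) {
    rater_ids <- colnames(values)
    if (is.null(rater_ids)) rater_ids <- paste0("R", seq_len(ncol(values)))
  }
  stopifnot(length(subject_ids) == nrow(values),
            length(rater_ids) == ncol(values))
  dimnames(values) <- list(subject_ids, rater_ids)
  structure(list(values = values,
                 subject_ids = subject_ids,
                 rater_ids = rater_ids),
            class = "rater_table")
}

#' Validate a complete imaging study
#'
#' Checks every domain invariant of a renogram + ROI + biometrics +
#' injection bundle and *reports* violations rather than raising: the
#' return value is a character vector of violation messages, empty when
#' the study is well formed. The function is pure; inputs are never
#' modified.
#'
#' Checked invariants include: frame/time-array alignment, strictly
#' increasing frame starts, positive durations, non-negative counts;
#' kidney masks non-empty, mutually disjoint and disjoint from background
#' masks, all masks matching the frame grid; biometrics within plausible
#' human ranges (height 50--250 cm, weight 2--300 kg); positive counting
#' durations and a positive net injected count rate.
#'
#' @param renogram a [dynamic_renogram()].
#' @param rois a [roi_set()].
#' @param biometrics a [patient_biometrics()].
#' @param injection an [injection_record()].
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_study <- function(renogram, rois, biometrics, injection) {
  v <- character(0)
  say <- function(...) sprintf(...)

  ## renogram
  d <- dim(renogram$frames)
  n <- d[1]
  if (length(renogram$frame_start_s) != n ||
      length(renogram$frame_duration_s) != n) {
    v <- c(v, "frames and time arrays are not aligned")
  }
  if (any(diff(renogram$frame_start_s) <= 0)) {
    v <- c(v, "frame_start_s is not strictly increasing")
  }
  if (any(renogram$frame_duration_s <= 0)) {
    v <- c(v, "frame_duration_s contains non-positive durations")
  }
  if (any(!is.finite(renogram$frames)) || any(renogram$frames < 0)) {
    v <- c(v, "frames contain negative or non-finite counts")
  }

  ## rois
  shape_ok <- vapply(rois$masks, function(m) all(dim(m) == d[2:3]),
                     logical(1))
  if (!all(shape_ok)) {
    v <- c(v, say("mask(s) %s do not match the %dx%d frame grid",
                  paste(names(rois$masks)[!shape_ok], collapse = ", "),
                  d[2], d[3]))
  }
  for (side in c("left_kidney", "right_kidney")) {
    m <- rois$masks[[side]]
    if (is.null(m)) {
      v <- c(v, say("missing %s mask", side))
    } else if (!any(m)) {
      v <- c(v, say("%s mask is empty", side))
    }
  }
  lk <- rois$masks$left_kidney
  rk <- rois$masks$right_kidney
  if (!is.null(lk) && !is.null(rk) && all(dim(lk) == dim(rk)) &&
      any(lk & rk)) {
    v <- c(v, "kidney masks are not disjoint")
  }
  for (side in c("left", "right")) {
    bg <- rois$masks[[paste0(side, "_background")]]
    if (!is.null(bg) && !is.null(lk) && !is.null(rk) &&
        all(dim(bg) == d[2:3])) {
      if (any(bg & lk) || any(bg & rk)) {
        v <- c(v, say("%s_background overlaps a kidney mask", side))
      }
    }
  }

  ## biometrics
  h <- biometrics$height_cm; w <- biometrics$weight_kg
  if (!is.finite(h) || h <= 0 || h < 50 || h > 250) {
    v <- c(v, "height_cm outside [50, 250]")
  }
  if (!is.finite(w) || w <= 0 || w < 2 || w > 300) {
    v <- c(v, "weight_kg outside [2, 300]")
  }

  ## injection
  if (injection$full_count_duration_s <= 0 ||
      injection$empty_count_duration_s <= 0) {
    v <- c(v, "syringe counting durations must be positive")
  } else {
    if (injection$full_syringe_counts < 0 ||
        injection$empty_syringe_counts < 0) {
      v <- c(v, "syringe counts must be non-negative")
    }
    net <- injection$full_syringe_counts / injection$full_count_duration_s -
      injection$empty_syringe_counts / injection$empty_count_duration_s
    if (!is.finite(net) || net <= 0) {
      v <- c(v, "net injected count rate is not positive")
    }
  }
  v
}
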