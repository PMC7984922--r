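## Directory-based study container: a JSON sidecar (study.json) next to
## plain-text CSV matrices (frames.csv, masks/<role>.csv). All numbers in
## the sidecar are stored as decimal strings at 17 significant digits so
## that serialize -> reload reproduces every field bit-exactly; frame and
## mask matrices are written one frame (or mask row) per line.

num_out <- function(x) {
  if (is.null(x)) return(NULL)
  sprintf("%.17g", as.numeric(x))
}
num_in <- function(x) {
  if (is.null(x)) return(NULL)
  as.numeric(unlist(x))
}

write_num_matrix <- function(m, path) {
  lines <- apply(m, 1, function(row) paste(sprintf("%.17g", row),
                                           collapse = ","))
  writeLines(lines, path)
}

read_num_matrix <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Bundle a complete study
#'
#' Groups the objects describing one imaging study (plus, optionally,
#' its plasma study and the phantom ground truth) for container
#' serialization and the end-to-end runner.
#'
#' @param renogram a [dynamic_renogram()].
#' @param rois a [roi_set()].
#' @param biometrics a [patient_biometrics()].
#' @param injection an [injection_record()].
#' @param plasma optional [plasma_study()].
#' @param truth optional phantom truth (as generated by
#'   [simulate_cohort()]).
#' @return A list of class `renogram_study`.
#' @export
renogram_study <- function(renogram, rois, biometrics, injection,
                           plasma = NULL, truth = NULL) {
  structure(list(renogram = renogram, rois = rois, biometrics = biometrics,
                 injection = injection, plasma = plasma, truth = truth),
            class = "renogram_study")
}

#' Write / read a study container
#'
#' Serializes a [renogram_study()] to a directory holding `study.json`
#' (acquisition timing, detector, biometrics, injection record, optional
#' plasma study and truth; numbers as full-precision decimal strings),
#' `frames.csv` (one frame per line, pixels in column-major order) and
#' one `masks/<role>.csv` per ROI. The round trip is bit-exact.
#'
#' @param study a [renogram_study()].
#' @param dir container directory (created if needed).
#' @return `write_study_container()` returns `dir` invisibly;
#'   `read_study_container()` returns the restored `renogram_study`.
#' @export
write_study_container <- function(study, dir) {
  stopifnot(inherits(study, "renogram_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  reno <- study$renogram
  d <- dim(reno$frames)
  side <- list(
    format = "splitgfr-study/1",
    n_frames = d[1], n_rows = d[2], n_cols = d[3],
    detector = reno$detector,
    frame_start_s = num_out(reno$frame_start_s),
    frame_duration_s = num_out(reno$frame_duration_s),
    biometrics = list(height_cm = num_out(study$biometrics$height_cm),
                      weight_kg = num_out(study$biometrics$weight_kg)),
    injection = lapply(unclass(study$injection), num_out),
    roles = names(study$rois$masks)
  )
  if (!is.null(study$plasma)) {
    side$plasma <- lapply(unclass(study$plasma), num_out)
  }
  if (!is.null(study$truth)) {
    side$truth <- lapply(unclass(study$truth), num_out)
  }
  jsonlite::write_json(side, file.path(dir, "study.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_num_matrix(matrix(reno$frames, nrow = d[1]),
                   file.path(dir, "frames.csv"))
  for (role in names(study$rois$masks)) {
    write_num_matrix(study$rois$masks[[role]] * 1L,
                     file.path(dir, "masks", paste0(role, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_study_container
#' @export
read_study_container <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  if (!identical(side$format, "splitgfr-study/1")) {
    stop("not a splitgfr study container: ", dir)
  }
  nf <- side$n_frames; nr <- side$n_rows; nc <- side$n_cols
  flat <- read_num_matrix(file.path(dir, "frames.csv"))
  stopifnot(nrow(flat) == nf, ncol(flat) == nr * nc)
  reno <- dynamic_renogram(array(flat, dim = c(nf, nr, nc)),
                           num_in(side$frame_start_s),
                           num_in(side$frame_duration_s),
                           side$detector)
  masks <- lapply(side$roles, function(role) {
    read_num_matrix(file.path(dir, "masks", paste0(role, ".csv"))) != 0
  })
  names(masks) <- side$roles
  plasma <- NULL
  if (!is.null(side$plasma)) {
    p <- lapply(side$plasma, num_in)
    plasma <- plasma_study(p$D, p$P1, p$P2, p$T1_min, p$T2_min,
                           validate = FALSE)
  }
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- structure(lapply(side$truth, num_in), class = "phantom_truth")
  }
  renogram_study(reno, roi_set(masks),
                 patient_biometrics(num_in(side$biometrics$height_cm),
                                    num_in(side$biometrics$weight_kg)),
                 do.call(injection_record, lapply(side$injection, num_in)),
                 plasma = plasma, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' One container per subject (`subject_01/`, ...; the true ROI set is
#' written in each container, each rater's ROI masks under
#' `raters/R<k>/`), plus a `truth.csv` table of the generative ground
#' truth.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject = s$id,
               tgfr_true = s$truth$tgfr_true,
               split_fraction_left_true = s$truth$split_fraction_left_true,
               depth_left_cm = s$truth$depth_left_cm,
               depth_right_cm = s$truth$depth_right_cm)
  })
  utils::write.csv(do.call(rbind, truth_rows), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sdir <- file.path(dir, sprintf("subject_%02d", i))
    write_study_container(
      renogram_study(s$renogram, s$rois_true, s$biometrics, s$injection,
                     plasma = s$plasma, truth = s$truth), sdir)
    for (r in seq_along(s$rater_rois)) {
      rdir <- file.path(sdir, "raters", paste0("R", r))
      dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
      for (role in names(s$rater_rois[[r]]$masks)) {
        write_num_matrix(s$rater_rois[[r]]$masks[[role]] * 1L,
                         file.path(rdir, paste0(role, ".csv")))
      }
    }
  }
  invisible(dir)
}
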