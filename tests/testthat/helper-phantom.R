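# Shared fixture builders; everything is generated in code at test time.

# Tiny hand-checkable 2-frame 2x2 renogram
tiny_renogram <- function() {
  a <- array(0, c(2, 2, 2))
  a[1, , ] <- rbind(c(1, 2), c(3, 4))
  a[2, , ] <- rbind(c(5, 6), c(7, 8))
  dynamic_renogram(a, frame_start_s = c(0, 2), frame_duration_s = 2)
}

# Small, fast phantom cohort for unit tests (quarter-resolution matrix)
quick_cohort <- function(n = 3, seed = 1, ...) {
  simulate_cohort(n, seed = seed,
                  acquisition = gates_acquisition(matrix_px = 32), ...)
}

# A well-formed single-study bundle drawn from the phantom
quick_study <- function(seed = 1, ...) {
  s <- quick_cohort(1, seed = seed, ...)$subjects[[1]]
  renogram_study(s$renogram, s$rois_true, s$biometrics, s$injection,
                 plasma = s$plasma, truth = s$truth)
}

# First-principles Kendall's W for tie-free tables via mean pairwise
# Spearman correlation: W = ((m - 1) * mean_rho + 1) / m
spearman_w_oracle <- function(values) {
  m <- ncol(values)
  rho <- stats::cor(values, method = "spearman")
  mean_rho <- mean(rho[upper.tri(rho)])
  ((m - 1) * mean_rho + 1) / m
}
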