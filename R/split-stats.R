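#' Precise per-kidney GFR by apportioning total GFR
#'
#' The core combination step: the blank-background Gates values fix the
#' left:right uptake ratio, and the dual-plasma total GFR fixes the
#' scale:
#'
#' \deqn{pGFR_{left} = \frac{gGFR'_{left}}{gGFR'_{left}+gGFR'_{right}}
#'   \times tGFR}
#'
#' and symmetrically for the right kidney. Conservation
#' `pgfr_left + pgfr_right == tgfr` holds exactly (the right value is
#' computed as the remainder).
#'
#' @param ggfr_left_prime,ggfr_right_prime blank-background per-kidney
#'   Gates GFRs (mL/min); non-negative, not both zero. Only their ratio
#'   matters.
#' @param tgfr total GFR from the dual-plasma method, `>= 0`. Same units
#'   as the desired output (raw or BSA-normalized).
#' @return A list of class `split_gfr_result` with `pgfr_left`,
#'   `pgfr_right`, `tgfr` and `split_fraction_left`.
#' @examples
#' split_pgfr(40, 60, 80)  # left 32, right 48
#' @export
split_pgfr <- function(ggfr_left_prime, ggfr_right_prime, tgfr) {
  if (!is.finite(ggfr_left_prime) || !is.finite(ggfr_right_prime) ||
      ggfr_left_prime < 0 || ggfr_right_prime < 0) {
    stop("blank-background GFRs must be non-negative")
  }
  if (!is.finite(tgfr) || tgfr < 0) stop("tGFR must be non-negative")
  total <- ggfr_left_prime + ggfr_right_prime
  if (total == 0) stop("no renal uptake to apportion")
  split_left <- ggfr_left_prime / total
  pl <- split_left * tgfr
  pr <- tgfr - pl   # guarantees exact conservation
  structure(list(pgfr_left = pl, pgfr_right = pr, tgfr = tgfr,
                 split_fraction_left = split_left),
            class = "split_gfr_result")
}

#' @export
print.split_gfr_result <- function(x, ...) {
  cat(sprintf("pGFR: left %.2f / right %.2f of tGFR %.2f mL/min (split %.1f%% L)\n",
              x$pgfr_left, x$pgfr_right, x$tgfr,
              100 * x$split_fraction_left))
  invisible(x)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement of m raters' rankings of n subjects. Subjects are ranked
#' within each rater (average ranks for ties); with rank sums
#' \eqn{R_i} and \eqn{S = \sum_i (R_i - \bar R)^2},
#'
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j}}
#'
#' where the tie correction \eqn{T_j = \sum (t^3 - t)} runs over tie
#' groups of rater j (dropped when `tie_correct = FALSE`). The
#' significance test is the chi-square approximation
#' \eqn{\chi^2 = m (n-1) W} on `n - 1` degrees of freedom; a permutation
#' p-value (exact by enumeration when feasible, Monte-Carlo otherwise)
#' is available for small tables.
#'
#' A table in which every rater assigns the same value to all subjects
#' carries no ranking information; W is then reported as `NA` with a
#' warning rather than a spurious number.
#'
#' @param table a [rater_table()] (or a bare subjects-by-raters matrix).
#' @param tie_correct apply the tie correction (default `TRUE`).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @return A list of class `concordance_result` with `w`, `chi2`, `df`,
#'   `p_value`, `tie_corrected`, `n_subjects`, `n_raters`.
#' @examples
#' m <- cbind(r1 = c(10, 20, 30), r2 = c(11, 19, 33), r3 = c(25, 21, 30))
#' kendalls_w(rater_table(m))
#' @export
kendalls_w <- function(table, tie_correct = TRUE,
                       p_method = c("chisq", "permutation"),
                       n_perm = 10000) {
  p_method <- match.arg(p_method)
  if (!inherits(table, "rater_table")) table <- rater_table(table)
  x <- table$values
  n <- nrow(x)   # subjects
  m <- ncol(x)   # raters
  ranks <- apply(x, 2, rank)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    warning("all raters assign constant values; W is undefined")
    return(structure(list(w = NA_real_, chi2 = NA_real_, df = n - 1L,
                          p_value = NA_real_, tie_corrected = tie_correct,
                          n_subjects = n, n_raters = m),
                     class = "concordance_result"))
  }
  w_stat <- function(rk) {
    R <- rowSums(rk)
    S <- sum((R - mean(R))^2)
    denom <- m^2 * (n^3 - n)
    if (tie_correct) {
      ties <- sum(apply(rk, 2, function(col) {
        t <- table(col)
        sum(t^3 - t)
      }))
      denom <- denom - m * ties
    }
    if (denom <= 0) return(NA_real_)
    12 * S / denom
  }
  w <- w_stat(ranks)
  chi2 <- m * (n - 1) * w
  p <- switch(
    p_method,
    chisq = stats::pchisq(chi2, df = n - 1, lower.tail = FALSE),
    permutation = perm_p_kendalls_w(ranks, w, tie_correct, n_perm)
  )
  structure(list(w = w, chi2 = chi2, df = n - 1L, p_value = p,
                 tie_corrected = tie_correct, n_subjects = n, n_raters = m),
            class = "concordance_result")
}

## Permutation null for W: rank permutations within raters. Exhaustive
## enumeration when (n!)^(m-1) stays small (W is invariant to a common
## relabeling, so one rater can be held fixed); Monte-Carlo otherwise.
perm_p_kendalls_w <- function(ranks, w_obs, tie_correct, n_perm) {
  n <- nrow(ranks); m <- ncol(ranks)
  stat <- function(rk) {
    R <- rowSums(rk)
    S <- sum((R - mean(R))^2)
    denom <- m^2 * (n^3 - n)
    if (tie_correct) {
      ties <- sum(apply(rk, 2, function(col) { t <- table(col); sum(t^3 - t) }))
      denom <- denom - m * ties
    }
    12 * S / denom
  }
  n_exhaustive <- factorial(n)^(m - 1)
  if (n_exhaustive <= 2e5) {
    perms <- all_permutations(n)
    idx <- rep(list(seq_len(nrow(perms))), m - 1)
    grid <- do.call(expand.grid, idx)
    vals <- vapply(seq_len(nrow(grid)), function(g) {
      rk <- ranks
      for (j in seq_len(m - 1)) {
        rk[, j + 1] <- ranks[perms[grid[g, j], ], j + 1]
      }
      stat(rk)
    }, numeric(1))
    mean(vals >= w_obs - 1e-12)
  } else {
    vals <- vapply(seq_len(n_perm), function(i) {
      rk <- ranks
      for (j in 2:m) rk[, j] <- sample(ranks[, j])
      stat(rk)
    }, numeric(1))
    (sum(vals >= w_obs - 1e-12) + 1) / (n_perm + 1)
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1
    }
  }
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (%d raters, %d subjects; chi2 = %.2f, df = %d, p = %.4g)%s\n",
              x$w, x$n_raters, x$n_subjects, x$chi2, x$df, x$p_value,
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

#' Pearson correlation with significance
#'
#' Standard product-moment correlation between two equal-length vectors,
#' with r^2 and a two-sided p-value from the t distribution on n - 2
#' degrees of freedom. Used to relate the plasma tGFR to biochemical
#' indices (creatinine, cystatin C, urea nitrogen, uric acid).
#'
#' Note r^2 is a square and thus never negative, whatever the sign of r.
#'
#' @param x,y numeric vectors, length >= 3, non-zero variance.
#' @return A list of class `correlation_result` with `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (r^2 = %.3f, n = %d, p = %.4g)\n",
              x$r, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Rater concordance study over per-kidney measurements
#'
#' Assembles a subjects-by-raters table from per-rater results and runs
#' Kendall's W. Each rater contributes a data frame with columns
#' `subject`, `left`, `right` (one scalar per kidney). The default
#' `"stacked"` mode treats left and right kidneys as separate subjects
#' (n = 2 x patients), matching a single concordance coefficient per
#' method over split-kidney values; `"left"`/`"right"` restrict to one
#' side.
#'
#' @param per_rater named list of data frames (`subject`, `left`,
#'   `right`), one per rater, all covering the same subjects.
#' @param stacking `"stacked"`, `"left"` or `"right"`.
#' @param tie_correct passed to [kendalls_w()].
#' @return A `concordance_result` (see [kendalls_w()]), with the
#'   assembled [rater_table()] attached as attribute `table`.
#' @export
rater_study <- function(per_rater, stacking = c("stacked", "left", "right"),
                        tie_correct = TRUE) {
  stacking <- match.arg(stacking)
  if (length(per_rater) < 2) stop("need at least 2 raters")
  ref <- per_rater[[1]]$subject
  for (df in per_rater) {
    if (!identical(as.character(df$subject), as.character(ref))) {
      stop("raters do not cover the same subjects")
    }
  }
  col_for <- function(df) {
    switch(stacking,
           stacked = c(df$left, df$right),
           left = df$left,
           right = df$right)
  }
  values <- vapply(per_rater, col_for, numeric(
    if (stacking == "stacked") 2 * length(ref) else length(ref)))
  subj_ids <- switch(stacking,
                     stacked = c(paste0(ref, ":L"), paste0(ref, ":R")),
                     left = paste0(ref, ":L"),
                     right = paste0(ref, ":R"))
  tab <- rater_table(values, subject_ids = subj_ids,
                     rater_ids = names(per_rater))
  res <- kendalls_w(tab, tie_correct = tie_correct)
  attr(res, "table") <- tab
  res
}
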