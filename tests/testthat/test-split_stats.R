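test_that("pGFR apportioning reproduces direct evaluations", {
  r <- split_pgfr(40, 60, 80)
  expect_equal(r$pgfr_left, 32)
  expect_equal(r$pgfr_right, 48)
  expect_equal(r$split_fraction_left, 0.4)
  ## symmetry and the single-kidney limit
  sym <- split_pgfr(37.3, 37.3, 100)
  expect_identical(sym$pgfr_left, 50)
  expect_identical(sym$pgfr_right, 50)
  single <- split_pgfr(50, 0, 70)
  expect_equal(single$pgfr_left, 70)
  expect_equal(single$pgfr_right, 0)
  expect_error(split_pgfr(0, 0, 70), "no renal uptake")
  expect_error(split_pgfr(-1, 5, 70), "non-negative")
})

test_that("conservation pgfr_left + pgfr_right = tgfr is exact", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      g <- runif(2, 0, 120)
      if (sum(g) == 0) next
      t <- runif(1, 0, 200)
      r <- split_pgfr(g[1], g[2], t)
      expect_lte(abs(r$pgfr_left + r$pgfr_right - t),
                 2 * .Machine$double.eps * t)
    }
  })
})

test_that("Kendall's W matches the hand-computed 3x3 example", {
  ## within-rater rankings (1,2,3), (1,2,3), (2,1,3): S = 14, max = 18
  vals <- cbind(c(1, 2, 3), c(10, 20, 30), c(5, 2, 9))
  res <- kendalls_w(rater_table(vals))
  expect_equal(res$w, 168 / 216, tolerance = 1e-12)
  expect_equal(res$chi2, 3 * 2 * 168 / 216, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value,
               stats::pchisq(res$chi2, 2, lower.tail = FALSE))
})

test_that("W hits its endpoints for perfect agreement and reversal", {
  ident <- matrix(rep(c(3, 1, 4, 2, 5), 4), ncol = 4)
  expect_equal(kendalls_w(rater_table(ident))$w, 1)
  rev2 <- cbind(1:3, 3:1)
  expect_equal(kendalls_w(rater_table(rev2))$w, 0)
})

test_that("W agrees with the Spearman-based oracle on all 2-rater orderings", {
  perms <- splitgfr:::all_permutations(3)
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(perms))) {
      vals <- cbind(perms[i, ], perms[j, ])
      expect_equal(kendalls_w(rater_table(vals))$w,
                   spearman_w_oracle(vals), tolerance = 1e-12)
    }
  }
})

test_that("W is rank-based: invariant to positive scaling and shifts", {
  withr::with_seed(11, {
    vals <- matrix(rnorm(40), 10, 4)
    w0 <- kendalls_w(rater_table(vals))$w
    expect_equal(kendalls_w(rater_table(vals * 3.7))$w, w0)
    expect_equal(kendalls_w(rater_table(vals + 100))$w, w0)
  })
})

test_that("W stays within [0, 1] over random tables", {
  withr::with_seed(12, {
    for (i in 1:200) {
      n <- sample(2:8, 1); m <- sample(2:6, 1)
      vals <- matrix(sample(1:4, n * m, replace = TRUE), n, m)  # many ties
      if (all(apply(vals, 2, function(c) length(unique(c)) == 1))) next
      w <- kendalls_w(rater_table(vals))$w
      expect_true(is.na(w) || (w >= 0 && w <= 1 + 1e-12))
    }
  })
})

test_that("tie-corrected and uncorrected W agree on tie-free tables", {
  withr::with_seed(13, {
    for (i in 1:50) {
      vals <- matrix(rnorm(24), 6, 4)  # continuous: ties a.s. absent
      expect_identical(kendalls_w(rater_table(vals), tie_correct = TRUE)$w,
                       kendalls_w(rater_table(vals), tie_correct = FALSE)$w)
    }
  })
})

test_that("a constant table is flagged as undefined, not NaN", {
  vals <- matrix(5, 4, 3)
  expect_warning(res <- kendalls_w(rater_table(vals)), "undefined")
  expect_true(is.na(res$w))
  expect_false(is.nan(res$w))
})

test_that("permutation p-values are exact for tiny tables", {
  ## two raters in perfect agreement over 3 subjects: 1 of the 6
  ## permutations of one rater attains W = 1
  res <- kendalls_w(rater_table(cbind(1:3, 1:3)), p_method = "permutation")
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)
})

test_that("implementation agrees with vegan's concordance on random tables", {
  skip_if_not_installed("vegan")
  withr::with_seed(14, {
    for (i in 1:10) {
      vals <- matrix(rnorm(30), 10, 3)
      ours <- kendalls_w(rater_table(vals))$w
      ref <- vegan::kendall.global(vals)$Concordance_analysis["W", 1]
      expect_equal(ours, unname(ref), tolerance = 1e-10)
    }
  })
})

test_that("Pearson correlation matches hand Sigma-formula evaluations", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  res <- pearson_r(x, y)
  ## independent oracle from the raw sums
  r_hand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) *
           (sum(y^2) - length(y) * mean(y)^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_equal(res$r_squared, 0.36, tolerance = 1e-12)
  t_stat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), res$n - 2),
               tolerance = 1e-12)

  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_gte(pearson_r(x, -x)$r_squared, 0)
  expect_error(pearson_r(x, rep(1, 4)), "zero variance")
  expect_error(pearson_r(x, y[1:3]), "equal length")
})

test_that("rater_study assembles stacked tables and detects mismatches", {
  mk <- function(l, r) data.frame(subject = c("a", "b", "c"),
                                  left = l, right = r)
  one <- mk(c(10, 20, 30), c(15, 25, 35))
  same <- list(R1 = one, R2 = one, R3 = one, R4 = one, R5 = one)
  res <- rater_study(same)
  expect_equal(res$w, 1)
  expect_equal(res$n_subjects, 6)  # left and right stacked
  expect_equal(attr(res, "table")$subject_ids,
               c("a:L", "b:L", "c:L", "a:R", "b:R", "c:R"))

  ## shuffling one rater strictly lowers concordance
  withr::with_seed(15, {
    shuffled <- same
    shuffled$R5 <- mk(c(30, 10, 20), c(35, 15, 25))
    expect_lt(rater_study(shuffled)$w, res$w)
  })

  bad <- same
  bad$R2$subject <- c("a", "b", "x")
  expect_error(rater_study(bad), "same subjects")

  res_l <- rater_study(same, stacking = "left")
  expect_equal(res_l$n_subjects, 3)
})
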