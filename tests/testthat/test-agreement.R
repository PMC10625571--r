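test_that("bland_altman reproduces hand-computed and degenerate cases", {
  same <- paired_series(c(8.5, 9.2, 10.1, 7.7), c(8.5, 9.2, 10.1, 7.7))
  ba0 <- bland_altman(same)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  expect_equal(ba0$pct_within_loa, 1)

  s <- paired_series(c(11, 12, 13), c(10, 10, 10))  # diffs 1, 2, 3
  ba <- bland_altman(s)
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, 2 - 1.96)
  expect_equal(ba$loa_upper, 2 + 1.96)

  expect_error(paired_series(1:2, 3:4), class = "nariform_too_few_pairs")
})

test_that("bland_altman limits are the closed form and scale with the data", {
  set.seed(41)
  a <- rnorm(50, 10, 2); b <- a + rnorm(50, -0.5, 0.8)
  ba <- bland_altman(paired_series(a, b))
  expect_equal(ba$loa_lower, ba$mean_diff - 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba$loa_upper, ba$mean_diff + 1.96 * ba$sd_diff, tolerance = 1e-12)
  ba3 <- bland_altman(paired_series(3 * a, 3 * b))
  expect_equal(ba3$mean_diff, 3 * ba$mean_diff, tolerance = 1e-12)
  expect_equal(ba3$sd_diff, 3 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba3$loa_upper, 3 * ba$loa_upper, tolerance = 1e-12)
})

test_that("bland_altman recovers a simulated bias with ~95% coverage", {
  set.seed(42)
  n <- 10000
  b <- rnorm(n, 10, 1.5)
  a <- b + rnorm(n, -1.1, 0.5)   # program reads larger than caliper by 1.1 mm
  ba <- bland_altman(paired_series(a, b))
  expect_lt(abs(ba$mean_diff - (-1.1)), 0.02)
  expect_lt(abs(ba$pct_within_loa - 0.95), 0.01)
})

test_that("icc is 1 for perfect agreement and flags constant ratings", {
  x <- c(8.1, 9.4, 10.2, 11.7, 12.3, 7.9)
  r1 <- icc(cbind(x, x))
  expect_equal(r1$icc_estimate, 1)
  expect_equal(r1$category, "excellent")
  expect_false(r1$degenerate)

  rc <- icc(matrix(5, nrow = 6, ncol = 3))
  expect_equal(rc$icc_estimate, 1)
  expect_true(rc$degenerate)

  expect_error(icc(matrix(rnorm(8), 4, 2)), class = "nariform_too_few_subjects")
})

test_that("icc matches an independent ANOVA route on a small matrix", {
  ratings <- rbind(c(9, 2), c(1, 10), c(8, 8), c(6, 4), c(8, 7), c(7, 9))
  res <- icc(ratings)
  # independent oracle: mean squares from stats::aov, variance components,
  # ICC(2,1) = sigma2_subject / (sigma2_subject + sigma2_rater + sigma2_error)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(1:6, times = 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  n <- 6; k <- 2
  s2_subj <- (ms[1] - ms[3]) / k
  s2_rater <- (ms[2] - ms[3]) / n
  s2_err <- ms[3]
  oracle <- s2_subj / (s2_subj + s2_rater + s2_err)
  expect_equal(res$icc_estimate, oracle, tolerance = 1e-9)
  expect_true(res$ci_lower <= res$icc_estimate && res$icc_estimate <= res$ci_upper)
})

test_that("icc recovers the generating reliability and is shift invariant", {
  sim <- simulate_raters(200, 2, subject_sd_mm = 2, error_sd_mm = 1, seed = 5)
  expect_equal(sim$true_icc, 0.8)
  est <- icc(sim$ratings)
  expect_lt(abs(est$icc_estimate - 0.8), 0.05)
  expect_equal(est$category, "good")
  # absolute-agreement ICC is invariant to a shift common to all raters
  shifted <- icc(sim$ratings + 100)
  expect_equal(shifted$icc_estimate, est$icc_estimate, tolerance = 1e-9)
})

test_that("reliability categories follow the left-closed bands", {
  expect_equal(nariform:::icc_category(0.963), "excellent")
  expect_equal(nariform:::icc_category(0.49), "poor")
  expect_equal(nariform:::icc_category(0.5), "moderate")
  expect_equal(nariform:::icc_category(0.75), "good")
  expect_equal(nariform:::icc_category(0.9), "excellent")
})

test_that("paired_compare gates on normality and handles the zero case", {
  z <- paired_compare(paired_series(c(5, 6, 7, 8), c(5, 6, 7, 8)))
  expect_equal(z$p_value, 1)
  expect_false(z$significant)

  set.seed(51)
  a <- rnorm(30, 10); s <- paired_series(a, a + rnorm(30, 0, 1))
  expect_equal(paired_compare(s)$test, "paired_t")

  heavy <- 0
  for (i in 1:50) {
    b <- rnorm(30, 10)
    sc <- paired_series(b + rcauchy(30, 0.3, 1), b)
    heavy <- heavy + (paired_compare(sc)$test == "wilcoxon")
  }
  expect_gt(heavy / 50, 0.8)  # heavy tails route to the rank test
})

test_that("the gated paired test holds its nominal type-I error", {
  set.seed(61)
  rejections <- 0L
  for (i in 1:1000) {
    a <- rnorm(30, 10, 1)
    s <- paired_series(a + rnorm(30, 0, 1), a)
    rejections <- rejections + paired_compare(s)$significant
  }
  expect_lt(abs(rejections / 1000 - 0.05), 0.02)
})

test_that("agreement_report analyses a long-format table per parameter", {
  set.seed(71)
  subj <- sprintf("s%02d", 1:20)
  df <- do.call(rbind, lapply(c("width_R", "height_R"), function(p) {
    direct <- rnorm(20, 8, 1)
    rbind(data.frame(subject_id = subj, parameter = p, method = "direct",
                     value_mm = direct),
          data.frame(subject_id = subj, parameter = p, method = "program",
                     value_mm = direct + rnorm(20, 0.4, 0.5)))
  }))
  rep_ <- agreement_report(df)
  expect_named(rep_, c("width_R", "height_R"))
  expect_s3_class(rep_$width_R$bland_altman, "bland_altman")
  expect_equal(rep_$width_R$bland_altman$n, 20)
  expect_s3_class(rep_$height_R$comparison, "paired_comparison")
  expect_error(agreement_report(df[df$method == "direct", ]),
               class = "nariform_invalid_params")
})
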