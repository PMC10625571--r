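#' Paired measurement series
#'
#' Two methods' measurements of the same quantity on the same subjects,
#' e.g. direct caliper ("method A") vs photograph-derived ("method B")
#' nostril dimensions. Pairs with a missing value must be removed
#' upstream (listwise deletion).
#'
#' @param a,b numeric vectors of equal length (mm).
#' @param subject_ids optional identifiers.
#' @param parameter label, e.g. `"width_R"`.
#' @return A list of class `paired_series`.
#' @export
paired_series <- function(a, b, subject_ids = seq_along(a), parameter = "") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    nf_stop("invalid_params", "paired series must have equal lengths")
  if (length(a) < 3L) nf_stop("too_few_pairs", "need at least 3 pairs, got %d", length(a))
  if (anyNA(a) || anyNA(b)) nf_stop("invalid_params", "missing pairs must be deleted upstream")
  structure(list(a = a, b = b, subject_ids = subject_ids, parameter = parameter),
            class = "paired_series")
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences `a - b` against per-pair means. The bias is the
#' mean difference; the limits of agreement are the bias plus or minus
#' `loa_multiplier` (1.96 by convention) times the sample standard
#' deviation of the differences (n - 1 denominator).
#'
#' @param s a [paired_series()].
#' @param loa_multiplier multiplier for the limits of agreement.
#' @return A list of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `pct_within_loa` and the per-pair
#'   `points` data frame (`mean`, `diff`).
#' @export
bland_altman <- function(s, loa_multiplier = 1.96) {
  stopifnot(inherits(s, "paired_series"))
  d <- s$a - s$b
  bias <- mean(d)
  sdd <- stats::sd(d)
  lo <- bias - loa_multiplier * sdd
  hi <- bias + loa_multiplier * sdd
  structure(list(
    parameter = s$parameter,
    n = length(d),
    mean_diff = bias, sd_diff = sdd,
    loa_lower = lo, loa_upper = hi,
    loa_multiplier = loa_multiplier,
    pct_within_loa = mean(d >= lo & d <= hi),
    points = data.frame(mean = (s$a + s$b) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman %s: n=%d bias=%.3f sd=%.3f LoA=[%.3f, %.3f] within=%.1f%%>\n",
              x$parameter, x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper,
              100 * x$pct_within_loa))
  invisible(x)
}

#' Difference-vs-mean agreement plot
#'
#' @param x a `bland_altman` result.
#' @param ... passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = "mean of methods (mm)", ylab = "difference A - B (mm)",
                 main = x$parameter, ...)
  graphics::abline(h = c(x$loa_lower, x$mean_diff, x$loa_upper),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

icc_category <- function(icc) {
  # reliability bands, left-closed at the boundaries
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate" else if (icc < 0.9) "good" else "excellent"
}

#' Intraclass correlation coefficient for rater reliability
#'
#' Default form is ICC(2,1): two-way random effects, absolute agreement,
#' single measures — the standard form for method/rater agreement when
#' raters are considered a random sample. From the two-way ANOVA mean
#' squares (subjects MSR, raters MSC, residual MSE; n subjects, k raters):
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' ICC(3,1) (two-way mixed, consistency) is available as an option. The
#' 95 percent confidence interval is the standard F-based interval for
#' the chosen form. Reliability categories: below 0.5 poor, 0.5 to 0.75
#' moderate, 0.75 to 0.9 good, 0.9 and above excellent.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @param form `"ICC2_1"` (default) or `"ICC3_1"`.
#' @param conf_level confidence level for the interval.
#' @return A list of class `icc_result` with `icc_estimate`, `ci_lower`,
#'   `ci_upper`, `model`, `category`, the mean squares and a `degenerate`
#'   flag (all cells equal).
#' @export
icc <- function(ratings, form = c("ICC2_1", "ICC3_1"), conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) nf_stop("invalid_params", "ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) nf_stop("too_few_subjects", "need at least 5 subjects, got %d", n)
  if (k < 2L) nf_stop("invalid_params", "need at least 2 raters, got %d", k)
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ss_r <- k * sum((rowm - grand)^2)
  ss_c <- n * sum((colm - grand)^2)
  ss_t <- sum((ratings - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1); msc <- ss_c / (k - 1); mse <- ss_e / ((n - 1) * (k - 1))
  if (ss_t < .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    return(structure(list(icc_estimate = 1, ci_lower = 1, ci_upper = 1,
                          model = form, category = "excellent",
                          msr = msr, msc = msc, mse = mse, n = n, k = k,
                          degenerate = TRUE),
                     class = "icc_result"))
  }
  alpha <- 1 - conf_level
  if (form == "ICC2_1") {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse <= 0) {  # perfect agreement: interval collapses on the estimate
      return(structure(list(icc_estimate = est, ci_lower = est, ci_upper = est,
                            model = form, category = icc_category(est),
                            msr = msr, msc = msc, mse = mse, n = n, k = k,
                            degenerate = FALSE),
                       class = "icc_result"))
    }
    # Shrout-Fleiss F-based interval with Satterthwaite df
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) * (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
    vd <- (n - 1) * k^2 * est^2 * fj^2 + (n * (1 + (k - 1) * est) - k * est)^2
    v <- vn / vd
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f_l - 1) / (f_l + k - 1)
    hi <- (f_u - 1) / (f_u + k - 1)
  }
  structure(list(icc_estimate = est, ci_lower = min(lo, est), ci_upper = max(hi, est),
                 model = form, category = icc_category(est),
                 msr = msr, msc = msc, mse = mse, n = n, k = k,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc %s: %.3f (%.3f-%.3f), %s%s>\n", x$model, x$icc_estimate,
              x$ci_lower, x$ci_upper, x$category,
              if (x$degenerate) ", degenerate (constant ratings)" else ""))
  invisible(x)
}

#' Paired comparison with a normality gate
#'
#' Compares the two methods' central tendency: a Shapiro-Wilk test on the
#' paired differences at `normality_alpha` chooses the route — paired
#' t-test when normality is not rejected, Wilcoxon signed-rank otherwise.
#' All-zero differences are the degenerate "no difference" case and
#' return p = 1 by convention.
#'
#' @param s a [paired_series()].
#' @param alpha significance level for the comparison.
#' @param normality_alpha level of the Shapiro-Wilk gate.
#' @return A list of class `paired_comparison` with the chosen `test`,
#'   `statistic`, two-sided `p_value`, `significant`, and the gate's
#'   `shapiro_p`.
#' @export
paired_compare <- function(s, alpha = 0.05, normality_alpha = 0.05) {
  stopifnot(inherits(s, "paired_series"))
  d <- s$a - s$b
  if (all(d == 0)) {
    return(structure(list(parameter = s$parameter, test = "wilcoxon",
                          statistic = NA_real_, p_value = 1, significant = FALSE,
                          shapiro_p = NA_real_, alpha = alpha,
                          note = "no difference (all paired differences zero)"),
                     class = "paired_comparison"))
  }
  sw <- if (length(unique(d)) > 1L) stats::shapiro.test(d)$p.value else 0
  if (sw >= normality_alpha) {
    ht <- stats::t.test(s$a, s$b, paired = TRUE)
    test <- "paired_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(s$a, s$b, paired = TRUE, exact = FALSE))
    test <- "wilcoxon"
  }
  structure(list(parameter = s$parameter, test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 significant = ht$p.value < alpha, shapiro_p = sw, alpha = alpha,
                 note = NULL),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_compare %s: %s, stat=%.3f, p=%.4f%s>\n", x$parameter, x$test,
              x$statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Agreement report for a long-format measurement table
#'
#' Runs [bland_altman()] and [paired_compare()] per parameter on a
#' long-format table with columns `subject_id`, `parameter`, `method`
#' (exactly two levels; the first sorted level is method A) and
#' `value_mm`. Replicate columns, if present, must be averaged upstream.
#'
#' @param df long-format `data.frame`.
#' @return Named list per parameter, each with `bland_altman` and
#'   `comparison` entries.
#' @export
agreement_report <- function(df) {
  need <- c("subject_id", "parameter", "method", "value_mm")
  if (!all(need %in% names(df)))
    nf_stop("invalid_params", "expected columns: %s", paste(need, collapse = ", "))
  methods <- sort(unique(df$method))
  if (length(methods) != 2L)
    nf_stop("invalid_params", "expected exactly 2 methods, got %d", length(methods))
  out <- list()
  for (p in unique(df$parameter)) {
    sub <- df[df$parameter == p, ]
    wa <- sub[sub$method == methods[1], ]
    wb <- sub[sub$method == methods[2], ]
    common <- intersect(wa$subject_id, wb$subject_id)
    s <- paired_series(wa$value_mm[match(common, wa$subject_id)],
                       wb$value_mm[match(common, wb$subject_id)],
                       subject_ids = common, parameter = p)
    out[[p]] <- list(bland_altman = bland_altman(s), comparison = paired_compare(s))
  }
  out
}
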