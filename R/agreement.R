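#' Interpretation bands for correlation and effect size
#'
#' Correlation strength is banded on the magnitude of r: very strong
#' (>= 0.9), strong (0.7-0.9), moderate (0.5-0.7), weak (0.3-0.5), very
#' weak (< 0.3). Effect sizes are banded on |d|: negligible (< 0.2), small
#' (0.2-0.5), medium (0.5-0.8), large (>= 0.8).
#'
#' @param r,d Correlation coefficient / Cohen's d.
#' @return A single band label.
#' @name interpretation-bands
NULL

#' @rdname interpretation-bands
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  dplyr::case_when(
    a >= 0.9 ~ "very strong",
    a >= 0.7 ~ "strong",
    a >= 0.5 ~ "moderate",
    a >= 0.3 ~ "weak",
    TRUE ~ "very weak")
}

#' @rdname interpretation-bands
#' @export
effect_size_band <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.2 ~ "negligible",
    a < 0.5 ~ "small",
    a < 0.8 ~ "medium",
    TRUE ~ "large")
}

check_pairs <- function(a, b, min_n = 3L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort("The two methods' series must have equal length.",
          class = "lp_config_error")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("Missing values in paired measurements; drop incomplete pairs first.",
          class = "lp_config_error")
  }
  if (length(a) < min_n) {
    abort(sprintf("At least %d pairs are required, got %d.", min_n, length(a)),
          class = "lp_insufficient_data")
  }
  list(a = a, b = b)
}

#' Pearson correlation with interpretation band
#'
#' @param a,b Paired measurements from the two methods (same unit).
#' @return A one-row tibble: `r`, `band` (band applied to |r|).
#' @export
pearson_with_band <- function(a, b) {
  p <- check_pairs(a, b)
  r <- cor(p$a, p$b)
  tibble::tibble(r = r, band = correlation_band(r))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`. The bias is their mean, and the 95% limits of
#' agreement (LoA) are `bias +/- 1.96 * sd(d)` with the sample (n-1)
#' standard deviation. The bias CI uses the t distribution
#' (`sd / sqrt(n)`); the LoA CIs use the standard Bland-Altman standard
#' error `sd * sqrt(1/n + 1.96^2 / (2 (n - 1)))` with the same t quantile.
#'
#' @inheritParams pearson_with_band
#' @param conf_level Confidence level for the CIs.
#' @return One-row tibble: `n`, `bias`, `bias_lo`, `bias_hi`, `sd_diff`,
#'   `loa_lower`, `loa_lower_lo`, `loa_lower_hi`, `loa_upper`,
#'   `loa_upper_lo`, `loa_upper_hi`.
#' @export
bland_altman <- function(a, b, conf_level = 0.95) {
  p <- check_pairs(a, b)
  d <- p$a - p$b
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  loa_l <- bias - 1.96 * s
  loa_u <- bias + 1.96 * s
  tibble::tibble(
    n = n, bias = bias,
    bias_lo = bias - tq * se_bias, bias_hi = bias + tq * se_bias,
    sd_diff = s,
    loa_lower = loa_l, loa_lower_lo = loa_l - tq * se_loa,
    loa_lower_hi = loa_l + tq * se_loa,
    loa_upper = loa_u, loa_upper_lo = loa_u - tq * se_loa,
    loa_upper_hi = loa_u + tq * se_loa)
}

#' Paired t-test between two methods
#'
#' Two-sided paired t-test on the differences `a - b` (delegates to
#' [stats::t.test()]).
#'
#' @inheritParams pearson_with_band
#' @return One-row tibble: `t_stat`, `df`, `p_value`.
#' @export
paired_t <- function(a, b) {
  p <- check_pairs(a, b)
  d <- p$a - p$b
  n <- length(d)
  if (sd(d) == 0) {
    # degenerate differences: identical methods give t = 0, p = 1
    if (mean(d) != 0) {
      abort("Constant non-zero differences: paired t is undefined.",
            class = "lp_degenerate_data")
    }
    return(tibble::tibble(t_stat = 0, df = n - 1, p_value = 1))
  }
  tt <- t.test(p$a, p$b, paired = TRUE)
  tibble::tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Paired Cohen's d
#'
#' The paired-differences convention `d_z = mean(a - b) / sd(a - b)`,
#' with the interpretation band applied to |d|. Degenerate
#' (zero-variance) differences yield `NA` with a warning.
#'
#' @inheritParams pearson_with_band
#' @return One-row tibble: `d`, `band`.
#' @export
cohens_d <- function(a, b) {
  p <- check_pairs(a, b)
  dd <- p$a - p$b
  s <- sd(dd)
  if (s == 0) {
    warn("Zero-variance differences: Cohen's d is undefined.",
         class = "lp_degenerate_data")
    return(tibble::tibble(d = NA_real_, band = NA_character_))
  }
  d <- mean(dd) / s
  tibble::tibble(d = d, band = effect_size_band(d))
}

deming_point <- function(x, y, lambda) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  if (sxy == 0) {
    abort("Zero covariance between methods: Deming slope is undefined.",
          class = "lp_degenerate_data")
  }
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = my - slope * mx)
}

#' Deming (errors-in-variables) regression
#'
#' Fits `y ~ x` allowing measurement error in both variables, with error
#' variance ratio `lambda` (`lambda = 1` is orthogonal regression, the
#' usual assumption when both methods have similar precision). The closed
#' form uses the sample moments; confidence intervals come from a
#' leave-one-out jackknife with a t quantile on n - 2 degrees of freedom
#' (deterministic, no resampling seed).
#'
#' By convention the comparator method is `x` and the method under
#' evaluation is `y`, so a slope above 1 means proportional
#' overestimation by `y`.
#'
#' @param x,y Paired measurements (comparator, evaluated method).
#' @param lambda Ratio of the error variances var(err_y) / var(err_x).
#' @param conf_level Confidence level for the jackknife CIs.
#' @return One-row tibble: `slope`, `slope_lo`, `slope_hi`, `intercept`,
#'   `intercept_lo`, `intercept_hi`, `lambda`, `n`.
#' @export
deming <- function(x, y, lambda = 1, conf_level = 0.95) {
  p <- check_pairs(x, y)
  x <- p$a; y <- p$b
  n <- length(x)
  est <- deming_point(x, y, lambda)
  # O(n) jackknife via moment downdating
  Sx <- sum(x); Sy <- sum(y)
  Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
  loo <- vapply(seq_len(n), function(i) {
    m <- n - 1
    mx <- (Sx - x[i]) / m; my <- (Sy - y[i]) / m
    sxx <- (Sxx - x[i]^2 - m * mx^2) / (m - 1)
    syy <- (Syy - y[i]^2 - m * my^2) / (m - 1)
    sxy <- (Sxy - x[i] * y[i] - m * mx * my) / (m - 1)
    if (sxy == 0) return(c(NA_real_, NA_real_))
    sl <- (syy - lambda * sxx +
             sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
    c(sl, my - sl * mx)
  }, numeric(2))
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  jack_se <- function(theta_i) {
    sqrt((n - 1) / n * sum((theta_i - mean(theta_i))^2))
  }
  se_slope <- jack_se(loo[1, ])
  se_int <- jack_se(loo[2, ])
  tibble::tibble(
    slope = est[["slope"]],
    slope_lo = est[["slope"]] - tq * se_slope,
    slope_hi = est[["slope"]] + tq * se_slope,
    intercept = est[["intercept"]],
    intercept_lo = est[["intercept"]] - tq * se_int,
    intercept_hi = est[["intercept"]] + tq * se_int,
    lambda = lambda, n = n)
}

#' Full two-method agreement report
#'
#' Runs the complete agreement battery on paired per-trial measurements
#' from two methods: Pearson correlation with band, Bland-Altman bias and
#' limits of agreement with CIs, paired t-test, paired Cohen's d with
#' band, and Deming regression (`y = method_a ~ x = method_b`, so
#' `method_b` is the comparator). Fixed bias is flagged when the Deming
#' intercept CI excludes 0; proportional bias when the slope CI
#' excludes 1.
#'
#' @param data A data frame of paired measurements.
#' @param method_a,method_b Columns (tidy-eval) holding the evaluated
#'   method's and the comparator's values, same unit.
#' @param lambda Deming error-variance ratio.
#' @param conf_level Confidence level used throughout.
#' @return An object of class `lp_agreement`; see [tidy.lp_agreement()] and
#'   [glance.lp_agreement()].
#' @examples
#' pairs <- tibble::tibble(vision = c(2.1, 2.4, 1.9, 2.6, 2.2),
#'                         lpt = c(1.9, 2.2, 1.8, 2.4, 2.0))
#' rep <- agreement_report(pairs, vision, lpt)
#' glance(rep)
#' @export
agreement_report <- function(data, method_a, method_b, lambda = 1,
                             conf_level = 0.95) {
  a <- dplyr::pull(data, {{ method_a }})
  b <- dplyr::pull(data, {{ method_b }})
  check_pairs(a, b)
  pr <- pearson_with_band(a, b)
  ba <- bland_altman(a, b, conf_level)
  tt <- paired_t(a, b)
  cd <- cohens_d(a, b)
  dm <- deming(b, a, lambda = lambda, conf_level = conf_level)
  structure(
    list(
      n = length(a), conf_level = conf_level,
      pearson = pr, bland_altman = ba, paired_t = tt, cohens_d = cd,
      deming = dm,
      fixed_bias = dm$intercept_lo > 0 | dm$intercept_hi < 0,
      proportional_bias = dm$slope_lo > 1 | dm$slope_hi < 1,
      a = a, b = b,
      labels = c(a = rlang::as_label(enquo(method_a)), b = rlang::as_label(enquo(method_b)))),
    class = "lp_agreement")
}

#' @export
print.lp_agreement <- function(x, digits = 4, ...) {
  ba <- x$bland_altman; dm <- x$deming
  cat(sprintf("<lp_agreement> %s vs %s (n = %d)\n",
              x$labels[["a"]], x$labels[["b"]], x$n))
  cat(sprintf("  Pearson r      %.*f (%s)\n", digits, x$pearson$r, x$pearson$band))
  cat(sprintf("  Bias (a - b)   %.*f [%.*f, %.*f]\n", digits, ba$bias,
              digits, ba$bias_lo, digits, ba$bias_hi))
  cat(sprintf("  95%% LoA        [%.*f, %.*f]\n", digits, ba$loa_lower,
              digits, ba$loa_upper))
  cat(sprintf("  Paired t       t = %.*f, p = %.4f\n", digits, x$paired_t$t_stat,
              x$paired_t$p_value))
  cat(sprintf("  Cohen's d      %.*f (%s)\n", digits, x$cohens_d$d,
              x$cohens_d$band))
  cat(sprintf("  Deming         slope %.*f [%.*f, %.*f], intercept %.*f [%.*f, %.*f]\n",
              digits, dm$slope, digits, dm$slope_lo, digits, dm$slope_hi,
              digits, dm$intercept, digits, dm$intercept_lo, digits,
              dm$intercept_hi))
  cat(sprintf("  Bias flags     fixed: %s | proportional: %s\n",
              ifelse(x$fixed_bias, "YES", "no"),
              ifelse(x$proportional_bias, "YES", "no")))
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `lp_agreement` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity: `term`,
#'   `estimate`, `conf.low`, `conf.high` (CIs where defined).
#' @method tidy lp_agreement
#' @export
tidy.lp_agreement <- function(x, ...) {
  ba <- x$bland_altman; dm <- x$deming
  tibble::tibble(
    term = c("pearson_r", "bias", "loa_lower", "loa_upper", "t_stat",
             "p_value", "cohens_d", "deming_slope", "deming_intercept"),
    estimate = c(x$pearson$r, ba$bias, ba$loa_lower, ba$loa_upper,
                 x$paired_t$t_stat, x$paired_t$p_value, x$cohens_d$d,
                 dm$slope, dm$intercept),
    conf.low = c(NA, ba$bias_lo, ba$loa_lower_lo, ba$loa_upper_lo, NA, NA,
                 NA, dm$slope_lo, dm$intercept_lo),
    conf.high = c(NA, ba$bias_hi, ba$loa_lower_hi, ba$loa_upper_hi, NA, NA,
                  NA, dm$slope_hi, dm$intercept_hi))
}

#' One-row summary of an agreement report
#'
#' @inheritParams tidy.lp_agreement
#' @return A one-row tibble with the headline statistics and bias flags.
#' @method glance lp_agreement
#' @export
glance.lp_agreement <- function(x, ...) {
  ba <- x$bland_altman; dm <- x$deming
  tibble::tibble(
    n = x$n, pearson_r = x$pearson$r, r_band = x$pearson$band,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
    t_stat = x$paired_t$t_stat, p_value = x$paired_t$p_value,
    cohens_d = x$cohens_d$d, d_band = x$cohens_d$band,
    deming_slope = dm$slope, deming_intercept = dm$intercept,
    fixed_bias = x$fixed_bias, proportional_bias = x$proportional_bias)
}

#' Group-wise agreement reports
#'
#' Runs [agreement_report()] within groups (e.g. per indicator and load)
#' and binds the one-row summaries.
#'
#' @inheritParams agreement_report
#' @param ... Grouping columns (tidy-eval).
#' @return A tibble with the grouping columns plus the
#'   [glance.lp_agreement()] columns, one row per group.
#' @export
agreement_by <- function(data, method_a, method_b, ..., lambda = 1,
                         conf_level = 0.95) {
  data |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(d, key) {
      glance(agreement_report(d, {{ method_a }}, {{ method_b }},
                              lambda = lambda, conf_level = conf_level))
    }) |>
    dplyr::ungroup()
}
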