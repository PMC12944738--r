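#' Published landmine-press method-comparison summaries
#'
#' Summary statistics from a published validation study comparing a
#' vision-based landmine-press measurement system against a linear position
#' transducer over 247 trials at four loads (20, 25, 30, 35 kg), for the
#' four per-repetition indicators (peak/mean velocity in m/s, peak/mean
#' power in W). Differences are vision-based minus transducer. For each
#' load group (including the pooled "all" group) the table carries the
#' printed Bland-Altman bias and 95% limits of agreement together with the
#' printed correlation, p-value, Cohen's d and Deming slope/intercept.
#'
#' These rows serve as a worked example for the cross-table consistency
#' check in [cohens_d_from_loa()]: the effect size is fully determined by
#' the bias and the LoA width under the paired-d convention.
#'
#' @return A 20-row tibble: `load` ("all", "20kg", ...), `indicator`,
#'   `bias`, `loa_lower`, `loa_upper`, `r`, `p_value`, `cohens_d`,
#'   `deming_slope`, `deming_intercept`.
#' @export
vbt_agreement_summaries <- function() {
  tibble::tribble(
    ~load, ~indicator, ~bias, ~loa_lower, ~loa_upper, ~r, ~p_value,
    ~cohens_d, ~deming_slope, ~deming_intercept,
    "all", "peak_velocity",  0.19,  -0.25,   0.64, 0.91, 0.00,  0.86, 1.18,   -0.15,
    "all", "mean_velocity",  0.23,   0.02,   0.45, 0.86, 0.00,  2.10, 1.14,    0.05,
    "all", "peak_power",    18.06, -312.52, 348.63, 0.86, 0.09,  0.11, 1.10,  -59.38,
    "all", "mean_power",    -7.63, -116.18, 100.92, 0.90, 0.03, -0.14, 0.92,   26.20,
    "20kg", "peak_velocity", 0.18,  -0.29,   0.64, 0.92, 0.00,  0.74, 1.12,   -0.08,
    "20kg", "mean_velocity", 0.26,  -0.03,   0.54, 0.91, 0.00,  1.78, 1.11,    0.11,
    "20kg", "peak_power",    7.26, -294.99, 309.52, 0.88, 0.69,  0.05, 0.99,   16.02,
    "20kg", "mean_power",  -19.92, -143.92, 104.07, 0.90, 0.01, -0.32, 0.77,   62.91,
    "25kg", "peak_velocity", 0.23,  -0.27,   0.72, 0.87, 0.00,  0.90, 1.27,   -0.35,
    "25kg", "mean_velocity", 0.24,   0.02,   0.46, 0.91, 0.00,  2.16, 1.05,    0.18,
    "25kg", "peak_power",   30.10, -285.51, 345.70, 0.83, 0.14,  0.19, 1.20, -133.39,
    "25kg", "mean_power",  -13.09, -116.78,  90.61, 0.89, 0.05, -0.25, 0.81,   66.51,
    "30kg", "peak_velocity", 0.13,  -0.17,   0.43, 0.93, 0.00,  0.87, 1.15,   -0.14,
    "30kg", "mean_velocity", 0.21,   0.05,   0.37, 0.94, 0.00,  2.54, 1.18,   -0.01,
    "30kg", "peak_power",  -27.90, -309.70, 253.91, 0.83, 0.15, -0.19, 1.04,  -55.85,
    "30kg", "mean_power",  -13.48, -117.57,  90.62, 0.87, 0.06, -0.25, 1.00,  -13.79,
    "35kg", "peak_velocity", 0.24,  -0.21,   0.69, 0.90, 0.00,  1.04, 1.26,   -0.23,
    "35kg", "mean_velocity", 0.22,   0.07,   0.38, 0.95, 0.00,  2.78, 1.07,    0.13,
    "35kg", "peak_power",   64.35, -337.25, 465.94, 0.85, 0.02,  0.31, 1.12,  -38.47,
    "35kg", "mean_power",   20.18,  -56.30,  96.66, 0.94, 0.00,  0.52, 0.99,   24.26)
}

#' Cohen's d reconstructed from Bland-Altman summaries
#'
#' Under the paired-differences convention `d_z = mean(d) / sd(d)`, the
#' effect size is fully determined by a Bland-Altman summary: the LoA span
#' `1.96 * sd` on either side of the bias, so
#' `sd_diff = (loa_upper - loa_lower) / (2 * 1.96)` and
#' `d = bias / sd_diff`. This lets published agreement tables be checked
#' for internal consistency without the raw trials.
#'
#' @param data A data frame with bias and LoA columns (e.g.
#'   [vbt_agreement_summaries()]).
#' @param bias,loa_lower,loa_upper Columns (tidy-eval) holding the printed
#'   bias and limits of agreement.
#' @return The input with `sd_diff` and `d_from_loa` appended.
#' @examples
#' vbt_agreement_summaries() |> cohens_d_from_loa()
#' @export
cohens_d_from_loa <- function(data, bias = bias, loa_lower = loa_lower,
                              loa_upper = loa_upper) {
  data |>
    dplyr::mutate(
      sd_diff = (({{ loa_upper }}) - ({{ loa_lower }})) / (2 * 1.96),
      d_from_loa = ({{ bias }}) / .data$sd_diff)
}
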