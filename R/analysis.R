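#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, the two-sided p-value is the sum of
#' hypergeometric point probabilities of all tables no more probable than the
#' observed one (the point-probability convention), with a small relative
#' slack (1e-7) absorbing floating-point ties. An empty margin admits a
#' single possible table, so p = 1 by convention (with a message).
#'
#' @param a,b Events and non-events in the first group.
#' @param c,d Events and non-events in the second group.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(3, 17, 1, 16) # day-14 mortality style counts
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    rlang::inform("degenerate margin: single possible table, p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param x,y Numeric samples, non-empty.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Group-comparison table (counts/medians with exact and rank tests)
#'
#' Emits one row per requested variable in the shape of a trial baseline or
#' outcome table: binary variables as n (%) per arm with a two-sided Fisher
#' exact p-value; continuous variables as median \[IQR\] per arm with a
#' Wilcoxon rank-sum p-value. IQRs are 25th/75th percentiles with linear
#' interpolation. All-missing columns yield a row of missing markers.
#'
#' @param data Per-patient tibble containing `arm` plus the variables.
#' @param binary_vars Character vector of logical/0-1 columns.
#' @param continuous_vars Character vector of numeric columns.
#' @param arms Length-2 character vector naming the comparison order,
#'   default `c("standard", "individualized")`.
#' @return Tibble: `variable`, `type`, one summary column per arm, `p_value`.
#' @export
summarize_groups <- function(data, binary_vars = character(0),
                             continuous_vars = character(0),
                             arms = c("standard", "individualized")) {
  stopifnot("arm" %in% names(data), all(arms %in% data$arm))
  g1 <- data[data$arm == arms[1], , drop = FALSE]
  g2 <- data[data$arm == arms[2], , drop = FALSE]
  fmt_pct <- function(v) {
    v <- as.logical(v); v <- v[!is.na(v)]
    sprintf("%d (%.0f%%)", sum(v), 100 * mean(v))
  }
  fmt_med <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_character_)
    q <- stats::quantile(v, c(.25, .5, .75), names = FALSE)
    sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
  }
  rows <- list()
  for (v in binary_vars) {
    x1 <- as.logical(g1[[v]]); x2 <- as.logical(g2[[v]])
    p <- if (all(is.na(x1)) || all(is.na(x2))) NA_real_ else {
      fisher_exact_two_sided(sum(x1, na.rm = TRUE), sum(!x1, na.rm = TRUE),
                             sum(x2, na.rm = TRUE), sum(!x2, na.rm = TRUE))
    }
    rows[[v]] <- tibble::tibble(variable = v, type = "binary",
                                !!arms[1] := fmt_pct(x1),
                                !!arms[2] := fmt_pct(x2), p_value = p)
  }
  for (v in continuous_vars) {
    x1 <- g1[[v]][is.finite(g1[[v]])]; x2 <- g2[[v]][is.finite(g2[[v]])]
    p <- if (!length(x1) || !length(x2)) NA_real_ else wilcoxon_rank_sum(x1, x2)
    rows[[v]] <- tibble::tibble(variable = v, type = "continuous",
                                !!arms[1] := fmt_med(g1[[v]]),
                                !!arms[2] := fmt_med(g2[[v]]), p_value = p)
  }
  dplyr::bind_rows(rows)
}

#' Random-intercept mixed model for repeated hemodynamic measures
#'
#' Fits, by restricted maximum likelihood, the repeated-measures model with a
#' random intercept per participant and fixed effects for treatment, days
#' from vasopressor initiation (T0) to randomization, days since
#' randomization, and the treatment-by-time interaction:
#' `outcome ~ treatment + days_t0_to_rand + days_since_rand +
#' treatment:days_since_rand + (1 | patient_id)`.
#' Wald 95% CIs are reported for the fixed effects. A singular fit is
#' flagged and refit by maximum likelihood with a warning. Only non-missing
#' observations are used.
#'
#' @param long Patient-day tibble with `patient_id`, `treatment` (0/1 or
#'   logical; 1 = individualized), `days_t0_to_rand`, `days_since_rand`,
#'   and the outcome column.
#' @param outcome Name of the outcome column (string).
#' @return Tibble of fixed effects: `term`, `estimate`, `se`, `conf_low`,
#'   `conf_high`; attribute `singular` records a singular-fit fallback.
#' @export
fit_lmm <- function(long, outcome) {
  stopifnot(outcome %in% names(long),
            all(c("patient_id", "treatment", "days_t0_to_rand",
                  "days_since_rand") %in% names(long)))
  dat <- long[is.finite(long[[outcome]]), , drop = FALSE]
  stopifnot(length(unique(dat$patient_id[dat$treatment == 0])) >= 2,
            length(unique(dat$patient_id[dat$treatment == 1])) >= 2)
  form <- stats::as.formula(paste(
    outcome, "~ treatment + days_t0_to_rand + days_since_rand +",
    "treatment:days_since_rand + (1 | patient_id)"))
  fit <- lme4::lmer(form, data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    rlang::warn("singular random-effects fit; refitting by maximum likelihood")
    fit <- lme4::lmer(form, data = dat, REML = FALSE)
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        se = unname(se),
                        conf_low = unname(est - z * se),
                        conf_high = unname(est + z * se))
  attr(out, "singular") <- singular
  out
}

#' Sample size for comparing two proportions (with attrition)
#'
#' Classical two-proportion formula with pooled variance under the null and
#' unpooled variance under the alternative:
#' `n = (z_{1-a/2} sqrt(2 pbar qbar) + z_{1-b} sqrt(p1 q1 + p2 q2))^2 /
#' (p1 - p2)^2` per group. The unrounded total `2n` is inflated by
#' `1 / (1 - attrition)` and then rounded up once, to an integer total.
#' z-quantiles are used at full double precision.
#'
#' @param p1,p2 Event proportions under control and intervention.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.80.
#' @param attrition Anticipated attrition fraction, default 0.
#' @return Total sample size (integer, both groups combined).
#' @examples
#' sample_size_two_proportions(0.20, 0.14, attrition = 0.025) # 1260
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                        attrition = 0) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            attrition >= 0, attrition < 1, p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  if (p1 == p2) {
    rlang::abort("p1 and p2 must differ", class = "mapdeficit_contract_error")
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(2 * n / (1 - attrition)))
}

#' Sample size for comparing two means
#'
#' `n = 2 (z_{1-a/2} + z_{1-b})^2 sd^2 / delta^2` per group, rounded up.
#'
#' @param delta Absolute difference in means to detect (outcome units).
#' @param sd Common standard deviation (outcome units).
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power, default 0.80.
#' @return List with `per_group` and `total`.
#' @examples
#' sample_size_two_means(8, 9) # per-group 20, total 40
#' @export
sample_size_two_means <- function(delta, sd, alpha = 0.05, power = 0.80) {
  stopifnot(sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (delta == 0) {
    rlang::abort("delta must be non-zero", class = "mapdeficit_contract_error")
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- ceiling(2 * (za + zb)^2 * sd^2 / delta^2)
  list(per_group = as.integer(n), total = as.integer(2 * n))
}

#' Daily group means with 95% confidence intervals
#'
#' Per T0-anchored 24-h day and arm: the mean of the patient-day values with
#' a t-based 95% confidence interval. A singleton cell reports the mean with
#' missing CI bounds; days with no data are absent.
#'
#' @param long Patient-day tibble with `arm`, `day` and the outcome column.
#' @param outcome Name of the outcome column (string).
#' @return Tibble: `day`, `arm`, `n`, `mean`, `conf_low`, `conf_high`.
#' @export
daily_group_means <- function(long, outcome) {
  stopifnot(all(c("arm", "day") %in% names(long)), outcome %in% names(long))
  long |>
    dplyr::filter(is.finite(.data[[outcome]])) |>
    dplyr::group_by(.data$day, .data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[outcome]]),
      sem = stats::sd(.data[[outcome]]) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(.data$n >= 2,
                    stats::qt(0.975, pmax(.data$n - 1, 1)) * .data$sem,
                    NA_real_),
      conf_low = .data$mean - .data$half,
      conf_high = .data$mean + .data$half
    ) |>
    dplyr::select("day", "arm", "n", "mean", "conf_low", "conf_high")
}

#' Patient-day long table for repeated-measures models
#'
#' Averages the 4-hourly vitals within each T0-anchored 24-h day and joins
#' arm, timing covariates, per-day MAP extremes, the percentage deficit, and
#' (when a labs table is supplied) the daily peak creatinine. This is the
#' long format consumed by [fit_lmm()] and [daily_group_means()].
#'
#' @param vitals Vitals long tibble (see [read_vitals()]).
#' @param cohort Cohort tibble with `patient_id`, `arm`, `pre_illness_map`,
#'   `randomization_delay_h`.
#' @param labs Optional labs tibble (see [read_labs()]).
#' @return Tibble with one row per patient-day: `patient_id`, `arm`,
#'   `treatment` (1 = individualized), `day`, `days_t0_to_rand`,
#'   `days_since_rand`, `pct_deficit`, `achieved_map`, `vasopressor_dose`,
#'   `daily_highest`, `daily_lowest`, and `daily_peak_creatinine` if labs
#'   are given.
#' @export
build_daily_long <- function(vitals, cohort, labs = NULL) {
  stopifnot(all(c("patient_id", "arm", "pre_illness_map",
                  "randomization_delay_h") %in% names(cohort)))
  out <- vitals |>
    dplyr::inner_join(
      cohort[c("patient_id", "arm", "pre_illness_map", "randomization_delay_h")],
      by = "patient_id") |>
    dplyr::filter(is.finite(.data$map_mmHg)) |>
    dplyr::mutate(day = floor(.data$t_hours / 24) + 1L) |>
    dplyr::group_by(.data$patient_id, .data$arm, .data$day) |>
    dplyr::summarise(
      pct_deficit = mean(deficit_at(.data$pre_illness_map[1], .data$map_mmHg)),
      achieved_map = mean(.data$map_mmHg),
      vasopressor_dose = mean(.data$ne_dose_ug_kg_min, na.rm = TRUE),
      daily_highest = max(.data$map_mmHg),
      daily_lowest = min(.data$map_mmHg),
      days_t0_to_rand = .data$randomization_delay_h[1] / 24,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      treatment = as.integer(.data$arm == "individualized"),
      days_since_rand = .data$day - .data$days_t0_to_rand,
      vasopressor_dose = ifelse(is.nan(.data$vasopressor_dose), NA_real_,
                                .data$vasopressor_dose)
    )
  if (!is.null(labs)) {
    out <- dplyr::left_join(
      out,
      dplyr::rename(labs[c("patient_id", "day_index", "peak_creatinine_umol_l")],
                    day = "day_index",
                    daily_peak_creatinine = "peak_creatinine_umol_l"),
      by = c("patient_id", "day"))
  }
  out
}
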