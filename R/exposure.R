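#' Active treatment window from vasopressor epochs
#'
#' Hemodynamic data contribute to exposure metrics from T0 until the patient
#' is weaned off vasopressor support for at least 24 h, or until 5 days
#' (120 h) from T0, whichever is earlier. A vasopressor-free gap shorter than
#' 24 h followed by a restart keeps the window open.
#'
#' @param epochs Data frame or matrix-like with columns `start_h`, `stop_h`
#'   (hours since T0), time-ordered.
#' @param cap_hours Maximum window length, default 120.
#' @return Numeric `c(start_h, end_h)`; the start is always 0 (T0).
#' @export
active_window <- function(epochs, cap_hours = 120) {
  if (is.null(epochs) || nrow(epochs) == 0) {
    rlang::abort("no vasopressor epochs: active window undefined",
                 class = "mapdeficit_empty_window")
  }
  stopifnot(all(c("start_h", "stop_h") %in% names(epochs)),
            all(epochs$stop_h >= epochs$start_h), all(epochs$start_h >= 0))
  end <- epochs$stop_h[1]
  for (i in seq_len(nrow(epochs))[-1]) {
    if (epochs$start_h[i] - end >= 24) break # weaned >= 24 h: window closed
    end <- max(end, epochs$stop_h[i])
  }
  c(0, min(cap_hours, end))
}

#' Percentage MAP-deficit
#'
#' The relative-hypotension measure: the percentage shortfall of the achieved
#' MAP relative to the patient's pre-illness MAP,
#' `100 * (pre-illness MAP - achieved MAP) / pre-illness MAP`. The value is
#' signed: it is negative whenever the achieved MAP exceeds the pre-illness
#' MAP. Clamping to the positive part happens only inside the time-weighted
#' integral ([twa_map_deficit()]).
#'
#' @param pre_illness_map Pre-illness MAP, mmHg (> 0).
#' @param map Achieved MAP, mmHg. Vectorised.
#' @return Signed percentage deficit.
#' @export
deficit_at <- function(pre_illness_map, map) {
  if (any(!is.finite(pre_illness_map)) || any(pre_illness_map <= 0)) {
    rlang::abort("pre-illness MAP must be positive",
                 class = "mapdeficit_contract_error")
  }
  100 * (pre_illness_map - map) / pre_illness_map
}

#' Time-weighted average MAP-deficit (positive incremental AUC)
#'
#' Treats the percentage deficit as a piecewise-linear signal between
#' observations, integrates only its positive part -- zero-crossings are
#' located exactly within each segment, not by clamping the sampled values --
#' and divides by the total observed duration (first to last observation).
#' This is the positive incremental area-under-the-curve of the MAP-deficit
#' during vasopressor therapy, expressed as an average percentage.
#'
#' @param t Observation times, hours since T0, strictly increasing.
#' @param map Observed MAP, mmHg (NA observations are dropped).
#' @param pre_illness_map Pre-illness MAP, mmHg.
#' @return Percentage (>= 0). A single observation returns
#'   `max(0, deficit)` at that point.
#' @export
twa_map_deficit <- function(t, map, pre_illness_map) {
  keep <- is.finite(t) & is.finite(map)
  t <- t[keep]; map <- map[keep]
  if (length(t) == 0) {
    rlang::abort("empty MAP series", class = "mapdeficit_empty_series")
  }
  stopifnot(!is.unsorted(t, strictly = TRUE))
  d <- deficit_at(pre_illness_map, map)
  if (length(t) == 1) return(max(0, d))
  d1 <- d[-length(d)]; d2 <- d[-1]
  dt <- diff(t)
  area <- numeric(length(dt))
  both_pos <- d1 >= 0 & d2 >= 0
  area[both_pos] <- (d1[both_pos] + d2[both_pos]) / 2 * dt[both_pos]
  down <- d1 > 0 & d2 < 0 # crossing: positive triangle before the zero
  area[down] <- dt[down] * d1[down]^2 / (2 * (d1[down] - d2[down]))
  up <- d1 < 0 & d2 > 0
  area[up] <- dt[up] * d2[up]^2 / (2 * (d2[up] - d1[up]))
  sum(area) / (t[length(t)] - t[1])
}

# Shared interval engine for the threshold-time fractions: classifies each
# inter-observation interval by its left endpoint (last observation carried
# forward); intervals adjacent to a missing observation drop out of both the
# numerator and the denominator.
pct_time_classified <- function(t, value, classify) {
  if (sum(is.finite(t)) < 2) return(NA_real_)
  stopifnot(!is.unsorted(t[is.finite(t)], strictly = TRUE))
  n <- length(t)
  left_ok <- is.finite(value[-n])
  right_ok <- is.finite(value[-1])
  usable <- left_ok & right_ok
  if (!any(usable)) return(NA_real_)
  dt <- diff(t)[usable]
  flagged <- classify(value[-n][usable])
  100 * sum(dt[flagged]) / sum(dt)
}

#' Percentage of time with MAP-deficit above a threshold
#'
#' `100 * sum(time-periods with deficit > threshold) / total time with
#' available MAP data`. Each inter-observation interval is classified by the
#' deficit at its left endpoint; intervals touching a missing observation are
#' excluded from numerator and denominator alike.
#'
#' @inheritParams twa_map_deficit
#' @param threshold Deficit threshold in percent, default 20.
#' @return Percentage in `[0, 100]`, or `NA` with fewer than two
#'   observations.
#' @export
pct_time_deficit_above <- function(t, map, pre_illness_map, threshold = 20) {
  d <- deficit_at(pre_illness_map, map) # NA maps propagate to NA deficits
  pct_time_classified(t, d, function(x) x > threshold)
}

#' Percentage of time with MAP below a cutoff
#'
#' `100 * sum(time-periods with MAP < cutoff) / total time with available MAP
#' data`, under the same left-endpoint interval convention as
#' [pct_time_deficit_above()].
#'
#' @inheritParams twa_map_deficit
#' @param cutoff MAP cutoff in mmHg, default 65.
#' @return Percentage in `[0, 100]`, or `NA` with fewer than two
#'   observations.
#' @export
pct_time_map_below <- function(t, map, cutoff = 65) {
  pct_time_classified(t, map, function(x) x < cutoff)
}

#' Achieved MAP: time-weighted average of the 4-hourly values
#'
#' The trapezoidal time-weighted mean of the MAP signal over the observed
#' span of the active treatment period.
#'
#' @inheritParams twa_map_deficit
#' @return mmHg. A single observation returns that value.
#' @export
achieved_map <- function(t, map) {
  keep <- is.finite(t) & is.finite(map)
  t <- t[keep]; map <- map[keep]
  if (length(t) == 0) {
    rlang::abort("empty MAP series", class = "mapdeficit_empty_series")
  }
  stopifnot(!is.unsorted(t, strictly = TRUE))
  if (length(t) == 1) return(map)
  dt <- diff(t)
  sum((map[-length(map)] + map[-1]) / 2 * dt) / (t[length(t)] - t[1])
}

#' Daily highest and lowest MAP
#'
#' Days are consecutive 24-h windows anchored at T0 (day 1 = hours 0 to 24).
#' Days with no observation are absent from the output.
#'
#' @inheritParams twa_map_deficit
#' @return Tibble with `day`, `highest_map`, `lowest_map`.
#' @export
daily_extremes <- function(t, map) {
  keep <- is.finite(t) & is.finite(map)
  t <- t[keep]; map <- map[keep]
  if (length(t) == 0) {
    return(tibble::tibble(day = integer(0), highest_map = numeric(0),
                          lowest_map = numeric(0)))
  }
  day <- floor(t / 24) + 1L
  out <- tibble::tibble(day = day, map = map) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(highest_map = max(.data$map),
                     lowest_map = min(.data$map), .groups = "drop")
  out
}

#' Joint deficit-category and vasopressor-escalation occupancy profile
#'
#' Classifies each inter-observation interval by the deficit at its left
#' endpoint into `<10`, `10-20` or `>20` percent, crossed with whether the
#' norepinephrine-equivalent dose was escalated over the interval (dose at the
#' right observation strictly greater than at the left). Occupancies are
#' percentages of the classified time and sum to 100. Intervals with a
#' missing dose at either end are excluded from numerator and denominator.
#'
#' @inheritParams twa_map_deficit
#' @param ne_dose Norepinephrine-equivalent dose, ug/kg/min, per observation.
#' @return Tibble with `deficit_bin`, `escalation`, `pct_time`.
#' @export
deficit_profile <- function(t, map, ne_dose, pre_illness_map) {
  stopifnot(length(t) >= 2, length(map) == length(t),
            length(ne_dose) == length(t))
  n <- length(t)
  ok <- is.finite(map[-n]) & is.finite(map[-1]) &
    is.finite(ne_dose[-n]) & is.finite(ne_dose[-1])
  dt <- diff(t)[ok]
  d_left <- deficit_at(pre_illness_map, map[-n])[ok]
  esc <- (ne_dose[-1] > ne_dose[-n])[ok]
  bins <- c("<10", "10-20", ">20")
  bin <- cut(d_left, breaks = c(-Inf, 10, 20, Inf), labels = bins, right = FALSE)
  # right = FALSE puts exactly 10 in the middle bin; exactly 20 must also sit
  # in the middle bin (">20" is strict), so shift the upper edge:
  bin[d_left == 20] <- "10-20"
  grid <- tidyr::expand_grid(deficit_bin = factor(bins, levels = bins),
                             escalation = c(FALSE, TRUE))
  obs <- tibble::tibble(deficit_bin = bin, escalation = esc, dt = dt) |>
    dplyr::group_by(.data$deficit_bin, .data$escalation) |>
    dplyr::summarise(time = sum(.data$dt), .groups = "drop")
  out <- dplyr::left_join(grid, obs, by = c("deficit_bin", "escalation")) |>
    dplyr::mutate(time = dplyr::coalesce(.data$time, 0))
  total <- sum(out$time)
  out$pct_time <- if (total > 0) 100 * out$time / total else NA_real_
  out[c("deficit_bin", "escalation", "pct_time")]
}

#' Per-patient exposure summary over a vitals table
#'
#' Computes, for every patient, the relative-hypotension exposure metrics
#' over the active treatment window: time-weighted average MAP-deficit,
#' percentage of time with deficit above 20%, percentage of time with
#' MAP below 65 mmHg, achieved MAP, and the total observed duration.
#'
#' @param vitals Long tibble: `patient_id`, `t_hours`, `map_mmHg`,
#'   `ne_dose_ug_kg_min` (4-hourly, T0-anchored).
#' @param cohort Cohort tibble with `patient_id` and `pre_illness_map`.
#' @return One row per patient with the exposure metrics; column names are
#'   stable across runs.
#' @export
exposure_summary <- function(vitals, cohort) {
  stopifnot(all(c("patient_id", "t_hours", "map_mmHg") %in% names(vitals)),
            all(c("patient_id", "pre_illness_map") %in% names(cohort)))
  vitals |>
    dplyr::inner_join(cohort[c("patient_id", "pre_illness_map")],
                      by = "patient_id") |>
    dplyr::arrange(.data$patient_id, .data$t_hours) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      twa_map_deficit = twa_map_deficit(.data$t_hours, .data$map_mmHg,
                                        .data$pre_illness_map[1]),
      pct_time_deficit_gt20 = pct_time_deficit_above(
        .data$t_hours, .data$map_mmHg, .data$pre_illness_map[1]),
      pct_time_map_lt65 = pct_time_map_below(.data$t_hours, .data$map_mmHg),
      achieved_map = achieved_map(.data$t_hours, .data$map_mmHg),
      total_observed_hours = max(.data$t_hours) - min(.data$t_hours),
      .groups = "drop"
    )
}

#' Expected time-average positive-part deficit under a stationary normal MAP
#'
#' For a MAP process that is stationary normal, the deficit signal is
#' `D ~ N(d, s)` (in percent), and the long-run time average of its positive
#' part is `E[max(0, D)] = d * pnorm(d/s) + s * dnorm(d/s)`. Used to state
#' the generator-implied (configured) exposure when validating parameter
#' recovery of the simulation pipeline.
#'
#' @param d Mean percentage deficit.
#' @param s Standard deviation of the percentage deficit.
#' @return Expected positive-part deficit, percent.
#' @export
expected_twa_deficit <- function(d, s) {
  ifelse(s <= 0, pmax(0, d), d * stats::pnorm(d / s) + s * stats::dnorm(d / s))
}

#' Read a vitals long table
#'
#' Tab-delimited text: `patient_id`, `t_hours`, `map_mmHg`,
#' `ne_dose_ug_kg_min`; empty fields are missing values. Hours are numeric,
#' T0-anchored, 0-based.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_vitals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    t_hours = readr::col_double(),
                    map_mmHg = readr::col_double(),
                    ne_dose_ug_kg_min = readr::col_double()
                  ))
}
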