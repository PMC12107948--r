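#' Mean arterial pressure from a cuff reading
#'
#' Converts a systolic/diastolic blood-pressure reading to mean arterial
#' pressure using the standard one-third pulse-pressure approximation,
#' `MAP = DBP + (SBP - DBP) / 3`. The result is unrounded.
#'
#' @param systolic Systolic pressure, mmHg. Must exceed `diastolic`.
#' @param diastolic Diastolic pressure, mmHg. Must be positive.
#' @return MAP in mmHg (numeric, same length as the inputs).
#' @examples
#' map_from_bp(120, 60) # 80
#' map_from_bp(135, 75) # 95
#' @export
map_from_bp <- function(systolic, diastolic) {
  if (any(!is.finite(systolic)) || any(!is.finite(diastolic))) {
    rlang::abort("blood-pressure values must be finite", class = "mapdeficit_invalid_reading")
  }
  if (any(diastolic <= 0) || any(systolic <= diastolic)) {
    rlang::abort(
      "require systolic > diastolic > 0 for every reading",
      class = "mapdeficit_invalid_reading"
    )
  }
  diastolic + (systolic - diastolic) / 3
}

#' Select qualifying pre-illness blood-pressure readings
#'
#' Applies the tracing rules for historical (usual-health) BP readings:
#' keep only readings from the 3 years before `screening_time`, prefer
#' clinic-type sources over readings charted during a prior hospitalization,
#' walk backwards from the most recent reading keeping a reading only when it
#' is at least 12 h from every reading already kept, and stop at 5 readings.
#' Hospital-chart readings are considered only when fewer than two clinic-type
#' readings qualify on their own.
#'
#' @param readings Data frame with columns `timestamp` (POSIXct), `sbp`,
#'   `dbp` (mmHg) and `source` (one of [bp_sources()]).
#' @param screening_time POSIXct screening instant.
#' @param min_spacing_hours Minimum spacing between kept readings (default 12).
#' @param max_readings Maximum number kept (default 5).
#' @param window_years Look-back horizon (default 3).
#' @return The selected rows, most recent first (2 to `max_readings` rows).
#'   Fewer than two qualifying readings is an error of class
#'   `mapdeficit_insufficient_readings` (the trial's "insufficient pre-morbid
#'   BP readings" exclusion).
#' @export
select_preillness_readings <- function(readings, screening_time,
                                       min_spacing_hours = 12,
                                       max_readings = 5,
                                       window_years = 3) {
  stopifnot(is.data.frame(readings),
            all(c("timestamp", "sbp", "dbp", "source") %in% names(readings)))
  horizon <- screening_time - as.difftime(window_years * 365.25, units = "days")
  ok <- readings$timestamp <= screening_time & readings$timestamp >= horizon
  pool <- readings[ok, , drop = FALSE]

  pick <- function(rows) {
    rows <- rows[order(rows$timestamp, decreasing = TRUE), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(rows))) {
      gaps <- abs(as.numeric(difftime(rows$timestamp[i], rows$timestamp[kept],
                                      units = "hours")))
      if (all(gaps >= min_spacing_hours)) kept <- c(kept, i)
      if (length(kept) == max_readings) break
    }
    rows[kept, , drop = FALSE]
  }

  clinic <- pick(pool[pool$source != "prior-hospitalization-last-48h", , drop = FALSE])
  if (nrow(clinic) >= 2) {
    sel <- clinic
  } else {
    sel <- pick(pool) # fall back to all sources, hospital chart included
  }
  if (nrow(sel) < 2) {
    rlang::abort(
      "fewer than two qualifying pre-illness BP readings",
      class = "mapdeficit_insufficient_readings"
    )
  }
  sel
}

#' Estimate pre-illness MAP
#'
#' The pre-illness MAP is the unweighted arithmetic mean of the per-reading
#' MAPs over the selected historical readings (2 to 5 of them).
#'
#' @param readings Data frame with `sbp` and `dbp` columns, 2--5 rows.
#' @return A list with elements `readings` (the input), `per_reading_map`
#'   and `pre_illness_map` (mmHg).
#' @export
estimate_preillness_map <- function(readings) {
  stopifnot(is.data.frame(readings), all(c("sbp", "dbp") %in% names(readings)))
  n <- nrow(readings)
  if (n < 2 || n > 5) {
    rlang::abort("pre-illness MAP needs 2 to 5 readings",
                 class = "mapdeficit_contract_error")
  }
  maps <- map_from_bp(readings$sbp, readings$dbp)
  list(
    readings = readings,
    per_reading_map = maps,
    pre_illness_map = mean(maps)
  )
}

#' Recognised historical BP reading sources
#' @return Character vector of source labels.
#' @export
bp_sources <- function() {
  c("ambulatory", "outpatient-clinic", "pre-admission", "echo-clinic",
    "prior-hospitalization-last-48h")
}

#' Recognised exclusion flags
#' @return Character vector of exclusion-flag labels.
#' @export
exclusion_flags <- function() {
  c("moribund", "rrt_current_or_imminent", "creatinine_rise_gt_350", "esrd",
    "vasopressor_older_than_24h", "trauma", "pregnancy", "active_bleeding",
    "insufficient_bp_readings", "ecmo", "bp_target_contraindication")
}

#' Screen a patient against trial eligibility criteria
#'
#' A patient is eligible when aged 40 or above, on clinician-initiated
#' vasopressor therapy, with at least one supporting hypoperfusion criterion
#' (lactate >= 2 mmol/l, base deficit >= 3 mmol/l, low urine output,
#' respiratory rate > 22 /min, or GCS < 14) and no exclusion flag set.
#' Missing optional criteria count as not met, never as errors, so screening
#' proceeds on partial data.
#'
#' @param age Age in years.
#' @param vasopressor_started Logical; continuous vasopressor therapy begun.
#' @param lactate,base_deficit mmol/l, or `NA` when not drawn.
#' @param urine_output_low Logical (oliguria criterion met); `NA` allowed.
#' @param respiratory_rate breaths/min or `NA`.
#' @param gcs Glasgow Coma Score 3--15 or `NA`.
#' @param flags Character vector of exclusion flags (subset of
#'   [exclusion_flags()]); empty when none apply.
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria; empty when eligible).
#' @export
screen_eligibility <- function(age, vasopressor_started,
                               lactate = NA_real_, base_deficit = NA_real_,
                               urine_output_low = NA,
                               respiratory_rate = NA_real_, gcs = NA_integer_,
                               flags = character(0)) {
  stopifnot(is.logical(vasopressor_started), length(vasopressor_started) == 1,
            !is.na(vasopressor_started))
  bad <- setdiff(flags, exclusion_flags())
  if (length(bad)) {
    rlang::abort(paste("unknown exclusion flag:", paste(bad, collapse = ", ")),
                 class = "mapdeficit_contract_error")
  }
  met <- function(x) isTRUE(x)
  supporting <- c(
    lactate = met(lactate >= 2),
    base_deficit = met(base_deficit >= 3),
    urine_output = met(urine_output_low),
    respiratory_rate = met(respiratory_rate > 22),
    gcs = met(gcs < 14)
  )
  reasons <- character(0)
  if (age < 40) reasons <- c(reasons, "age")
  if (!vasopressor_started) reasons <- c(reasons, "vasopressor_not_started")
  if (!any(supporting)) reasons <- c(reasons, "no_supporting_criterion")
  reasons <- c(reasons, flags)
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Assign the arm-specific MAP target band
#'
#' Standard care targets a default MAP of 65 mmHg unless the treating team
#' specifies otherwise. The individualized arm targets the patient's own
#' pre-illness MAP +/- 2 mmHg, with the target centre first limited to the
#' 55--95 mmHg range (so an estimated pre-illness MAP of 100 yields the
#' band 93--97).
#'
#' @param arm `"standard"` or `"individualized"`.
#' @param pre_illness_map mmHg; required for the individualized arm.
#' @param override Optional clinician-specified centre, mmHg.
#' @return List with `arm`, `center`, `low`, `high` and
#'   `clinician_override` (NA when unset).
#' @export
assign_target <- function(arm = c("standard", "individualized"),
                          pre_illness_map = NULL, override = NULL) {
  arm <- match.arg(arm)
  if (arm == "standard") {
    center <- if (!is.null(override) && !is.na(override)) override else 65
    half <- 2
  } else {
    if (is.null(pre_illness_map) || is.na(pre_illness_map)) {
      rlang::abort("individualized arm requires a pre-illness MAP",
                   class = "mapdeficit_contract_error")
    }
    center <- if (!is.null(override) && !is.na(override)) {
      override
    } else {
      min(max(pre_illness_map, 55), 95)
    }
    half <- 2
  }
  list(
    arm = arm, center = center, low = center - half, high = center + half,
    clinician_override = if (is.null(override)) NA_real_ else override
  )
}

#' Read a historical blood-pressure readings table
#'
#' Delimited text with columns `patient_id`, `timestamp` (ISO-8601),
#' `sbp`, `dbp`, `source`.
#'
#' @param path File path (tab-delimited).
#' @return A tibble with `timestamp` parsed as POSIXct (UTC).
#' @export
read_bp_readings <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           sbp = readr::col_double(),
                           dbp = readr::col_double(),
                           source = readr::col_character()
                         ))
  stopifnot(all(out$source %in% bp_sources()))
  out
}
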