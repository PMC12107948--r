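#' Baseline (pre-morbid) serum creatinine
#'
#' Uses the measured pre-morbid value when one is available. Otherwise the
#' baseline is back-estimated following the KDIGO convention: solve the MDRD
#' equation `eGFR = 175 * Scr^-1.154 * age^-0.203 * (0.742 if female)`
#' (Scr in mg/dl, no race term) for the serum creatinine at an assumed eGFR
#' of 75 ml/min/1.73 m2, and convert to umol/l (x 88.4).
#'
#' @param age Age in years (>= 40 in this trial population).
#' @param sex `"male"` or `"female"`.
#' @param measured Measured pre-morbid creatinine, umol/l, or `NA`.
#' @param measured_source Source label for a measured value, default
#'   `"premorbid-12mo"` (the alternative is `"in-hospital-7d-before-icu"`).
#' @return List with `value` (umol/l) and `source`
#'   (`"kdigo-estimated"` when back-estimated).
#' @export
estimate_baseline_creatinine <- function(age, sex = c("male", "female"),
                                         measured = NA_real_,
                                         measured_source = "premorbid-12mo") {
  sex <- match.arg(sex)
  if (is.finite(measured)) {
    return(list(value = measured, source = measured_source))
  }
  sex_factor <- if (sex == "female") 0.742 else 1
  scr_mgdl <- (175 * age^-0.203 * sex_factor / 75)^(1 / 1.154)
  list(value = scr_mgdl * 88.4, source = "kdigo-estimated")
}

#' KDIGO acute-kidney-injury stage from creatinine
#'
#' Creatinine/RRT-based staging (urine-output criteria are not assessable
#' from daily peak values and are not used):
#' stage 3 when on RRT, or creatinine >= 3.0 x baseline, or >= 353.6 umol/l;
#' stage 2 when >= 2.0 x baseline; stage 1 when >= 1.5 x baseline or the
#' rise over baseline is >= 26.5 umol/l; otherwise stage 0.
#'
#' @param baseline Baseline creatinine, umol/l (> 0).
#' @param current Current creatinine, umol/l (> 0). Vectorised.
#' @param on_rrt Logical; receiving renal replacement therapy.
#' @return Integer stage 0--3.
#' @export
kdigo_stage <- function(baseline, current, on_rrt = FALSE) {
  stopifnot(all(baseline > 0), all(current > 0))
  ratio <- current / baseline
  stage <- ifelse(on_rrt | ratio >= 3 | current >= 353.6, 3L,
           ifelse(ratio >= 2, 2L,
           ifelse(ratio >= 1.5 | (current - baseline) >= 26.5, 1L, 0L)))
  as.integer(stage)
}

#' Construct a per-patient creatinine series
#'
#' Bundles the inputs of the renal-outcome derivations: the pre-morbid
#' baseline, the value at randomization, daily peak creatinines over days
#' 1--14 from T0, and event days.
#'
#' @param baseline Baseline creatinine, umol/l.
#' @param at_randomization Creatinine at randomization, umol/l.
#' @param daily_peaks Numeric vector of daily peak creatinines, umol/l.
#' @param days Day indices (1-based from T0) matching `daily_peaks`.
#' @param rrt_start_day,death_day,icu_discharge_day Event days (`NA` if the
#'   event did not occur).
#' @param baseline_source Provenance of the baseline value.
#' @return A list of class `creatinine_series`.
#' @export
creatinine_series <- function(baseline, at_randomization, daily_peaks,
                              days = seq_along(daily_peaks),
                              rrt_start_day = NA_integer_,
                              death_day = NA_integer_,
                              icu_discharge_day = NA_integer_,
                              baseline_source = "premorbid-12mo") {
  stopifnot(baseline > 0, at_randomization > 0,
            length(days) == length(daily_peaks),
            all(days >= 1), !is.unsorted(days, strictly = TRUE))
  structure(list(baseline = baseline, baseline_source = baseline_source,
                 at_randomization = at_randomization,
                 daily_peaks = daily_peaks, days = as.integer(days),
                 rrt_start_day = rrt_start_day, death_day = death_day,
                 icu_discharge_day = icu_discharge_day),
            class = "creatinine_series")
}

#' Daily KDIGO stages over the first 14 days
#'
#' Stages each observed day against the fixed pre-morbid baseline, with RRT
#' forcing stage 3 from its start day onwards. With only daily peak values
#' available, the 48-h window of the KDIGO absolute-rise criterion
#' (>= 26.5 umol/l) is approximated by also counting a qualifying rise
#' between adjacent observed days.
#'
#' @param series A [creatinine_series()].
#' @return Tibble with `day` and `stage` for observed days within 1--14.
#' @export
daily_kdigo_stages <- function(series) {
  stopifnot(inherits(series, "creatinine_series"))
  keep <- series$days <= 14
  days <- series$days[keep]; peaks <- series$daily_peaks[keep]
  ok <- is.finite(peaks)
  days <- days[ok]; peaks <- peaks[ok]
  on_rrt <- !is.na(series$rrt_start_day) & days >= series$rrt_start_day
  stage <- kdigo_stage(series$baseline, peaks, on_rrt)
  if (length(days) > 1) {
    adj <- diff(peaks) >= 26.5 & diff(days) == 1L
    stage[-1][adj & stage[-1] == 0L] <- 1L
  }
  tibble::tibble(day = days, stage = stage)
}

#' New significant acute kidney injury within 14 days
#'
#' TRUE when the peak KDIGO stage over days 1--14 exceeds the stage at
#' study entry (staged at the randomization creatinine) by at least two.
#'
#' @param series A [creatinine_series()].
#' @return Logical.
#' @export
new_significant_aki <- function(series) {
  stopifnot(inherits(series, "creatinine_series"))
  entry <- kdigo_stage(series$baseline, series$at_randomization, FALSE)
  stages <- daily_kdigo_stages(series)
  if (nrow(stages) == 0) return(FALSE)
  (max(stages$stage) - entry) >= 2
}

#' MAKE-14: major adverse kidney events by day 14
#'
#' Composite of death within 14 days, new renal replacement therapy within
#' 14 days, or doubling of serum creatinine from the pre-morbid level at the
#' assessment day -- day 14 or the day of ICU discharge, whichever is earlier
#' (the last daily peak at or before that day is used). When no assessment-day
#' creatinine exists and no other component fires, the doubling flag is FALSE
#' and a data-gap warning is issued.
#'
#' @param series A [creatinine_series()].
#' @return List with `make14` and component flags `death`, `new_rrt`,
#'   `doubling`.
#' @export
make14 <- function(series) {
  stopifnot(inherits(series, "creatinine_series"))
  death <- !is.na(series$death_day) && series$death_day <= 14
  new_rrt <- !is.na(series$rrt_start_day) && series$rrt_start_day <= 14
  assess_day <- min(14, series$icu_discharge_day, na.rm = TRUE)
  at_or_before <- series$days <= assess_day & is.finite(series$daily_peaks)
  doubling <- FALSE
  if (any(at_or_before)) {
    cr <- series$daily_peaks[max(which(at_or_before))]
    doubling <- cr >= 2 * series$baseline
  } else if (!death && !new_rrt) {
    rlang::warn("no creatinine at the MAKE-14 assessment day; doubling set FALSE",
                class = "mapdeficit_data_gap")
  }
  list(make14 = death || new_rrt || doubling,
       death = death, new_rrt = new_rrt, doubling = doubling)
}

#' Peak percentage increase in serum creatinine within 14 days
#'
#' `100 * (peak creatinine during days 1--14 - creatinine at randomization) /
#' creatinine at randomization`, reported only among patients who did not
#' receive renal replacement therapy within 14 days (otherwise `NA`). The
#' value is signed: a peak below the randomization level gives a negative
#' percentage.
#'
#' @param series A [creatinine_series()].
#' @return Percentage, or `NA` for RRT-treated patients or when no daily
#'   peak was observed.
#' @export
peak_creatinine_increase <- function(series) {
  stopifnot(inherits(series, "creatinine_series"))
  if (!is.na(series$rrt_start_day) && series$rrt_start_day <= 14) {
    return(NA_real_)
  }
  keep <- series$days <= 14 & is.finite(series$daily_peaks)
  if (!any(keep)) return(NA_real_)
  peak <- max(series$daily_peaks[keep])
  100 * (peak - series$at_randomization) / series$at_randomization
}

#' Per-patient renal outcomes over a labs table
#'
#' Assembles a [creatinine_series()] for each patient from the labs long
#' table and cohort event columns, and derives the renal endpoints.
#'
#' @param labs Long tibble: `patient_id`, `day_index`,
#'   `peak_creatinine_umol_l`, `rrt` (0/1).
#' @param cohort Cohort tibble with `patient_id`, `baseline_creatinine`,
#'   `creatinine_at_randomization`, `death_day`, `icu_discharge_day`.
#' @return One row per patient: `new_significant_aki`, `make14`, component
#'   flags, `peak_creatinine_increase_pct`, `rrt_within_14d`.
#' @export
renal_outcomes <- function(labs, cohort) {
  stopifnot(all(c("patient_id", "day_index", "peak_creatinine_umol_l", "rrt")
                %in% names(labs)))
  per_patient <- function(pid) {
    li <- labs[labs$patient_id == pid, , drop = FALSE]
    li <- li[order(li$day_index), , drop = FALSE]
    co <- cohort[cohort$patient_id == pid, , drop = FALSE]
    rrt_day <- if (any(li$rrt == 1)) min(li$day_index[li$rrt == 1]) else NA_integer_
    s <- creatinine_series(
      baseline = co$baseline_creatinine,
      at_randomization = co$creatinine_at_randomization,
      daily_peaks = li$peak_creatinine_umol_l,
      days = li$day_index,
      rrt_start_day = rrt_day,
      death_day = co$death_day,
      icu_discharge_day = co$icu_discharge_day
    )
    mk <- make14(s)
    tibble::tibble(
      patient_id = pid,
      new_significant_aki = new_significant_aki(s),
      make14 = mk$make14,
      make14_death = mk$death,
      make14_new_rrt = mk$new_rrt,
      make14_doubling = mk$doubling,
      peak_creatinine_increase_pct = peak_creatinine_increase(s),
      rrt_within_14d = !is.na(rrt_day) && rrt_day <= 14
    )
  }
  dplyr::bind_rows(lapply(unique(labs$patient_id), per_patient))
}

#' Norepinephrine-equivalent combined vasopressor dose
#'
#' Converts raw agent doses to a single norepinephrine-equivalent scale,
#' ug/kg/min. The default equivalence table follows common published
#' practice: norepinephrine 1.0 and epinephrine 1.0 (ug/kg/min),
#' phenylephrine 0.1 per ug/kg/min, vasopressin 2.5 per U/min. Dobutamine is
#' an inotrope and is excluded. The table is overridable.
#'
#' @param doses Named numeric vector or list of agent doses (agents in their
#'   native units; unknown agents are an error).
#' @param equivalence Named numeric vector of conversion factors.
#' @return Total norepinephrine-equivalent dose, ug/kg/min.
#' @export
ne_equivalent_dose <- function(doses,
                               equivalence = c(norepinephrine = 1,
                                               epinephrine = 1,
                                               phenylephrine = 0.1,
                                               vasopressin = 2.5)) {
  doses <- unlist(doses)
  doses <- doses[names(doses) != "dobutamine"]
  unknown <- setdiff(names(doses), names(equivalence))
  if (length(unknown)) {
    rlang::abort(paste("no equivalence factor for:", paste(unknown, collapse = ", ")),
                 class = "mapdeficit_contract_error")
  }
  sum(doses * equivalence[names(doses)])
}

#' Read a labs long table
#'
#' Tab-delimited text: `patient_id`, `day_index` (1-based from T0),
#' `peak_creatinine_umol_l`, `rrt` (0/1).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_labs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    day_index = readr::col_integer(),
                    peak_creatinine_umol_l = readr::col_double(),
                    rrt = readr::col_integer()
                  ))
}
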