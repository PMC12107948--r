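#!/usr/bin/env Rscript
# Per-patient relative-hypotension exposure over the active treatment window:
# time-weighted average MAP-deficit (positive incremental AUC), threshold-time
# fractions, achieved MAP, and the deficit-category x escalation profile.
# Reads results/trial/, writes results/exposure_summary.tsv and
# results/deficit_profile.tsv.

suppressPackageStartupMessages({
  library(mapdeficit)
  library(dplyr)
})

trial <- read_trial_tables("results/trial")
es <- exposure_summary(trial$vitals, trial$cohort)
readr::write_tsv(es, "results/exposure_summary.tsv")

by_arm <- es |>
  inner_join(trial$cohort[c("patient_id", "arm")], by = "patient_id") |>
  group_by(arm) |>
  summarise(across(c(twa_map_deficit, pct_time_deficit_gt20,
                     pct_time_map_lt65, achieved_map),
                   ~ median(.x, na.rm = TRUE)))
cat("Arm-level medians over", nrow(es), "patients:\n")
print(as.data.frame(by_arm), digits = 3)

# group-level deficit/escalation occupancy profile
prof <- trial$vitals |>
  inner_join(trial$cohort[c("patient_id", "arm", "pre_illness_map")],
             by = "patient_id") |>
  group_by(arm, patient_id) |>
  group_modify(~ deficit_profile(.x$t_hours, .x$map_mmHg,
                                 .x$ne_dose_ug_kg_min, .x$pre_illness_map[1])) |>
  group_by(arm, deficit_bin, escalation) |>
  summarise(pct_time = mean(pct_time, na.rm = TRUE), .groups = "drop")
readr::write_tsv(prof, "results/deficit_profile.tsv")
cat("\nDeficit-category occupancy (mean % of classified time):\n")
print(as.data.frame(tidyr::pivot_wider(prof, names_from = arm,
                                       values_from = pct_time)), digits = 2)
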