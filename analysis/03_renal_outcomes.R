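#!/usr/bin/env Rscript
# KDIGO-based renal endpoints per patient: new significant AKI (peak stage
# shift >= 2), the MAKE-14 composite and its components, peak creatinine rise
# and RRT. Reads results/trial/, writes results/renal_outcomes.tsv.

suppressPackageStartupMessages({
  library(mapdeficit)
  library(dplyr)
})

trial <- read_trial_tables("results/trial")
ro <- renal_outcomes(trial$labs, trial$cohort)
readr::write_tsv(ro, "results/renal_outcomes.tsv")

tab <- ro |>
  inner_join(trial$cohort[c("patient_id", "arm")], by = "patient_id") |>
  group_by(arm) |>
  summarise(n = n(),
            make14 = sum(make14),
            new_aki = sum(new_significant_aki),
            rrt = sum(rrt_within_14d),
            median_peak_rise_pct = median(peak_creatinine_increase_pct,
                                          na.rm = TRUE))
cat("Renal endpoints by arm:\n")
print(as.data.frame(tab), digits = 3)
cat("\nDeaths by day 14:",
    sum(!is.na(trial$cohort$death_day) & trial$cohort$death_day <= 14), "\n")
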