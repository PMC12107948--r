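#!/usr/bin/env Rscript
# Trial-style statistical outputs: the outcome comparison table (counts and
# medians with Fisher / Wilcoxon p-values), random-intercept mixed-model
# coefficients for the repeated hemodynamic measures, and daily group means
# with 95% CIs. Reads results/trial/, writes results/outcome_comparison.tsv,
# results/lmm_coefficients.tsv and results/daily_means.tsv.

suppressPackageStartupMessages({
  library(mapdeficit)
  library(dplyr)
})

trial <- read_trial_tables("results/trial")
es <- exposure_summary(trial$vitals, trial$cohort)
ro <- renal_outcomes(trial$labs, trial$cohort)

per_patient <- trial$cohort |>
  inner_join(es, by = "patient_id") |>
  inner_join(ro, by = "patient_id") |>
  mutate(death_14d = !is.na(death_day) & death_day <= 14)

comparison <- summarize_groups(
  per_patient,
  binary_vars = c("death_14d", "make14", "new_significant_aki",
                  "rrt_within_14d"),
  continuous_vars = c("twa_map_deficit", "pct_time_deficit_gt20",
                      "pct_time_map_lt65", "achieved_map",
                      "peak_creatinine_increase_pct")
)
readr::write_tsv(comparison, "results/outcome_comparison.tsv")
cat("Outcome comparison (standard vs individualized):\n")
print(as.data.frame(comparison), digits = 2, right = FALSE)

long <- build_daily_long(trial$vitals, trial$cohort, trial$labs)
coefs <- lapply(c("pct_deficit", "achieved_map", "vasopressor_dose",
                  "daily_highest", "daily_lowest", "daily_peak_creatinine"),
                function(oc) {
  f <- suppressWarnings(fit_lmm(long, oc))
  f$outcome <- oc
  f
}) |> bind_rows()
readr::write_tsv(coefs, "results/lmm_coefficients.tsv")
cat("\nMixed-model treatment effects (estimate [95% CI]):\n")
tr <- coefs |> filter(term %in% c("treatment", "treatment:days_since_rand"))
print(as.data.frame(tr[c("outcome", "term", "estimate",
                         "conf_low", "conf_high")]), digits = 3)

daily <- lapply(c("pct_deficit", "achieved_map", "vasopressor_dose"),
                function(oc) {
  dm <- daily_group_means(long, oc)
  dm$outcome <- oc
  dm
}) |> bind_rows()
readr::write_tsv(daily, "results/daily_means.tsv")
cat("\nDaily means written for",
    length(unique(daily$outcome)), "outcomes over",
    max(daily$day), "days\n")
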