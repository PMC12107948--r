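#' Configuration for the synthetic-trial generator
#'
#' Bundles every tunable of the cohort generator with defaults that emulate
#' the pilot-trial conditions: 37 patients over two sites (22/15), pre-illness
#' MAP centred near 95 mmHg, a standard-care achieved-MAP centre of 77 mmHg
#' (the documented overshoot above the 65 mmHg default target), individualized
#' patients achieving their own target centre, AR(1) hemodynamics at 4-h
#' resolution, log-normal vasopressor durations with a median of 90 h capped
#' at 120 h, creatinine trajectories whose upward-drift probability rises
#' with deficit exposure, and a 14-day mortality base rate of 11%.
#'
#' @param n_patients Number of enrolled patients.
#' @param sites Named numeric vector of site enrolment weights.
#' @param seed Master seed (mandatory). All randomness flows from it through
#'   per-patient substreams, so adding a patient does not perturb others.
#' @param preillness_map_mean,preillness_map_sd Population distribution of
#'   the true pre-illness MAP, mmHg.
#' @param standard_achieved_center Stationary mean of the achieved MAP in the
#'   standard arm, mmHg. The individualized arm's stationary mean is its
#'   assigned target centre.
#' @param achieved_sd Stationary SD of the achieved-MAP process, mmHg.
#' @param ar1_coefficient Lag-1 autocorrelation of the 4-hourly MAP process.
#' @param obs_interval Observation spacing, hours.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of the
#'   vasopressor-support duration (hours), truncated to `[8, 120]`.
#' @param vasopressor_dose_gain Norepinephrine-equivalent dose per mmHg of
#'   pressure support above the patient's latent unsupported MAP.
#' @param aki_logit_intercept,aki_logit_slope_per_deficit_pct Logistic
#'   parameters of the daily probability of an upward creatinine drift as a
#'   function of the time-weighted average percentage deficit.
#' @param aki_phase_decline_per_day Daily decline (logit scale) of the
#'   upward-drift probability, encoding resolution of the acute insult.
#' @param rrt_prob_at_stage3 Daily probability that stage-3 AKI triggers RRT.
#' @param mortality_14d_base Marginal 14-day mortality probability.
#' @param block_sizes Permitted permuted-block sizes (even integers).
#' @param creat_baseline_meanlog,creat_baseline_sdlog Log-normal parameters
#'   of the pre-morbid baseline creatinine, umol/l.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 37,
                       sites = c(AUS = 22, IRL = 15),
                       seed = NULL,
                       preillness_map_mean = 95,
                       preillness_map_sd = 8,
                       standard_achieved_center = 77,
                       achieved_sd = 6,
                       ar1_coefficient = 0.6,
                       obs_interval = 4,
                       duration_meanlog = log(90),
                       duration_sdlog = 0.6,
                       vasopressor_dose_gain = 0.01,
                       aki_logit_intercept = -0.4,
                       aki_logit_slope_per_deficit_pct = 0.06,
                       aki_phase_decline_per_day = 0.45,
                       rrt_prob_at_stage3 = 0.05,
                       mortality_14d_base = 0.11,
                       block_sizes = c(2, 4),
                       creat_baseline_meanlog = log(80),
                       creat_baseline_sdlog = 0.2) {
  if (is.null(seed)) {
    rlang::abort("a seed is mandatory", class = "mapdeficit_config_error")
  }
  if (any(block_sizes %% 2 != 0) || any(block_sizes < 2)) {
    rlang::abort("block sizes must be positive even integers",
                 class = "mapdeficit_config_error")
  }
  stopifnot(n_patients >= 1, all(sites > 0), achieved_sd >= 0,
            abs(ar1_coefficient) < 1, obs_interval > 0,
            mortality_14d_base >= 0, mortality_14d_base <= 1,
            rrt_prob_at_stage3 >= 0, rrt_prob_at_stage3 <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Permuted-block randomization stratified by site
#'
#' Within each site, arm assignments are the concatenation of shuffled
#' balanced blocks of randomly chosen (even) sizes, truncated to the site's
#' enrolment count -- so the per-site arm imbalance never exceeds
#' `max(block_sizes) / 2`. Deterministic given the seed.
#'
#' @param site Character vector: site label per patient, in enrolment order.
#' @param block_sizes Permitted block sizes (even integers).
#' @param seed Integer seed.
#' @return Character vector of `"standard"` / `"individualized"`, one per
#'   patient.
#' @export
permuted_block_randomize <- function(site, block_sizes = c(2, 4), seed) {
  if (any(block_sizes %% 2 != 0) || any(block_sizes < 2)) {
    rlang::abort("block sizes must be positive even integers",
                 class = "mapdeficit_config_error")
  }
  stopifnot(length(site) >= 1)
  arms <- c("standard", "individualized")
  out <- character(length(site))
  sites <- sort(unique(site))
  for (k in seq_along(sites)) {
    idx <- which(site == sites[k])
    # each stratum runs on its own derived stream, so enrolment at one site
    # never perturbs another site's block sequence
    out[idx] <- withr::with_seed((seed + 7919L * k) %% .Machine$integer.max, {
      seq_arms <- character(0)
      while (length(seq_arms) < length(idx)) {
        size <- block_sizes[sample.int(length(block_sizes), 1)]
        seq_arms <- c(seq_arms, sample(rep(arms, size / 2)))
      }
      seq_arms[seq_along(idx)]
    })
  }
  out
}

#' Simulate historical blood-pressure readings for one patient
#'
#' Draws 2--5 usual-health readings (count weighted as observed in pilot
#' enrolment), spaced weeks apart within the 3 years before screening, with
#' per-reading MAP scattered around the patient's true pre-illness MAP and a
#' realistic pulse pressure. Readings are returned most recent first.
#'
#' @param true_map Patient's true pre-illness MAP, mmHg.
#' @param screening_time POSIXct screening instant.
#' @return Tibble with `timestamp`, `sbp`, `dbp`, `source`.
#' @export
simulate_preillness_readings <- function(true_map, screening_time) {
  n <- sample(2:5, 1, prob = c(0.13, 0.14, 0.27, 0.46))
  gaps_weeks <- stats::rlnorm(n, log(6), 0.8) # first gap: screening to newest
  ts <- screening_time - as.difftime(cumsum(gaps_weeks) * 7 * 24, units = "hours")
  map <- stats::rnorm(n, true_map, 3)
  pp <- stats::rnorm(n, 50, 7)
  dbp <- round(map - pp / 3)
  sbp <- round(dbp + pp)
  src <- sample(c("ambulatory", "outpatient-clinic", "pre-admission"),
                n, replace = TRUE)
  tibble::new_tibble(list(timestamp = ts, sbp = sbp, dbp = dbp, source = src),
                     nrow = n)
}

#' Simulate a 4-hourly MAP and vasopressor-dose series
#'
#' First-order autoregressive process around the arm's achieved-MAP centre
#' with the configured stationary SD and lag-1 coefficient, observed every
#' `obs_interval` hours from T0 for the given duration. The
#' norepinephrine-equivalent dose is proportional to the pressure support
#' (target centre minus the patient's latent unsupported MAP) plus noise,
#' floored at zero.
#'
#' @param center Stationary mean of the achieved MAP, mmHg.
#' @param duration_h Duration of vasopressor support, hours.
#' @param latent_map Patient's latent unsupported MAP, mmHg.
#' @param config A [sim_config()].
#' @return Tibble with `t_hours`, `map_mmHg`, `ne_dose_ug_kg_min`.
#' @export
simulate_map_series <- function(center, duration_h, latent_map, config) {
  t <- seq(0, max(config$obs_interval, duration_h), by = config$obs_interval)
  n <- length(t)
  phi <- config$ar1_coefficient
  s <- config$achieved_sd
  if (s == 0) {
    map <- rep(center, n)
  } else {
    e <- stats::rnorm(n - 1, 0, s * sqrt(1 - phi^2))
    x0 <- stats::rnorm(1, 0, s)
    dev <- if (n > 1) {
      as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
    } else numeric(0)
    map <- center + c(x0, dev)
  }
  support <- max(0, center - latent_map)
  dose <- pmax(0, config$vasopressor_dose_gain * support +
                  stats::rnorm(n, 0, 0.03))
  tibble::new_tibble(list(t_hours = t, map_mmHg = round(map, 1),
                          ne_dose_ug_kg_min = round(dose, 3)), nrow = n)
}

#' Simulate a daily peak-creatinine trajectory
#'
#' Daily multiplicative innovations on the log scale: each day the
#' trajectory drifts upward with probability
#' `plogis(intercept + slope * twa_deficit - phase_decline * (day - 1))` --
#' an exposure--AKI dose-response whose acute phase resolves over the first
#' week -- and otherwise relaxes toward the pre-morbid baseline. Reaching
#' KDIGO stage 3 triggers RRT with the configured daily probability.
#'
#' @param baseline Pre-morbid baseline creatinine, umol/l.
#' @param at_randomization Creatinine at randomization, umol/l.
#' @param twa_deficit Time-weighted average percentage MAP-deficit.
#' @param n_days Number of days to simulate.
#' @param config A [sim_config()].
#' @return Tibble with `day_index`, `peak_creatinine_umol_l`, `rrt`.
#' @export
simulate_creatinine <- function(baseline, at_randomization, twa_deficit,
                                n_days = 14, config) {
  lcr <- log(at_randomization)
  lbase <- log(baseline)
  peaks <- numeric(n_days)
  rrt <- integer(n_days)
  on_rrt <- FALSE
  for (d in seq_len(n_days)) {
    p_up <- stats::plogis(config$aki_logit_intercept +
                          config$aki_logit_slope_per_deficit_pct * twa_deficit -
                          config$aki_phase_decline_per_day * (d - 1))
    if (stats::runif(1) < p_up) {
      lcr <- lcr + abs(stats::rnorm(1, 0.22, 0.08))
    } else {
      lcr <- lcr - 0.25 * (lcr - lbase) + stats::rnorm(1, 0, 0.04)
    }
    peaks[d] <- round(exp(lcr), 1)
    if (!on_rrt && kdigo_stage(baseline, peaks[d]) == 3L &&
        stats::runif(1) < config$rrt_prob_at_stage3) {
      on_rrt <- TRUE
    }
    rrt[d] <- as.integer(on_rrt)
  }
  tibble::new_tibble(list(day_index = seq_len(n_days),
                          peak_creatinine_umol_l = peaks, rrt = rrt),
                     nrow = n_days)
}

#' Generate a complete synthetic trial dataset
#'
#' Composes eligibility-consistent patients, site-stratified permuted-block
#' randomization, arm-specific MAP target assignment, AR(1) hemodynamic
#' trajectories, exposure-linked creatinine trajectories, and event days
#' into the three standard tables (cohort, vitals, labs) plus the historical
#' BP readings table. Fully reproducible from the config's master seed; each
#' patient draws from a derived substream.
#'
#' The cohort table carries the generator's per-patient truth
#' (`achieved_center`, the stationary mean of that patient's MAP process),
#' which downstream parameter-recovery checks compare against the pipeline's
#' measured exposure.
#'
#' @param config A [sim_config()].
#' @return List of tibbles: `cohort`, `vitals`, `labs`, `bp_readings`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  base_t0 <- as.POSIXct("2021-01-04 08:00:00", tz = "UTC")

  # separate derived streams per head draw, so each is prefix-stable in n
  head_draws <- list(
    patient_seed = withr::with_seed(config$seed,
      sample.int(.Machine$integer.max - 1L, n)),
    site = withr::with_seed(config$seed + 2L,
      sample(names(config$sites), n, replace = TRUE,
             prob = config$sites / sum(config$sites)))
  )
  arm <- permuted_block_randomize(head_draws$site, config$block_sizes,
                                  seed = config$seed + 1L)

  cohort <- vector("list", n)
  vitals <- vector("list", n)
  labs <- vector("list", n)
  readings_all <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    rows <- withr::with_seed(head_draws$patient_seed[i], {
      age <- max(40, round(stats::rnorm(1, 67, 12)))
      sex <- sample(c("male", "female"), 1, prob = c(0.57, 0.43))
      apache3 <- round(min(150, max(25, stats::rnorm(1, 75, 18))))
      shock_type <- sample(c("septic", "cardiogenic", "mixed"), 1,
                           prob = c(0.89, 0.08, 0.03))
      lactate <- round(2 + stats::rexp(1, 1), 1) # inclusion-consistent
      t0 <- base_t0 + as.difftime(round(stats::runif(1, 0, 720)) * 24 +
                                    round(stats::runif(1, 0, 23)),
                                  units = "hours")
      true_map <- stats::rnorm(1, config$preillness_map_mean,
                               config$preillness_map_sd)
      bp <- simulate_preillness_readings(true_map, t0)
      profile <- estimate_preillness_map(bp)
      target <- assign_target(arm[i], profile$pre_illness_map)
      center <- if (arm[i] == "standard") {
        config$standard_achieved_center
      } else {
        target$center
      }
      duration <- min(120, max(8, stats::rlnorm(1, config$duration_meanlog,
                                                config$duration_sdlog)))
      rand_delay <- min(duration, max(1, stats::rlnorm(1, log(18), 0.4)))
      latent_map <- stats::rnorm(1, 55, 8)
      vit <- simulate_map_series(center, duration, latent_map, config)
      deficit <- twa_map_deficit(vit$t_hours, vit$map_mmHg,
                                 profile$pre_illness_map)
      baseline_cr <- round(stats::rlnorm(1, config$creat_baseline_meanlog,
                                         config$creat_baseline_sdlog), 1)
      cr_rand <- round(baseline_cr * stats::rlnorm(1, log(1.6), 0.3), 1)
      death_p <- config$mortality_14d_base
      death_day <- if (stats::runif(1) < death_p) {
        sample(2:14, 1)
      } else NA_integer_
      discharge_day <- min(28L,
                           as.integer(ceiling(duration / 24)) + 1L +
                             stats::rpois(1, 4))
      last_lab_day <- min(14L, discharge_day,
                          if (is.na(death_day)) 14L else death_day)
      lab <- simulate_creatinine(baseline_cr, cr_rand, deficit,
                                 n_days = last_lab_day, config = config)
      prepend_id <- function(df) {
        tibble::new_tibble(c(list(patient_id = rep(pid, nrow(df))), df),
                           nrow = nrow(df))
      }
      list(
        cohort = tibble::new_tibble(list(
          patient_id = pid, site = head_draws$site[i], arm = arm[i],
          age = age, sex = sex, apache3 = apache3, shock_type = shock_type,
          lactate_at_t0 = lactate, t0 = t0,
          randomization_delay_h = round(rand_delay, 1),
          pre_illness_map = profile$pre_illness_map,
          target_center = target$center, achieved_center = center,
          baseline_creatinine = baseline_cr,
          baseline_creatinine_source = "premorbid-12mo",
          creatinine_at_randomization = cr_rand,
          death_day = death_day, icu_discharge_day = discharge_day
        ), nrow = 1L),
        vitals = prepend_id(vit),
        labs = prepend_id(lab),
        readings = prepend_id(bp)
      )
    })
    cohort[[i]] <- rows$cohort
    vitals[[i]] <- rows$vitals
    labs[[i]] <- rows$labs
    readings_all[[i]] <- rows$readings
  }
  list(
    cohort = dplyr::bind_rows(cohort),
    vitals = dplyr::bind_rows(vitals),
    labs = dplyr::bind_rows(labs),
    bp_readings = dplyr::bind_rows(readings_all)
  )
}

#' Write / read the synthetic trial tables
#'
#' Tab-delimited text files `cohort.tsv`, `vitals.tsv`, `labs.tsv`,
#' `bp_readings.tsv` under `dir`. [read_trial_tables()] restores them with
#' typed columns so a generated dataset round-trips without loss.
#'
#' @param trial A list as returned by [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_tables <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(trial$cohort, file.path(dir, "cohort.tsv"))
  readr::write_tsv(trial$vitals, file.path(dir, "vitals.tsv"))
  readr::write_tsv(trial$labs, file.path(dir, "labs.tsv"))
  if (!is.null(trial$bp_readings)) {
    readr::write_tsv(trial$bp_readings, file.path(dir, "bp_readings.tsv"))
  }
  invisible(dir)
}

#' @rdname write_trial_tables
#' @export
read_trial_tables <- function(dir) {
  cohort <- readr::read_tsv(file.path(dir, "cohort.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              patient_id = readr::col_character(),
                              site = readr::col_character(),
                              arm = readr::col_character(),
                              sex = readr::col_character(),
                              shock_type = readr::col_character(),
                              baseline_creatinine_source = readr::col_character(),
                              t0 = readr::col_datetime(),
                              death_day = readr::col_integer(),
                              icu_discharge_day = readr::col_integer(),
                              age = readr::col_double(),
                              apache3 = readr::col_double(),
                              .default = readr::col_double()
                            ))
  list(
    cohort = cohort,
    vitals = read_vitals(file.path(dir, "vitals.tsv")),
    labs = read_labs(file.path(dir, "labs.tsv")),
    bp_readings = if (file.exists(file.path(dir, "bp_readings.tsv"))) {
      read_bp_readings(file.path(dir, "bp_readings.tsv"))
    }
  )
}

#' Simulate long-format repeated measures for mixed-model calibration
#'
#' Generates patient-day data straight from the random-intercept model that
#' [fit_lmm()] estimates: a grand intercept, a treatment effect, linear time
#' trends, a treatment-by-time interaction, a per-patient random intercept
#' and i.i.d. residual noise. Used to validate estimator recovery and
#' confidence-interval calibration.
#'
#' @param n_patients Number of patients (split 1:1 between arms).
#' @param treatment_effect Fixed treatment effect on the outcome.
#' @param interaction Treatment-by-time interaction slope per day.
#' @param time_slope Common slope per day since randomization.
#' @param intercept Grand intercept.
#' @param rand_sd Random-intercept SD.
#' @param resid_sd Residual SD.
#' @param n_days Days of follow-up per patient.
#' @param seed Integer seed.
#' @return Long tibble compatible with [fit_lmm()]; the outcome column is
#'   `pct_deficit`.
#' @export
simulate_lmm_data <- function(n_patients = 100, treatment_effect = -10,
                              interaction = 0, time_slope = -0.5,
                              intercept = 18, rand_sd = 5, resid_sd = 4,
                              n_days = 5, seed) {
  withr::with_seed(seed, {
    treatment <- rep(c(0L, 1L), length.out = n_patients)
    u <- stats::rnorm(n_patients, 0, rand_sd)
    delay <- stats::runif(n_patients, 0.3, 1.5)
    long <- tidyr::expand_grid(idx = seq_len(n_patients),
                               day = seq_len(n_days))
    long$patient_id <- sprintf("P%03d", long$idx)
    long$treatment <- treatment[long$idx]
    long$days_t0_to_rand <- delay[long$idx]
    long$days_since_rand <- long$day - delay[long$idx]
    long$pct_deficit <- intercept +
      treatment_effect * long$treatment +
      time_slope * long$days_since_rand +
      interaction * long$treatment * long$days_since_rand +
      u[long$idx] + stats::rnorm(nrow(long), 0, resid_sd)
    long[c("patient_id", "treatment", "day", "days_t0_to_rand",
           "days_since_rand", "pct_deficit")]
  })
}
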