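#' Generate the randomised patient table
#'
#' Allocates 2 x `n_per_arm` patients to centres and randomises them 1:1
#' within centre using permuted blocks of `block_size`, so that within every
#' completed block the two arms are exactly balanced and the per-centre arm
#' imbalance never exceeds half a block. Baseline covariates (age, sex, BMI,
#' performance status, smoking) are drawn from distributions typical of an
#' early-stage lung-cancer surgical population and are identical across arms
#' by construction. Deaths are simulated per follow-up window and the d30 /
#' m3 visit dates carry configurable jitter, occasional far-off-window
#' placement and occasional missing dates, so the downstream complete-case
#' exclusion cascade has realistic work to do.
#'
#' Day offsets are integers with surgery at day 0; a death date censors all
#' later visits.
#'
#' @param config A [trial_config()].
#' @return data.frame with one row per patient: `patient_id`, `centre_id`,
#'   `arm`, covariates, `death_day` (NA if alive at 3 months),
#'   `visit_d30_day` / `visit_m3_day` (NA if the visit did not happen or is
#'   undated) and `visit_d30_undated` / `visit_m3_undated` flags.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n_total <- 2L * config$n_per_arm
  centre <- sort(sample.int(config$n_centres, n_total, replace = TRUE))
  arm <- character(n_total)
  half <- config$block_size / 2L
  for (cid in unique(centre)) {
    idx <- which(centre == cid)
    n_blocks <- ceiling(length(idx) / config$block_size)
    seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(trial_arms(), each = half))
    }))
    arm[idx] <- seq_arms[seq_along(idx)]
  }

  age <- round(stats::rnorm(n_total, 64.5, 9.3), 1)
  sex <- sample(c("male", "female"), n_total, replace = TRUE,
                prob = c(0.61, 0.39))
  bmi <- round(stats::rnorm(n_total, 26.6, 5.0), 1)
  performance_status <- stats::rbinom(n_total, 1, 0.293)
  smoking <- sample(c("smoker", "ex-smoker", "non-smoker"), n_total,
                    replace = TRUE, prob = c(0.297, 0.521, 0.182))

  d30_nominal <- unname(eq5d_timepoints()["d30"])
  m3_nominal <- unname(eq5d_timepoints()["m3"])

  death_day <- rep(NA_integer_, n_total)
  die30 <- stats::rbinom(n_total, 1, config$death_prob_30d[arm]) == 1
  death_day[die30] <- sample.int(d30_nominal, sum(die30), replace = TRUE)
  die3m <- !die30 & stats::rbinom(n_total, 1, config$death_prob_3m[arm]) == 1
  death_day[die3m] <- d30_nominal +
    sample.int(m3_nominal - d30_nominal, sum(die3m), replace = TRUE)

  jittered_visit <- function(nominal, floor_day) {
    day <- nominal + round(stats::rnorm(n_total, 0, config$visit_jitter_sd))
    off <- stats::runif(n_total) < config$prob_visit_off_window
    day[off] <- nominal + sample(c(-1, 1), sum(off), replace = TRUE) *
      sample(16:45, sum(off), replace = TRUE)
    pmax(day, floor_day)
  }
  d30_day <- jittered_visit(d30_nominal, 5L)
  m3_day <- pmax(jittered_visit(m3_nominal, 40L), d30_day + 7L)

  d30_occurs <- is.na(death_day) | death_day > d30_day
  m3_occurs <- is.na(death_day) | death_day > m3_day
  d30_undated <- d30_occurs & stats::runif(n_total) < config$prob_visit_undated
  m3_undated <- m3_occurs & stats::runif(n_total) < config$prob_visit_undated
  d30_day[!d30_occurs | d30_undated] <- NA_integer_
  m3_day[!m3_occurs | m3_undated] <- NA_integer_

  data.frame(
    patient_id = sprintf("P%04d", seq_len(n_total)),
    centre_id = centre, arm = arm, age = age, sex = sex, bmi = bmi,
    performance_status = performance_status, smoking = smoking,
    death_day = as.integer(death_day),
    visit_d30_day = as.integer(d30_day), visit_d30_undated = d30_undated,
    visit_m3_day = as.integer(m3_day), visit_m3_undated = m3_undated,
    stringsAsFactors = FALSE)
}

#' Simulate EQ-5D-3L observations at the four administration times
#'
#' For each living, non-censored patient and each timepoint, draws a latent
#' normal utility whose mean is calibrated ([calibrate_latent_mean()]) so
#' that the mean of the *scored* utilities matches the configured per-arm
#' per-timepoint target, then maps it to the nearest achievable health state
#' ([map_latent_to_state()]). The pre-operative questionnaire is anchored at
#' day 0 (surgery); d30/m3 observations inherit the patient's (possibly
#' jittered or missing) visit date.
#'
#' @param patients Output of [generate_trial()].
#' @param config The same [trial_config()].
#' @param value_set An `eq5d_value_set`; the tariff the latent utilities are
#'   inverted against and scored with.
#' @return data.frame with `patient_id`, `timepoint`, `day`, the five level
#'   columns ([eq5d_dimensions()]) and `utility`.
#' @export
simulate_eq5d <- function(patients, config, value_set = load_value_set()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed + 1L)
  tps <- eq5d_timepoints()
  mu <- config$utility_means
  latent_mu <- mu
  for (a in rownames(mu)) for (tp in colnames(mu)) {
    latent_mu[a, tp] <- calibrate_latent_mean(mu[a, tp], config$utility_sd,
                                              value_set)
  }
  out <- list()
  for (tp in names(tps)) {
    present <- switch(tp,
      preop = rep(TRUE, nrow(patients)),
      d3 = is.na(patients$death_day) | patients$death_day > tps["d3"],
      d30 = !is.na(patients$visit_d30_day) | patients$visit_d30_undated,
      m3 = !is.na(patients$visit_m3_day) | patients$visit_m3_undated)
    p <- patients[present, ]
    if (!nrow(p)) next
    latent <- stats::rnorm(nrow(p), latent_mu[p$arm, tp], config$utility_sd)
    st <- map_latent_to_state(latent, value_set)
    day <- switch(tp,
      preop = rep(0L, nrow(p)), d3 = rep(unname(tps["d3"]), nrow(p)),
      d30 = p$visit_d30_day, m3 = p$visit_m3_day)
    out[[tp]] <- data.frame(patient_id = p$patient_id, timepoint = tp,
                            day = as.integer(day),
                            st[, eq5d_dimensions()],
                            utility = st$utility, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  obs <- obs[order(obs$patient_id, match(obs$timepoint, names(tps))), ]
  rownames(obs) <- NULL
  obs
}

#' Simulate hospital-stay events
#'
#' Every patient gets exactly one initial stay (admission day 0, length of
#' stay gamma-distributed with the configured per-arm mean/SD, rounded up to
#' whole days, minimum 1; the gamma mean is shifted down by half a day so
#' the rounded-up LOS matches the configured mean). Re-hospitalisations and
#' rehabilitation admissions occur with the configured per-window
#' probabilities, fall strictly inside their window (discharge to d30, d30
#' to m3), and are censored by death: no event starts on or after the death
#' day, and a death during the initial stay truncates its discharge.
#' Re-hospitalisations carry an admission `reason` that keys the DRG rule
#' table; the configured reason mix includes a small share of reasons absent
#' from the table, which later surface as uncostable stays.
#'
#' @inheritParams simulate_eq5d
#' @return data.frame of stay events: `patient_id`, `stay_type` (initial /
#'   rehospitalisation / rehabilitation), `admission_day`, `discharge_day`,
#'   `los`, `reason`, `complication_level`.
#' @export
simulate_resource_use <- function(patients, config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed + 2L)
  n <- nrow(patients)
  arm <- patients$arm
  gamma_los <- function(n, mean, sd) {
    m <- pmax(mean - 0.5, 0.51)  # compensate ceiling() upward shift
    shape <- (m / sd)^2
    pmax(1L, as.integer(ceiling(stats::rgamma(n, shape = shape,
                                              rate = m / sd^2))))
  }
  los <- gamma_los(n, config$los_mean[arm], config$los_sd[arm])
  discharge <- los
  died_in_initial <- !is.na(patients$death_day) & patients$death_day <= los
  discharge[died_in_initial] <- patients$death_day[died_in_initial]
  major <- stats::rbinom(n, 1, config$major_complication_prob) == 1
  reint <- stats::rbinom(n, 1, config$reintervention_prob) == 1
  prolonged <- los > config$los_mean[arm] + 2 * config$los_sd[arm]
  initial <- data.frame(
    patient_id = patients$patient_id, stay_type = "initial",
    admission_day = 0L, discharge_day = as.integer(discharge),
    los = as.integer(discharge), reason = NA_character_,
    complication_level = severity_level(major, reint, prolonged),
    stringsAsFactors = FALSE)

  d30 <- unname(eq5d_timepoints()["d30"])
  m3 <- unname(eq5d_timepoints()["m3"])
  window_events <- function(type, prob_by_arm, win_lo, win_hi, los_mean, los_sd) {
    happens <- stats::rbinom(n, 1, prob_by_arm[arm]) == 1
    lo <- pmax(win_lo, initial$discharge_day + 1L)
    hi <- rep(win_hi, n)
    dead <- !is.na(patients$death_day)
    hi[dead] <- pmin(hi[dead], patients$death_day[dead] - 1L)
    ok <- happens & lo <= hi
    if (!any(ok)) return(NULL)
    adm <- lo[ok] + as.integer(floor(stats::runif(sum(ok)) *
                                     (hi[ok] - lo[ok] + 1L)))
    elos <- gamma_los(sum(ok), los_mean, los_sd)
    reason <- if (type == "rehospitalisation") {
      sample(names(config$rehosp_reason_probs), sum(ok), replace = TRUE,
             prob = config$rehosp_reason_probs)
    } else rep("rehabilitation", sum(ok))
    data.frame(patient_id = patients$patient_id[ok], stay_type = type,
               admission_day = adm, discharge_day = adm + elos,
               los = elos, reason = reason,
               complication_level = NA_integer_, stringsAsFactors = FALSE)
  }
  events <- rbind(
    window_events("rehospitalisation", config$rehosp_prob_30d, 1L, d30 - 1L, 5, 3),
    window_events("rehabilitation", config$rehab_prob_30d, 1L, d30 - 1L, 20, 8),
    window_events("rehospitalisation", config$rehosp_prob_3m, d30 + 1L, m3 - 2L, 5, 3),
    window_events("rehabilitation", config$rehab_prob_3m, d30 + 1L, m3 - 2L, 20, 8))
  stays <- rbind(initial, events)
  stays <- stays[order(stays$patient_id, stays$admission_day), ]
  rownames(stays) <- NULL
  stays
}

#' Delete EQ-5D records according to the configured missingness mechanism
#'
#' MCAR deletes each timepoint record independently with the per-timepoint
#' rate. MAR deletes with a probability that is logistic in the arm and the
#' patient's (pre-deletion) pre-operative utility, with the intercept
#' calibrated per timepoint so the average deletion probability still equals
#' the configured rate; the pre-operative record itself is deleted MCAR.
#' A deleted record keeps its row and day but has all five levels and the
#' utility set to `NA`.
#'
#' @param observations Output of [simulate_eq5d()].
#' @inheritParams simulate_eq5d
#' @param patients The patient table (for arm membership under MAR).
#' @return `observations` with responses blanked on deleted records.
#' @export
apply_missingness <- function(observations, config, patients = NULL) {
  stopifnot(inherits(config, "trial_config"))
  rate <- config$missing_rate
  if (any(rate < 0 | rate > 1)) stop("missing_rate outside [0, 1]")
  set.seed(config$seed + 3L)
  obs <- observations
  if (config$missing_mechanism == "MCAR") {
    p <- rate[obs$timepoint]
    drop <- stats::runif(nrow(obs)) < p
  } else {
    if (is.null(patients)) stop("MAR missingness needs the patient table")
    pre <- obs[obs$timepoint == "preop", c("patient_id", "utility")]
    u_pre <- pre$utility[match(obs$patient_id, pre$patient_id)]
    u_pre[is.na(u_pre)] <- mean(pre$utility, na.rm = TRUE)
    arm <- patients$arm[match(obs$patient_id, patients$patient_id)]
    lp <- config$mar_arm_coef * (arm == "VATS") +
      config$mar_utility_coef * u_pre
    drop <- logical(nrow(obs))
    for (tp in names(rate)) {
      i <- obs$timepoint == tp
      if (!any(i)) next
      if (tp == "preop") {
        drop[i] <- stats::runif(sum(i)) < rate[tp]
      } else {
        a <- stats::uniroot(function(a) mean(stats::plogis(a + lp[i])) - rate[tp],
                            c(-30, 30))$root
        drop[i] <- stats::runif(sum(i)) < stats::plogis(a + lp[i])
      }
    }
  }
  obs[drop, c(eq5d_dimensions(), "utility")] <- NA
  obs
}

#' Simulate a complete synthetic trial dataset
#'
#' Convenience wrapper running [generate_trial()], [simulate_eq5d()],
#' [simulate_resource_use()] and [apply_missingness()] under one seed.
#'
#' @inheritParams simulate_eq5d
#' @return list with `patients`, `observations` (missingness applied),
#'   `observations_complete` (before deletion, the simulation truth) and
#'   `stays`.
#' @export
simulate_trial <- function(config, value_set = load_value_set()) {
  patients <- generate_trial(config)
  complete <- simulate_eq5d(patients, config, value_set)
  stays <- simulate_resource_use(patients, config)
  observations <- apply_missingness(complete, config, patients)
  list(patients = patients, observations = observations,
       observations_complete = complete, stays = stays)
}

#' Write a simulated trial to three CSV files
#'
#' Files `patients.csv`, `eq5d_observations.csv` and `stays.csv` with the
#' column layouts documented in [generate_trial()], [simulate_eq5d()] and
#' [simulate_resource_use()]; all dates are integer day offsets from surgery
#' (day 0).
#'
#' @param trial Output of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trial_csvs <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$observations, file.path(dir, "eq5d_observations.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$stays, file.path(dir, "stays.csv"), row.names = FALSE)
  invisible(dir)
}
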