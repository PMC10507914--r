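test_that("one complete block forces exact arm balance, and seeds are reproducible", {
  cfg <- trial_config(n_per_arm = 6, n_centres = 1, seed = 1)
  p <- generate_trial(cfg)
  expect_equal(nrow(p), 12)
  expect_equal(unname(table(p$arm)["VATS"]), 6L)
  expect_identical(generate_trial(cfg), p)
  tr1 <- simulate_trial(cfg)
  tr2 <- simulate_trial(cfg)
  expect_identical(tr1, tr2)
})

test_that("blocked randomisation keeps per-centre imbalance within half a block", {
  cfg <- trial_config(n_per_arm = 130, n_centres = 10, seed = 2)
  p <- generate_trial(cfg)
  expect_equal(nrow(p), 260)
  imb <- tapply(p$arm == "VATS", p$centre_id,
                function(x) abs(sum(x) - sum(!x)))
  expect_true(all(imb <= 6))
})

test_that("complete blocks are always exactly balanced across many trials", {
  for (s in 1:1000) {
    p <- generate_trial(trial_config(n_per_arm = 6, n_centres = 1, seed = s))
    expect_identical(sum(p$arm == "VATS"), 6L)
  }
})

test_that("scored utilities are calibrated to the configured arm/timepoint means", {
  cfg <- trial_config(n_per_arm = 130, seed = 3, missing_rate = c(
    preop = 0, d3 = 0, d30 = 0, m3 = 0))
  tr <- simulate_trial(cfg)
  obs <- merge(tr$observations, tr$patients[, c("patient_id", "arm")])
  for (a in trial_arms()) for (tp in names(eq5d_timepoints())) {
    m <- mean(obs$utility[obs$arm == a & obs$timepoint == tp], na.rm = TRUE)
    expect_lt(abs(m - cfg$utility_means[a, tp]), 0.05)
  }
  # the day-3 thoracoscopy mean specifically: target 0.66, n ~ 130
  m_d3 <- mean(obs$utility[obs$arm == "VATS" & obs$timepoint == "d3"],
               na.rm = TRUE)
  expect_gt(m_d3, 0.61)
  expect_lt(m_d3, 0.71)
})

test_that("a full-health target with zero spread yields only state 11111", {
  um <- default_utility_means()
  um[] <- 1
  cfg <- trial_config(n_per_arm = 10, n_centres = 1, seed = 4,
                      utility_means = um, utility_sd = 0,
                      missing_rate = c(preop = 0, d3 = 0, d30 = 0, m3 = 0))
  obs <- simulate_eq5d(generate_trial(cfg), cfg, the_value_set)
  expect_true(all(obs[, eq5d_dimensions()] == 1))
  expect_true(all(obs$utility == 1))
})

test_that("zero event probabilities yield only initial stays; every patient has exactly one", {
  cfg <- trial_config(n_per_arm = 40, seed = 5,
                      rehosp_prob_30d = 0, rehosp_prob_3m = 0,
                      rehab_prob_30d = 0, rehab_prob_3m = 0)
  stays <- simulate_resource_use(generate_trial(cfg), cfg)
  expect_true(all(stays$stay_type == "initial"))
  expect_equal(nrow(stays), 80)
  expect_equal(anyDuplicated(stays$patient_id), 0L)
})

test_that("death censors stay events and truncates the initial discharge", {
  cfg <- trial_config(n_per_arm = 80, seed = 6,
                      death_prob_30d = 0.3, death_prob_3m = 0.4,
                      rehosp_prob_30d = 0.4, rehosp_prob_3m = 0.4,
                      rehab_prob_30d = 0.3, rehab_prob_3m = 0.3)
  p <- generate_trial(cfg)
  stays <- simulate_resource_use(p, cfg)
  dd <- p$death_day[match(stays$patient_id, p$patient_id)]
  ev <- stays$stay_type != "initial" & !is.na(dd)
  expect_true(all(stays$admission_day[ev] < dd[ev]))
  ini <- stays$stay_type == "initial" & !is.na(dd)
  expect_true(all(stays$discharge_day[ini] <= dd[ini]))
  expect_true(all(stays$los >= 1))
})

test_that("re-hospitalisation counts match the configured window probability", {
  counts <- vapply(1:30, function(s) {
    cfg <- trial_config(n_per_arm = 131, seed = s)
    p <- generate_trial(cfg)
    stays <- simulate_resource_use(p, cfg)
    arm <- p$arm[match(stays$patient_id, p$patient_id)]
    sum(stays$stay_type == "rehospitalisation" & arm == "VATS" &
          stays$admission_day <= 30)
  }, numeric(1))
  # expectation ~ 0.0458 * 131 = 6 per trial, SE of the 30-trial mean ~ 0.45
  expect_lt(abs(mean(counts) - 0.0458 * 131), 1.5)
})

test_that("MCAR missingness hits the per-timepoint target rate and rate 0 is a no-op", {
  cfg0 <- trial_config(n_per_arm = 40, seed = 7,
                       missing_rate = c(preop = 0, d3 = 0, d30 = 0, m3 = 0))
  p0 <- generate_trial(cfg0)
  obs0 <- simulate_eq5d(p0, cfg0, the_value_set)
  expect_identical(apply_missingness(obs0, cfg0, p0), obs0)

  cfg <- trial_config(n_per_arm = 130, seed = 8, missing_rate = c(
    preop = 0.25, d3 = 0.25, d30 = 0.25, m3 = 0.25))
  tr <- simulate_trial(cfg)
  m3 <- tr$observations[tr$observations$timepoint == "m3", ]
  frac <- mean(is.na(m3$utility))
  n <- nrow(m3)
  expect_lt(abs(frac - 0.25), 3.5 * sqrt(0.25 * 0.75 / n))
})

test_that("MAR missingness selects on pre-operative utility", {
  cfg <- trial_config(n_per_arm = 250, seed = 9, missing_mechanism = "MAR",
                      missing_rate = c(preop = 0, d3 = 0.2, d30 = 0.2, m3 = 0.3))
  p <- generate_trial(cfg)
  complete <- simulate_eq5d(p, cfg, the_value_set)
  obs <- apply_missingness(complete, cfg, p)
  pre <- complete[complete$timepoint == "preop", c("patient_id", "utility")]
  m3 <- obs[obs$timepoint == "m3", ]
  u_pre <- pre$utility[match(m3$patient_id, pre$patient_id)]
  miss <- is.na(m3$utility)
  tt <- t.test(u_pre[miss], u_pre[!miss])
  expect_lt(mean(u_pre[miss]), mean(u_pre[!miss]))
  expect_lt(tt$p.value, 0.01)
})

test_that("generator moments converge to configuration at large n", {
  cfg <- trial_config(n_per_arm = 2500, n_centres = 10, seed = 10,
                      missing_rate = c(preop = 0, d3 = 0, d30 = 0, m3 = 0))
  tr <- simulate_trial(cfg)
  p <- tr$patients
  obs <- merge(tr$observations, p[, c("patient_id", "arm")])
  for (a in trial_arms()) {
    expect_lt(abs(mean(obs$utility[obs$arm == a & obs$timepoint == "preop"]) -
                    cfg$utility_means[a, "preop"]), 0.02)
  }
  stays <- tr$stays
  arm <- p$arm[match(stays$patient_id, p$patient_id)]
  ini <- stays$stay_type == "initial"
  for (a in trial_arms()) {
    expect_lt(abs(mean(stays$los[ini & arm == a]) - cfg$los_mean[a]), 0.25)
  }
  rate <- sum(stays$stay_type == "rehospitalisation" & arm == "VATS" &
                stays$admission_day <= 30) / sum(p$arm == "VATS")
  expect_lt(abs(rate - cfg$rehosp_prob_30d["VATS"]),
            3 * sqrt(0.0458 * 0.9542 / 2500))
})

test_that("visit dates are strictly increasing and censored by death", {
  tr <- small_trial()$trial
  p <- tr$patients
  both <- !is.na(p$visit_d30_day) & !is.na(p$visit_m3_day)
  expect_true(all(p$visit_d30_day[both] < p$visit_m3_day[both]))
  dead <- !is.na(p$death_day)
  expect_true(all(is.na(p$visit_d30_day[dead]) |
                    p$visit_d30_day[dead] < p$death_day[dead]))
})

test_that("config validation rejects impossible settings", {
  expect_error(trial_config(seed = 1, n_per_arm = 0), "positive")
  expect_error(trial_config(seed = 1, block_size = 7), "even")
  expect_error(trial_config(seed = 1, rehosp_prob_30d = 1.2), "\\[0, 1\\]")
  expect_error(trial_config(), "seed")
})
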