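imputation_fixture <- function(seed = 303, n_per_arm = 80,
                               rate = 0.2, mechanism = "MCAR", ...) {
  cfg <- trial_config(seed = seed, n_per_arm = n_per_arm,
                      missing_rate = c(preop = rate, d3 = rate,
                                       d30 = rate, m3 = rate),
                      missing_mechanism = mechanism, ...)
  tr <- simulate_trial(cfg)
  costed <- suppressWarnings(cost_stays(tr$stays, tr$patients))
  cc <- suppressWarnings(cumulative_costs(tr$patients, costed))
  eligible <- tr$patients[is.na(tr$patients$death_day), ]
  list(trial = tr, costs = cc, eligible = eligible,
       frame = build_imputation_frame(eligible, tr$observations, cc))
}

test_that("a complete dataset passes through as m identical copies", {
  # all admission reasons costable, so no NA cost components either
  fx <- imputation_fixture(rate = 0,
                           rehosp_reason_probs = c(respiratory = 1))
  expect_false(anyNA(fx$frame))
  ic <- imputation_config(m = 4, seed = 1)
  res <- mice_impute(fx$frame, ic)
  expect_length(res$completed, 4)
  for (d in res$completed) expect_identical(d, fx$frame)
})

test_that("imputation preserves observed cells and fills items on the ordinal scale", {
  fx <- imputation_fixture()
  ic <- imputation_config(m = 3, max_iterations = 3, seed = 2)
  res <- mice_impute(fx$frame, ic)
  items <- as.vector(outer(eq5d_dimensions(), names(eq5d_timepoints()),
                           paste, sep = "_"))
  obs_mask <- !is.na(fx$frame[items])
  for (d in res$completed) {
    expect_false(anyNA(d[items]))
    expect_true(all(as.matrix(d[items]) %in% 1:3))
    expect_identical(as.matrix(d[items])[obs_mask],
                     as.matrix(fx$frame[items])[obs_mask])
    expect_identical(d$age, fx$frame$age)
  }
})

test_that("PMM-imputed costs are drawn from the observed donor pool", {
  fx <- imputation_fixture(seed = 404, n_per_arm = 130)
  frame <- fx$frame
  # ensure there is cost missingness even if no stay was uncostable
  set.seed(8)
  hole <- sample(which(!is.na(frame$cost_initial)), 20)
  frame$cost_initial[hole] <- NA
  ic <- imputation_config(m = 2, max_iterations = 3, seed = 3)
  res <- mice_impute(frame, ic)
  donors <- frame$cost_initial[!is.na(frame$cost_initial)]
  for (d in res$completed) {
    expect_true(all(d$cost_initial[hole] %in% donors))
  }
})

test_that("imputation is deterministic under its seed and reports its trace", {
  fx <- imputation_fixture()
  ic <- imputation_config(m = 2, max_iterations = 2, seed = 4)
  r1 <- mice_impute(fx$frame, ic)
  r2 <- mice_impute(fx$frame, ic)
  expect_identical(r1$completed, r2$completed)
  expect_equal(dim(r1$trace)[1:2], c(2L, 2L))
  expect_false(anyNA(r1$trace))
})

test_that("a variable that is entirely missing is refused", {
  fx <- imputation_fixture()
  frame <- fx$frame
  frame$mobility_m3 <- NA_integer_
  expect_error(mice_impute(frame, imputation_config(m = 2, seed = 5)),
               "100% missing")
})

test_that("pooling follows Rubin's rule for point estimates", {
  r <- list(list(delta_cost = 100, delta_effect = 0.01,
                 se_cost = 50, se_effect = 0.005),
            list(delta_cost = 200, delta_effect = 0.03,
                 se_cost = 60, se_effect = 0.006))
  p <- pool_estimates(r)
  expect_equal(p$pooled_delta_cost, 150)
  expect_equal(p$pooled_delta_effect, 0.02)
  expect_equal(p$pooled_icer, 7500)
  expect_equal(p$var_cost$W, mean(c(50, 60)^2))
  expect_equal(p$var_cost$B, var(c(100, 200)))
  expect_equal(p$var_cost$total, p$var_cost$W + 1.5 * p$var_cost$B)
  # identical results pool to themselves with zero between-variance
  same <- list(r[[1]], r[[1]])
  ps <- pool_estimates(same)
  expect_equal(ps$pooled_delta_cost, 100)
  expect_equal(ps$var_cost$B, 0)
  expect_error(pool_estimates(list(list(delta_cost = 1))), "structure")
})

test_that("pooled 3-month differentials reproduce their printed ratio", {
  p <- pool_estimates(list(list(delta_cost = 1801, delta_effect = 0.0421),
                           list(delta_cost = 1801, delta_effect = 0.0421)))
  expect_equal(icer_reported(icer(p$pooled_delta_cost, p$pooled_delta_effect)),
               42779)
})

test_that("with no missing data the imputed analysis equals the complete-data analysis", {
  fx <- imputation_fixture(rate = 0,
                           rehosp_reason_probs = c(respiratory = 1))
  ic <- imputation_config(m = 2, max_iterations = 2, seed = 6)
  res <- imputed_cua(fx$frame, ic, the_value_set, "d30", B = 200, seed = 7)
  out <- thoracoCUA:::completed_outcomes(fx$frame, the_value_set, "d30")
  truth <- mean(out$cost[out$arm == "VATS"]) -
    mean(out$cost[out$arm == "THORACOTOMY"])
  expect_equal(res$pooled$pooled_delta_cost, truth)
  expect_equal(res$pooled$var_cost$B, 0)
  # same seed twice: identical interval
  res2 <- imputed_cua(fx$frame, ic, the_value_set, "d30", B = 200, seed = 7)
  expect_identical(res$ci, res2$ci)
})

test_that("re-imputing inside each bootstrap resample is available as an alternative ordering", {
  fx <- imputation_fixture(seed = 505, n_per_arm = 40)
  ic <- imputation_config(m = 2, max_iterations = 2, seed = 8)
  res <- imputed_cua(fx$frame, ic, the_value_set, "d30", B = 5, seed = 9,
                     nesting = "reimpute")
  expect_equal(nrow(res$replicates), 5)
  expect_false(anyNA(res$replicates))
})

test_that("interval width grows with the missingness rate", {
  widths <- sapply(c(0, 0.3), function(rate) {
    mean(sapply(1:4, function(s) {
      fx <- imputation_fixture(seed = 600 + s, n_per_arm = 60, rate = rate)
      ic <- imputation_config(m = 3, max_iterations = 3, seed = s,
                              predictors = c(default_imputation_predictors(),
                                             "arm"))
      res <- imputed_cua(fx$frame, ic, the_value_set, "d30",
                         B = 600, seed = s + 50)
      q <- quantile(res$replicates$delta_effect, c(0.025, 0.975))
      diff(q)
    }))
  })
  expect_gt(widths[2], widths[1])
})
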