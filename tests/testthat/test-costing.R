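cpi_fixture <- data.frame(year = c(2015, 2016, 2017, 2018),
                          index = c(100, 100.4, 100.9, 101.5))

test_that("price inflation follows the index ratio", {
  expect_equal(inflate_cost(100, 2015, 2015, cpi_fixture), 100)
  expect_equal(inflate_cost(100, 2015, 2017, cpi_fixture), 100.9)
  # hand arithmetic: amount * idx(2018)/idx(2016)
  expect_equal(inflate_cost(2455.58, 2016, 2018, cpi_fixture),
               2455.58 * 101.5 / 100.4)
  expect_error(inflate_cost(100, 2012, 2018, cpi_fixture), "2012")
})

test_that("severity levels add one per aggravating factor, capped at 4", {
  expect_equal(severity_level(FALSE, FALSE, FALSE), 1L)
  expect_equal(severity_level(TRUE, FALSE, TRUE), 3L)
  expect_equal(severity_level(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE)),
               c(4L, 3L))
})

test_that("DRG assignment maps stay types to their codes and flags uncostable stays", {
  stays <- rbind(stay_row("A", "initial", 0, 7, level = 1L),
                 stay_row("A", "rehabilitation", 10, 20),
                 stay_row("B", "initial", 0, 5, level = 3L),
                 stay_row("B", "rehospitalisation", 12, 4, reason = "respiratory"))
  out <- assign_drg(stays)
  expect_equal(out$drg_code, c("04C021", "0403B1", "04C023", "04M051"))
  bad <- stay_row("B", "rehospitalisation", 12, 4, reason = "martian")
  expect_warning(out2 <- assign_drg(bad), "uncostable")
  expect_true(is.na(out2$drg_code))
  expect_error(assign_drg(stay_row("A", "day_case", 0, 1)), "stay_type")
})

test_that("adjusted-DRG cost substitutes theatre cost and prorates the remainder", {
  cat1 <- data.frame(drg_code = "04C021", label = "x", total_cost = 9000,
                     operating_room_cost = 2000, national_mean_los = 7)
  expect_equal(adjusted_drg_cost(7, "04C021", "THORACOTOMY", cat1), 9455.58)
  expect_equal(adjusted_drg_cost(0, "04C021", "THORACOTOMY", cat1), 2455.58)
  # identical catalog and LOS: arm difference is exactly the theatre cost gap
  expect_equal(adjusted_drg_cost(9, "04C021", "VATS", cat1) -
                 adjusted_drg_cost(9, "04C021", "THORACOTOMY", cat1),
               3870.49 - 2455.58)
  expect_error(adjusted_drg_cost(7, "99Z999", "VATS", cat1), "missing")
})

test_that("standard DRG costing: flat rehabilitation tariff, catalog pass-through, optional prorating", {
  expect_equal(standard_drg_cost(25, "0403B1"), 6222.20)
  cat2 <- data.frame(drg_code = c("04M051", "04X001"), label = "x",
                     total_cost = c(4205, 4200),
                     operating_room_cost = 0, national_mean_los = c(6.2, 7))
  expect_equal(standard_drg_cost(4, "04M051", cat2), 4205)
  expect_equal(standard_drg_cost(3, "04X001", cat2, prorate = TRUE), 1800)
})

test_that("cumulative costs respect the half-open visit windows", {
  p <- two_patients()
  stays <- rbind(stay_row("A", "initial", 0, 7, level = 1L),
                 stay_row("A", "rehabilitation", 20, 25),
                 stay_row("B", "initial", 0, 7, level = 1L),
                 stay_row("B", "rehospitalisation", 95, 4,
                          reason = "respiratory"))
  costed <- cost_stays(stays, p)
  cc <- cumulative_costs(p, costed)
  # patient A: initial (thoracotomy, los 7, daily 946) + one rehab before d30
  ini_a <- 2455.58 + 946 * 7
  expect_equal(cc$cost_d30[cc$patient_id == "A"], ini_a + 6222.20)
  expect_equal(cc$cost_m3[cc$patient_id == "A"], ini_a + 6222.20)
  # patient B: re-hospitalisation after the m3 visit is outside both horizons
  ini_b <- 3870.49 + 946 * 7
  expect_equal(cc$cost_d30[cc$patient_id == "B"], ini_b)
  expect_equal(cc$cost_m3[cc$patient_id == "B"], ini_b)
})

test_that("an initial stay alone gives equal horizons", {
  p <- two_patients()[1, ]
  costed <- cost_stays(stay_row("A", "initial", 0, 7, level = 1L), p)
  cc <- cumulative_costs(p, costed)
  expect_equal(cc$cost_d30, cc$cost_m3)
  expect_equal(cc$cost_d30, 2455.58 + 946 * 7)
})

test_that("uncostable stays are excluded from sums with a warning and counted", {
  p <- two_patients()
  stays <- rbind(stay_row("A", "initial", 0, 7, level = 1L),
                 stay_row("A", "rehospitalisation", 10, 4, reason = "martian"),
                 stay_row("B", "initial", 0, 7, level = 1L))
  costed <- suppressWarnings(cost_stays(stays, p))
  expect_warning(cc <- cumulative_costs(p, costed), "uncosted")
  expect_equal(cc$cost_d30[cc$patient_id == "A"], 2455.58 + 946 * 7)
  expect_equal(cc$n_uncosted_30d[cc$patient_id == "A"], 1L)
  expect_equal(cc$n_uncosted_30d[cc$patient_id == "B"], 0L)
})

test_that("cumulative costs are monotone, additive and scale-equivariant on a synthetic cohort", {
  tc <- small_trial(seed = 202, n_per_arm = 100)
  tr <- tc$trial
  costed <- suppressWarnings(cost_stays(tr$stays, tr$patients))
  cc <- suppressWarnings(cumulative_costs(tr$patients, costed))
  expect_true(all(cc$cost_m3 >= cc$cost_d30))
  # additivity: independent per-patient summation over window membership
  d30_end <- ifelse(is.na(tr$patients$visit_d30_day), 30,
                    tr$patients$visit_d30_day)
  for (pid in sample(cc$patient_id, 25)) {
    s <- costed[costed$patient_id == pid & !is.na(costed$cost), ]
    lim <- d30_end[tr$patients$patient_id == pid]
    manual <- sum(s$cost[s$stay_type == "initial"]) +
      sum(s$cost[s$stay_type != "initial" & s$admission_day > 0 &
                   s$admission_day <= lim])
    expect_equal(cc$cost_d30[cc$patient_id == pid], manual)
  }
  # scale equivariance (cent rounding allows a sub-cent slack per stay)
  k <- 2.5
  catk <- load_drg_catalog()
  catk$total_cost <- catk$total_cost * k
  catk$operating_room_cost <- catk$operating_room_cost * k
  costedk <- suppressWarnings(cost_stays(tr$stays, tr$patients, catalog = catk,
    surgery_costs = surgery_cost_table(3870.49 * k, 2455.58 * k)))
  cck <- suppressWarnings(cumulative_costs(tr$patients, costedk))
  expect_equal(cck$cost_m3, cc$cost_m3 * k, tolerance = 1e-6)
})

test_that("degenerate limit: zero theatre cost and zero OR component reduce to daily cost times LOS", {
  cat3 <- data.frame(drg_code = "04C021", label = "x", total_cost = 7000,
                     operating_room_cost = 0, national_mean_los = 7)
  eps <- 1e-9
  expect_equal(adjusted_drg_cost(5, "04C021", "VATS", cat3,
                                 surgery_cost_table(eps, eps)),
               round(1000 * 5 + eps, 2))
})

test_that("catalog loading enforces its invariants", {
  cat_ok <- load_drg_catalog()
  expect_s3_class(cat_ok, "drg_catalog")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(drg_code = "X", label = "x", total_cost = 10,
                       operating_room_cost = 20, national_mean_los = 5),
            bad, row.names = FALSE)
  expect_error(load_drg_catalog(bad), "total_cost")
})
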