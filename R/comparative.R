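#' Complete-case exclusion cascade for the cost-utility analysis
#'
#' Applies the exclusion criteria in their stated order, attributing each
#' excluded patient to the first failing criterion. At the 30-day horizon:
#' (i) died before the d30 visit; (ii) d30 visit performed much earlier or
#' later than day 30 (outside +/- `window_tol` days); (iii) undated d30
#' visit; (iv) missing EQ-5D data among the required timepoints. At the
#' 3-month horizon: (i) excluded from the 30-day complete-case set; then
#' (ii) died between the d30 and m3 visits; (iii) m3 visit off-window; (iv)
#' undated m3 visit; (v) missing EQ-5D data.
#'
#' @param patients Patient table.
#' @param qalys Output of [compute_qalys()] at the same horizon.
#' @param horizon `"d30"` or `"m3"`.
#' @param window_tol Half-width (days) of the acceptable visit window.
#' @param d30_included For the m3 horizon: patient ids included at 30 days
#'   (computed internally when omitted).
#' @param qalys_d30 For the m3 horizon when `d30_included` is omitted: the
#'   30-day QALY table.
#' @return list with `included` (patient ids), `counts` (named exclusion
#'   counts, in cascade order, plus `included`), and `flags` (per-patient
#'   first failing criterion, `"included"` if none).
#' @export
apply_cua_exclusions <- function(patients, qalys, horizon = c("d30", "m3"),
                                 window_tol = 14, d30_included = NULL,
                                 qalys_d30 = NULL) {
  horizon <- match.arg(horizon)
  tps <- eq5d_timepoints()
  qal <- qalys[match(patients$patient_id, qalys$patient_id), ]
  flag <- rep(NA_character_, nrow(patients))
  mark <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    flag[is.na(flag) & cond] <<- label
  }
  if (horizon == "d30") {
    nominal <- unname(tps["d30"])
    visit <- patients$visit_d30_day
    died_before <- !is.na(patients$death_day) &
      (is.na(visit) | patients$death_day <= visit) &
      patients$death_day <= nominal + window_tol
    mark(died_before, "died_before_d30")
    mark(!is.na(visit) & abs(visit - nominal) > window_tol, "d30_off_window")
    mark(patients$visit_d30_undated | is.na(visit), "d30_undated")
    mark(!qal$complete, "missing_eq5d")
    order_labels <- c("died_before_d30", "d30_off_window", "d30_undated",
                      "missing_eq5d")
  } else {
    if (is.null(d30_included)) {
      if (is.null(qalys_d30)) stop("m3 cascade needs d30_included or qalys_d30")
      d30_included <- apply_cua_exclusions(patients, qalys_d30, "d30",
                                           window_tol)$included
    }
    nominal <- unname(tps["m3"])
    visit <- patients$visit_m3_day
    mark(!patients$patient_id %in% d30_included, "excluded_at_d30")
    died_between <- !is.na(patients$death_day) &
      patients$death_day > tps["d30"] &
      (is.na(visit) | patients$death_day <= visit) &
      patients$death_day <= nominal + window_tol
    mark(died_between, "died_d30_to_m3")
    mark(!is.na(visit) & abs(visit - nominal) > window_tol, "m3_off_window")
    mark(patients$visit_m3_undated | is.na(visit), "m3_undated")
    mark(!qal$complete, "missing_eq5d")
    order_labels <- c("excluded_at_d30", "died_d30_to_m3", "m3_off_window",
                      "m3_undated", "missing_eq5d")
  }
  flag[is.na(flag)] <- "included"
  counts <- c(stats::setNames(
    vapply(order_labels, function(l) sum(flag == l), integer(1)), order_labels),
    included = sum(flag == "included"))
  list(included = patients$patient_id[flag == "included"],
       counts = counts,
       flags = data.frame(patient_id = patients$patient_id, exclusion = flag,
                          stringsAsFactors = FALSE))
}

#' Assemble the per-patient cost-effectiveness outcomes for an included set
#'
#' @param patients Patient table.
#' @param costs Output of [cumulative_costs()].
#' @param qalys Output of [compute_qalys()].
#' @param horizon `"d30"` or `"m3"`.
#' @param included Patient ids retained by the exclusion cascade; defaults
#'   to all patients with a complete QALY.
#' @return data.frame `patient_id`, `arm`, `cost`, `effect`.
#' @export
ce_outcomes <- function(patients, costs, qalys, horizon = c("d30", "m3"),
                        included = NULL) {
  horizon <- match.arg(horizon)
  if (is.null(included)) {
    included <- qalys$patient_id[qalys$complete]
  }
  keep <- patients$patient_id %in% included
  cost_col <- if (horizon == "d30") "cost_d30" else "cost_m3"
  data.frame(
    patient_id = patients$patient_id[keep],
    arm = patients$arm[keep],
    cost = costs[[cost_col]][match(patients$patient_id[keep], costs$patient_id)],
    effect = qalys$qaly[match(patients$patient_id[keep], qalys$patient_id)],
    stringsAsFactors = FALSE)
}

#' Two-sample mean difference with confidence interval
#'
#' Student's t-test (pooled variance by default, Welch optionally) on two
#' groups; the difference is mean(a) - mean(b).
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @param method `"student"` (pooled variance) or `"welch"`.
#' @param conf_level Confidence level.
#' @return list of class `mean_difference`: `mean_a`, `mean_b`,
#'   `difference`, `ci_low`, `ci_high`, `p_value`, `n_a`, `n_b`, `se`.
#' @export
mean_difference <- function(values_a, values_b,
                            method = c("student", "welch"),
                            conf_level = 0.95) {
  method <- match.arg(method)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = method == "student",
                      conf.level = conf_level)
  structure(list(mean_a = mean(values_a), mean_b = mean(values_b),
                 difference = mean(values_a) - mean(values_b),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 p_value = tt$p.value, n_a = length(values_a),
                 n_b = length(values_b), se = tt$stderr),
            class = "mean_difference")
}

#' Mortality contrast: risk difference and logistic odds ratio
#'
#' Risk difference p_a - p_b with a Wald confidence interval, and the odds
#' ratio from a single-covariate logistic regression on the arm indicator
#' with its Wald interval. With zero events in both arms the odds ratio is
#' undefined and flagged.
#'
#' @param deaths_a,n_a,deaths_b,n_b Event and group counts.
#' @param conf_level Confidence level.
#' @return list: `risk_a`, `risk_b`, `risk_difference` with `rd_ci_low/high`,
#'   `odds_ratio` with `or_ci_low/high` (NA when undefined), `or_defined`.
#' @export
mortality_contrast <- function(deaths_a, n_a, deaths_b, n_b,
                               conf_level = 0.95) {
  stopifnot(n_a > 0, n_b > 0, deaths_a <= n_a, deaths_b <= n_b)
  p_a <- deaths_a / n_a
  p_b <- deaths_b / n_b
  rd <- p_a - p_b
  se_rd <- sqrt(p_a * (1 - p_a) / n_a + p_b * (1 - p_b) / n_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(risk_a = p_a, risk_b = p_b, risk_difference = rd,
              rd_ci_low = rd - z * se_rd, rd_ci_high = rd + z * se_rd,
              odds_ratio = NA_real_, or_ci_low = NA_real_,
              or_ci_high = NA_real_, or_defined = FALSE)
  if (deaths_a + deaths_b > 0 && deaths_a < n_a && deaths_b < n_b &&
      deaths_a > 0 && deaths_b > 0) {
    y <- c(rep(1, deaths_a), rep(0, n_a - deaths_a),
           rep(1, deaths_b), rep(0, n_b - deaths_b))
    g <- c(rep(1, n_a), rep(0, n_b))
    fit <- stats::glm(y ~ g, family = stats::binomial())
    beta <- stats::coef(fit)["g"]
    se <- sqrt(stats::vcov(fit)["g", "g"])
    out$odds_ratio <- unname(exp(beta))
    out$or_ci_low <- unname(exp(beta - z * se))
    out$or_ci_high <- unname(exp(beta + z * se))
    out$or_defined <- TRUE
  }
  out
}

#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' `icer = delta_cost / delta_effect`; undefined when the effect
#' differential is zero. The quadrant places (delta_effect, delta_cost) on
#' the cost-utility plane: NE = more effective and more costly, SE = more
#' effective and cheaper, NW = less effective and more costly, SW = less
#' effective and cheaper; a zero differential lands on an axis.
#'
#' @param delta_cost,delta_effect Differentials (intervention minus
#'   comparator) computed on the same patient set.
#' @return list of class `icer_result`: `delta_cost`, `delta_effect`,
#'   `icer` (NA when undefined), `quadrant`.
#' @export
icer <- function(delta_cost, delta_effect) {
  quadrant <- if (delta_cost == 0 || delta_effect == 0) {
    "axis"
  } else if (delta_effect > 0) {
    if (delta_cost > 0) "NE" else "SE"
  } else {
    if (delta_cost > 0) "NW" else "SW"
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 icer = if (delta_effect == 0) NA_real_ else
                   delta_cost / delta_effect,
                 quadrant = quadrant),
            class = "icer_result")
}

#' Round an ICER to whole euros for reporting
#' @param x An `icer_result` or numeric ratio.
#' @export
icer_reported <- function(x) {
  v <- if (inherits(x, "icer_result")) x$icer else x
  round(v)
}
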