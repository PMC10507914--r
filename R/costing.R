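#' Load the DRG production-cost catalog
#'
#' The catalog mirrors a national hospital cost survey: one row per DRG with
#' its mean total production cost, the operating-room component (0 where not
#' applicable) and the national mean length of stay. A synthetic catalog
#' covering the thoracic-surgery DRGs used by the pipeline ships with the
#' package; the rehabilitation DRG 0403B1 carries its published flat cost of
#' 6,222.20 EUR, the other rows are synthetic and documented as such.
#'
#' @param path CSV with columns
#'   `drg_code,label,total_cost,operating_room_cost,national_mean_los`.
#' @return data.frame of class `drg_catalog`.
#' @export
load_drg_catalog <- function(path = system.file("extdata",
                                                "drg_catalog_synthetic.csv",
                                                package = "thoracoCUA")) {
  stopifnot(nzchar(path), file.exists(path))
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("drg_code", "label", "total_cost", "operating_room_cost",
              "national_mean_los")
  stopifnot(all(needed %in% names(cat)))
  if (any(cat$total_cost < cat$operating_room_cost) ||
      any(cat$operating_room_cost < 0)) {
    stop("catalog requires total_cost >= operating_room_cost >= 0")
  }
  if (any(cat$national_mean_los <= 0)) stop("national_mean_los must be > 0")
  class(cat) <- c("drg_catalog", "data.frame")
  cat
}

#' Load the re-hospitalisation DRG rule table
#'
#' Maps an admission reason to the DRG used to cost a re-hospitalisation.
#' Reasons with no row in the table make the stay uncostable.
#'
#' @param path CSV with columns `reason,drg_code`.
#' @export
load_rehosp_rules <- function(path = system.file("extdata",
                                                 "rehosp_drg_rules.csv",
                                                 package = "thoracoCUA")) {
  stopifnot(nzchar(path), file.exists(path))
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reason", "drg_code") %in% names(rules)))
  rules
}

#' Load a consumer price index series
#'
#' @param path CSV with columns `year,index` (base 100 in 2015 for the
#'   bundled synthetic health-services series).
#' @export
load_cpi <- function(path = system.file("extdata", "cpi_health_synthetic.csv",
                                        package = "thoracoCUA")) {
  stopifnot(nzchar(path), file.exists(path))
  cpi <- utils::read.csv(path)
  stopifnot(all(c("year", "index") %in% names(cpi)), all(cpi$index > 0))
  cpi
}

#' Micro-costed theatre costs per surgical approach
#'
#' The operating-room production costs substituted into the initial-stay DRG
#' cost under the adjusted-DRG method, in 2018 euros. Defaults are the
#' micro-costing estimates for video-assisted thoracoscopic surgery and open
#' thoracotomy.
#'
#' @param vats_cost,thoracotomy_cost Theatre production costs in EUR (> 0).
#' @return Named numeric vector over the arms.
#' @export
surgery_cost_table <- function(vats_cost = 3870.49, thoracotomy_cost = 2455.58) {
  stopifnot(vats_cost > 0, thoracotomy_cost > 0)
  c(VATS = vats_cost, THORACOTOMY = thoracotomy_cost)
}

#' Update an amount between price years
#'
#' `amount * index[year_to] / index[year_from]` using the supplied CPI
#' series.
#'
#' @param amount Monetary amount.
#' @param year_from,year_to Years present in the index.
#' @param cpi A data.frame from [load_cpi()].
#' @export
inflate_cost <- function(amount, year_from, year_to, cpi = load_cpi()) {
  idx <- function(y) {
    i <- cpi$index[match(y, cpi$year)]
    if (any(is.na(i))) stop("year ", paste(y[is.na(i)], collapse = ", "),
                            " missing from CPI index")
    i
  }
  amount * idx(year_to) / idx(year_from)
}

#' DRG severity level of an initial stay
#'
#' Rule: level 1, plus one for a major post-operative complication, one for
#' a re-intervention, one for a prolonged stay, capped at level 4.
#'
#' @param major_complication,reintervention,prolonged_stay Logical vectors.
#' @return Integer severity level in 1..4.
#' @export
severity_level <- function(major_complication, reintervention, prolonged_stay) {
  pmin(4L, 1L + as.integer(major_complication) + as.integer(reintervention) +
         as.integer(prolonged_stay))
}

#' Assign DRG codes to stay events
#'
#' Initial stays map to the thoracic-surgery root plus their severity digit
#' (04C021..04C024); rehabilitation stays map to the single rehabilitation
#' DRG 0403B1; re-hospitalisations map through the admission-reason rule
#' table. A re-hospitalisation whose reason has no rule gets `NA` and a
#' warning: the stay is uncostable and will be excluded from cost sums.
#'
#' @param stays data.frame of stay events (see [simulate_resource_use()]).
#' @param rules Rule table from [load_rehosp_rules()].
#' @return `stays` with a `drg_code` column.
#' @export
assign_drg <- function(stays, rules = load_rehosp_rules()) {
  type <- stays$stay_type
  unknown_type <- !type %in% c("initial", "rehospitalisation", "rehabilitation")
  if (any(unknown_type)) {
    stop("unknown stay_type: ", paste(unique(type[unknown_type]), collapse = ", "))
  }
  drg <- rep(NA_character_, nrow(stays))
  ini <- type == "initial"
  if (any(ini)) {
    lvl <- stays$complication_level[ini]
    if (any(is.na(lvl) | !(lvl %in% 1:4))) {
      stop("initial stays need complication_level in 1..4")
    }
    drg[ini] <- paste0("04C02", lvl)
  }
  drg[type == "rehabilitation"] <- "0403B1"
  reh <- type == "rehospitalisation"
  if (any(reh)) {
    drg[reh] <- rules$drg_code[match(stays$reason[reh], rules$reason)]
    n_bad <- sum(is.na(drg[reh]))
    if (n_bad > 0) {
      warning(n_bad, " re-hospitalisation stay(s) could not be assigned a DRG",
              " (no rule for reason); they are uncostable and excluded",
              call. = FALSE)
    }
  }
  stays$drg_code <- drg
  stays
}

catalog_row <- function(drg, catalog) {
  i <- match(drg, catalog$drg_code)
  if (any(is.na(i))) {
    stop("DRG ", paste(unique(drg[is.na(i)]), collapse = ", "),
         " missing from catalog")
  }
  catalog[i, , drop = FALSE]
}

#' Cost an initial stay by the adjusted-DRG method
#'
#' Replaces the catalog's operating-room component with the micro-costed
#' theatre cost of the patient's arm, and reconstitutes the rest of the stay
#' at the DRG's average daily cost weighted by the patient's own length of
#' stay: `cost = surgery_cost(arm) + los * (total - operating_room) /
#' national_mean_los`. Costs are kept at cent precision.
#'
#' @param los Patient length of stay in days (vector).
#' @param drg_code Assigned DRG codes (vector, must exist in `catalog`).
#' @param arm Arm labels, matched against `surgery_costs`.
#' @param catalog [load_drg_catalog()].
#' @param surgery_costs [surgery_cost_table()].
#' @return Costs in EUR, rounded to cents.
#' @export
adjusted_drg_cost <- function(los, drg_code, arm,
                              catalog = load_drg_catalog(),
                              surgery_costs = surgery_cost_table()) {
  entry <- catalog_row(drg_code, catalog)
  if (any(entry$national_mean_los <= 0)) stop("national_mean_los must be > 0")
  daily <- (entry$total_cost - entry$operating_room_cost) / entry$national_mean_los
  round(unname(surgery_costs[arm]) + daily * los, 2)
}

#' Cost a re-hospitalisation or rehabilitation stay from the catalog
#'
#' Gross costing: the stay takes its DRG's catalog total production cost
#' (for the bundled catalog every rehabilitation stay is therefore costed at
#' exactly 6,222.20 EUR). With `prorate = TRUE` the cost is instead the
#' DRG's average daily cost times the patient's length of stay, using the
#' same daily-cost rule as the adjusted-DRG method.
#'
#' @param los Patient length of stay (used only when `prorate = TRUE`).
#' @param drg_code Assigned DRG codes.
#' @param catalog [load_drg_catalog()].
#' @param prorate Whether to weight the catalog cost by LOS.
#' @return Costs in EUR, rounded to cents.
#' @export
standard_drg_cost <- function(los, drg_code, catalog = load_drg_catalog(),
                              prorate = FALSE) {
  entry <- catalog_row(drg_code, catalog)
  if (prorate) {
    daily <- (entry$total_cost - entry$operating_room_cost) /
      entry$national_mean_los
    round(daily * los, 2)
  } else {
    round(entry$total_cost, 2)
  }
}

#' Cost every stay event
#'
#' Assigns DRGs ([assign_drg()]) and applies the adjusted-DRG method to
#' initial stays and gross costing to re-hospitalisations and rehabilitation
#' stays. Uncostable stays (no DRG) keep `NA` cost.
#'
#' @param stays Stay events with arm available via `patients`.
#' @param patients Patient table (for the arm of each stay).
#' @param catalog,rules,surgery_costs Costing inputs.
#' @param prorate_rehosp Opt-in LOS-prorating of re-hospitalisation costs.
#' @return `stays` with `drg_code` and `cost` columns.
#' @export
cost_stays <- function(stays, patients, catalog = load_drg_catalog(),
                       rules = load_rehosp_rules(),
                       surgery_costs = surgery_cost_table(),
                       prorate_rehosp = FALSE) {
  stays <- assign_drg(stays, rules)
  arm <- patients$arm[match(stays$patient_id, patients$patient_id)]
  cost <- rep(NA_real_, nrow(stays))
  ini <- stays$stay_type == "initial"
  if (any(ini)) {
    cost[ini] <- adjusted_drg_cost(stays$los[ini], stays$drg_code[ini],
                                   arm[ini], catalog, surgery_costs)
  }
  std <- !ini & !is.na(stays$drg_code)
  if (any(std)) {
    pro <- prorate_rehosp & stays$stay_type[std] == "rehospitalisation"
    cost[std] <- ifelse(pro,
      standard_drg_cost(stays$los[std], stays$drg_code[std], catalog,
                        prorate = TRUE),
      standard_drg_cost(stays$los[std], stays$drg_code[std], catalog,
                        prorate = FALSE))
  }
  stays$cost <- cost
  stays
}

#' Cumulative per-patient hospital costs at both horizons
#'
#' The 30-day cumulative cost is the initial-stay cost plus every costed
#' re-hospitalisation/rehabilitation admitted in the half-open window
#' (initial discharge, d30 visit]; the 3-month cost adds events admitted in
#' (d30 visit, m3 visit]. When a visit is undated or did not occur the
#' nominal horizon day (30 or 91) bounds the window instead. Uncosted stays
#' inside a window are excluded with a warning.
#'
#' @param patients Patient table.
#' @param costed_stays Output of [cost_stays()].
#' @return data.frame `patient_id`, `arm`, `cost_initial`,
#'   `cost_rehosp_30d`, `cost_rehab_30d`, `cost_rehosp_3m`, `cost_rehab_3m`,
#'   `cost_d30`, `cost_m3`.
#' @export
cumulative_costs <- function(patients, costed_stays) {
  s <- costed_stays
  uncosted <- is.na(s$cost)
  if (any(uncosted)) {
    warning(sum(uncosted), " uncosted stay(s) excluded from cumulative costs",
            call. = FALSE)
  }
  d30_end <- ifelse(is.na(patients$visit_d30_day),
                    unname(eq5d_timepoints()["d30"]), patients$visit_d30_day)
  m3_end <- ifelse(is.na(patients$visit_m3_day),
                   unname(eq5d_timepoints()["m3"]), patients$visit_m3_day)
  m3_end <- pmax(m3_end, d30_end)
  pid <- patients$patient_id
  i <- match(s$patient_id, pid)
  sum_by <- function(keep) {
    x <- rep(0, length(pid))
    if (any(keep)) {
      agg <- tapply(s$cost[keep], i[keep], sum)
      x[as.integer(names(agg))] <- as.numeric(agg)
    }
    x
  }
  ini <- s$stay_type == "initial" & !uncosted
  in30 <- !uncosted & s$stay_type != "initial" &
    s$admission_day > 0 & s$admission_day <= d30_end[i]
  in3m <- !uncosted & s$stay_type != "initial" &
    s$admission_day > d30_end[i] & s$admission_day <= m3_end[i]
  out <- data.frame(
    patient_id = pid, arm = patients$arm,
    cost_initial = sum_by(ini),
    cost_rehosp_30d = sum_by(in30 & s$stay_type == "rehospitalisation"),
    cost_rehab_30d = sum_by(in30 & s$stay_type == "rehabilitation"),
    cost_rehosp_3m = sum_by(in3m & s$stay_type == "rehospitalisation"),
    cost_rehab_3m = sum_by(in3m & s$stay_type == "rehabilitation"),
    stringsAsFactors = FALSE)
  out$cost_d30 <- out$cost_initial + out$cost_rehosp_30d + out$cost_rehab_30d
  out$cost_m3 <- out$cost_d30 + out$cost_rehosp_3m + out$cost_rehab_3m
  # tally excluded (uncostable) stays per window so sensitivity analyses can
  # treat the affected components as missing rather than silently zero
  un30 <- uncosted & s$admission_day > 0 & s$admission_day <= d30_end[i]
  un3m <- uncosted & s$admission_day > d30_end[i] & s$admission_day <= m3_end[i]
  count_by <- function(keep) {
    x <- integer(length(pid))
    if (any(keep)) {
      agg <- table(i[keep])
      x[as.integer(names(agg))] <- as.integer(agg)
    }
    x
  }
  out$n_uncosted_30d <- count_by(un30)
  out$n_uncosted_3m <- count_by(un3m)
  out
}
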