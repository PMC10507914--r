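#' Configuration of an end-to-end pipeline run
#'
#' Either a [trial_config()] for simulation or paths to the three
#' patient-level CSV files (`patients`, `observations`, `stays` as written
#' by [write_trial_csvs()]) must be supplied — not neither.
#'
#' @param trial A [trial_config()], or NULL when reading files.
#' @param patients_csv,observations_csv,stays_csv Input files when not
#'   simulating.
#' @param drg_catalog_csv,rehosp_rules_csv,value_set_csv,cpi_csv Costing and
#'   tariff inputs; defaults are the bundled fixtures.
#' @param horizons Analysis horizons.
#' @param B Bootstrap replicates.
#' @param m,imputation_iterations Imputed datasets and burn-in cycles.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param window_tol Visit-window tolerance (days) of the exclusion cascade.
#' @param prorate_rehosp LOS-prorate re-hospitalisation costs.
#' @param out_dir Output directory (NULL: nothing written).
#' @param seed Root seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(trial = NULL, patients_csv = NULL,
                       observations_csv = NULL, stays_csv = NULL,
                       drg_catalog_csv = NULL, rehosp_rules_csv = NULL,
                       value_set_csv = NULL, cpi_csv = NULL,
                       horizons = c("d30", "m3"), B = 10000L, m = 10L,
                       imputation_iterations = 10L,
                       wtp_grid = seq(0, 100000, by = 1000),
                       window_tol = 14, prorate_rehosp = FALSE,
                       out_dir = NULL, seed) {
  if (missing(seed)) stop("run_config(): seed is mandatory")
  from_files <- !is.null(patients_csv)
  if (is.null(trial) && !from_files) {
    stop("run_config: supply either a trial_config (field 'trial') or input",
         " CSV paths (field 'patients_csv' etc.)")
  }
  if (from_files) {
    for (f in c(patients_csv, observations_csv, stays_csv)) {
      if (is.null(f) || !file.exists(f)) {
        stop("run_config: input file missing or not found: ",
             if (is.null(f)) "(unset path field)" else f)
      }
    }
  }
  for (nm in c("drg_catalog_csv", "rehosp_rules_csv", "value_set_csv",
               "cpi_csv")) {
    val <- get(nm)
    if (!is.null(val) && !file.exists(val)) {
      stop("run_config: field ", nm, " points to a missing file: ", val)
    }
  }
  structure(list(trial = trial, patients_csv = patients_csv,
                 observations_csv = observations_csv, stays_csv = stays_csv,
                 drg_catalog_csv = drg_catalog_csv,
                 rehosp_rules_csv = rehosp_rules_csv,
                 value_set_csv = value_set_csv, cpi_csv = cpi_csv,
                 horizons = match.arg(horizons, several.ok = TRUE),
                 B = as.integer(B), m = as.integer(m),
                 imputation_iterations = as.integer(imputation_iterations),
                 wtp_grid = wtp_grid, window_tol = window_tol,
                 prorate_rehosp = prorate_rehosp, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

arm_summary <- function(values, arm) {
  sapply(trial_arms(), function(a) {
    x <- values[arm == a]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(n = 0, mean = NA, sd = NA, median = NA,
                             q1 = NA, q3 = NA))
    c(n = length(x), mean = mean(x), sd = stats::sd(x),
      median = stats::median(x),
      q1 = unname(stats::quantile(x, 0.25)), q3 = unname(stats::quantile(x, 0.75)))
  })
}

comparison_row <- function(label, values, arm) {
  s <- arm_summary(values, arm)
  row <- data.frame(outcome = label, t(c(s[, "VATS"], s[, "THORACOTOMY"])))
  names(row) <- c("outcome", paste0("vats_", rownames(s)),
                  paste0("thor_", rownames(s)))
  d <- if (s["n", "VATS"] >= 2 && s["n", "THORACOTOMY"] >= 2) {
    # degenerate groups (e.g. flat-cost rehabilitation stays) have no t-test
    tryCatch(mean_difference(values[arm == "VATS"],
                             values[arm == "THORACOTOMY"]),
             error = function(e) NULL)
  } else NULL
  if (!is.null(d)) {
    row$difference <- d$difference
    row$ci_low <- d$ci_low; row$ci_high <- d$ci_high; row$p_value <- d$p_value
  } else {
    row$difference <- row$ci_low <- row$ci_high <- row$p_value <- NA_real_
  }
  row
}

#' Run the full medico-economic pipeline
#'
#' Simulates (or reads) the trial, costs every hospital stay, scores EQ-5D
#' utilities and interval-weighted QALYs, applies the complete-case
#' exclusion cascade, and produces: the cost-minimisation comparison of
#' cumulative costs on all randomised patients; the complete-case
#' cost-utility analysis (differentials, ICER, bootstrap mean ICER with
#' percentile CI, cost-utility-plane quadrant shares, acceptability curve);
#' mortality contrasts at both horizons; and the multiply-imputed
#' sensitivity analysis with its pooled ICER and bootstrap CI. Every number
#' in the written tables is drawn from the returned summary object, which is
#' serialised as `summary.json`; the run is a deterministic function of the
#' root seed.
#'
#' @param config A [run_config()].
#' @return The summary list (invisibly when writing to `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  or_default <- function(x, loader) if (is.null(x)) loader() else loader(x)
  value_set <- or_default(config$value_set_csv, load_value_set)
  catalog <- or_default(config$drg_catalog_csv, load_drg_catalog)
  rules <- or_default(config$rehosp_rules_csv, load_rehosp_rules)

  if (!is.null(config$trial)) {
    trial <- simulate_trial(config$trial, value_set)
  } else {
    trial <- list(
      patients = utils::read.csv(config$patients_csv, stringsAsFactors = FALSE),
      observations = utils::read.csv(config$observations_csv,
                                     stringsAsFactors = FALSE),
      stays = utils::read.csv(config$stays_csv, stringsAsFactors = FALSE))
  }
  patients <- trial$patients
  observations <- trial$observations
  n_uncostable <- 0L
  costed <- withCallingHandlers(
    cost_stays(trial$stays, patients, catalog, rules,
               prorate_rehosp = config$prorate_rehosp),
    warning = function(w) {
      n_uncostable <<- n_uncostable + 1L
      invokeRestart("muffleWarning")
    })
  costs <- suppressWarnings(cumulative_costs(patients, costed))
  arm_all <- patients$arm

  summary <- list(
    seed = config$seed, B = config$B, m = config$m,
    n_randomised = as.list(table(arm_all)),
    n_stays = nrow(costed),
    n_uncostable_stays = sum(is.na(costed$cost)))

  tables <- list()
  cost_min <- rbind(
    comparison_row("initial_stay", costs$cost_initial, arm_all),
    comparison_row("rehosp_30d",
                   ifelse(costs$cost_rehosp_30d > 0, costs$cost_rehosp_30d, NA),
                   arm_all),
    comparison_row("rehab_30d",
                   ifelse(costs$cost_rehab_30d > 0, costs$cost_rehab_30d, NA),
                   arm_all),
    comparison_row("rehosp_3m",
                   ifelse(costs$cost_rehosp_3m > 0, costs$cost_rehosp_3m, NA),
                   arm_all),
    comparison_row("rehab_3m",
                   ifelse(costs$cost_rehab_3m > 0, costs$cost_rehab_3m, NA),
                   arm_all),
    comparison_row("cumulative_d30", costs$cost_d30, arm_all),
    comparison_row("cumulative_m3", costs$cost_m3, arm_all))
  tables$cost_minimisation <- cost_min
  summary$cost_minimisation <- list(
    delta_cost_d30 = cost_min$difference[cost_min$outcome == "cumulative_d30"],
    delta_cost_m3 = cost_min$difference[cost_min$outcome == "cumulative_m3"],
    p_d30 = cost_min$p_value[cost_min$outcome == "cumulative_d30"],
    p_m3 = cost_min$p_value[cost_min$outcome == "cumulative_m3"])

  deaths30 <- tapply(!is.na(patients$death_day) & patients$death_day <= 30,
                     arm_all, sum)
  deaths90 <- tapply(!is.na(patients$death_day) & patients$death_day <= 91,
                     arm_all, sum)
  n_arm <- table(arm_all)
  summary$mortality <- list(
    d30 = mortality_contrast(deaths30[["VATS"]], n_arm[["VATS"]],
                             deaths30[["THORACOTOMY"]], n_arm[["THORACOTOMY"]]),
    d90 = mortality_contrast(deaths90[["VATS"]], n_arm[["VATS"]],
                             deaths90[["THORACOTOMY"]], n_arm[["THORACOTOMY"]]))
  summary$cost_minimisation$label <-
    if (!summary$mortality$d30$or_defined ||
        (summary$mortality$d30$rd_ci_low <= 0 &&
         summary$mortality$d30$rd_ci_high >= 0)) {
      "cost-minimisation analysis (mortality not significantly different)"
    } else "cost comparison (mortality differs; see cost-utility analysis)"

  qal_d30 <- compute_qalys(observations, "d30")
  cascades <- list()
  for (h in config$horizons) {
    qal <- if (h == "d30") qal_d30 else compute_qalys(observations, "m3")
    casc <- apply_cua_exclusions(patients, qal, h, config$window_tol,
                                 qalys_d30 = qal_d30)
    cascades[[h]] <- casc
    out <- ce_outcomes(patients, costs, qal, h, included = casc$included)
    dcost <- mean_difference(out$cost[out$arm == "VATS"],
                             out$cost[out$arm == "THORACOTOMY"])
    deff <- mean_difference(out$effect[out$arm == "VATS"],
                            out$effect[out$arm == "THORACOTOMY"])
    ic <- icer(dcost$difference, deff$difference)
    boot <- bootstrap_ce(out, B = config$B,
                         seed = config$seed + 100L + match(h, config$horizons))
    ci <- icer_ci(boot)
    quad <- quadrant_proportions(boot)
    curve <- ceac(boot, config$wtp_grid)
    p_at_25k <- ceac(boot, 25000)$probability
    tables[[paste0("cu_plane_", h)]] <- boot$replicates
    tables[[paste0("ceac_", h)]] <- as.data.frame(curve)
    tables[[paste0("exclusions_", h)]] <-
      data.frame(criterion = names(casc$counts),
                 n = as.integer(casc$counts))
    summary[[paste0("cua_", h)]] <- list(
      n_included = as.list(table(out$arm)),
      exclusion_counts = as.list(casc$counts),
      delta_cost = dcost$difference,
      delta_cost_ci = c(dcost$ci_low, dcost$ci_high),
      delta_cost_p = dcost$p_value,
      delta_effect = deff$difference,
      delta_effect_ci = c(deff$ci_low, deff$ci_high),
      delta_effect_p = deff$p_value,
      icer = icer_reported(ic), quadrant = ic$quadrant,
      bootstrap_mean_icer = ci$mean_icer,
      bootstrap_icer_ci = c(ci$ci_low, ci$ci_high),
      quadrant_shares = as.list(quad),
      ceac_at_25000 = p_at_25k)
  }

  eligible <- patients$patient_id[is.na(patients$death_day)]
  frame <- build_imputation_frame(patients[patients$patient_id %in% eligible, ],
                                  observations, costs)
  imp_cfg <- imputation_config(m = config$m,
                               max_iterations = config$imputation_iterations,
                               seed = config$seed + 200L)
  imps <- mice_impute(frame, imp_cfg)
  for (h in config$horizons) {
    res <- imputed_cua(frame, imp_cfg, value_set, h, B = config$B,
                       seed = config$seed + 300L + match(h, config$horizons),
                       imputations = imps)
    summary[[paste0("imputed_", h)]] <- list(
      n = nrow(frame),
      delta_cost = res$pooled$pooled_delta_cost,
      delta_effect = res$pooled$pooled_delta_effect,
      icer = icer_reported(res$icer),
      bootstrap_mean_icer = res$ci$mean_icer,
      bootstrap_icer_ci = c(res$ci$ci_low, res$ci$ci_high))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
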