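#' Configuration of the chained-equations imputation
#'
#' @param m Number of imputed datasets (>= 2).
#' @param max_iterations Burn-in cycles of the chained equations per chain.
#' @param k_pmm Number of donors for predictive mean matching.
#' @param seed Mandatory seed.
#' @param predictors Variables used in every conditional model. The default
#'   is the trial's imputation-model set: age, sex, performance status,
#'   smoking status, BMI, the five EQ-5D items at the four timepoints, and
#'   the hospital cost components (initial stay, re-hospitalisations and
#'   rehabilitation, split by follow-up window so costs can be cumulated per
#'   horizon).
#' @return list of class `imputation_config`.
#' @export
imputation_config <- function(m = 10L, max_iterations = 10L, k_pmm = 5L, seed,
                              predictors = default_imputation_predictors()) {
  if (missing(seed)) stop("imputation_config(): seed is mandatory")
  if (m < 2) stop("m must be >= 2")
  structure(list(m = as.integer(m), max_iterations = as.integer(max_iterations),
                 k_pmm = as.integer(k_pmm), seed = as.integer(seed),
                 predictors = predictors),
            class = "imputation_config")
}

#' @rdname imputation_config
#' @export
default_imputation_predictors <- function() {
  items <- as.vector(outer(eq5d_dimensions(), names(eq5d_timepoints()),
                           paste, sep = "_"))
  c("age", "sex", "performance_status", "smoking", "bmi", items,
    "cost_initial", "cost_rehosp_30d", "cost_rehab_30d",
    "cost_rehosp_3m", "cost_rehab_3m")
}

#' Build the wide per-patient frame the imputation models operate on
#'
#' One row per patient: baseline covariates, the 20 EQ-5D item columns
#' (`<dimension>_<timepoint>`), and the five cost components. Cost
#' components touched by an uncostable stay are set to `NA` so the chained
#' equations impute them.
#'
#' @param patients Patient table.
#' @param observations EQ-5D observation table (with missingness).
#' @param costs Output of [cumulative_costs()].
#' @return data.frame keyed by `patient_id`.
#' @export
build_imputation_frame <- function(patients, observations, costs) {
  out <- patients[, c("patient_id", "arm", "age", "sex", "bmi",
                      "performance_status", "smoking")]
  for (tp in names(eq5d_timepoints())) {
    o <- observations[observations$timepoint == tp, ]
    idx <- match(out$patient_id, o$patient_id)
    for (d in eq5d_dimensions()) {
      out[[paste(d, tp, sep = "_")]] <- o[[d]][idx]
    }
  }
  ci <- match(out$patient_id, costs$patient_id)
  for (cc in c("cost_initial", "cost_rehosp_30d", "cost_rehab_30d",
               "cost_rehosp_3m", "cost_rehab_3m")) {
    out[[cc]] <- costs[[cc]][ci]
  }
  out$cost_rehosp_30d[costs$n_uncosted_30d[ci] > 0] <- NA_real_
  out$cost_rehosp_3m[costs$n_uncosted_3m[ci] > 0] <- NA_real_
  rownames(out) <- NULL
  out
}

# Numeric design columns for one predictor variable (factors -> dummies).
predictor_columns <- function(data, vars) {
  cols <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stop("predictor '", v, "' not found in data")
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1]) cols[[paste(v, l, sep = ".")]] <- as.numeric(x == l)
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

# Bayesian-draw linear regression + predictive mean matching (k donors).
impute_pmm <- function(y, miss, X, k) {
  Xo <- cbind(1, X[!miss, , drop = FALSE])
  yo <- y[!miss]
  Xm <- cbind(1, X[miss, , drop = FALSE])
  p <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(1e-6, p)   # tiny ridge guards collinearity
  Xty <- crossprod(Xo, yo)
  V <- chol2inv(chol(XtX))
  beta_hat <- V %*% Xty
  res <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta <- beta_hat + t(chol(V)) %*% stats::rnorm(p) * sqrt(sigma2)
  yhat_obs <- as.numeric(Xo %*% beta_hat)
  yhat_mis <- as.numeric(Xm %*% beta)
  out <- numeric(sum(miss))
  for (j in seq_along(yhat_mis)) {
    donors <- order(abs(yhat_obs - yhat_mis[j]))[seq_len(min(k, length(yo)))]
    out[j] <- yo[donors[sample.int(length(donors), 1)]]
  }
  out
}

# One logistic fit with a coefficient draw from the asymptotic normal;
# returns draw probabilities for the missing design rows. Falls back to the
# marginal rate when the fit is degenerate.
logistic_draw_prob <- function(yb, Xo, Xm) {
  if (length(unique(yb)) < 2) return(rep(mean(yb), nrow(Xm)))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, yb, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) {
    return(rep(mean(yb), nrow(Xm)))
  }
  R <- qr.R(fit$qr)
  V <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) return(rep(mean(yb), nrow(Xm)))
  beta <- fit$coefficients +
    tryCatch(t(chol(V)) %*% stats::rnorm(ncol(Xo)),
             error = function(e) matrix(0, ncol(Xo), 1))
  stats::plogis(as.numeric(Xm %*% beta))
}

# Sequential (continuation-ratio) draw for a 3-level ordinal item:
# P(level >= 2) then P(level = 3 | level >= 2).
impute_ordinal3 <- function(y, miss, X) {
  Xo <- cbind(1, X[!miss, , drop = FALSE])
  Xm <- cbind(1, X[miss, , drop = FALSE])
  yo <- y[!miss]
  p_ge2 <- logistic_draw_prob(as.numeric(yo >= 2), Xo, Xm)
  ge2_obs <- yo >= 2
  if (any(ge2_obs)) {
    p_3g2 <- logistic_draw_prob(as.numeric(yo[ge2_obs] == 3),
                                Xo[ge2_obs, , drop = FALSE], Xm)
  } else {
    p_3g2 <- rep(0, nrow(Xm))
  }
  ge2 <- stats::runif(nrow(Xm)) < p_ge2
  is3 <- ge2 & stats::runif(nrow(Xm)) < p_3g2
  1L + as.integer(ge2) + as.integer(is3)
}

#' Multiple imputation by chained equations
#'
#' In-package chained-equations engine: EQ-5D items (3-level ordinal) are
#' imputed by sequential logistic draws with regression coefficients drawn
#' from their asymptotic normal distribution; continuous cost components by
#' predictive mean matching with `k_pmm` donors after a Bayesian draw of the
#' regression parameters. Each of the `m` chains initialises missing cells
#' from random observed values and cycles `max_iterations` times through
#' the incomplete variables (ordered by increasing missingness). Observed
#' values are never altered. Dead and lost-to-follow-up patients are
#' expected to have been removed by the caller before imputation.
#'
#' @param data Wide frame from [build_imputation_frame()] (or any frame
#'   containing the configured predictors).
#' @param config An [imputation_config()].
#' @return list of class `mice_result`: `completed` (list of m completed
#'   data.frames), `trace` (per-chain, per-iteration means of each imputed
#'   variable, for convergence inspection), `config`.
#' @export
mice_impute <- function(data, config) {
  stopifnot(inherits(config, "imputation_config"))
  vars <- intersect(config$predictors, names(data))
  absent <- setdiff(config$predictors, names(data))
  if (length(absent)) stop("predictors missing from data: ",
                           paste(absent, collapse = ", "))
  miss_count <- vapply(vars, function(v) sum(is.na(data[[v]])), integer(1))
  if (any(miss_count == nrow(data))) {
    stop("variable(s) 100% missing: ",
         paste(vars[miss_count == nrow(data)], collapse = ", "))
  }
  targets <- vars[miss_count > 0]
  targets <- targets[order(miss_count[targets])]
  if (!length(targets)) {
    return(structure(list(completed = replicate(config$m, data,
                                                simplify = FALSE),
                          trace = NULL, config = config),
                     class = "mice_result"))
  }
  item_cols <- as.vector(outer(eq5d_dimensions(), names(eq5d_timepoints()),
                               paste, sep = "_"))
  method <- ifelse(targets %in% item_cols, "ordinal", "pmm")
  names(method) <- targets
  miss_idx <- lapply(targets, function(v) is.na(data[[v]]))
  names(miss_idx) <- targets

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$m)
  completed <- vector("list", config$m)
  trace <- array(NA_real_, dim = c(config$m, config$max_iterations,
                                   length(targets)),
                 dimnames = list(NULL, NULL, targets))
  for (chain in seq_len(config$m)) {
    set.seed(chain_seeds[chain])
    work <- data
    for (v in targets) {
      obs_vals <- work[[v]][!miss_idx[[v]]]
      work[[v]][miss_idx[[v]]] <- sample(obs_vals, sum(miss_idx[[v]]),
                                         replace = TRUE)
    }
    for (it in seq_len(config$max_iterations)) {
      for (v in targets) {
        miss <- miss_idx[[v]]
        X <- predictor_columns(work, setdiff(vars, v))
        if (method[v] == "ordinal") {
          work[[v]][miss] <- impute_ordinal3(data[[v]], miss, X)
        } else {
          work[[v]][miss] <- impute_pmm(data[[v]], miss, X, config$k_pmm)
        }
        trace[chain, it, v] <- mean(work[[v]][miss])
      }
    }
    completed[[chain]] <- work
  }
  structure(list(completed = completed, trace = trace, config = config),
            class = "mice_result")
}

#' Pool per-imputation cost-utility estimates
#'
#' Point estimates are pooled as arithmetic means across imputations
#' (Rubin's rule for the point estimate); the pooled ICER is the ratio of
#' the pooled differentials. Within-imputation variance is the mean squared
#' standard error, between-imputation variance the variance of the
#' estimates, and the total follows Rubin's combination
#' `W + (1 + 1/m) * B`.
#'
#' @param per_imputation list of per-imputation results, each a list with
#'   `delta_cost`, `delta_effect` and optionally `se_cost`, `se_effect`.
#' @return list of class `pooled_result`.
#' @export
pool_estimates <- function(per_imputation) {
  m <- length(per_imputation)
  stopifnot(m >= 1)
  grab <- function(f) vapply(per_imputation, function(r) {
    if (is.null(r[[f]])) NA_real_ else r[[f]]
  }, numeric(1))
  dc <- grab("delta_cost"); de <- grab("delta_effect")
  if (anyNA(dc) || anyNA(de)) stop("per-imputation results have mismatched structure")
  rubin <- function(est, se) {
    W <- if (anyNA(se)) NA_real_ else mean(se^2)
    B <- if (m > 1) stats::var(est) else 0
    list(W = W, B = B, total = if (is.na(W)) NA_real_ else W + (1 + 1 / m) * B)
  }
  vc <- rubin(dc, grab("se_cost"))
  ve <- rubin(de, grab("se_effect"))
  structure(list(pooled_delta_cost = mean(dc), pooled_delta_effect = mean(de),
                 pooled_icer = mean(dc) / mean(de),
                 var_cost = vc, var_effect = ve, m = m,
                 per_imputation = data.frame(delta_cost = dc, delta_effect = de)),
            class = "pooled_result")
}

#' Imputed-data cost-utility analysis with bootstrap confidence interval
#'
#' Runs the chained-equations imputation on the eligible patients (dead and
#' lost-to-follow-up patients must be excluded by the caller), rescores the
#' imputed EQ-5D items to utilities, recomputes interval-weighted QALYs at
#' nominal visit days and cumulative costs from the imputed components, and
#' analyses each completed dataset. Under the default `nesting = "within"`,
#' each completed dataset is bootstrapped `ceiling(B/m)` times and the m
#' replicate clouds are pooled for the percentile interval. With
#' `nesting = "reimpute"` the data are re-imputed (single imputation) inside
#' each of `B` bootstrap resamples — markedly more expensive; intended for
#' small `B`.
#'
#' @param frame [build_imputation_frame()] output restricted to eligible
#'   patients.
#' @param imp_config [imputation_config()].
#' @param value_set Tariff used to rescore imputed items.
#' @param horizon `"d30"` or `"m3"`.
#' @param B Total bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param nesting Bootstrap/imputation ordering (see above).
#' @param imputations Optional precomputed [mice_impute()] result, so the
#'   same completed datasets can be analysed at both horizons.
#' @return list: `pooled` ([pool_estimates()]), `icer` (pooled-point ICER,
#'   whole euros at reporting via [icer_reported()]), `ci` (percentile
#'   bounds and mean over the combined replicate ICERs), `replicates`
#'   (combined cloud), `per_imputation`.
#' @export
imputed_cua <- function(frame, imp_config, value_set = load_value_set(),
                        horizon = c("d30", "m3"), B = 10000L, seed,
                        nesting = c("within", "reimpute"),
                        imputations = NULL) {
  horizon <- match.arg(horizon)
  nesting <- match.arg(nesting)
  if (missing(seed)) stop("imputed_cua(): seed is mandatory")
  if (nesting == "reimpute") {
    return(imputed_cua_reimpute(frame, imp_config, value_set, horizon, B, seed))
  }
  imps <- if (is.null(imputations)) mice_impute(frame, imp_config) else
    imputations
  m <- imp_config$m
  per_imp <- vector("list", m)
  clouds <- vector("list", m)
  b_each <- as.integer(ceiling(B / m))
  for (i in seq_len(m)) {
    out <- completed_outcomes(imps$completed[[i]], value_set, horizon)
    dcost <- mean_difference(out$cost[out$arm == "VATS"],
                             out$cost[out$arm == "THORACOTOMY"])
    deff <- mean_difference(out$effect[out$arm == "VATS"],
                            out$effect[out$arm == "THORACOTOMY"])
    per_imp[[i]] <- list(delta_cost = dcost$difference,
                         delta_effect = deff$difference,
                         se_cost = dcost$se, se_effect = deff$se)
    clouds[[i]] <- bootstrap_ce(out, B = b_each, seed = seed + i)$replicates
  }
  pooled <- pool_estimates(per_imp)
  cloud <- do.call(rbind, clouds)
  defined <- cloud$delta_effect != 0
  ratios <- cloud$delta_cost[defined] / cloud$delta_effect[defined]
  q <- unname(stats::quantile(ratios, c(0.025, 0.975)))
  list(pooled = pooled,
       icer = icer(pooled$pooled_delta_cost, pooled$pooled_delta_effect),
       ci = list(mean_icer = mean(ratios), ci_low = q[1], ci_high = q[2],
                 n_undefined = sum(!defined)),
       replicates = cloud, per_imputation = per_imp)
}

imputed_cua_reimpute <- function(frame, imp_config, value_set, horizon,
                                 B, seed) {
  set.seed(seed)
  arms <- split(seq_len(nrow(frame)), frame$arm)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, B)
  reps <- matrix(NA_real_, B, 2)
  single <- imp_config
  single$m <- 2L  # engine minimum; first completed dataset is used
  for (b in seq_len(B)) {
    idx <- unlist(lapply(arms, function(ii) ii[sample.int(length(ii),
                                                          length(ii),
                                                          replace = TRUE)]))
    fb <- frame[idx, ]
    fb$patient_id <- sprintf("B%05d", seq_len(nrow(fb)))
    single$seed <- boot_seeds[b]
    imp <- mice_impute(fb, single)
    out <- completed_outcomes(imp$completed[[1]], value_set, horizon)
    reps[b, 1] <- mean(out$cost[out$arm == "VATS"]) -
      mean(out$cost[out$arm == "THORACOTOMY"])
    reps[b, 2] <- mean(out$effect[out$arm == "VATS"]) -
      mean(out$effect[out$arm == "THORACOTOMY"])
  }
  cloud <- data.frame(delta_cost = reps[, 1], delta_effect = reps[, 2])
  defined <- cloud$delta_effect != 0
  ratios <- cloud$delta_cost[defined] / cloud$delta_effect[defined]
  q <- unname(stats::quantile(ratios, c(0.025, 0.975)))
  list(pooled = NULL,
       icer = icer(mean(cloud$delta_cost), mean(cloud$delta_effect)),
       ci = list(mean_icer = mean(ratios), ci_low = q[1], ci_high = q[2],
                 n_undefined = sum(!defined)),
       replicates = cloud, per_imputation = NULL)
}

# Cost and QALY outcomes of one completed (no-missing) wide dataset: items
# rescored to utilities, QALYs at nominal visit days, costs summed from the
# imputed components.
completed_outcomes <- function(completed, value_set, horizon) {
  tps <- names(eq5d_timepoints())
  obs <- do.call(rbind, lapply(tps, function(tp) {
    lv <- as.matrix(completed[paste(eq5d_dimensions(), tp, sep = "_")])
    colnames(lv) <- eq5d_dimensions()
    data.frame(patient_id = completed$patient_id, timepoint = tp,
               day = unname(eq5d_timepoints()[tp]), lv,
               utility = score_eq5d(lv, value_set), stringsAsFactors = FALSE)
  }))
  qal <- compute_qalys(obs, horizon, use_nominal_days = TRUE)
  cost <- completed$cost_initial + completed$cost_rehosp_30d +
    completed$cost_rehab_30d
  if (horizon == "m3") {
    cost <- cost + completed$cost_rehosp_3m + completed$cost_rehab_3m
  }
  data.frame(patient_id = completed$patient_id, arm = completed$arm,
             cost = cost,
             effect = qal$qaly[match(completed$patient_id, qal$patient_id)],
             stringsAsFactors = FALSE)
}
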