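#' Trial arms
#' @export
trial_arms <- function() c("VATS", "THORACOTOMY")

#' EQ-5D administration timepoints and their nominal day offsets
#' @return Named integer vector: preop (day 0, anchored at surgery), d3,
#'   d30 and m3 visits.
#' @export
eq5d_timepoints <- function() {
  c(preop = 0L, d3 = 3L, d30 = 30L, m3 = 91L)
}

default_utility_means <- function() {
  m <- rbind(VATS        = c(0.83, 0.66, 0.80, 0.79),
             THORACOTOMY = c(0.78, 0.58, 0.74, 0.76))
  colnames(m) <- names(eq5d_timepoints())
  m
}

per_arm <- function(x, what) {
  arms <- trial_arms()
  if (length(x) == 1) x <- rep(x, 2)
  if (is.null(names(x))) names(x) <- arms
  stopifnot(setequal(names(x), arms))
  x[arms]
}

#' Configuration of the synthetic two-arm surgical trial
#'
#' Defines the study conditions the generator emulates: two arms of
#' `n_per_arm` patients randomised 1:1 with centre-stratified permuted
#' blocks; per-arm/per-timepoint EQ-5D utility means; an initial hospital
#' stay with gamma length of stay; rare re-hospitalisations, rehabilitation
#' admissions and deaths per follow-up window; and per-timepoint
#' questionnaire missingness (MCAR or MAR). Defaults are calibrated to a
#' multicentre lobectomy/segmentectomy trial comparing video-assisted
#' thoracoscopic surgery with open thoracotomy: ~130 patients per arm in 10
#' centres, blocks of 12, day-3/day-30/3-month follow-up.
#'
#' @param n_per_arm Patients per arm (total 2 x `n_per_arm`).
#' @param n_centres Number of recruiting centres.
#' @param block_size Randomisation block size; must be even for 1:1.
#' @param seed Mandatory integer seed; the whole dataset is a deterministic
#'   function of the config.
#' @param utility_means 2 x 4 matrix (arms x timepoints) of target mean
#'   utilities on the tariff scale.
#' @param utility_sd Latent utility standard deviation (scalar).
#' @param los_mean,los_sd Per-arm mean/SD of the initial-stay length of stay
#'   in days (gamma, rounded up, minimum 1).
#' @param rehosp_prob_30d,rehosp_prob_3m Per-arm probability of a
#'   re-hospitalisation in (discharge, d30 visit] and (d30, m3 visit].
#' @param rehab_prob_30d,rehab_prob_3m Per-arm probability of a
#'   rehabilitation admission in the same windows.
#' @param death_prob_30d,death_prob_3m Per-arm probability of death within
#'   30 days, and additionally between day 30 and 3 months.
#' @param missing_rate Per-timepoint probability that an EQ-5D record is
#'   absent (named vector over preop/d3/d30/m3).
#' @param missing_mechanism `"MCAR"` (record deleted independently) or
#'   `"MAR"` (deletion probability logistic in arm and pre-operative
#'   utility, intercept calibrated to hit `missing_rate` on average).
#' @param mar_utility_coef,mar_arm_coef MAR logistic coefficients on the
#'   pre-operative utility and on the VATS-arm indicator.
#' @param visit_jitter_sd SD (days) of the rounded-normal jitter on the d30
#'   and m3 visit dates.
#' @param prob_visit_off_window Probability a visit lands far outside its
#'   nominal window (16-45 days off), exercising the exclusion cascade.
#' @param prob_visit_undated Probability a performed visit has no recorded
#'   date.
#' @param major_complication_prob,reintervention_prob Probabilities feeding
#'   the DRG severity-level rule for the initial stay.
#' @param rehosp_reason_probs Named probabilities over re-hospitalisation
#'   admission reasons; reasons absent from the DRG rule table become
#'   uncostable stays downstream.
#' @return A validated list of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 130L,
                         n_centres = 10L,
                         block_size = 12L,
                         seed,
                         utility_means = default_utility_means(),
                         utility_sd = 0.25,
                         los_mean = c(VATS = 7.20, THORACOTOMY = 7.13),
                         los_sd = c(VATS = 3.72, THORACOTOMY = 2.85),
                         rehosp_prob_30d = c(VATS = 0.0458, THORACOTOMY = 0.0313),
                         rehosp_prob_3m = c(VATS = 0.0839, THORACOTOMY = 0.0234),
                         rehab_prob_30d = c(VATS = 0.0687, THORACOTOMY = 0.0625),
                         rehab_prob_3m = c(VATS = 0.0382, THORACOTOMY = 0),
                         death_prob_30d = c(VATS = 0.0076, THORACOTOMY = 0.0078),
                         death_prob_3m = c(VATS = 0.02, THORACOTOMY = 0.02),
                         missing_rate = c(preop = 0.10, d3 = 0.17,
                                          d30 = 0.15, m3 = 0.27),
                         missing_mechanism = c("MCAR", "MAR"),
                         mar_utility_coef = -2,
                         mar_arm_coef = 0.3,
                         visit_jitter_sd = 4,
                         prob_visit_off_window = 0.03,
                         prob_visit_undated = 0.03,
                         major_complication_prob = 0.10,
                         reintervention_prob = 0.03,
                         rehosp_reason_probs = c(respiratory = 0.32,
                                                 respiratory_severe = 0.10,
                                                 cardiac = 0.15,
                                                 infection = 0.15,
                                                 pleural = 0.12,
                                                 other = 0.08,
                                                 unknown = 0.08)) {
  if (missing(seed)) stop("trial_config(): seed is mandatory")
  missing_mechanism <- match.arg(missing_mechanism)
  n_per_arm <- as.integer(n_per_arm)
  if (n_per_arm <= 0) stop("n_per_arm must be positive")
  if (n_centres < 1) stop("n_centres must be >= 1")
  if (block_size %% 2 != 0) stop("block_size must be even for 1:1 allocation")
  cfg <- list(
    n_per_arm = n_per_arm, n_centres = as.integer(n_centres),
    block_size = as.integer(block_size), seed = as.integer(seed),
    utility_means = utility_means, utility_sd = utility_sd,
    los_mean = per_arm(los_mean), los_sd = per_arm(los_sd),
    rehosp_prob_30d = per_arm(rehosp_prob_30d),
    rehosp_prob_3m = per_arm(rehosp_prob_3m),
    rehab_prob_30d = per_arm(rehab_prob_30d),
    rehab_prob_3m = per_arm(rehab_prob_3m),
    death_prob_30d = per_arm(death_prob_30d),
    death_prob_3m = per_arm(death_prob_3m),
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    mar_utility_coef = mar_utility_coef, mar_arm_coef = mar_arm_coef,
    visit_jitter_sd = visit_jitter_sd,
    prob_visit_off_window = prob_visit_off_window,
    prob_visit_undated = prob_visit_undated,
    major_complication_prob = major_complication_prob,
    reintervention_prob = reintervention_prob,
    rehosp_reason_probs = rehosp_reason_probs / sum(rehosp_reason_probs))
  probs <- unlist(cfg[c("rehosp_prob_30d", "rehosp_prob_3m", "rehab_prob_30d",
                        "rehab_prob_3m", "death_prob_30d", "death_prob_3m",
                        "missing_rate", "prob_visit_off_window",
                        "prob_visit_undated", "major_complication_prob",
                        "reintervention_prob")])
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (any(cfg$los_mean <= 0) || any(cfg$los_sd < 0)) {
    stop("length-of-stay parameters must be positive")
  }
  stopifnot(identical(dim(utility_means), c(2L, 4L)),
            setequal(rownames(utility_means), trial_arms()),
            setequal(colnames(utility_means), names(eq5d_timepoints())))
  stopifnot(setequal(names(missing_rate), names(eq5d_timepoints())))
  class(cfg) <- "trial_config"
  cfg
}
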