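# Shared fixtures, built in code at test time.

the_value_set <- load_value_set()

# A small-but-realistic simulated trial, cached per (seed, n) so several
# tests can share one simulation.
.trial_cache <- new.env(parent = emptyenv())
small_trial <- function(seed = 101, n_per_arm = 60, ...) {
  key <- paste(seed, n_per_arm, length(list(...)))
  if (is.null(.trial_cache[[key]])) {
    cfg <- trial_config(seed = seed, n_per_arm = n_per_arm, ...)
    .trial_cache[[key]] <- list(config = cfg, trial = simulate_trial(cfg))
  }
  .trial_cache[[key]]
}

# A value set in which every decrement is zero: all 243 states score 1.
null_value_set <- function() {
  vs <- the_value_set
  vs$terms[] <- 0
  vs$floor <- 1
  vs
}

# Hand-built patient/stay tables for costing tests.
two_patients <- function() {
  data.frame(
    patient_id = c("A", "B"), arm = c("THORACOTOMY", "VATS"),
    death_day = NA_integer_,
    visit_d30_day = c(30L, 30L), visit_d30_undated = FALSE,
    visit_m3_day = c(91L, 91L), visit_m3_undated = FALSE,
    stringsAsFactors = FALSE)
}

stay_row <- function(patient_id, type, admission, los, reason = NA,
                     level = NA_integer_) {
  data.frame(patient_id = patient_id, stay_type = type,
             admission_day = as.integer(admission),
             discharge_day = as.integer(admission + los),
             los = as.integer(los), reason = reason,
             complication_level = level, stringsAsFactors = FALSE)
}
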