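#' EQ-5D-3L dimension names used throughout the package
#'
#' The five dimensions of the EQ-5D-3L descriptive system, in their
#' conventional order: mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression.
#'
#' @export
eq5d_dimensions <- function() {
  c("mobility", "selfcare", "activity", "pain", "anxiety")
}

#' Load an EQ-5D-3L value set (tariff) from CSV
#'
#' A value set maps each EQ-5D-3L health state (a 5-tuple of levels in
#' \{1,2,3\}) to a utility on a scale anchored at 1 for full health. The CSV
#' has columns `term,value` with terms `constant` (decrement applied to any
#' state other than full health), `<dimension>2` / `<dimension>3`
#' (per-dimension level decrements, dimensions as in [eq5d_dimensions()]),
#' and `n3` (extra decrement when any dimension is at level 3). This additive
#' structure covers the classical TTO value sets (e.g. the UK MVH tariff,
#' the bundled default, for which state 33333 scores -0.594).
#'
#' @param path CSV file; default is the bundled UK TTO tariff.
#' @return An object of class `eq5d_value_set`: a list with `name`, `terms`
#'   (named numeric), and `floor` (minimum achievable utility).
#' @export
load_value_set <- function(path = system.file("extdata", "eq5d3l_tariff_uk_tto.csv",
                                              package = "thoracoCUA")) {
  stopifnot(nzchar(path), file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "value") %in% names(tab)))
  terms <- stats::setNames(as.numeric(tab$value), tab$term)
  needed <- c("constant", paste0(rep(eq5d_dimensions(), each = 2), 2:3), "n3")
  missing <- setdiff(needed, names(terms))
  if (length(missing)) {
    stop("value set is missing terms: ", paste(missing, collapse = ", "))
  }
  vs <- structure(list(name = sub("\\.csv$", "", basename(path)),
                       terms = terms[needed], floor = NA_real_),
                  class = "eq5d_value_set")
  vs$floor <- min(eq5d_state_table(vs)$utility)
  # full-health anchor: state (1,1,1,1,1) must score exactly 1
  stopifnot(score_eq5d(matrix(1, 1, 5), vs) == 1)
  vs
}

#' Score EQ-5D-3L states with a value set
#'
#' Computes the utility index 1 - constant - per-level decrements - n3 term.
#' Rows with any missing level get `NA` (an incomplete observation has no
#' score); levels outside \{1,2,3\} are an error.
#'
#' @param levels An integer vector of length 5 (one state) or an n x 5 matrix /
#'   data.frame of states, columns ordered as [eq5d_dimensions()].
#' @param value_set An `eq5d_value_set`.
#' @return Numeric vector of utilities (NA where a level is missing).
#' @export
score_eq5d <- function(levels, value_set) {
  if (is.data.frame(levels)) levels <- as.matrix(levels)
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  stopifnot(ncol(levels) == 5)
  bad <- !is.na(levels) & !(levels %in% 1:3)
  if (any(bad)) stop("EQ-5D-3L levels must be in {1,2,3}")
  tr <- value_set$terms
  dims <- eq5d_dimensions()
  dec <- matrix(0, nrow(levels), 5)
  for (j in seq_len(5)) {
    dec[, j] <- ifelse(levels[, j] == 2, tr[paste0(dims[j], 2)],
                ifelse(levels[, j] == 3, tr[paste0(dims[j], 3)], 0))
  }
  any2 <- rowSums(levels > 1, na.rm = FALSE) > 0
  any3 <- rowSums(levels == 3, na.rm = FALSE) > 0
  u <- 1 - tr["constant"] * any2 - rowSums(dec) - tr["n3"] * any3
  u[apply(is.na(levels), 1, any)] <- NA_real_
  unname(u)
}

#' Enumerate all 243 EQ-5D-3L states and their tariff values
#'
#' @param value_set An `eq5d_value_set`.
#' @return data.frame with the five level columns, a `state` label
#'   (e.g. "21232"), and `utility`.
#' @export
eq5d_state_table <- function(value_set) {
  grid <- expand.grid(anxiety = 1:3, pain = 1:3, activity = 1:3,
                      selfcare = 1:3, mobility = 1:3)
  grid <- grid[, rev(seq_len(5))]  # conventional dimension order
  grid$state <- apply(grid, 1, paste0, collapse = "")
  grid <- grid[order(grid$state), ]
  rownames(grid) <- NULL
  grid$utility <- score_eq5d(as.matrix(grid[, eq5d_dimensions()]), value_set)
  grid
}

# Representative state per distinct tariff value: the lexicographically
# smallest state attaining that value. Used by the latent-utility inversion.
value_set_support <- function(value_set) {
  tab <- eq5d_state_table(value_set)          # already in state order
  tab <- tab[order(tab$utility, tab$state), ]
  keep <- !duplicated(round(tab$utility, 9))
  sup <- tab[keep, ]
  rownames(sup) <- NULL
  sup
}

#' Map latent utilities to the nearest achievable EQ-5D-3L state
#'
#' For each latent value, returns the health state whose tariff value is
#' closest; exact distance ties go to the lexicographically smallest state.
#' This is the inversion step of the synthetic EQ-5D generator.
#'
#' @param u Numeric vector of latent utilities (any real values).
#' @param value_set An `eq5d_value_set`.
#' @return data.frame of states (five level columns, `state`, `utility`),
#'   one row per element of `u`.
#' @export
map_latent_to_state <- function(u, value_set) {
  sup <- value_set_support(value_set)
  v <- sup$utility
  mids <- (v[-1] + v[-length(v)]) / 2
  idx <- findInterval(u, mids) + 1L          # nearest value; at a midpoint -> upper
  at_mid <- which(u %in% mids)
  for (i in at_mid) {
    lo <- findInterval(u[i], mids)           # lower candidate index
    # equidistant: keep the lexicographically smaller of the two states
    if (sup$state[lo] < sup$state[lo + 1L]) idx[i] <- lo
  }
  out <- sup[idx, c(eq5d_dimensions(), "state", "utility")]
  rownames(out) <- NULL
  out
}

#' Latent mean that reproduces a target mean scored utility
#'
#' The generator draws a latent normal utility and maps it to the nearest
#' achievable state ([map_latent_to_state()]); discretisation shifts the mean
#' of the scored values away from the latent mean. This solves for the latent
#' mean mu such that E[score(nearest-state(N(mu, sd)))] equals `target`,
#' using the exact partition of the real line induced by midpoints between
#' adjacent tariff values. With `sd = 0` the latent is degenerate and `target`
#' itself is returned (it then maps to its nearest state).
#'
#' @param target Desired mean scored utility; must lie strictly between the
#'   tariff floor and 1 (or equal either bound).
#' @param sd Latent standard deviation (>= 0).
#' @param value_set An `eq5d_value_set`.
#' @return The calibrated latent mean.
#' @export
calibrate_latent_mean <- function(target, sd, value_set) {
  sup <- value_set_support(value_set)
  v <- sup$utility
  if (target < min(v) || target > max(v)) {
    stop("target utility mean ", target, " outside achievable tariff range [",
         round(min(v), 3), ", 1]")
  }
  if (sd == 0) return(target)
  mids <- (v[-1] + v[-length(v)]) / 2
  expected <- function(mu) {
    p_up <- stats::pnorm(mids, mean = mu, sd = sd)  # P(latent <= midpoint)
    probs <- diff(c(0, p_up, 1))
    # diff of upper-tail complement: P(state j) mass between midpoints
    sum(v * probs)
  }
  lo <- min(v) - 6 * sd
  hi <- max(v) + 6 * sd
  stats::uniroot(function(mu) expected(mu) - target, c(lo, hi),
                 tol = 1e-10)$root
}
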