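# Derive a reproducible per-replicate seed from the master seed, so
# replicate r can be rerun in isolation. Kept within 32-bit integer range.
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + r * 999983) %% 2147483647)
}

#' Individual-level Monte-Carlo cohort simulation
#'
#' Simulates a cohort of individuals whose yearly state changes are
#' multinomial draws from the row of the annual transition matrix matching
#' their current state, and tallies occupancy proportions per year.
#' Replicates rerun the whole cohort with independent, deterministically
#' derived random substreams, so the same \code{seed} always reproduces
#' the same result and any single replicate can be regenerated alone.
#' Percentile intervals across replicates stand in for cohort sampling
#' uncertainty.
#'
#' Individuals are exchangeable, so draws are aggregated: the occupants of
#' each state are redistributed with one multinomial draw per state per
#' year, which is distributionally identical to per-individual draws.
#'
#' @param tm A [transition_matrix()].
#' @param initial Initial distribution (state name or 8-vector).
#' @param n_individuals Cohort size per replicate (>= 1).
#' @param horizon_years Number of annual cycles (>= 1).
#' @param n_replicates Number of cohort replicates (default 1).
#' @param seed Master RNG seed.
#' @param ci_level Two-sided percentile interval level (default 0.95).
#' @return A list of class \code{cohort_result}: \code{occupancy}
#'   (replicates x years+1 x 8 array of proportions), \code{point} (mean
#'   across replicates), \code{lower}/\code{upper} (percentile bounds;
#'   NULL when \code{n_replicates} < 2), and the configuration.
#' @examples
#' M <- mets_fixture_matrix("men")
#' res <- simulate_cohort(M, "no_component", n_individuals = 2000,
#'                        horizon_years = 15, n_replicates = 20, seed = 1)
#' res$point[16, "mets"] * 100
#' @export
simulate_cohort <- function(tm, initial, n_individuals, horizon_years,
                            n_replicates = 1, seed = 1, ci_level = 0.95) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (n_individuals < 1 || n_individuals != round(n_individuals)) {
    stop("n_individuals must be a positive integer", call. = FALSE)
  }
  if (horizon_years < 1 || horizon_years != round(horizon_years)) {
    stop("horizon_years must be a positive integer", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  d0 <- state_distribution(initial)
  P <- tm$probs
  states <- mets_states()
  occ <- array(NA_real_, c(n_replicates, horizon_years + 1, 8),
               dimnames = list(NULL, NULL, states))
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    counts <- as.numeric(stats::rmultinom(1, n_individuals, d0))
    occ[r, 1, ] <- counts / n_individuals
    for (k in seq_len(horizon_years)) {
      nxt <- numeric(8)
      for (i in which(counts > 0)) {
        nxt <- nxt + as.numeric(stats::rmultinom(1, counts[i], P[i, ]))
      }
      counts <- nxt
      occ[r, k + 1, ] <- counts / n_individuals
    }
  }
  point <- apply(occ, c(2, 3), mean)
  lower <- upper <- NULL
  if (n_replicates >= 2) {
    a <- (1 - ci_level) / 2
    lower <- apply(occ, c(2, 3), stats::quantile, probs = a, names = FALSE)
    upper <- apply(occ, c(2, 3), stats::quantile, probs = 1 - a,
                   names = FALSE)
    dimnames(lower) <- dimnames(upper) <- list(NULL, states)
  }
  dimnames(point) <- list(NULL, states)
  structure(list(occupancy = occ, point = point, lower = lower,
                 upper = upper, n_individuals = n_individuals,
                 horizon_years = horizon_years,
                 n_replicates = n_replicates, seed = seed,
                 ci_level = ci_level),
            class = "cohort_result")
}

#' Percentile interval for one state-year occupancy
#'
#' @param result A \code{cohort_result} from [simulate_cohort()].
#' @param state State name or canonical index.
#' @param year Year (0..horizon).
#' @return Named numeric vector \code{c(lower, upper)} at the result's
#'   \code{ci_level}.
#' @export
occupancy_interval <- function(result, state, year) {
  stopifnot(inherits(result, "cohort_result"))
  if (result$n_replicates < 2) {
    stop("percentile intervals need at least 2 replicates; ",
         "increase n_replicates", call. = FALSE)
  }
  if (year < 0 || year > result$horizon_years) {
    stop("year outside the simulated horizon", call. = FALSE)
  }
  j <- state_index(state)
  c(lower = unname(result$lower[year + 1, j]),
    upper = unname(result$upper[year + 1, j]))
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort microsimulation:", x$n_individuals, "individuals,",
      x$n_replicates, "replicate(s),", x$horizon_years, "years\n")
  cat("Final-year mean occupancy (%):\n")
  print(round(x$point[x$horizon_years + 1, ] * 100, 2))
  invisible(x)
}
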