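#' Tally state transitions from a two-wave panel
#'
#' Counts subjects by (baseline state, follow-up state) pair and
#' accumulates person-years per baseline state.  Each subject contributes
#' their full follow-up interval to their baseline state: with only two
#' observation waves no intermediate states are known, so this is the
#' simplest person-time attribution consistent with an annual incidence
#' rate, documented as an approximation.
#'
#' @param panel A data frame with columns \code{subject_id}, \code{sex},
#'   \code{state_t0}, \code{state_t1} (canonical state names) and
#'   \code{interval_years} (> 0); all rows must belong to one sex stratum.
#' @param mean_interval If non-NULL, every subject is assigned this fixed
#'   interval (e.g. the cohort mean) instead of their recorded one.
#' @return A list of class \code{transition_counts}: \code{counts} (8x8
#'   integer matrix, from-state rows), \code{origin_totals} (length 8) and
#'   \code{person_years} (length 8).
#' @export
count_transitions <- function(panel, mean_interval = NULL) {
  states <- mets_states()
  panel <- as.data.frame(panel)
  if (nrow(panel) == 0) {
    warning("empty panel: returning an all-zero count table")
    z <- matrix(0L, 8, 8, dimnames = list(states, states))
    return(structure(list(counts = z,
                          origin_totals = stats::setNames(integer(8), states),
                          person_years = stats::setNames(numeric(8), states)),
                     class = "transition_counts"))
  }
  required <- c("subject_id", "sex", "state_t0", "state_t1", "interval_years")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    stop("panel lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(panel$sex)) > 1) {
    stop("panel mixes sex strata; estimate each stratum separately",
         call. = FALSE)
  }
  iv <- if (is.null(mean_interval)) panel$interval_years else
    rep(mean_interval, nrow(panel))
  if (anyNA(iv) || any(iv <= 0)) {
    stop("interval_years must be positive", call. = FALSE)
  }
  i0 <- factor(panel$state_t0, levels = states)
  i1 <- factor(panel$state_t1, levels = states)
  if (anyNA(i0) || anyNA(i1)) {
    stop("panel contains states outside the canonical 8-state space",
         call. = FALSE)
  }
  counts <- unclass(table(i0, i1))
  dimnames(counts) <- list(states, states)
  structure(list(
    counts = counts,
    origin_totals = rowSums(counts),
    person_years = stats::setNames(
      as.numeric(tapply(iv, i0, sum, default = 0)), states)
  ), class = "transition_counts")
}

#' Estimate annual incidence rates from transition counts
#'
#' The annual rate out of state i into state j is the event count divided
#' by the person-years observed in state i: \eqn{r_{ij} = n_{ij} / PY_i}.
#' The diagonal is unused (set to 0); staying put is handled downstream as
#' the residual probability.
#'
#' @param tab A \code{transition_counts} table from [count_transitions()].
#' @param continuity Add 0.5 events to zero-count off-diagonal cells of
#'   rows with observed person-time, so that no estimated rate is exactly
#'   zero (off by default).
#' @return An 8x8 matrix of nonnegative annual rates (per person-year).
#' @export
estimate_rates <- function(tab, continuity = FALSE) {
  stopifnot(inherits(tab, "transition_counts"))
  counts <- tab$counts
  py <- tab$person_years
  events_no_time <- py == 0 & (rowSums(counts) - diag(counts)) > 0
  if (any(events_no_time)) {
    stop("inconsistent table: transition events with zero person-years in ",
         paste(mets_states()[events_no_time], collapse = ", "),
         call. = FALSE)
  }
  ev <- counts
  diag(ev) <- 0
  if (continuity) ev[ev == 0 & py > 0] <- 0.5
  rates <- matrix(0, 8, 8, dimnames = dimnames(counts))
  pos <- py > 0
  rates[pos, ] <- ev[pos, , drop = FALSE] / py[pos]
  diag(rates) <- 0
  if (any(!pos & tab$origin_totals == 0)) {
    warning("origin state(s) with no observations get all-zero rates: ",
            paste(mets_states()[!pos & tab$origin_totals == 0],
                  collapse = ", "))
  }
  rates
}

#' Convert an annual rate to a transition probability
#'
#' The probability of at least one transition within time \code{t} under a
#' constant annual incidence rate \code{r} is \eqn{P = 1 - e^{-rt}}.
#'
#' @param r Nonnegative annual rate(s) (per person-year).
#' @param t Positive duration(s) in years.
#' @return Probability in [0, 1); vectorized over \code{r} and \code{t}.
#' @examples
#' annualize_probability(0.0195, 1)  # 0.019311
#' @export
annualize_probability <- function(r, t) {
  if (anyNA(r) || any(r < 0)) stop("rate must be nonnegative", call. = FALSE)
  if (anyNA(t) || any(t <= 0)) stop("duration must be positive", call. = FALSE)
  1 - exp(-r * t)
}

#' Build an annual transition matrix from estimated rates
#'
#' Each off-diagonal probability is the one-year annualization of its rate,
#' \eqn{P_{ij} = 1 - e^{-r_{ij}}}; the diagonal is the residual
#' \eqn{1 - \sum_{j \ne i} P_{ij}}, which guarantees row-stochasticity.
#' Rows whose off-diagonal annualized probabilities already exceed 1 are
#' rejected: per-cell annualization is only coherent when competing risks
#' out of a state are jointly modest.
#'
#' @param rates An 8x8 nonnegative rate matrix from [estimate_rates()].
#' @param sex Optional stratum label carried onto the result.
#' @return A [transition_matrix()].
#' @export
build_transition_matrix <- function(rates, sex = NA_character_) {
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(8L, 8L))) stop("rates must be 8x8", call. = FALSE)
  if (anyNA(rates) || any(rates < 0) || any(!is.finite(rates))) {
    stop("rates must be finite and nonnegative", call. = FALSE)
  }
  P <- annualize_probability(rates, 1)
  diag(P) <- 0
  off <- rowSums(P)
  if (any(off > 1)) {
    stop("off-diagonal probabilities exceed 1 for row(s): ",
         paste(mets_states()[off > 1], collapse = ", "),
         "; rates too large for per-cell annualization", call. = FALSE)
  }
  diag(P) <- 1 - off
  transition_matrix(P, sex = sex)
}

#' Estimate an annual transition matrix from a two-wave panel
#'
#' Convenience pipeline: [count_transitions()], [estimate_rates()],
#' [build_transition_matrix()].
#'
#' @inheritParams count_transitions
#' @inheritParams estimate_rates
#' @return A [transition_matrix()] for the panel's sex stratum.
#' @export
estimate_transition_matrix <- function(panel, mean_interval = NULL,
                                       continuity = FALSE) {
  tab <- count_transitions(panel, mean_interval = mean_interval)
  sex <- if (nrow(as.data.frame(panel)) > 0) panel$sex[1] else NA_character_
  build_transition_matrix(estimate_rates(tab, continuity = continuity),
                          sex = sex)
}

#' Read / write a state panel CSV
#'
#' One row per subject with columns \code{subject_id}, \code{sex},
#' \code{state_t0}, \code{state_t1} (canonical state names) and
#' \code{interval_years}.
#'
#' @param path CSV path.
#' @return \code{read_state_panel}: the panel data frame.
#' @export
read_state_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "sex", "state_t0", "state_t1", "interval_years")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_state_panel
#' @param panel A state panel data frame.
#' @export
write_state_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
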