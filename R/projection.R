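#' Build a state occupancy distribution
#'
#' @param x A state name (point mass), a named numeric vector over the
#'   canonical states, or a bare numeric vector of length 8 in canonical
#'   order.  Must be nonnegative and sum to 1 within 1e-9.
#' @return A named numeric vector of length 8 summing to 1.
#' @export
state_distribution <- function(x) {
  states <- mets_states()
  if (is.character(x) && length(x) == 1) {
    d <- stats::setNames(numeric(8), states)
    d[state_index(x)] <- 1
    return(d)
  }
  x <- unlist(x)
  if (!is.numeric(x) || length(x) != 8) {
    stop("distribution must be a state name or a numeric vector of length 8",
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), states)) {
      stop("distribution names must be the canonical states", call. = FALSE)
    }
    x <- x[states]
  } else {
    names(x) <- states
  }
  if (anyNA(x) || any(x < 0) || abs(sum(x) - 1) > 1e-9) {
    stop("occupancy must be nonnegative and sum to 1", call. = FALSE)
  }
  x
}

#' Project state occupancy over yearly cycles
#'
#' Deterministic cohort projection: starting from an initial occupancy
#' distribution, each annual cycle left-multiplies the row vector by the
#' annual transition matrix, so the year-k occupancy is the initial
#' distribution times the k-th matrix power.  Cycles are whole years; no
#' half-cycle correction is applied.
#'
#' @param initial Initial distribution: a state name or an 8-vector (see
#'   [state_distribution()]).
#' @param tm A [transition_matrix()].
#' @param horizon Nonnegative integer number of annual cycles.
#' @return A data frame of class \code{state_trajectory} with a
#'   \code{year} column (0..horizon) and one probability column per state.
#' @examples
#' M <- mets_fixture_matrix("men")
#' traj <- project_occupancy("no_component", M, 15)
#' traj[traj$year == 15, "mets"] * 100  # percent developing MetS
#' @export
project_occupancy <- function(initial, tm, horizon) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (length(horizon) != 1 || is.na(horizon) || horizon < 0 ||
      horizon != round(horizon)) {
    stop("horizon must be a nonnegative integer number of years",
         call. = FALSE)
  }
  d <- state_distribution(initial)
  out <- matrix(NA_real_, horizon + 1, 8,
                dimnames = list(NULL, mets_states()))
  out[1, ] <- d
  v <- d
  for (k in seq_len(horizon)) {
    v <- as.numeric(v %*% tm$probs)
    out[k + 1, ] <- v
  }
  structure(data.frame(year = 0:horizon, out, check.names = FALSE),
            class = c("state_trajectory", "data.frame"))
}

#' Occupancy of a target state after a number of years
#'
#' The probability that an individual starting in \code{start} occupies
#' \code{target} after \code{year} annual cycles — i.e. the
#' (start, target) entry of the year-th matrix power.
#'
#' @param start,target State names (or 1-based canonical indices).
#' @param tm A [transition_matrix()].
#' @param year Nonnegative integer.
#' @return A single probability.
#' @export
occupancy_at <- function(start, target, tm, year) {
  traj <- project_occupancy(mets_states()[state_index(start)], tm, year)
  traj[traj$year == year, mets_states()[state_index(target)]]
}

#' Write a trajectory to CSV (percent occupancy per year)
#'
#' @param traj A \code{state_trajectory} from [project_occupancy()].
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "state_trajectory"))
  out <- traj
  out[mets_states()] <- out[mets_states()] * 100
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
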