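#' Construct an annual transition matrix
#'
#' An 8x8 row-stochastic matrix of annual transition probabilities over the
#' metabolic state space, with from-states as rows in the canonical order
#' of [mets_states()].  The cycle length is fixed at one year.
#'
#' @param probs Numeric 8x8 matrix of probabilities, rows summing to 1.
#' @param sex Optional stratum label ("male"/"female"/other).
#' @return An object of class \code{transition_matrix}.
#' @export
transition_matrix <- function(probs, sex = NA_character_) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(8L, 8L))) {
    stop("transition matrix must be 8x8", call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9)) {
    bad <- which(abs(rs - 1) > 1e-9)
    stop("row(s) not summing to 1: ",
         paste(mets_states()[bad], collapse = ", "), call. = FALSE)
  }
  dimnames(probs) <- list(mets_states(), mets_states())
  structure(list(probs = probs, sex = sex), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Annual metabolic-state transition matrix",
      if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  print(round(x$probs, digits))
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) x$probs

#' Load a published transition matrix printed in percent
#'
#' Published annualized transition matrices are printed as percentages
#' rounded to two decimals, so their rows rarely sum to exactly 100.  This
#' loader accepts an 8x8 table of percentages (or a CSV file with a
#' \code{from} column and the eight state columns), checks each row sum
#' lies within 99.5--100.5, divides by 100, and renormalizes each row to
#' sum exactly to 1.  The original row sums are retained in the
#' \code{printed_row_sums} element for provenance logging.
#'
#' @param x An 8x8 numeric matrix/data frame of percentages, or a path to a
#'   CSV file in the fixture dialect.
#' @param sex Optional stratum label.
#' @return A [transition_matrix()] with a \code{printed_row_sums} element.
#' @seealso [mets_fixture_matrix()] for the bundled published matrices.
#' @export
load_printed_matrix <- function(x, sex = NA_character_) {
  if (is.character(x) && length(x) == 1) {
    df <- utils::read.csv(x, stringsAsFactors = FALSE)
    if (!identical(names(df)[1], "from") ||
        !identical(names(df)[-1], mets_states())) {
      stop("matrix file must have a 'from' column followed by the eight ",
           "canonical state columns", call. = FALSE)
    }
    if (!identical(df$from, mets_states())) {
      stop("matrix file rows must be in canonical state order", call. = FALSE)
    }
    x <- as.matrix(df[, -1])
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(8L, 8L))) stop("expected an 8x8 table", call. = FALSE)
  if (anyNA(x) || any(x < 0)) {
    stop("percentage entries must be nonnegative and complete", call. = FALSE)
  }
  rs <- rowSums(x)
  bad <- which(rs < 99.5 | rs > 100.5)
  if (length(bad) > 0) {
    stop("row sum outside 99.5-100.5 for state(s): ",
         paste0(mets_states()[bad], " (", round(rs[bad], 2), ")",
                collapse = ", "), call. = FALSE)
  }
  tm <- transition_matrix(sweep(x / 100, 1, rs / 100, "/"), sex = sex)
  tm$printed_row_sums <- stats::setNames(rs, mets_states())
  tm
}

#' Bundled published annual transition matrices
#'
#' Returns the sex-specific annualized transition matrix estimated from a
#' five-year Taiwanese population-based follow-up of 2,247 adults aged
#' 18--45, shipped bit-exact to the published percentages and renormalized
#' on load (see [load_printed_matrix()]).
#'
#' @param sex "men" or "women".
#' @return A [transition_matrix()].
#' @examples
#' M <- mets_fixture_matrix("men")
#' occupancy_at("no_component", "mets", M, 15)
#' @export
mets_fixture_matrix <- function(sex = c("men", "women")) {
  sex <- match.arg(sex)
  path <- system.file("extdata",
                      paste0("annual_transitions_", sex, ".csv"),
                      package = "metsmarkov", mustWork = TRUE)
  load_printed_matrix(path, sex = if (sex == "men") "male" else "female")
}

#' Write a transition matrix to CSV in the fixture dialect
#'
#' @param tm A [transition_matrix()].
#' @param path Output CSV path.
#' @param percent Write entries as percentages (default) or probabilities.
#' @return Invisibly, \code{path}.
#' @export
write_matrix_csv <- function(tm, path, percent = TRUE) {
  stopifnot(inherits(tm, "transition_matrix"))
  m <- tm$probs * if (percent) 100 else 1
  df <- data.frame(from = mets_states(), m, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
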