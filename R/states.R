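#' The 8-state metabolic state space
#'
#' Canonical state names, in the fixed index order used by every matrix and
#' trajectory in the package: the no-component state, the five
#' isolated-component states (abdominal obesity, high triglycerides, low HDL
#' cholesterol, high blood pressure, high fasting plasma glucose), the
#' 2-component state (any pair of components), and the MetS state (three or
#' more components).
#'
#' @return Character vector of length 8.
#' @examples
#' mets_states()
#' @export
mets_states <- function() {
  c("no_component", "abdominal_obesity", "high_tg", "low_hdl",
    "high_bp", "high_fpg", "two_components", "mets")
}

#' Names of the five MetS components
#'
#' @return Character vector of length 5, in the order used by component
#'   profiles: abdominal obesity, high TG, low HDL, high BP, high FPG.
#' @export
mets_components <- function() {
  c("abdominal_obesity", "high_tg", "low_hdl", "high_bp", "high_fpg")
}

# Resolve a state given by name or 1-based index to its canonical index.
state_index <- function(state) {
  states <- mets_states()
  if (is.character(state)) {
    idx <- match(state, states)
    if (anyNA(idx)) {
      stop("unknown state(s): ", paste(state[is.na(idx)], collapse = ", "),
           "; valid states are: ", paste(states, collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  if (is.numeric(state)) {
    if (any(state < 1 | state > 8 | state != round(state))) {
      stop("state index must be an integer in 1..8", call. = FALSE)
    }
    return(as.integer(state))
  }
  stop("state must be a character name or integer index", call. = FALSE)
}

# Sex-specific clinical cutoffs (revised AHA/NHLBI consensus definition).
# Units: waist cm, TG mg/dl, HDL mg/dl, BP mmHg, FPG mg/dl.
mets_cutoffs <- function(sex) {
  list(
    waist_cm = ifelse(sex == "male", 90, 80),
    tg_mg_dl = 150,
    hdl_mg_dl = ifelse(sex == "male", 40, 50),
    systolic_mmHg = 130,
    diastolic_mmHg = 85,
    fpg_mg_dl = 100
  )
}

check_measurements <- function(m) {
  required <- c("sex", "waist_cm", "triglycerides_mg_dl", "hdl_mg_dl",
                "systolic_mmHg", "diastolic_mmHg", "fpg_mg_dl",
                "on_antihypertensives", "on_antidiabetics")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("missing required measurement field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(m$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  num <- c("waist_cm", "triglycerides_mg_dl", "hdl_mg_dl",
           "systolic_mmHg", "diastolic_mmHg", "fpg_mg_dl")
  for (f in num) {
    if (anyNA(m[[f]])) stop("missing value in field: ", f, call. = FALSE)
    if (any(m[[f]] <= 0)) stop("non-positive value in field: ", f, call. = FALSE)
  }
  if (any(m$systolic_mmHg <= m$diastolic_mmHg)) {
    stop("systolic pressure must exceed diastolic pressure", call. = FALSE)
  }
  invisible(m)
}

#' Evaluate the five MetS components from raw measurements
#'
#' Applies the sex-specific clinical cutoffs to one or more rows of raw
#' measurements: waist circumference > 90 cm (men) / > 80 cm (women) for
#' abdominal obesity; triglycerides at or above 150 mg/dl; HDL below
#' 40 mg/dl (men) / 50 mg/dl (women); blood pressure at or above 130
#' systolic or 85 diastolic, or antihypertensive use; fasting plasma glucose
#' at or above 100 mg/dl, or antidiabetic use.  Medication use is not part
#' of the TG or HDL criteria.
#'
#' The numeric boundary convention is switchable: with
#' \code{boundary = "inclusive"} (default) the TG, BP and FPG cutoffs are
#' met at the cutoff value itself (\eqn{\ge}); with \code{boundary =
#' "strict"} a value must exceed the cutoff.  Waist is always strictly
#' above its cutoff and HDL strictly below, under both conventions.
#'
#' @param m A data frame (or list coercible to one) with columns
#'   \code{sex} ("male"/"female"), \code{waist_cm},
#'   \code{triglycerides_mg_dl}, \code{hdl_mg_dl}, \code{systolic_mmHg},
#'   \code{diastolic_mmHg}, \code{fpg_mg_dl}, \code{on_antihypertensives},
#'   \code{on_antidiabetics}.
#' @param boundary "inclusive" or "strict"; see Details.
#' @return A data frame of five logical columns, one per component, one row
#'   per input row (see [mets_components()] for the order).
#' @seealso [component_state()] to collapse a profile to the 8-state space.
#' @export
classify_components <- function(m, boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  check_measurements(m)
  cut <- mets_cutoffs(m$sex)
  at_or_above <- if (boundary == "inclusive") `>=` else `>`
  data.frame(
    abdominal_obesity = m$waist_cm > cut$waist_cm,
    high_tg = at_or_above(m$triglycerides_mg_dl, cut$tg_mg_dl),
    low_hdl = m$hdl_mg_dl < cut$hdl_mg_dl,
    high_bp = at_or_above(m$systolic_mmHg, cut$systolic_mmHg) |
      at_or_above(m$diastolic_mmHg, cut$diastolic_mmHg) |
      as.logical(m$on_antihypertensives),
    high_fpg = at_or_above(m$fpg_mg_dl, cut$fpg_mg_dl) |
      as.logical(m$on_antidiabetics)
  )
}

#' Map a component profile to the 8-state space
#'
#' Zero abnormal components map to the no-component state, exactly one to
#' the matching isolated state, exactly two (any pair) to the 2-component
#' state, and three or more to the MetS state.  The mapping is total:
#' every one of the 32 possible profiles lands in exactly one state.
#'
#' @param profile A logical data frame as returned by
#'   [classify_components()], or a logical vector of length 5 for a single
#'   person (order as [mets_components()]).
#' @return Character vector of state names, one per profile row.
#' @export
component_state <- function(profile) {
  if (is.logical(profile) && is.null(dim(profile))) {
    profile <- as.data.frame(as.list(stats::setNames(profile, mets_components())))
  }
  profile <- as.data.frame(profile)
  comps <- mets_components()
  if (!all(comps %in% names(profile))) {
    stop("profile must contain the five component columns: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  pm <- as.matrix(profile[comps])
  if (anyNA(pm)) stop("profile contains missing values", call. = FALSE)
  n_abn <- rowSums(pm)
  states <- mets_states()
  out <- character(nrow(pm))
  out[n_abn == 0] <- states[1]
  one <- which(n_abn == 1)
  if (length(one) > 0) {
    # isolated states sit at indices 2..6 in component order
    out[one] <- states[1 + max.col(pm[one, , drop = FALSE])]
  }
  out[n_abn == 2] <- states[7]
  out[n_abn >= 3] <- states[8]
  out
}

#' Read a two-wave measurement panel from CSV
#'
#' Reads raw measurements, one row per subject per wave, with the fixed
#' header \code{subject_id, wave, sex, waist_cm, triglycerides_mg_dl,
#' hdl_mg_dl, systolic_mmHg, diastolic_mmHg, fpg_mg_dl,
#' on_antihypertensives, on_antidiabetics, interval_years} (units cm,
#' mg/dl, mmHg; \code{interval_years} is the follow-up interval and may be
#' blank on baseline rows).
#'
#' @param path Path to the CSV file.
#' @return A data frame with those columns; medication flags as logical.
#' @export
read_measurement_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "wave", "sex", "waist_cm",
                "triglycerides_mg_dl", "hdl_mg_dl", "systolic_mmHg",
                "diastolic_mmHg", "fpg_mg_dl", "on_antihypertensives",
                "on_antidiabetics")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("panel file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$on_antihypertensives <- as.logical(df$on_antihypertensives)
  df$on_antidiabetics <- as.logical(df$on_antidiabetics)
  df
}
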