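# Truncated-normal sampler via inverse-CDF; lo/hi bound the support.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# Package-defined measurement distributions for each component, per sex:
# a "normal" truncated-normal range strictly on the healthy side of the
# clinical cutoff and an "abnormal" range strictly beyond it, with a
# 0.5-unit guard band so classification is boundary-convention-proof.
measurement_ranges <- function(sex) {
  waist_cut <- if (sex == "male") 90 else 80
  hdl_cut <- if (sex == "male") 40 else 50
  list(
    waist = list(
      normal = c(mean = waist_cut - 9, sd = 5, lo = 55, hi = waist_cut - 0.5),
      abnormal = c(mean = waist_cut + 8, sd = 6, lo = waist_cut + 0.5, hi = 140)),
    tg = list(
      normal = c(mean = 100, sd = 25, lo = 40, hi = 149),
      abnormal = c(mean = 210, sd = 50, lo = 151, hi = 600)),
    hdl = list(
      normal = c(mean = hdl_cut + 12, sd = 8, lo = hdl_cut + 0.5, hi = 100),
      abnormal = c(mean = hdl_cut - 7, sd = 4, lo = 22, hi = hdl_cut - 0.5)),
    systolic = list(
      normal = c(mean = 114, sd = 8, lo = 95, hi = 129),
      abnormal = c(mean = 142, sd = 9, lo = 131, hi = 185)),
    diastolic = list(
      normal = c(mean = 72, sd = 6, lo = 55, hi = 84),
      abnormal = c(mean = 90, sd = 5, lo = 85.5, hi = 110)),
    fpg = list(
      normal = c(mean = 88, sd = 6, lo = 65, hi = 99),
      abnormal = c(mean = 115, sd = 12, lo = 101, hi = 200))
  )
}

draw_range <- function(spec) {
  rtruncnorm(1, spec["mean"], spec["sd"], spec["lo"], spec["hi"])
}

# All component subsets consistent with a given state, as logical vectors
# over mets_components().
state_component_subsets <- function(state) {
  comps <- mets_components()
  none <- stats::setNames(rep(FALSE, 5), comps)
  switch(state,
    no_component = list(none),
    abdominal_obesity = ,
    high_tg = ,
    low_hdl = ,
    high_bp = ,
    high_fpg = {
      p <- none; p[state] <- TRUE; list(p)
    },
    two_components = apply(utils::combn(5, 2), 2, function(ix) {
      p <- none; p[ix] <- TRUE; p
    }, simplify = FALSE),
    mets = {
      subs <- list()
      for (k in 3:5) {
        subs <- c(subs, apply(utils::combn(5, k), 2, function(ix) {
          p <- none; p[ix] <- TRUE; p
        }, simplify = FALSE))
      }
      subs
    },
    stop("unknown state: ", state, call. = FALSE)
  )
}

#' Generate raw measurements consistent with a metabolic state
#'
#' Draws one person's component measurements from documented
#' truncated-normal ranges placed strictly on either side of each clinical
#' cutoff, such that classifying the generated measurements recovers the
#' requested state exactly.  For the 2-component and MetS states the
#' abnormal component subset is chosen uniformly among all subsets of the
#' right size (10 pairs; 16 subsets of three or more).  Medication flags
#' are always FALSE: abnormality is expressed through the measurements.
#'
#' @param state Canonical state name.
#' @param sex "male" or "female".
#' @param seed RNG seed for this draw.
#' @return A one-row data frame of measurements (see
#'   [classify_components()] for columns).
#' @export
generate_measurements <- function(state, sex = c("male", "female"), seed) {
  sex <- match.arg(sex)
  state <- mets_states()[state_index(state)]
  set.seed(as.integer(seed %% 2147483647))
  subsets <- state_component_subsets(state)
  profile <- subsets[[sample.int(length(subsets), 1)]]
  rg <- measurement_ranges(sex)
  side <- function(abn) if (abn) "abnormal" else "normal"
  bp_abn <- profile[["high_bp"]]
  # when BP is abnormal, raise systolic always and diastolic half the time
  dia_abn <- bp_abn && stats::runif(1) < 0.5
  data.frame(
    sex = sex,
    waist_cm = draw_range(rg$waist[[side(profile[["abdominal_obesity"]])]]),
    triglycerides_mg_dl = draw_range(rg$tg[[side(profile[["high_tg"]])]]),
    hdl_mg_dl = draw_range(rg$hdl[[side(profile[["low_hdl"]])]]),
    systolic_mmHg = draw_range(rg$systolic[[side(bp_abn)]]),
    diastolic_mmHg = draw_range(rg$diastolic[[side(dia_abn)]]),
    fpg_mg_dl = draw_range(rg$fpg[[side(profile[["high_fpg"]])]]),
    on_antihypertensives = FALSE,
    on_antidiabetics = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-wave state panel with known ground truth
#'
#' Emulates a two-wave cohort follow-up: baseline states are drawn from
#' \code{baseline_distribution}, and each subject's follow-up state is a
#' draw from the true annual matrix compounded over
#' \code{round(interval_years)} integer yearly cycles (the model itself is
#' annual-cycle).  With \code{interval_jitter_years > 0} each subject's
#' interval is perturbed uniformly within that half-width before rounding,
#' and the recorded per-subject interval is the jittered one, so
#' estimation can exercise exact per-subject person-time.
#'
#' @param true_matrix A [transition_matrix()] — the generating truth.
#' @param n_subjects Number of subjects.
#' @param interval_years Follow-up interval in years (default 5.4, a
#'   typical cohort mean).
#' @param baseline_distribution Baseline occupancy (default uniform over
#'   the 8 states, so every origin row is populated).
#' @param seed RNG seed.
#' @param sex Stratum label stamped on every row.
#' @param interval_jitter_years Half-width of uniform per-subject interval
#'   jitter (default 0).
#' @return A state panel data frame (columns \code{subject_id},
#'   \code{sex}, \code{state_t0}, \code{state_t1}, \code{interval_years})
#'   with a \code{truth} attribute recording the generating matrix, seed,
#'   compounded matrix and cycle count.
#' @export
generate_panel <- function(true_matrix, n_subjects, interval_years = 5.4,
                           baseline_distribution = NULL, seed = 1,
                           sex = "male", interval_jitter_years = 0) {
  stopifnot(inherits(true_matrix, "transition_matrix"))
  if (n_subjects < 1 || n_subjects != round(n_subjects)) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  if (interval_years <= 0) stop("interval_years must be > 0", call. = FALSE)
  if (interval_jitter_years < 0 || interval_jitter_years >= interval_years) {
    stop("interval_jitter_years must be in [0, interval_years)",
         call. = FALSE)
  }
  if (is.null(baseline_distribution)) {
    baseline_distribution <- rep(1 / 8, 8)
  }
  d0 <- state_distribution(baseline_distribution)
  states <- mets_states()
  set.seed(as.integer(seed %% 2147483647))
  iv <- rep(interval_years, n_subjects)
  if (interval_jitter_years > 0) {
    iv <- iv + stats::runif(n_subjects, -interval_jitter_years,
                            interval_jitter_years)
  }
  cycles <- pmax(1L, as.integer(round(iv)))
  s0 <- sample.int(8, n_subjects, replace = TRUE, prob = d0)
  s1 <- integer(n_subjects)
  # compound the annual matrix once per distinct cycle count, then draw
  # follow-up states stratum-by-stratum for speed
  for (k in sort(unique(cycles))) {
    Pk <- matrix_power(true_matrix$probs, k)
    for (i in 1:8) {
      sel <- which(cycles == k & s0 == i)
      if (length(sel) > 0) {
        s1[sel] <- sample.int(8, length(sel), replace = TRUE, prob = Pk[i, ])
      }
    }
  }
  panel <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n_subjects)),
    sex = sex,
    state_t0 = states[s0],
    state_t1 = states[s1],
    interval_years = iv,
    stringsAsFactors = FALSE
  )
  attr(panel, "truth") <- list(
    matrix = true_matrix$probs, seed = seed,
    interval_years = interval_years,
    cycles = sort(unique(cycles)),
    compounded = lapply(stats::setNames(sort(unique(cycles)),
                                        sort(unique(cycles))),
                        function(k) matrix_power(true_matrix$probs, k))
  )
  panel
}

matrix_power <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}

#' Write the generating truth of a synthetic panel to JSON
#'
#' @param panel A panel from [generate_panel()].
#' @param path Output JSON path.
#' @export
write_panel_truth <- function(panel, path) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) stop("panel carries no truth attribute", call. = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, interval_years = truth$interval_years,
         states = mets_states(),
         annual_matrix = truth$matrix),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
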