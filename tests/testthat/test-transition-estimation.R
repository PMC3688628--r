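panel_row <- function(id, s0, s1, iv = 5, sex = "male") {
  data.frame(subject_id = id, sex = sex, state_t0 = s0, state_t1 = s1,
             interval_years = iv, stringsAsFactors = FALSE)
}

test_that("transition counting tallies events and person-years by origin", {
  panel <- rbind(
    panel_row("a", "no_component", "high_bp"),
    panel_row("b", "no_component", "high_bp"),
    panel_row("c", "no_component", "high_bp"),
    panel_row("d", "no_component", "no_component"))
  tab <- count_transitions(panel)
  expect_equal(tab$counts["no_component", "high_bp"], 3)
  expect_equal(tab$counts["no_component", "no_component"], 1)
  expect_equal(sum(tab$counts), 4)
  expect_equal(unname(tab$person_years["no_component"]), 20)
  expect_equal(tab$origin_totals, rowSums(tab$counts))

  # fixed mean interval overrides recorded per-subject intervals
  tab_m <- count_transitions(panel, mean_interval = 5.4)
  expect_equal(unname(tab_m$person_years["no_component"]), 4 * 5.4)

  expect_warning(z <- count_transitions(panel[0, ]), "empty")
  expect_true(all(z$counts == 0) && all(z$person_years == 0))
  expect_error(count_transitions(rbind(panel, panel_row("e", "mets", "mets",
                                                        sex = "female"))),
               "sex")
})

test_that("rate estimation divides events by origin person-years", {
  panel <- do.call(rbind, c(
    lapply(1:3, function(i) panel_row(paste0("e", i), "no_component", "mets",
                                      iv = 10)),
    lapply(1:12, function(i) panel_row(paste0("s", i), "no_component",
                                       "no_component", iv = 10))))
  # origin states never observed draw a warning and all-zero rates
  expect_warning(r <- estimate_rates(count_transitions(panel)),
                 "no observations")
  # 3 events over 150 person-years
  expect_equal(r["no_component", "mets"], 0.02)
  expect_equal(r["no_component", "high_tg"], 0)
  expect_equal(unname(diag(r)), rep(0, 8))

  # continuity correction lifts only zero-count cells of observed rows
  rc <- suppressWarnings(
    estimate_rates(count_transitions(panel), continuity = TRUE))
  expect_equal(rc["no_component", "mets"], 0.02)
  expect_equal(rc["no_component", "high_tg"], 0.5 / 150)
  expect_equal(rc["mets", "no_component"], 0)

  # events recorded against zero person-time are inconsistent
  tab <- count_transitions(panel)
  tab$person_years["no_component"] <- 0
  expect_error(suppressWarnings(estimate_rates(tab)), "zero person-years")
})

test_that("rate-to-probability annualization follows 1 - exp(-rt)", {
  expect_equal(annualize_probability(0, 7), 0)
  # closed form at the cohort's male MetS incidence rate of 19.5/1000 PY
  expect_equal(annualize_probability(0.0195, 1), 1 - exp(-0.0195))
  expect_equal(annualize_probability(0.0195, 1), 0.019311, tolerance = 1e-4)
  expect_lt(annualize_probability(10, 1), 1)
  expect_gt(annualize_probability(10, 1), 0.9999)
  expect_error(annualize_probability(-0.1, 1), "nonnegative")
  expect_error(annualize_probability(0.1, 0), "positive")

  # strictly increasing in both the rate and the horizon
  rs <- seq(0.01, 2, length.out = 30)
  expect_true(all(diff(annualize_probability(rs, 1)) > 0))
  ts <- seq(0.5, 20, length.out = 30)
  expect_true(all(diff(annualize_probability(0.3, ts)) > 0))
})

test_that("matrix building annualizes off-diagonals with a residual diagonal", {
  tm <- build_transition_matrix(matrix(0, 8, 8))
  expect_equal(unname(tm$probs), diag(8))

  rates <- matrix(0.01, 8, 8)
  tm <- build_transition_matrix(rates)
  expect_equal(unname(rowSums(tm$probs)), rep(1, 8), tolerance = 1e-12)
  expect_equal(tm$probs[1, 2], 1 - exp(-0.01))

  # a row whose competing annualized risks exceed 1 is refused by name
  big <- rates
  big[3, ] <- 3
  expect_error(build_transition_matrix(big), "high_tg")
})

test_that("published-table loading renormalizes rows and keeps provenance", {
  men <- mets_fixture_matrix("men")
  expect_s3_class(men, "transition_matrix")
  expect_equal(unname(rowSums(men$probs)), rep(1, 8), tolerance = 1e-12)
  # the published no-component row sums to 99.99 before renormalization
  expect_equal(unname(men$printed_row_sums["no_component"]), 99.99)
  expect_equal(men$probs["no_component", "mets"] *
                 men$printed_row_sums["no_component"],
               0.45, ignore_attr = TRUE, tolerance = 1e-12)

  # round trip: undoing renormalization recovers the printed percentages
  for (sex in c("men", "women")) {
    tm <- mets_fixture_matrix(sex)
    path <- system.file("extdata",
                        paste0("annual_transitions_", sex, ".csv"),
                        package = "metsmarkov")
    printed <- as.matrix(utils::read.csv(path)[, -1])
    recovered <- sweep(tm$probs * 100, 1, tm$printed_row_sums / 100, "*")
    expect_equal(unname(recovered), unname(printed), tolerance = 0.01)
  }

  # an exactly normalized table is returned unchanged
  exact <- matrix(100 / 8, 8, 8)
  expect_equal(unname(load_printed_matrix(exact)$probs),
               matrix(1 / 8, 8, 8), tolerance = 1e-15)

  # row sums outside 99.5-100.5 are refused naming the row
  off <- exact
  off[5, ] <- off[5, ] * 1.02
  expect_error(load_printed_matrix(off), "high_bp")
})

test_that("estimation recovers a known matrix from one-year synthetic panels", {
  truth <- mets_fixture_matrix("men")
  errs <- vapply(c(500, 5000, 50000), function(n) {
    panel <- generate_panel(truth, n, interval_years = 1, seed = 2024)
    est <- estimate_transition_matrix(panel)
    max(abs(est$probs - truth$probs))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # at n = 50,000 every off-diagonal entry is within Monte-Carlo error
  expect_lt(errs[3], 0.01)
})
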