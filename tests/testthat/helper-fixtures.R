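# One row of raw measurements with every value comfortably normal unless
# overridden.
measurement_row <- function(sex = "male", waist = 80, tg = 100, hdl = 55,
                            sys = 115, dia = 75, fpg = 90,
                            aht = FALSE, adm = FALSE) {
  data.frame(sex = sex, waist_cm = waist, triglycerides_mg_dl = tg,
             hdl_mg_dl = hdl, systolic_mmHg = sys, diastolic_mmHg = dia,
             fpg_mg_dl = fpg, on_antihypertensives = aht,
             on_antidiabetics = adm, stringsAsFactors = FALSE)
}

# All 32 component profiles as a logical data frame.
all_profiles <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(g) <- mets_components()
  g
}

# A small asymmetric but strongly diagonal 8x8 transition matrix for
# property tests that must not depend on the bundled fixtures.
toy_matrix <- function() {
  set.seed(424242)
  P <- matrix(stats::runif(64, 0, 0.02), 8, 8)
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  transition_matrix(P)
}

# Independent matrix-power oracle (plain repeated %*%, no package code).
power_oracle <- function(M, k) {
  R <- diag(8)
  for (i in seq_len(k)) R <- R %*% M
  R
}
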