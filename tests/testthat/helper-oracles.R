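# Independent oracles used across the suite.

# Dense-grid quadrature of the boundary-extended piecewise-linear lactate
# curve. The grid contains the knots, so trapezoidal quadrature on it is
# exact for the piecewise-linear interpolant; the extension rule is
# re-stated here independently of extend_to_window().
grid_load_oracle <- function(times, values, window = c(0, 24),
                             step = 1e-4) {
  ord <- order(times)
  tt <- times[ord]
  vv <- values[ord]
  if (tt[1] > window[1]) { tt <- c(window[1], tt); vv <- c(vv[1], vv) }
  n <- length(tt)
  if (tt[n] < window[2]) { tt <- c(tt, window[2]); vv <- c(vv, vv[n]) }
  grid <- sort(unique(c(seq(window[1], window[2], by = step), tt)))
  y <- stats::approx(tt, vv, xout = grid, ties = "ordered")$y
  sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
}

# Exhaustive pairwise Mann-Whitney AUC with half credit for ties.
pairwise_auc_oracle <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Brute-force maximum Youden index over all observed cutoffs under the
# "positive if score >= cutoff" convention.
brute_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cands <- sort(unique(scores))
  j <- vapply(cands, function(cut) {
    mean(scores[labels] >= cut) + mean(scores[!labels] < cut) - 1
  }, numeric(1))
  list(cutoff = cands[which.max(j)], j_max = max(j))
}

# Random irregular lactate series: n in [1, 20], uniform times, lognormal
# values; occasional duplicated timestamps to exercise tie handling.
random_series <- function(window = c(0, 24)) {
  n <- sample(1:20, 1)
  times <- round(runif(n, window[1], window[2]), 3)
  values <- rlnorm(n, log(2), 0.5)
  list(times = times, values = values)
}

# The five-patient eligibility fixture: one failure per criterion, one
# eligible patient.
fixture_cohort <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    age_years = c(17, 50, 60, 55, 70),
    first_icu_stay = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    icu_los_hours = c(48, 48, 48, 20, 48),
    sepsis = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    death_28d = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3",
                   "p4", "p4", "p4", "p5", "p5", "p5"),
    time_hours = c(2, 8, 15, 1, 6, 12, 5, 3, 9, 18, 2, 10, 20),
    lactate_mmol_l = c(2.1, 1.9, 1.8, 3.5, 3.0, 2.4, 2.5,
                       4.0, 3.2, 2.8, 4.5, 3.1, 2.2),
    stringsAsFactors = FALSE)
  list(patients = patients, measurements = measurements)
}
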