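test_that("the eligibility cascade counts each patient at its first failure", {
  fix <- fixture_cohort()
  res <- apply_exclusions(fix$patients, fix$measurements)
  expect_equal(res$included, "p5")
  expect_equal(res$report$n_excluded, c(1L, 1L, 1L, 1L))
  expect_equal(attr(res$report, "n_screened"), 5L)
  expect_equal(attr(res$report, "n_included"), 1L)

  # a patient failing several criteria is counted once, at the earliest
  multi <- fix$patients
  multi$age_years[1] <- 17
  multi$first_icu_stay[1] <- FALSE      # p1 fails criteria 1 and 2
  res2 <- apply_exclusions(multi, fix$measurements)
  expect_equal(res2$report$n_excluded[1], 1L)
  expect_equal(res2$report$n_excluded[2], 1L)  # only p2 remains at crit 2
})

test_that("empty input yields an empty report with consistent totals", {
  empty_p <- fixture_cohort()$patients[0, ]
  empty_m <- fixture_cohort()$measurements[0, ]
  res <- apply_exclusions(empty_p, empty_m)
  expect_equal(length(res$included), 0L)
  expect_equal(res$report$n_excluded, rep(0L, 4))
  expect_equal(attr(res$report, "n_included"), 0L)
})

test_that("unknown measurement ids warn and are ignored", {
  fix <- fixture_cohort()
  extra <- rbind(fix$measurements,
                 data.frame(patient_id = "ghost", time_hours = 3,
                            lactate_mmol_l = 2))
  expect_warning(res <- apply_exclusions(fix$patients, extra),
                 "not present in the patient table")
  expect_equal(res$included, "p5")
})

test_that("filter report identity holds and the cascade is idempotent", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    patients <- data.frame(
      patient_id = sprintf("q%03d", seq_len(n)),
      age_years = sample(c(10, 16, 25, 50, 80), n, replace = TRUE),
      first_icu_stay = runif(n) < 0.8,
      icu_los_hours = runif(n, 5, 200),
      sepsis = runif(n) < 0.3,
      death_28d = runif(n) < 0.2)
    n_meas <- sample(0:5, n, replace = TRUE)
    measurements <- data.frame(
      patient_id = rep(patients$patient_id, n_meas),
      time_hours = runif(sum(n_meas), 0, 24),
      lactate_mmol_l = rlnorm(sum(n_meas), log(2), 0.4))
    res <- apply_exclusions(patients, measurements)
    expect_equal(attr(res$report, "n_screened") - sum(res$report$n_excluded),
                 attr(res$report, "n_included"))
    expect_equal(length(res$included), attr(res$report, "n_included"))

    # idempotence: re-screening the included cohort excludes nobody
    inc <- patients[patients$patient_id %in% res$included, ]
    res2 <- apply_exclusions(
      inc, measurements[measurements$patient_id %in% res$included, ])
    expect_equal(sum(res2$report$n_excluded), 0L)
    expect_equal(res2$included, res$included)
  }
})

test_that("sepsis split is an order-preserving partition", {
  fix <- fixture_cohort()
  sp <- split_by_sepsis(fix$patients)
  expect_equal(nrow(sp$sepsis) + nrow(sp$non_sepsis), nrow(fix$patients))
  expect_equal(sp$sepsis$patient_id, c("p2", "p4", "p5"))
  expect_equal(sp$non_sepsis$patient_id, c("p1", "p3"))

  all_sep <- fix$patients
  all_sep$sepsis <- TRUE
  expect_equal(nrow(split_by_sepsis(all_sep)$non_sepsis), 0L)

  bad <- fix$patients
  bad$sepsis[2] <- NA
  expect_error(split_by_sepsis(bad), "sepsis")
})

test_that("measurement-count strata are nested and consistent with the cascade", {
  patients <- data.frame(patient_id = c("A", "B", "C"),
                         age_years = 50, first_icu_stay = TRUE,
                         icu_los_hours = 48, sepsis = FALSE,
                         death_28d = FALSE)
  measurements <- data.frame(
    patient_id = rep(c("A", "B", "C"), c(2, 3, 5)),
    time_hours = c(1, 2, 1, 2, 3, 1, 2, 3, 4, 5),
    lactate_mmol_l = 2)
  s3 <- stratify_by_measurement_count(patients, measurements, 3)
  expect_equal(s3$patient_id, c("B", "C"))
  expect_equal(stratify_by_measurement_count(patients, measurements, 3,
                                             rule = "exactly")$patient_id,
               "B")
  # nesting and >=2 consistency with the exclusion cascade
  s2 <- stratify_by_measurement_count(patients, measurements, 2)
  s4 <- stratify_by_measurement_count(patients, measurements, 4)
  s5 <- stratify_by_measurement_count(patients, measurements, 5)
  expect_equal(s2$patient_id, patients$patient_id)
  expect_true(all(s5$patient_id %in% s4$patient_id))
  expect_true(all(s4$patient_id %in% s3$patient_id))
  expect_error(stratify_by_measurement_count(patients, measurements, 1),
               ">= 2")
})

test_that("CSV readers enforce the documented dialects", {
  pts <- read_patients(system.file("extdata", "example_patients.csv",
                                   package = "lactload"))
  mes <- read_measurements(system.file("extdata", "example_measurements.csv",
                                       package = "lactload"))
  expect_type(pts$sepsis, "logical")
  expect_equal(nrow(pts), 5L)
  res <- apply_exclusions(pts, mes)
  expect_equal(res$included, "p5")

  bad <- tempfile(fileext = ".csv")
  writeLines("id,time,value\n1,2,3", bad)
  expect_error(read_measurements(bad), "patient_id")
  expect_error(read_patients(bad), "age_years")
})
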