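markers <- c(normalized_lactate_load = "normalized lactate load",
             max_lactate = "maximum lactate",
             mean_lactate = "mean lactate")

# One Table-2-style row: cutoff, AUC with CI, operating characteristics.
performance_row <- function(scores, labels, cohort, marker, level) {
  if (!any(labels) || all(labels) || length(labels) < 4L) {
    message(sprintf("cohort '%s': single-class or too small; marker '%s' skipped",
                    cohort, marker))
    return(data.frame(cohort = cohort, marker = marker,
                      n = length(labels), n_pos = sum(labels),
                      cutoff = NA_real_, auc = NA_real_,
                      auc_lo = NA_real_, auc_hi = NA_real_,
                      sensitivity = NA_real_, sens_lo = NA_real_,
                      sens_hi = NA_real_, specificity = NA_real_,
                      spec_lo = NA_real_, spec_hi = NA_real_,
                      lr_pos = NA_real_, lr_pos_lo = NA_real_,
                      lr_pos_hi = NA_real_, lr_neg = NA_real_,
                      lr_neg_lo = NA_real_, lr_neg_hi = NA_real_,
                      ppv = NA_real_, ppv_lo = NA_real_, ppv_hi = NA_real_,
                      npv = NA_real_, npv_lo = NA_real_, npv_hi = NA_real_,
                      stringsAsFactors = FALSE))
  }
  roc <- roc_curve(scores, labels, level)
  cut <- youden_cutoff(scores, labels)
  op <- operating_characteristics(scores, labels, cut, level)
  data.frame(cohort = cohort, marker = marker,
             n = length(labels), n_pos = sum(labels),
             cutoff = cut, auc = roc$auc,
             auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
             sensitivity = op$sensitivity$estimate,
             sens_lo = op$sensitivity$ci[1], sens_hi = op$sensitivity$ci[2],
             specificity = op$specificity$estimate,
             spec_lo = op$specificity$ci[1], spec_hi = op$specificity$ci[2],
             lr_pos = op$lr_pos$estimate,
             lr_pos_lo = op$lr_pos$ci[1], lr_pos_hi = op$lr_pos$ci[2],
             lr_neg = op$lr_neg$estimate,
             lr_neg_lo = op$lr_neg$ci[1], lr_neg_hi = op$lr_neg$ci[2],
             ppv = op$ppv$estimate, ppv_lo = op$ppv$ci[1],
             ppv_hi = op$ppv$ci[2],
             npv = op$npv$estimate, npv_lo = op$npv$ci[1],
             npv_hi = op$npv$ci[2],
             stringsAsFactors = FALSE)
}

two_class <- function(labels) length(labels) >= 4L && any(labels) && !all(labels)

#' Run the end-to-end lactate burden analysis
#'
#' Orchestrates the whole pipeline on a measurement table and a patient
#' table: eligibility cascade, per-patient burden metrics, sepsis /
#' non-sepsis split, ROC analysis with Youden cutoffs and operating
#' characteristics for the three markers (normalized lactate load, maximum
#' lactate, mean lactate) in each cohort, paired DeLong comparisons of the
#' normalized load against the other two markers within each cohort,
#' unpaired sepsis-versus-non-sepsis AUC comparisons per marker, the
#' measurement-count sensitivity analysis (strata >=2, >=3, >=4, >=5),
#' and a descriptive table-one. Fully deterministic given its inputs.
#'
#' Cohorts in which only one outcome class is present are skipped for
#' inference (their cells are `NA`) and the run continues.
#'
#' @param measurements Measurement data.frame or path to a measurement CSV
#'   (see [read_measurements()]).
#' @param patients Patient data.frame or path to a patient CSV
#'   (see [read_patients()]).
#' @param window An [observation_window()]; default first 24 h.
#' @param ci_level Confidence level for every interval (default 0.95).
#' @param strata Measurement-count thresholds of the sensitivity analysis
#'   (default `2:5`, each interpreted as "at least k").
#' @return An object of class `lactload_report`: a list with elements
#'   `filter_report`, `burden` (per-patient metrics of included patients,
#'   with sepsis and outcome flags), `burden_summary`, `performance`
#'   (Table-2-shaped data.frame), `comparisons` (paired and unpaired
#'   DeLong tests), `sensitivity` (Table-3-shaped AUC by measurement
#'   count), `table_one` and `metadata`.
#' @export
run_analysis <- function(measurements, patients,
                         window = observation_window(),
                         ci_level = 0.95, strata = 2:5) {
  window <- as_window(window)
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(patients)) patients <- read_patients(patients)

  excl <- apply_exclusions(patients, measurements, window)
  included <- patients[patients$patient_id %in% excl$included, , drop = FALSE]

  burden <- compute_burden(
    measurements[measurements$patient_id %in% excl$included, , drop = FALSE],
    window)
  burden <- merge(burden,
                  included[c("patient_id", "sepsis", "death_28d")],
                  by = "patient_id", sort = TRUE)

  cohorts <- list(all = burden,
                  sepsis = burden[burden$sepsis, , drop = FALSE],
                  non_sepsis = burden[!burden$sepsis, , drop = FALSE])

  # Table-2-shaped performance rows
  perf <- do.call(rbind, lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    do.call(rbind, lapply(names(markers), function(mk)
      performance_row(co[[mk]], co$death_28d, cn, markers[[mk]], ci_level)))
  }))
  rownames(perf) <- NULL

  # paired comparisons: normalized load vs max, vs mean, within cohorts
  paired <- do.call(rbind, lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    if (!two_class(co$death_28d)) return(NULL)
    do.call(rbind, lapply(c("max_lactate", "mean_lactate"), function(mk) {
      cmp <- delong_paired_test(co$normalized_lactate_load, co[[mk]],
                                co$death_28d)
      data.frame(comparison = "paired", cohort = cn,
                 marker_a = markers[["normalized_lactate_load"]],
                 marker_b = markers[[mk]],
                 auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                 z = cmp$z, p_two_sided = cmp$p_two_sided,
                 stringsAsFactors = FALSE)
    }))
  }))

  # unpaired comparisons: sepsis vs non-sepsis, per marker
  unpaired <- NULL
  if (two_class(cohorts$sepsis$death_28d) &&
      two_class(cohorts$non_sepsis$death_28d)) {
    unpaired <- do.call(rbind, lapply(names(markers), function(mk) {
      ca <- delong_components(
        cohorts$sepsis[[mk]][cohorts$sepsis$death_28d],
        cohorts$sepsis[[mk]][!cohorts$sepsis$death_28d])
      cb <- delong_components(
        cohorts$non_sepsis[[mk]][cohorts$non_sepsis$death_28d],
        cohorts$non_sepsis[[mk]][!cohorts$non_sepsis$death_28d])
      cmp <- independent_auc_test(ca, cb)
      data.frame(comparison = "unpaired",
                 cohort = "sepsis vs non_sepsis",
                 marker_a = markers[[mk]], marker_b = markers[[mk]],
                 auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                 z = cmp$z, p_two_sided = cmp$p_two_sided,
                 stringsAsFactors = FALSE)
    }))
  }
  comparisons <- rbind(paired, unpaired)
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  # Table-3-shaped sensitivity analysis: AUC of normalized load by
  # minimum measurement count, per sepsis stratum
  sens_rows <- list()
  for (cn in c("sepsis", "non_sepsis")) {
    co <- cohorts[[cn]]
    for (k in strata) {
      sub <- co[co$n_measurements >= k, , drop = FALSE]
      if (two_class(sub$death_28d)) {
        comp <- delong_components(
          sub$normalized_lactate_load[sub$death_28d],
          sub$normalized_lactate_load[!sub$death_28d])
        ci <- delong_ci(comp, ci_level)
        sens_rows[[length(sens_rows) + 1L]] <-
          data.frame(cohort = cn, min_measurements = k, n = nrow(sub),
                     auc = comp$auc, auc_lo = ci[1], auc_hi = ci[2],
                     stringsAsFactors = FALSE)
      } else {
        message(sprintf(
          "sensitivity stratum >=%d in cohort '%s' is degenerate; skipped", k, cn))
        sens_rows[[length(sens_rows) + 1L]] <-
          data.frame(cohort = cn, min_measurements = k, n = nrow(sub),
                     auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                     stringsAsFactors = FALSE)
      }
    }
  }
  sensitivity <- do.call(rbind, sens_rows)

  # descriptive table-one on included patients + burden metrics
  t1_data <- merge(included[setdiff(names(included), "true_nll")],
                   burden[c("patient_id", "n_measurements", "max_lactate",
                            "mean_lactate", "lactate_load",
                            "normalized_lactate_load")],
                   by = "patient_id", sort = TRUE)
  tab1 <- if (two_class(t1_data$sepsis) || (any(t1_data$sepsis) &&
                                            any(!t1_data$sepsis)))
    table_one(t1_data, group = "sepsis",
              variables = setdiff(names(t1_data),
                                  c("patient_id", "sepsis", "first_icu_stay")))
  else NULL

  burden_summary <- do.call(rbind, lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    data.frame(cohort = cn, n = nrow(co),
               mortality_pct = 100 * mean(co$death_28d),
               median_max_lactate = stats::median(co$max_lactate),
               median_mean_lactate = stats::median(co$mean_lactate),
               median_lactate_load = stats::median(co$lactate_load),
               median_nll = stats::median(co$normalized_lactate_load),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    filter_report = excl$report,
    burden = burden,
    burden_summary = burden_summary,
    performance = perf,
    comparisons = comparisons,
    sensitivity = sensitivity,
    table_one = tab1,
    metadata = list(window_start = window$start, window_end = window$end,
                    ci_level = ci_level, strata = strata,
                    n_screened = attr(excl$report, "n_screened"),
                    n_included = attr(excl$report, "n_included"),
                    package_version =
                      as.character(utils::packageVersion("lactload")))
  ), class = "lactload_report")
}

#' @export
print.lactload_report <- function(x, ...) {
  cat("== Lactate burden analysis report ==\n\n")
  print(x$filter_report)
  cat("\nCohort summaries:\n")
  print(x$burden_summary, row.names = FALSE, digits = 4)
  cat("\nMarker performance (28-day mortality):\n")
  print(x$performance[c("cohort", "marker", "n", "cutoff", "auc",
                        "auc_lo", "auc_hi", "sensitivity", "specificity")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("\nDeLong AUC comparisons:\n")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  cat("\nAUC of normalized lactate load by measurement count:\n")
  print(x$sensitivity, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Serializes every table of a [run_analysis()] report as CSV (full
#' precision; rounding is left to the presentation layer) plus a JSON-like
#' metadata file, producing byte-identical output for identical inputs.
#'
#' @param report A `lactload_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "lactload_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files[[length(files) + 1L]] <<- path
  }
  fr <- as.data.frame(report$filter_report)
  fr_tot <- data.frame(criterion = c("screened", "included"),
                       n_excluded = NA_integer_)
  fr_tot$n_excluded <- c(attr(report$filter_report, "n_screened"),
                         attr(report$filter_report, "n_included"))
  names(fr_tot) <- names(fr)
  wr(rbind(fr, fr_tot), "filter_report.csv")
  wr(report$burden_summary, "burden_summary.csv")
  wr(report$performance, "performance.csv")
  wr(report$comparisons, "comparisons.csv")
  wr(report$sensitivity, "sensitivity.csv")
  wr(report$table_one, "table_one.csv")
  meta <- report$metadata
  meta$strata <- paste(meta$strata, collapse = ",")
  wr(data.frame(key = names(meta),
                value = vapply(meta, as.character, character(1))),
     "metadata.csv")
  invisible(unlist(files))
}
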