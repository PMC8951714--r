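#' Kolmogorov-Smirnov normality gate
#'
#' Decides whether a sample is treated as normally distributed for the
#' purpose of choosing a descriptive summary and a two-group test: a
#' one-sample Kolmogorov-Smirnov test against a normal distribution with
#' the sample's estimated mean and standard deviation, declaring normality
#' when p >= 0.05. Samples with fewer than three observations, or
#' degenerate (constant) samples, are treated as non-normal.
#'
#' @param x Numeric sample.
#' @param alpha Significance level of the gate (default 0.05).
#' @return TRUE if the sample passes the normality gate.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    message("normality gate: n < 3, treated as non-normal")
    return(FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) return(FALSE)
  p <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = s)$p.value)
  p >= alpha
}

#' Normality-gated comparison of two continuous samples
#'
#' Applies Student's t-test when both samples pass the
#' [normality_gate()], otherwise the Wilcoxon rank-sum test; two-sided in
#' either case.
#'
#' @param a,b Numeric samples, each with at least two observations.
#' @return A list with `test` (`"t-test"` or `"wilcoxon"`), `statistic`
#'   and `p_value`.
#' @export
compare_continuous <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must have at least two observations", call. = FALSE)
  if (normality_gate(a) && normality_gate(b)) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(test = "t-test", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test = "wilcoxon", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square test without continuity correction, for comparing
#' categorical variables between cohorts.
#'
#' @param table A 2xk matrix of nonnegative counts with positive margins.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
compare_categorical <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

# Format helpers for table-one summaries (one decimal by default).
fmt_mean_sd <- function(x, digits) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          mean(x), stats::sd(x))
}
fmt_median_iqr <- function(x, digits) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
          q[2], q[1], q[3])
}
fmt_count_pct <- function(x, digits) {
  sprintf(paste0("%d (%.", digits, "f)"), sum(x), 100 * mean(x))
}

#' Descriptive comparison table between two cohorts
#'
#' Builds a table-one-style summary: continuous variables are shown as
#' mean ± SD (and compared with Student's t-test) when both cohorts pass
#' the [normality_gate()], otherwise as median (IQR) with the Wilcoxon
#' rank-sum test; logical variables are shown as count (%) and compared
#' with the chi-square test.
#'
#' @param patients Patient data.frame.
#' @param group Name of a logical column defining the two cohorts
#'   (default `"sepsis"`).
#' @param variables Character vector of column names to summarize; default:
#'   every numeric or logical column other than the grouping column and
#'   `patient_id`.
#' @param digits Decimals used in the formatted summaries (default 1).
#' @return A data.frame with one row per variable: the two cohort
#'   summaries, the test used and its p-value.
#' @export
table_one <- function(patients, group = "sepsis", variables = NULL,
                      digits = 1) {
  stopifnot(is.data.frame(patients), group %in% names(patients))
  g <- as.logical(patients[[group]])
  if (anyNA(g)) stop("grouping column must be non-missing", call. = FALSE)
  if (is.null(variables)) {
    is_summarizable <- vapply(patients, function(col)
      is.numeric(col) || is.logical(col), logical(1))
    variables <- setdiff(names(patients)[is_summarizable],
                         c(group, "patient_id"))
  }
  rows <- lapply(variables, function(v) {
    x <- patients[[v]]
    xa <- x[g]
    xb <- x[!g]
    if (is.logical(x) || all(x %in% c(0, 1, NA))) {
      xa <- as.logical(xa); xb <- as.logical(xb)
      tab <- rbind(c(sum(xa, na.rm = TRUE), sum(!xa, na.rm = TRUE)),
                   c(sum(xb, na.rm = TRUE), sum(!xb, na.rm = TRUE)))
      res <- tryCatch(compare_categorical(tab),
                      error = function(e) list(p_value = NA_real_))
      data.frame(variable = v,
                 group_true = fmt_count_pct(xa[!is.na(xa)], digits),
                 group_false = fmt_count_pct(xb[!is.na(xb)], digits),
                 test = "chi-square", p_value = res$p_value,
                 stringsAsFactors = FALSE)
    } else {
      normal <- normality_gate(xa) && normality_gate(xb)
      res <- compare_continuous(xa, xb)
      data.frame(variable = v,
                 group_true = if (normal) fmt_mean_sd(xa[!is.na(xa)], digits)
                              else fmt_median_iqr(xa[!is.na(xa)], digits),
                 group_false = if (normal) fmt_mean_sd(xb[!is.na(xb)], digits)
                               else fmt_median_iqr(xb[!is.na(xb)], digits),
                 test = res$test, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group_true"] <- paste0(group, "_true")
  names(out)[names(out) == "group_false"] <- paste0(group, "_false")
  rownames(out) <- NULL
  out
}
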