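#' Nonparametric AUC (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive (e.g. a non-survivor)
#' has a higher marker value than a randomly chosen negative, with ties
#' given half credit:
#' \deqn{\widehat{AUC} = \frac{1}{mn}\sum_{i,j}\psi(X_i, Y_j)}
#' where \eqn{\psi = 1} if \eqn{X_i > Y_j}, \eqn{1/2} if equal, 0
#' otherwise. Higher marker values are always treated as indicating the
#' positive class (no automatic direction detection). Computed via
#' midranks in O(N log N).
#'
#' @param pos_scores Marker values for the positive class (nonempty).
#' @param neg_scores Marker values for the negative class (nonempty).
#' @return The AUC, a number in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(3, 1, 2), c(2, 0))  # 0.75
#' @export
auc_mann_whitney <- function(pos_scores, neg_scores) {
  m <- length(pos_scores)
  n <- length(neg_scores)
  if (m == 0L || n == 0L)
    stop("single-class cohort: both score groups must be nonempty",
         call. = FALSE)
  if (anyNA(pos_scores) || anyNA(neg_scores))
    stop("scores must be non-missing", call. = FALSE)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' DeLong structural components of the AUC
#'
#' Computes the placement values underlying the DeLong variance estimator:
#' for each positive score the tie-corrected fraction of negatives it
#' exceeds (`v10`), and for each negative the fraction of positives
#' exceeding it is subtracted from one (`v01`). Both sets of placements
#' average to the Mann-Whitney AUC, and
#' \deqn{\widehat{var}(AUC) = S_{10}/m + S_{01}/n}
#' with \eqn{S} the sample variances of the placements.
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `delong_components`: a list with `v10`,
#'   `v01`, `auc`, `var_auc` (NA when either group has fewer than two
#'   observations), `m` and `n`.
#' @export
delong_components <- function(pos_scores, neg_scores) {
  m <- length(pos_scores)
  n <- length(neg_scores)
  if (m == 0L || n == 0L)
    stop("single-class cohort: both score groups must be nonempty",
         call. = FALSE)
  if (anyNA(pos_scores) || anyNA(neg_scores))
    stop("scores must be non-missing", call. = FALSE)
  r_all <- rank(c(pos_scores, neg_scores), ties.method = "average")
  r_pos <- rank(pos_scores, ties.method = "average")
  r_neg <- rank(neg_scores, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- mean(v10)
  var_auc <- if (m >= 2L && n >= 2L)
    stats::var(v10) / m + stats::var(v01) / n
  else NA_real_
  structure(list(v10 = v10, v01 = v01, auc = auc, var_auc = var_auc,
                 m = m, n = n),
            class = "delong_components")
}

#' @export
print.delong_components <- function(x, ...) {
  cat(sprintf("<delong_components: AUC %.4f (SE %s), %d pos / %d neg>\n",
              x$auc,
              if (is.na(x$var_auc)) "NA" else sprintf("%.4f", sqrt(x$var_auc)),
              x$m, x$n))
  invisible(x)
}

#' Wald confidence interval for an AUC from DeLong components
#'
#' `auc ± z * SE` on the probability scale, truncated to \[0, 1\]. A
#' zero-variance degenerate case (e.g. perfectly separated groups) yields
#' the degenerate interval `(auc, auc)`.
#'
#' @param components A [delong_components()] object with a valid variance
#'   (both groups of size >= 2).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
delong_ci <- function(components, level = 0.95) {
  stopifnot(inherits(components, "delong_components"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  if (is.na(components$var_auc))
    stop("variance requires both groups of size >= 2", call. = FALSE)
  if (components$var_auc <= 0)
    return(c(components$auc, components$auc))
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(components$var_auc)
  lo <- max(0, components$auc - z * se)
  hi <- min(1, components$auc + z * se)
  c(lo, hi)
}

new_delong_comparison <- function(auc_a, auc_b, var_a, var_b, cov_ab, z, p,
                                  paired) {
  structure(list(auc_a = auc_a, auc_b = auc_b, variance_a = var_a,
                 variance_b = var_b, covariance = cov_ab, z = z,
                 p_two_sided = p, paired = paired),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<delong_comparison (%s)>\n",
              if (x$paired) "paired" else "unpaired"))
  cat(sprintf("  AUC A = %.4f, AUC B = %.4f (difference %+.4f)\n",
              x$auc_a, x$auc_b, x$auc_a - x$auc_b))
  cat(sprintf("  z = %.4f, two-sided p = %.4g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same patients (same
#' outcome labels), using the covariance of their structural components:
#' \deqn{z = \frac{AUC_A - AUC_B}{\sqrt{var_A + var_B - 2\,cov_{AB}}}}
#' with a two-sided p-value from the standard normal reference.
#'
#' @param scores_a,scores_b Marker values for the same patients.
#' @param labels Logical outcome vector (TRUE = positive class, e.g. died
#'   by day 28), shared by both markers.
#' @return A `delong_comparison` object.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be non-missing", call. = FALSE)
  comp_a <- delong_components(scores_a[labels], scores_a[!labels])
  comp_b <- delong_components(scores_b[labels], scores_b[!labels])
  m <- comp_a$m
  n <- comp_a$n
  if (m < 2L || n < 2L)
    stop("paired DeLong test requires >= 2 patients in each class",
         call. = FALSE)
  cov_ab <- stats::cov(comp_a$v10, comp_b$v10) / m +
    stats::cov(comp_a$v01, comp_b$v01) / n
  var_diff <- comp_a$var_auc + comp_b$var_auc - 2 * cov_ab
  d <- comp_a$auc - comp_b$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps ^ 0.5) {
      z <- 0
      p <- 1
    } else {
      stop("degenerate zero variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_delong_comparison(comp_a$auc, comp_b$auc, comp_a$var_auc,
                        comp_b$var_auc, cov_ab, z, p, paired = TRUE)
}

#' Unpaired comparison of AUCs from independent cohorts
#'
#' Compares AUCs estimated on disjoint cohorts (e.g. sepsis versus
#' non-sepsis), where the structural components are independent and the
#' covariance term is zero:
#' \deqn{z = \frac{AUC_A - AUC_B}{\sqrt{var_A + var_B}}}
#'
#' @param comp_a,comp_b [delong_components()] objects from the two
#'   cohorts (each with valid variance).
#' @return A `delong_comparison` object.
#' @export
independent_auc_test <- function(comp_a, comp_b) {
  stopifnot(inherits(comp_a, "delong_components"),
            inherits(comp_b, "delong_components"))
  if (is.na(comp_a$var_auc) || is.na(comp_b$var_auc))
    stop("both components must carry a valid variance (groups of size >= 2)",
         call. = FALSE)
  var_sum <- comp_a$var_auc + comp_b$var_auc
  d <- comp_a$auc - comp_b$auc
  if (var_sum <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps ^ 0.5) {
      z <- 0
      p <- 1
    } else {
      stop("degenerate zero variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
  } else {
    z <- d / sqrt(var_sum)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_delong_comparison(comp_a$auc, comp_b$auc, comp_a$var_auc,
                        comp_b$var_auc, 0, z, p, paired = FALSE)
}

# Sensitivity/specificity at every observed threshold under the
# "positive if score >= cutoff" convention. Returns one row per candidate
# cutoff (the sorted unique observed scores).
threshold_profile <- function(scores, labels) {
  labels <- as.logical(labels)
  m <- sum(labels)
  n <- sum(!labels)
  us <- sort(unique(scores))
  idx <- match(scores, us)
  pos_tab <- tabulate(idx[labels], nbins = length(us))
  neg_tab <- tabulate(idx[!labels], nbins = length(us))
  pos_ge <- rev(cumsum(rev(pos_tab)))          # positives with score >= cutoff
  neg_lt <- cumsum(neg_tab) - neg_tab          # negatives with score <  cutoff
  data.frame(cutoff = us,
             sensitivity = pos_ge / m,
             specificity = neg_lt / n)
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Builds the empirical ROC curve of a marker against a binary outcome
#' under the "positive if score >= threshold" rule, together with the
#' Mann-Whitney AUC and its DeLong Wald confidence interval.
#'
#' @param scores Numeric marker values.
#' @param labels Logical outcome (TRUE = positive class).
#' @param level Confidence level for the AUC interval (default 0.95).
#' @return An object of class `roc_result`: a list with `thresholds`,
#'   `sensitivities`, `specificities` (threshold -Inf included so the
#'   curve starts at sensitivity 1), `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("single-class cohort: both outcome classes must be present",
         call. = FALSE)
  prof <- threshold_profile(scores, labels)
  comp <- delong_components(scores[labels], scores[!labels])
  ci <- if (is.na(comp$var_auc)) c(NA_real_, NA_real_)
        else delong_ci(comp, level)
  structure(list(
    thresholds = c(-Inf, prof$cutoff),
    sensitivities = c(1, prof$sensitivity),
    specificities = c(0, prof$specificity),
    auc = comp$auc,
    auc_ci = ci,
    level = level,
    n_pos = comp$m,
    n_neg = comp$n
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f (%d%% CI %.4f-%.4f), %d pos / %d neg>\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Returns the observed score value maximizing the Youden index
#' \eqn{J = sensitivity + specificity - 1} under the "positive if
#' score >= cutoff" convention. Ties in J are broken toward the smallest
#' cutoff.
#'
#' @inheritParams roc_curve
#' @return The selected cutoff (one of the observed score values).
#' @examples
#' youden_cutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))  # 5
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("single-class cohort: both outcome classes must be present",
         call. = FALSE)
  prof <- threshold_profile(scores, labels)
  j <- prof$sensitivity + prof$specificity - 1
  prof$cutoff[which.max(j)]   # which.max picks the first (smallest) maximizer
}

# Clopper-Pearson exact binomial CI for x successes out of n.
clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

# Log-method CI for a likelihood ratio built from sens = a/m and
# 1 - spec = b/n (LR+) or analogous fractions. ratio must be finite, > 0.
lr_log_ci <- function(ratio, x1, n1, x2, n2, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  se_log <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
  exp(log(ratio) + c(-1, 1) * z * se_log)
}

#' Operating characteristics at a fixed cutoff
#'
#' Summarizes the 2x2 classification table obtained by predicting the
#' positive class when `score >= cutoff`: sensitivity and specificity with
#' Clopper-Pearson exact intervals, positive and negative likelihood
#' ratios with log-method intervals, and predictive values at the observed
#' prevalence with Clopper-Pearson intervals. A likelihood ratio with a
#' zero denominator is reported as `Inf` with a one-sided interval (a
#' message is logged).
#'
#' @inheritParams roc_curve
#' @param cutoff The decision threshold.
#' @return An object of class `operating_point`: a list with `cutoff`, the
#'   2x2 counts (`tp`, `fp`, `tn`, `fn`) and components `sensitivity`,
#'   `specificity`, `lr_pos`, `lr_neg`, `ppv`, `npv`, each a list with
#'   `estimate` and `ci`.
#' @export
operating_characteristics <- function(scores, labels, cutoff, level = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("single-class cohort: both outcome classes must be present",
         call. = FALSE)
  pred <- scores >= cutoff
  tp <- sum(pred & labels)
  fn <- sum(!pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  m <- tp + fn
  n <- fp + tn

  sens <- tp / m
  spec <- tn / n

  lr_pos_est <- if (fp == 0) Inf else sens / (1 - spec)
  lr_neg_est <- if (tn == 0) Inf else (1 - sens) / spec

  lr_pos_ci <- if (fp == 0 || tp == 0) {
    if (fp == 0)
      message("LR+ undefined denominator (no false positives); reported as infinite")
    c(if (tp == 0) 0 else NA_real_, Inf)
  } else lr_log_ci(lr_pos_est, tp, m, fp, n, level)

  lr_neg_ci <- if (tn == 0 || fn == 0) {
    if (tn == 0)
      message("LR- undefined denominator (no true negatives); reported as infinite")
    c(if (fn == 0) 0 else NA_real_, Inf)
  } else lr_log_ci(lr_neg_est, fn, m, tn, n, level)

  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)

  structure(list(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = list(estimate = sens, ci = clopper_pearson(tp, m, level)),
    specificity = list(estimate = spec, ci = clopper_pearson(tn, n, level)),
    lr_pos = list(estimate = lr_pos_est, ci = lr_pos_ci),
    lr_neg = list(estimate = lr_neg_est, ci = lr_neg_ci),
    ppv = list(estimate = ppv,
               ci = if (is.na(ppv)) c(NA_real_, NA_real_)
                    else clopper_pearson(tp, tp + fp, level)),
    npv = list(estimate = npv,
               ci = if (is.na(npv)) c(NA_real_, NA_real_)
                    else clopper_pearson(tn, tn + fn, level)),
    level = level
  ), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  fmt <- function(comp) {
    sprintf("%.3f (%.3f-%.3f)", comp$estimate, comp$ci[1], comp$ci[2])
  }
  cat(sprintf("<operating_point at cutoff %g>\n", x$cutoff))
  cat(sprintf("  2x2: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  LR+:", fmt(x$lr_pos), "  LR-:", fmt(x$lr_neg), "\n")
  cat("  PPV:", fmt(x$ppv), "  NPV:", fmt(x$npv), "\n")
  invisible(x)
}
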