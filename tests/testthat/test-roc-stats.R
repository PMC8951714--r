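make_scored <- function(n_pos, n_neg, mu = 1, tie_grid = NULL) {
  pos <- rnorm(n_pos, mu)
  neg <- rnorm(n_neg)
  if (!is.null(tie_grid) && !is.na(tie_grid)) {  # coarse rounding induces ties
    pos <- round(pos, tie_grid)
    neg <- round(neg, tie_grid)
  }
  list(pos = pos, neg = neg)
}

proc_roc <- function(scores, labels) {
  pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
            predictor = scores, direction = "<", quiet = TRUE)
}

test_that("Mann-Whitney AUC matches hand values and edge cases", {
  expect_equal(auc_mann_whitney(c(3, 1, 2), c(2, 0)), 4.5 / 6)
  expect_equal(auc_mann_whitney(rep(1, 5), rep(1, 7)), 0.5)  # all ties
  expect_equal(auc_mann_whitney(c(5, 6), c(1, 2)), 1)        # separated
  expect_error(auc_mann_whitney(numeric(0), 1:3), "single-class")
})

test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  set.seed(31)
  for (i in 1:60) {
    sc <- make_scored(sample(2:200, 1), sample(2:200, 1),
                      tie_grid = sample(c(NA, 0, 1), 1))
    expect_equal(auc_mann_whitney(sc$pos, sc$neg),
                 pairwise_auc_oracle(sc$pos, sc$neg))
  }
})

test_that("DeLong placements average to the AUC and match pROC", {
  set.seed(32)
  for (i in 1:10) {
    sc <- make_scored(sample(5:80, 1), sample(5:80, 1),
                      tie_grid = sample(c(NA, 1), 1))
    comp <- delong_components(sc$pos, sc$neg)
    expect_equal(mean(comp$v10), comp$auc)
    expect_equal(mean(comp$v01), comp$auc)
    expect_equal(comp$auc, auc_mann_whitney(sc$pos, sc$neg))

    labels <- rep(c(TRUE, FALSE), c(length(sc$pos), length(sc$neg)))
    r <- proc_roc(c(sc$pos, sc$neg), labels)
    expect_equal(comp$auc, as.numeric(r$auc))
    expect_equal(comp$var_auc, as.numeric(pROC::var(r, method = "delong")),
                 tolerance = 1e-10)
  }

  # perfectly separated groups: all placements 1, zero variance
  comp <- delong_components(c(5, 6, 7), c(1, 2))
  expect_equal(comp$v10, rep(1, 3))
  expect_equal(comp$var_auc, 0)
})

test_that("DeLong Wald interval matches pROC and truncates to [0, 1]", {
  set.seed(33)
  sc <- make_scored(60, 60)
  comp <- delong_components(sc$pos, sc$neg)
  ci <- delong_ci(comp)
  labels <- rep(c(TRUE, FALSE), c(60, 60))
  pci <- as.numeric(pROC::ci.auc(proc_roc(c(sc$pos, sc$neg), labels),
                                 method = "delong"))
  expect_equal(ci, pci[c(1, 3)], tolerance = 1e-10)

  expect_equal(delong_ci(delong_components(c(5, 6), c(1, 2))),
               c(1, 1))   # degenerate zero-variance case
  sc2 <- make_scored(10, 10, mu = 4)
  ci2 <- delong_ci(delong_components(sc2$pos, sc2$neg))
  expect_lte(ci2[2], 1)
  expect_gte(ci2[1], 0)
  expect_error(delong_ci(delong_components(3, c(1, 2))), ">= 2")
})

test_that("interval coverage is near nominal in a binormal simulation", {
  set.seed(34)
  true_auc <- pnorm(1 / sqrt(2))
  hits <- 0L
  reps <- 500
  for (i in seq_len(reps)) {
    sc <- make_scored(200, 200)
    ci <- delong_ci(delong_components(sc$pos, sc$neg))
    hits <- hits + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("paired DeLong test: identity, antisymmetry, pROC agreement", {
  set.seed(35)
  n <- 150
  latent <- c(rnorm(n, 1), rnorm(n))
  labels <- rep(c(TRUE, FALSE), each = n)
  a <- latent + rnorm(2 * n, 0, 0.5)
  b <- latent + rnorm(2 * n, 0, 0.8)

  self <- delong_paired_test(a, a, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)

  ab <- delong_paired_test(a, b, labels)
  ba <- delong_paired_test(b, a, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_two_sided, ba$p_two_sided)

  ra <- proc_roc(a, labels)
  rb <- proc_roc(b, labels)
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ab$z, as.numeric(pt$statistic), tolerance = 1e-10)
  expect_equal(ab$p_two_sided, pt$p.value, tolerance = 1e-10)
})

test_that("unpaired DeLong test uses zero covariance and matches pROC", {
  set.seed(36)
  sc_a <- make_scored(120, 150)
  sc_b <- make_scored(90, 200, mu = 0.4)
  ca <- delong_components(sc_a$pos, sc_a$neg)
  cb <- delong_components(sc_b$pos, sc_b$neg)
  cmp <- independent_auc_test(ca, cb)
  expect_equal(cmp$covariance, 0)

  la <- rep(c(TRUE, FALSE), c(120, 150))
  lb <- rep(c(TRUE, FALSE), c(90, 200))
  # pROC agrees on the standardized statistic; its unpaired test then
  # refers it to a t distribution, whereas this package uses the normal
  # reference, so only the statistic is compared
  pt <- pROC::roc.test(proc_roc(c(sc_a$pos, sc_a$neg), la),
                       proc_roc(c(sc_b$pos, sc_b$neg), lb),
                       method = "delong", paired = FALSE)
  expect_equal(cmp$z, as.numeric(pt$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_two_sided, 2 * pnorm(-abs(cmp$z)))

  expect_equal(independent_auc_test(ca, ca)$z, 0)
})

test_that("power of the unpaired test grows with the true AUC gap", {
  set.seed(37)
  rej <- vapply(c(0, 0.35, 0.7), function(gap) {
    mean(vapply(1:150, function(i) {
      sc_a <- make_scored(80, 80, mu = 0.5)
      sc_b <- make_scored(80, 80, mu = 0.5 + gap)
      cmp <- independent_auc_test(delong_components(sc_a$pos, sc_a$neg),
                                  delong_components(sc_b$pos, sc_b$neg))
      cmp$p_two_sided < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rej) > 0))
  expect_lt(rej[1], 0.15)
})

test_that("Youden cutoff maximizes J with the smallest-cutoff tie-break", {
  # perfect separation: several cutoffs reach J = 1; smallest wins
  expect_equal(youden_cutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 5)

  set.seed(38)
  for (i in 1:60) {
    sc <- make_scored(sample(3:60, 1), sample(3:60, 1),
                      tie_grid = sample(c(NA, 0, 1), 1))
    scores <- c(sc$pos, sc$neg)
    labels <- rep(c(TRUE, FALSE), c(length(sc$pos), length(sc$neg)))
    cut <- youden_cutoff(scores, labels)
    bf <- brute_youden(scores, labels)
    j_at <- mean(scores[labels] >= cut) + mean(scores[!labels] < cut) - 1
    expect_equal(j_at, bf$j_max)
    expect_equal(cut, bf$cutoff)

    # J is rank-based: a strictly monotone transform moves the cutoff
    # to the transformed value
    expect_equal(youden_cutoff(exp(scores), labels), exp(cut))
  }
})

test_that("operating characteristics reproduce the hand 2x2 table", {
  op <- operating_characteristics(c(3, 1, 2, 0),
                                  c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(c(op$tp, op$fn, op$tn, op$fp), c(1, 1, 1, 1))
  expect_equal(op$sensitivity$estimate, 0.5)
  expect_equal(op$specificity$estimate, 0.5)
  expect_equal(op$lr_pos$estimate, 1)
  expect_equal(op$ppv$estimate, 0.5)
  expect_equal(op$npv$estimate, 0.5)

  # Clopper-Pearson agrees with binom.test
  bt <- binom.test(1, 2)$conf.int
  expect_equal(op$sensitivity$ci, as.numeric(bt))

  # perfect classifier
  opp <- operating_characteristics(c(5, 6, 1, 2),
                                   c(TRUE, TRUE, FALSE, FALSE), 4)
  expect_equal(opp$sensitivity$estimate, 1)
  expect_equal(opp$specificity$estimate, 1)
  expect_equal(opp$ppv$estimate, 1)
  expect_equal(opp$npv$estimate, 1)
  expect_message(
    operating_characteristics(c(5, 6, 1, 2),
                              c(TRUE, TRUE, FALSE, FALSE), 4),
    "LR\\+ undefined")
  expect_equal(suppressMessages(
    operating_characteristics(c(5, 6, 1, 2),
                              c(TRUE, TRUE, FALSE, FALSE), 4))$lr_pos$estimate,
    Inf)
})

test_that("operating sensitivity agrees with the ROC curve at the cutoff", {
  set.seed(39)
  sc <- make_scored(40, 60, tie_grid = 1)
  scores <- c(sc$pos, sc$neg)
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  roc <- roc_curve(scores, labels)
  cut <- youden_cutoff(scores, labels)
  op <- operating_characteristics(scores, labels, cut)
  i <- match(cut, roc$thresholds)
  expect_equal(op$sensitivity$estimate, roc$sensitivities[i])
  expect_equal(op$specificity$estimate, roc$specificities[i])
  # monotone ROC: sensitivity non-increasing in the threshold
  expect_true(all(diff(roc$sensitivities) <= 1e-12))
  expect_true(all(diff(roc$specificities) >= -1e-12))
  expect_gte(roc$auc_ci[1], 0)
  expect_lte(roc$auc_ci[2], 1)
  expect_lte(roc$auc_ci[1], roc$auc)
  expect_gte(roc$auc_ci[2], roc$auc)
})
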