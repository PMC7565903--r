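test_that("confusion metrics reproduce hand counts and edge cases", {
  toy <- toy_cohort()
  d <- confusion_at_cutoff(toy$labels, toy$mp, 25)
  expect_equal(d$sensitivity, 0.5)
  expect_equal(d$specificity, 0.5)
  expect_equal(d$ppv, 0.5)
  expect_equal(d$npv, 0.5)
  expect_equal(d$n_under$count, d$tn + d$fn)

  # cutoff below all scores: everything operated, perfect sensitivity
  low <- confusion_at_cutoff(toy$labels, toy$mp, 5)
  expect_equal(low$sensitivity, 1)
  expect_true(is.na(low$npv))  # nobody under the cutoff: NPV undefined, not 0

  # perfectly separated classes with the cutoff between them
  sep <- confusion_at_cutoff(c(FALSE, FALSE, TRUE, TRUE),
                             c(0.1, 0.2, 0.8, 0.9), 50)
  expect_equal(unlist(sep[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  # degenerate one-class cohort is flagged, undefined metric reported NA
  deg <- confusion_at_cutoff(c(FALSE, FALSE), c(0.1, 0.2), 50)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$sensitivity))
})

test_that("class totals are conserved at every cutoff", {
  ch <- random_scored_cohort(150, seed = 5)
  for (ct in seq(5, 95, by = 10)) {
    d <- confusion_at_cutoff(ch$labels, ch$mp, ct)
    expect_equal(d$tp + d$fn, sum(ch$labels))
    expect_equal(d$tn + d$fp, sum(!ch$labels))
  }
})

test_that("roc_auc equals the all-pairs Mann-Whitney count", {
  # perfect separation
  # perfect separation (pROC warns that the degenerate CI is 1-1)
  expect_equal(suppressWarnings(roc_auc(c(TRUE, TRUE, FALSE),
                                        c(0.9, 0.8, 0.1))$auc), 1)
  for (seed in 1:30) {
    set.seed(3000 + seed)
    n <- sample(20:200, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.3)
    scores <- round(rnorm(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(labels, scores)$auc, auc_oracle(labels, scores))
  }
  expect_error(roc_auc(c(TRUE, TRUE), c(0.1, 0.2)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  labels <- runif(300) < 0.25
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(300)
  base <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, plogis(scores))$auc, base)
  expect_equal(roc_auc(labels, exp(scores / 3))$auc, base)
})

test_that("AUC of uninformative scores is near one half", {
  set.seed(17)
  n <- 4000
  labels <- runif(n) < 0.3
  scores <- runif(n)  # independent of the labels
  a <- roc_auc(labels, scores)
  n1 <- sum(labels); n0 <- n - n1
  # null SD of the Mann-Whitney AUC
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a$auc - 0.5), 3 * se)
  expect_true(a$ci[1] < 0.5 && a$ci[2] > 0.5)
})

test_that("calibration bins partition the cohort and order by risk", {
  set.seed(4)
  probs <- runif(400, 0.02, 0.8)
  labels <- runif(400) < probs
  bt <- calibration_bins(labels, probs, 10)
  expect_equal(sum(bt$n), 400)
  expect_equal(sum(bt$observed), sum(labels))        # conservation of events
  expect_equal(sum(bt$expected), sum(probs))
  expect_true(all(diff(bt$mean_pred) >= 0))          # quantile ordering

  # equal probabilities still bin: equal-frequency fallback
  expect_message(bt2 <- calibration_bins(rep(FALSE, 10), rep(0.3, 10), 5),
                 "rank bins")
  expect_equal(bt2$n, rep(2L, 5))
})

test_that("Hosmer-Lemeshow is exact on a perfectly calibrated constant-rate cohort", {
  # alternating events at the constant predicted rate: O = E in every bin
  labels <- rep(c(TRUE, FALSE), 25)
  probs <- rep(0.5, 50)
  res <- suppressMessages(hosmer_lemeshow(labels, probs, n_bins = 5))
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("Hosmer-Lemeshow detects a systematic logit shift", {
  set.seed(12)
  n <- 20000
  p_true <- plogis(rnorm(n, -1.2, 0.8))
  y <- runif(n) < p_true
  shifted <- plogis(qlogis(p_true) + 1)
  res <- hosmer_lemeshow(y, shifted, n_bins = 10)
  expect_lt(res$p_value, 0.001)
  # and the well-specified probabilities are not rejected on this draw
  expect_gt(hosmer_lemeshow(y, p_true, n_bins = 10)$chi2, 0)
})
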