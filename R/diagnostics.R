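# Discrimination and calibration ---------------------------------------------

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix diagnostics at a cutoff
#'
#' Sensitivity, specificity, PPV and NPV of the ">= cutoff implies operate"
#' rule, plus the count and fraction of the cohort under the cutoff (the
#' surgery-reduction the cutoff would achieve, `TN + FN`). A metric whose
#' denominator is empty (e.g. PPV when nobody is operated) is reported as
#' `NA`, never silently as zero; degenerate one-class cohorts are flagged.
#'
#' @param labels logical malignancy labels.
#' @param mp malignancy probabilities in `[0, 1]`.
#' @param cutoff cutoff in percent, in `(0, 100)`.
#' @return an object of class `diagnostic_summary`: a list with `cutoff`,
#'   counts `tp`, `fp`, `tn`, `fn`, `n_under` (list: `count`, `fraction`),
#'   the four proportions and a `degenerate` flag.
#' @examples
#' confusion_at_cutoff(c(FALSE, FALSE, TRUE, TRUE),
#'                     c(0.10, 0.30, 0.20, 0.40), 25)
#' @export
confusion_at_cutoff <- function(labels, mp, cutoff) {
  errs <- count_errors(labels, mp, cutoff)
  labels <- as.logical(labels)
  n <- length(labels)
  n_pos <- sum(labels)
  n_neg <- n - n_pos
  fp <- errs[["fp"]]
  fn <- errs[["fn"]]
  tp <- n_pos - fn
  tn <- n_neg - fp
  out <- list(
    cutoff = cutoff,
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_under = list(count = tn + fn, fraction = (tn + fn) / n),
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn),
    degenerate = n_pos == 0 || n_neg == 0
  )
  structure(out, class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("Cutoff %g%%: under cutoff %d (%.1f%%)\n",
              x$cutoff, x$n_under$count, 100 * x$n_under$fraction))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC %.4f (95%% CI %.4f-%.4f)\n", x$auc,
                x$auc_ci[1], x$auc_ci[2]))
  }
  if (x$degenerate) cat("  [degenerate cohort: a class is absent]\n")
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney probability that a malignant patient scores above
#' a benign one (ties counted half), with the DeLong variance estimate for
#' the confidence interval. The score orientation is fixed — higher score
#' means malignant — so an inverted marker genuinely reports AUC below 0.5.
#'
#' @param labels logical malignancy labels; both classes must be present.
#' @param scores numeric scores (any monotone transform of a probability).
#' @param conf_level confidence level for the DeLong interval.
#' @return list with `auc`, `ci` (length-2 vector), `n_pos`, `n_neg`.
#' @examples
#' set.seed(1)
#' labels <- rep(c(TRUE, FALSE), each = 50)
#' scores <- rnorm(100, mean = ifelse(labels, 1, 0))
#' roc_auc(labels, scores)
#' @export
roc_auc <- function(labels, scores, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stop("missing labels or scores", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("labels and scores must have the same length", call. = FALSE)
  }
  if (all(labels) || !any(labels)) {
    stop("both classes must be present to compute an ROC curve", call. = FALSE)
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(roc, conf.level = conf_level, method = "delong")
  list(auc = as.numeric(pROC::auc(roc)),
       ci = c(ci[1], ci[3]),
       n_pos = sum(labels), n_neg = sum(!labels))
}

#' Full diagnostic summary at a cutoff, including AUC
#'
#' [confusion_at_cutoff()] augmented with the cohort ROC AUC and its DeLong
#' interval (the AUC is a property of the continuous score, not of the
#' cutoff; it is attached for worksheet-style reporting).
#'
#' @inheritParams confusion_at_cutoff
#' @return a `diagnostic_summary` with `auc` and `auc_ci` fields.
#' @export
diagnose_at_cutoff <- function(labels, mp, cutoff) {
  out <- confusion_at_cutoff(labels, mp, cutoff)
  a <- roc_auc(labels, mp)
  out$auc <- a$auc
  out$auc_ci <- a$ci
  out
}

# Quantile binning shared by the Hosmer-Lemeshow test and the calibration
# plot. Ties-kept: duplicate quantile breaks merge bins. When ties are so
# heavy that fewer than 3 usable bins remain, fall back to equal-frequency
# rank bins (stable order) so near-constant predictors still bin.
quantile_bins <- function(probs, n_bins) {
  breaks <- unique(stats::quantile(probs, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) - 1 >= 3) {
    cut(probs, breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    message("quantile breaks collapsed under ties; using equal-frequency rank bins")
    as.integer(cut(rank(probs, ties.method = "first"),
                   breaks = n_bins, labels = FALSE))
  }
}

#' Observed-versus-expected calibration bins
#'
#' Partitions the cohort into quantile bins of predicted probability and
#' tabulates per bin the size, observed event count, expected event count
#' (sum of predicted probabilities) and the mean predicted/observed rates —
#' the table behind a calibration plot.
#'
#' @param labels logical event labels.
#' @param probs predicted probabilities in `[0, 1]`.
#' @param n_bins requested number of bins (>= 3); 10 and 5 correspond to the
#'   10 % and 20 % quantile scales.
#' @return data.frame with one row per (possibly merged) bin: `bin`, `n`,
#'   `observed`, `expected`, `mean_pred`, `mean_obs`.
#' @export
calibration_bins <- function(labels, probs, n_bins = 10) {
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(probs)) stop("missing labels or probs", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]", call. = FALSE)
  if (n_bins < 3) stop("n_bins must be >= 3", call. = FALSE)
  if (length(labels) < n_bins) {
    stop("cohort smaller than the number of bins", call. = FALSE)
  }
  bin <- quantile_bins(probs, n_bins)
  idx <- sort(unique(bin))
  data.frame(
    bin = seq_along(idx),
    n = vapply(idx, function(b) sum(bin == b), integer(1)),
    observed = vapply(idx, function(b) sum(labels[bin == b]), integer(1)),
    expected = vapply(idx, function(b) sum(probs[bin == b]), numeric(1)),
    mean_pred = vapply(idx, function(b) mean(probs[bin == b]), numeric(1)),
    mean_obs = vapply(idx, function(b) mean(labels[bin == b]), numeric(1))
  )
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square comparison of observed and expected event counts across
#' quantile bins of predicted probability:
#' `chi2 = sum (O - E)^2 / (E (1 - E/n))` over bins, referred to a chi-square
#' distribution with `n_bins - 2` degrees of freedom (the classical reference
#' for probabilities fitted on the same data). Bins whose expected variance is
#' zero (mean probability exactly 0 or 1) are merged with their neighbour and
#' the merge is reported via `message()`.
#'
#' @inheritParams calibration_bins
#' @return an object of class `calibration_result`: list with `n_bins`
#'   (requested), `bins_used`, `chi2`, `df`, `p_value`, `bin_table`.
#' @examples
#' set.seed(1)
#' p <- runif(500, 0.05, 0.6)
#' y <- runif(500) < p
#' hosmer_lemeshow(y, p, n_bins = 10)
#' @export
hosmer_lemeshow <- function(labels, probs, n_bins = 10) {
  bt <- calibration_bins(labels, probs, n_bins)
  # merge zero-variance bins (expected 0 or n) into the adjacent bin
  repeat {
    var0 <- with(bt, expected <= 0 | expected >= n)
    if (!any(var0) || nrow(bt) <= 1) break
    i <- which(var0)[1]
    j <- if (i == nrow(bt)) i - 1L else i + 1L
    message("merging zero-variance calibration bin ", bt$bin[i],
            " with neighbour")
    bt$n[j] <- bt$n[j] + bt$n[i]
    bt$observed[j] <- bt$observed[j] + bt$observed[i]
    bt$expected[j] <- bt$expected[j] + bt$expected[i]
    bt <- bt[-i, , drop = FALSE]
    bt$mean_pred <- bt$expected / bt$n
    bt$mean_obs <- bt$observed / bt$n
    bt$bin <- seq_len(nrow(bt))
  }
  chi2 <- with(bt, sum((observed - expected)^2 / (expected * (1 - expected / n))))
  df <- nrow(bt) - 2L
  if (df < 1) stop("too few usable bins for the Hosmer-Lemeshow test", call. = FALSE)
  structure(
    list(n_bins = n_bins, bins_used = nrow(bt), chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         bin_table = bt),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.4g (%d bins)\n",
              x$chi2, x$df, x$p_value, x$bins_used))
  invisible(x)
}
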