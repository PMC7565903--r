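# Direct per-patient probability-versus-risk rule ----------------------------

#' Direct surgical decision: malignancy probability versus surgical risk
#'
#' Operate exactly when the patient's malignancy probability strictly exceeds
#' their predicted surgical risk (`mp > sc`). At a tie the rule stays
#' conservative toward surveillance: no surgery.
#'
#' @param mp malignancy probabilities in `[0, 1]`.
#' @param sc surgical-risk probabilities in `[0, 1]`.
#' @return logical vector, `TRUE` where surgery is indicated.
#' @examples
#' direct_decision(c(0.30, 0.05), c(0.122, 0.084))
#' @export
direct_decision <- function(mp, sc) {
  if (length(mp) != length(sc)) {
    stop("mp and sc must have the same length", call. = FALSE)
  }
  if (anyNA(mp) || anyNA(sc)) stop("missing mp or sc score", call. = FALSE)
  if (any(mp < 0 | mp > 1) || any(sc < 0 | sc > 1)) {
    stop("mp and sc must lie in [0, 1]", call. = FALSE)
  }
  mp > sc
}

#' Cohort summary of the direct decision rule
#'
#' Applies [direct_decision()] and summarises it against the malignancy
#' labels: the number and fraction operated, the surgery reduction (fraction
#' spared, the complement), confusion metrics treating `mp > sc` as the
#' positive call, and two AUC readings for the rule. A binary rule has a
#' single ROC point, so its trapezoid AUC is `(sensitivity + specificity)/2`
#' (`auc_point`); the AUC of the continuous difference score `mp - sc`
#' (`auc_diff`, with DeLong CI) is reported alongside as the rule's natural
#' continuous relaxation. Both are emitted; neither is a property of the
#' other.
#'
#' @param labels logical malignancy labels.
#' @param mp,sc probability vectors aligned with `labels`.
#' @return an object of class `direct_decision_summary`: list with
#'   `n_operate` (list `count`, `fraction`), `surgery_reduction`,
#'   `diagnostics` (sensitivity/specificity/ppv/npv and counts),
#'   `auc_point`, `auc_diff`, `auc_diff_ci`.
#' @examples
#' summarize_direct(c(TRUE, TRUE, FALSE, FALSE),
#'                  mp = c(0.4, 0.1, 0.5, 0.05),
#'                  sc = c(0.12, 0.12, 0.084, 0.084))
#' @export
summarize_direct <- function(labels, mp, sc) {
  labels <- as.logical(labels)
  if (length(labels) != length(mp)) {
    stop("labels and scores must have the same length", call. = FALSE)
  }
  operate <- direct_decision(mp, sc)
  n <- length(labels)
  tp <- sum(labels & operate)
  fp <- sum(!labels & operate)
  tn <- sum(!labels & !operate)
  fn <- sum(labels & !operate)
  diag <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn)
  )
  auc_point <- if (is.na(diag$sensitivity) || is.na(diag$specificity)) {
    NA_real_
  } else {
    (diag$sensitivity + diag$specificity) / 2
  }
  auc_diff <- auc_diff_ci <- NA_real_
  if (any(labels) && !all(labels)) {
    a <- roc_auc(labels, mp - sc)
    auc_diff <- a$auc
    auc_diff_ci <- a$ci
  }
  structure(
    list(n_operate = list(count = sum(operate), fraction = mean(operate)),
         surgery_reduction = mean(!operate),
         diagnostics = diag,
         auc_point = auc_point,
         auc_diff = auc_diff,
         auc_diff_ci = auc_diff_ci,
         operate = operate),
    class = "direct_decision_summary"
  )
}

#' @export
print.direct_decision_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("Direct rule (mp > sc): operate %d (%.1f%%), surgery reduced %.1f%%\n",
              x$n_operate$count, 100 * x$n_operate$fraction,
              100 * x$surgery_reduction))
  d <- x$diagnostics
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(d$sensitivity), fmt(d$specificity), fmt(d$ppv), fmt(d$npv)))
  cat(sprintf("  AUC (binary point) %s  AUC (mp - sc) %s\n",
              fmt(x$auc_point), fmt(x$auc_diff)))
  invisible(x)
}
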