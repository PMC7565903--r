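# Balance worksheet: FN versus complication-weighted FP ----------------------
#
# The decision rule at the heart of the package: over a grid of malignancy-
# probability cutoffs, count malignant patients the cutoff would leave
# unoperated (false negatives) and benign patients it would send to surgery
# (false positives), weight the false positives by the group's complication
# rate, and pick the cutoff where the two error burdens balance:
#
#   FN = FP x complication rate
#
# On integer counts the equality is almost never exact, so selection minimises
# |FN - FP x rate|, with ties broken toward the lower cutoff (favouring
# sensitivity).

#' Count decision errors at a malignancy-probability cutoff
#'
#' Positive decision convention: a patient with `mp * 100 >= cutoff` is
#' operated. A false positive is a benign patient at or above the cutoff; a
#' false negative is a malignant patient below it.
#'
#' @param labels logical vector, `TRUE` for malignant pathology.
#' @param mp malignancy probabilities in `[0, 1]`.
#' @param cutoff cutoff in percent, in `(0, 100)`.
#' @return named integer vector `c(fp = ..., fn = ...)`.
#' @examples
#' count_errors(c(FALSE, FALSE, TRUE, TRUE), c(0.10, 0.30, 0.20, 0.40), 25)
#' @export
count_errors <- function(labels, mp, cutoff) {
  if (length(labels) == 0) stop("empty cohort", call. = FALSE)
  if (length(labels) != length(mp)) {
    stop("labels and mp must have the same length", call. = FALSE)
  }
  if (anyNA(labels) || anyNA(mp)) stop("missing labels or scores", call. = FALSE)
  if (any(mp < 0 | mp > 1)) stop("mp must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 100) {
    stop("cutoff must be a single percent in (0, 100)", call. = FALSE)
  }
  labels <- as.logical(labels)
  # decimal-exact boundary: 0.29 * 100 is 28.999... in binary floating point
  # and must still meet a cutoff of 29 under the >= convention
  operate <- round(mp * 100, 9) >= cutoff
  c(fp = sum(!labels & operate), fn = sum(labels & !operate))
}

#' Complication-weighted false-positive burden
#'
#' The right-hand side of the balance equation: the expected number of benign
#' patients harmed by unnecessary surgery, `FP x rate`. Reported on the same
#' percent-rate convention the balance worksheets print (e.g. 274 benign
#' patients at a 2.4 % rate give 6.576).
#'
#' @param fp non-negative false-positive count.
#' @param rate complication probability in `[0, 1]`.
#' @return `fp * rate`.
#' @examples
#' balance_product(274, 0.024)
#' @export
balance_product <- function(fp, rate) {
  if (any(fp < 0)) stop("fp must be non-negative", call. = FALSE)
  if (any(rate < 0 | rate > 1)) stop("rate must lie in [0, 1]", call. = FALSE)
  fp * rate
}

#' Construct a balance table from pre-tabulated rows
#'
#' Builds the worksheet object directly from `(cutoff, fp, fn)` rows — e.g.
#' rows transcribed from a published worksheet — recomputing the weighted
#' false-positive column for every severity threshold in `rate_set`.
#'
#' @param cutoff strictly increasing cutoffs in percent.
#' @param fp,fn non-negative integer error counts per cutoff.
#' @param rate_set a [complication_rates()] object.
#' @return an object of class `balance_table`: a data.frame with columns
#'   `cutoff`, `fp`, `fn` and one `w_<severity>` column per threshold, plus
#'   `group` and `rate_set` attributes.
#' @export
balance_table <- function(cutoff, fp, fn, rate_set) {
  if (!inherits(rate_set, "complication_rates")) {
    stop("rate_set must be a complication_rates object", call. = FALSE)
  }
  if (length(cutoff) == 0) stop("cutoff grid must be non-empty", call. = FALSE)
  if (any(diff(cutoff) <= 0)) {
    stop("cutoff grid must be strictly increasing", call. = FALSE)
  }
  if (any(fp < 0) || any(fn < 0) || any(fp != round(fp)) || any(fn != round(fn))) {
    stop("fp and fn must be non-negative integers", call. = FALSE)
  }
  tab <- data.frame(cutoff = cutoff, fp = as.integer(fp), fn = as.integer(fn))
  for (s in severity_levels()) {
    tab[[paste0("w_", s)]] <- balance_product(tab$fp, rate_set$rate_ge[[s]])
  }
  structure(tab, group = rate_set$group, rate_set = rate_set,
            class = c("balance_table", "data.frame"))
}

#' Build the balance worksheet over a cutoff grid
#'
#' One row per grid cutoff with the false-positive and false-negative counts
#' of [count_errors()] and the weighted false-positive burden per severity
#' threshold. Across the grid `fp` is weakly decreasing and `fn` weakly
#' increasing.
#'
#' @param labels logical malignancy labels.
#' @param mp malignancy probabilities in `[0, 1]`.
#' @param cutoff_grid non-empty strictly increasing cutoffs in percent;
#'   defaults to integer percents 1-99.
#' @param rate_set a [complication_rates()] object.
#' @return a `balance_table`.
#' @examples
#' set.seed(1)
#' mp <- runif(40)
#' labels <- runif(40) < mp
#' build_balance_table(labels, mp, rate_set = default_rate_set("PD"))
#' @export
build_balance_table <- function(labels, mp, cutoff_grid = 1:99, rate_set) {
  counts <- vapply(cutoff_grid, function(ct) count_errors(labels, mp, ct),
                   integer(2))
  balance_table(cutoff_grid, counts["fp", ], counts["fn", ], rate_set)
}

#' Select the balance cutoff for a severity threshold
#'
#' Returns the grid cutoff minimising `|fn - fp * rate|` for the requested
#' complication-severity threshold; ties break toward the lower cutoff
#' (favouring sensitivity). When the minimiser sits at the first or last grid
#' point there is no interior crossing and the result carries
#' `boundary = TRUE`.
#'
#' @param table a `balance_table`.
#' @param severity one of `"II"`, `"IIIa"`, `"IIIb"`, `"IV"`.
#' @return the selected cutoff (percent) with attributes `severity`,
#'   `boundary` (logical) and `gap` (the minimised `|fn - fp * rate|`).
#' @examples
#' tab <- reference_balance_table("PD")
#' select_cutoff(tab, "IIIa")
#' @export
select_cutoff <- function(table, severity) {
  if (!inherits(table, "balance_table")) {
    stop("table must be a balance_table", call. = FALSE)
  }
  if (nrow(table) == 0) stop("balance table is empty", call. = FALSE)
  severity <- match.arg(severity, severity_levels())
  rate <- attr(table, "rate_set")$rate_ge[[severity]]
  gap <- abs(table$fn - balance_product(table$fp, rate))
  i <- which.min(gap)  # which.min takes the first minimum: the lower cutoff
  structure(table$cutoff[i],
            severity = severity,
            boundary = i == 1L || i == nrow(table),
            gap = gap[i])
}

#' Balance cutoffs for every severity threshold
#'
#' @param table a `balance_table`.
#' @return named numeric vector of selected cutoffs (percent), one per
#'   severity threshold, with a `boundary` attribute (named logical).
#' @export
select_cutoffs <- function(table) {
  sel <- lapply(severity_levels(), function(s) select_cutoff(table, s))
  out <- stats::setNames(vapply(sel, as.numeric, numeric(1)), severity_levels())
  attr(out, "boundary") <- stats::setNames(
    vapply(sel, function(x) attr(x, "boundary"), logical(1)), severity_levels())
  out
}

#' Reference balance worksheets
#'
#' The `(cutoff, FP, FN)` worksheet rows of a published reference
#' pancreatectomy cohort (464 pancreaticoduodenectomy and 293 distal
#' pancreatectomy patients), bundled as plain-text data. Combined with
#' [default_rate_set()] they reproduce the reference weighted columns and
#' selected cutoffs exactly, and serve as a fixed testbed for the selection
#' rule.
#'
#' @param group `"PD"` or `"DP"`.
#' @return a `balance_table` built from the bundled rows.
#' @examples
#' select_cutoffs(reference_balance_table("DP"))
#' @export
reference_balance_table <- function(group = c("PD", "DP")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      paste0(tolower(group), "_reference_worksheet.tsv"),
                      package = "ipmnbalance", mustWork = TRUE)
  rows <- utils::read.delim(path)
  balance_table(rows$cutoff, rows$fp, rows$fn, default_rate_set(group))
}

#' @export
print.balance_table <- function(x, ...) {
  cat("Balance worksheet (", attr(x, "group"), " group, ", nrow(x),
      " cutoffs)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  sel <- select_cutoffs(x)
  cat("Selected cutoffs (%):",
      paste(sprintf(">=%s: %g", names(sel), sel), collapse = "  "), "\n")
  invisible(x)
}

#' Write a balance table as TSV
#'
#' Mirrors the worksheet layout: cutoff, FP, FN, then one weighted column per
#' severity threshold (three decimal places), with the selected row per
#' severity listed in a trailing comment line.
#'
#' @param table a `balance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_balance_table <- function(table, path) {
  out <- data.frame(cutoff = table$cutoff, fp = table$fp, fn = table$fn)
  for (s in severity_levels()) {
    out[[paste0("w_", s)]] <- sprintf("%.3f", table[[paste0("w_", s)]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# group\t", attr(table, "group")), con)
  sel <- select_cutoffs(table)
  writeLines(paste0("# selected\t",
                    paste(sprintf("%s=%g", names(sel), sel), collapse = "\t")),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a balance table written by [write_balance_table()]
#'
#' @param path TSV path.
#' @param rate_set the [complication_rates()] the table was built with.
#' @return a `balance_table`.
#' @export
read_balance_table <- function(path, rate_set) {
  rows <- utils::read.delim(path, comment.char = "#")
  balance_table(rows$cutoff, rows$fp, rows$fn, rate_set)
}
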