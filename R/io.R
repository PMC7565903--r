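# Cohort CSV input/output -----------------------------------------------------
#
# Fixed header: id,age,sex,mpd_mm,cyst_mm,mural_nodule,ca19_9,cea,surgery,
# pathology,clavien. Optional trailing columns mp, sc, latent_p are carried
# through when present. Booleans are stored as 0/1; grades as their literal
# strings; numerics at full double precision so a write/read round trip is
# value-exact.

cohort_columns <- function() {
  c("id", "age", "sex", "mpd_mm", "cyst_mm", "mural_nodule",
    "ca19_9", "cea", "surgery", "pathology", "clavien")
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  sub("^(-?\\d+)\\.0*$", "\\1", out)
}

#' Write a cohort table as CSV
#'
#' @param cohort cohort data.frame (as produced by [generate_cohort()] or
#'   [score_cohort()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c(cohort_columns(), "mp", "sc", "latent_p"), names(cohort))
  out <- cohort[, cols, drop = FALSE]
  out$mural_nodule <- as.integer(out$mural_nodule)
  for (cc in intersect(c("age", "mpd_mm", "cyst_mm", "ca19_9", "cea",
                         "mp", "sc", "latent_p"), names(out))) {
    out[[cc]] <- fmt_num(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

row_fail <- function(row, msg) {
  stop("cohort row ", row, ": ", msg, call. = FALSE)
}

#' Read and validate a cohort CSV
#'
#' Parses a cohort table with the documented fixed header and validates every
#' row: numeric fields must parse and be in range, `sex`, `surgery`,
#' `pathology` and `clavien` must be known category strings, and
#' `mpd_mm` must not exceed 10 mm — main-duct dilatation beyond 10 mm is an
#' eligibility exclusion for the branch/mixed-type analysis, so such rows are
#' a hard error, not a warning. Validation failures name the offending row.
#'
#' @param path CSV path.
#' @return a cohort `data.frame` (class `ipmn_cohort`) with a `malignant`
#'   column derived from pathology; optional `mp`, `sc`, `latent_p` columns
#'   are carried through.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("cohort file has a header but no rows", call. = FALSE)
  }
  num_col <- function(name, lower = 0, upper = Inf, allow_zero = TRUE) {
    v <- suppressWarnings(as.numeric(raw[[name]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) row_fail(bad[1], paste0("malformed numeric in ", name))
    oob <- which(v < lower | v > upper | (!allow_zero & v == lower))
    if (length(oob) > 0) {
      row_fail(oob[1], paste0(name, " value ", raw[[name]][oob[1]],
                              " outside [", lower, ", ", upper, "]"))
    }
    v
  }
  cat_col <- function(name, levels) {
    v <- raw[[name]]
    bad <- which(!v %in% levels)
    if (length(bad) > 0) {
      row_fail(bad[1], paste0("unknown ", name, " value '", v[bad[1]], "'"))
    }
    v
  }
  mpd <- num_col("mpd_mm", lower = 0, upper = Inf, allow_zero = FALSE)
  over <- which(mpd > 10)
  if (length(over) > 0) {
    row_fail(over[1], paste0(
      "mpd_mm ", raw$mpd_mm[over[1]],
      " exceeds 10 mm: main-duct dilatation > 10 mm is excluded from the ",
      "branch/mixed-type analysis"))
  }
  nodule_raw <- raw$mural_nodule
  bad_nod <- which(!nodule_raw %in% c("0", "1"))
  if (length(bad_nod) > 0) {
    row_fail(bad_nod[1], "mural_nodule must be 0 or 1")
  }
  cohort <- data.frame(
    id = raw$id,
    age = num_col("age", lower = 0),
    sex = cat_col("sex", c("male", "female")),
    mpd_mm = mpd,
    cyst_mm = num_col("cyst_mm", lower = 0, allow_zero = FALSE),
    mural_nodule = nodule_raw == "1",
    ca19_9 = num_col("ca19_9", lower = 0),
    cea = num_col("cea", lower = 0),
    surgery = cat_col("surgery", c("PD", "DP", "other")),
    pathology = cat_col("pathology", pathology_levels()),
    clavien = cat_col("clavien", clavien_levels()),
    stringsAsFactors = FALSE
  )
  cohort$malignant <- is_malignant(cohort$pathology)
  for (extra in c("mp", "sc", "latent_p")) {
    if (extra %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[extra]]))
      bad <- which(is.na(v))
      if (length(bad) > 0) row_fail(bad[1], paste0("malformed numeric in ", extra))
      if (extra != "latent_p" && any(v < 0 | v > 1)) {
        row_fail(which(v < 0 | v > 1)[1], paste0(extra, " outside [0, 1]"))
      }
      cohort[[extra]] <- v
    }
  }
  class(cohort) <- c("ipmn_cohort", "data.frame")
  cohort
}

# Pipeline configuration -------------------------------------------------------

#' Read a pipeline configuration from YAML or JSON
#'
#' Schema-validates the file and fills defaults. Recognised fields:
#' `cohort_csv` (optional path; when absent a synthetic cohort is generated),
#' `n_pd`, `n_dp`, `sc_noise_sd`, `seed`, `cutoff_grid` (defaults 1-99),
#' `out_dir`, `mp_spec` / `sc_specs` (paths to model-spec JSON files),
#' `rate_sets` (per-group named rate maps). Errors name the offending field.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("cohort_csv", "n_pd", "n_dp", "sc_noise_sd", "seed",
             "cutoff_grid", "out_dir", "mp_spec", "sc_specs", "rate_sets",
             "hl_bins")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- list(n_pd = 464, n_dp = 293, sc_noise_sd = 0.4, seed = 1L,
                   cutoff_grid = 1:99, hl_bins = c(10L, 5L))
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (is.null(cfg$out_dir)) {
    stop("configuration error: out_dir is required", call. = FALSE)
  }
  if (any(diff(cfg$cutoff_grid) <= 0)) {
    stop("configuration error: cutoff_grid must be strictly increasing",
         call. = FALSE)
  }
  cfg$mp_spec <- if (is.null(cfg$mp_spec)) default_mp_spec() else {
    read_model_spec(cfg$mp_spec)
  }
  cfg$sc_specs <- if (is.null(cfg$sc_specs)) default_sc_specs() else {
    lapply(cfg$sc_specs, read_model_spec)
  }
  cfg$rate_sets <- if (is.null(cfg$rate_sets)) {
    list(PD = default_rate_set("PD"), DP = default_rate_set("DP"))
  } else {
    stats::setNames(
      lapply(names(cfg$rate_sets),
             function(g) complication_rates(g, unlist(cfg$rate_sets[[g]]))),
      names(cfg$rate_sets))
  }
  structure(cfg, class = "pipeline_config")
}
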