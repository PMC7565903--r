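# Logistic risk scoring ------------------------------------------------------

#' Specification of a logistic scoring model
#'
#' Holds an intercept, named coefficients and the per-feature transform used
#' before the coefficient is applied. Transforms: `"identity"` uses the raw
#' value, `"log1p"` applies `log(1 + x)` (the default for skewed tumour
#' markers), `"indicator"` converts a logical or a coded binary feature to
#' 0/1 (for `sex`, male codes as 1).
#'
#' @param intercept real intercept on the logit scale.
#' @param coefficients named numeric vector; names must be `PatientRecord`
#'   features (`age`, `sex`, `mpd_mm`, `cyst_mm`, `mural_nodule`, `ca19_9`,
#'   `cea`).
#' @param transforms named character vector giving the transform per
#'   coefficient; defaults to `"identity"` for any coefficient not named.
#' @return an object of class `logistic_model_spec`.
#' @examples
#' spec <- logistic_model_spec(-2, c(mpd_mm = 0.3, mural_nodule = 1),
#'                             c(mural_nodule = "indicator"))
#' @export
logistic_model_spec <- function(intercept, coefficients = numeric(0),
                                transforms = character(0)) {
  allowed <- c("age", "sex", "mpd_mm", "cyst_mm", "mural_nodule",
               "ca19_9", "cea")
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    stop("intercept must be a single finite number", call. = FALSE)
  }
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    stop("coefficients must be named", call. = FALSE)
  }
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad) > 0) {
    stop("coefficient(s) on unknown feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tr <- stats::setNames(rep("identity", length(coefficients)), names(coefficients))
  if (length(transforms) > 0) {
    unknown <- setdiff(names(transforms), names(coefficients))
    if (length(unknown) > 0) {
      stop("transform(s) for feature(s) without a coefficient: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad_tr <- setdiff(transforms, c("identity", "log1p", "indicator"))
    if (length(bad_tr) > 0) {
      stop("unknown transform(s): ", paste(bad_tr, collapse = ", "), call. = FALSE)
    }
    tr[names(transforms)] <- transforms
  }
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 transforms = tr),
            class = "logistic_model_spec")
}

#' @export
print.logistic_model_spec <- function(x, ...) {
  cat("Logistic model spec: intercept", format(x$intercept), "\n")
  if (length(x$coefficients) > 0) {
    df <- data.frame(coef = x$coefficients, transform = x$transforms)
    print(df)
  }
  invisible(x)
}

transform_feature <- function(value, feature, transform) {
  switch(transform,
    identity = as.numeric(value),
    log1p = log1p(as.numeric(value)),
    indicator = {
      if (feature == "sex") as.numeric(value == "male") else as.numeric(value)
    },
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

#' Default malignancy-probability (MP) surrogate spec
#'
#' A documented stand-in for the published IPMN malignancy nomogram, whose
#' fitted coefficients are distributed as an online calculator rather than in
#' print. It carries positive weights on duct diameter, mural nodule and
#' `log1p(CA19-9)` — the factors with the strongest multivariable association
#' with malignancy in branch/mixed-type cohorts — plus smaller terms on age,
#' sex, cyst size and CEA. Surrogate only: calibrate against institutional
#' data before any clinical use.
#'
#' @return a [logistic_model_spec()] object.
#' @export
default_mp_spec <- function() {
  cf <- default_malignancy_coefs()
  logistic_model_spec(
    intercept = cf[["intercept"]],
    coefficients = c(age = cf[["age"]], sex = cf[["sex_male"]],
                     mpd_mm = cf[["mpd_mm"]], cyst_mm = cf[["cyst_mm"]],
                     mural_nodule = cf[["mural_nodule"]],
                     ca19_9 = cf[["ca19_9"]], cea = cf[["cea"]]),
    transforms = c(sex = "indicator", mural_nodule = "indicator",
                   ca19_9 = "log1p", cea = "log1p")
  )
}

#' Default surgical-risk (SC) surrogate specs per surgery group
#'
#' Baseline-only logistic specs standing in for the proprietary ACS NSQIP
#' serious-complication calculator: intercepts `logit(0.122)` for
#' pancreaticoduodenectomy and `logit(0.084)` for distal pancreatectomy, the
#' minimal serious-complication levels reported for pancreatic resections.
#' Patient-level dispersion comes from the logit-scale gaussian noise of
#' [sc_surrogate()]; covariate terms can be added through
#' [logistic_model_spec()].
#'
#' @return a named list of [logistic_model_spec()] objects (`PD`, `DP`).
#' @export
default_sc_specs <- function() {
  list(PD = logistic_model_spec(stats::qlogis(0.122)),
       DP = logistic_model_spec(stats::qlogis(0.084)))
}

#' Score patients with a logistic model
#'
#' Computes `plogis(intercept + sum coef * transform(feature))` per record.
#' Strictly increasing in any feature with a positive coefficient. Missing
#' feature values are a hard error: cohorts with incomplete data for scoring
#' are excluded rather than imputed.
#'
#' @param records data.frame of patient records.
#' @param spec a [logistic_model_spec()].
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pd = 5, n_dp = 5, seed = 1))
#' logistic_score(cohort, default_mp_spec())
#' @export
logistic_score <- function(records, spec) {
  if (!inherits(spec, "logistic_model_spec")) {
    stop("spec must be a logistic_model_spec", call. = FALSE)
  }
  eta <- rep(spec$intercept, nrow(records))
  for (feature in names(spec$coefficients)) {
    if (!feature %in% names(records)) {
      stop("missing feature column: ", feature, call. = FALSE)
    }
    value <- records[[feature]]
    if (anyNA(value)) {
      stop("missing data in feature '", feature,
           "': records with incomplete data cannot be scored (no imputation)",
           call. = FALSE)
    }
    eta <- eta + spec$coefficients[[feature]] *
      transform_feature(value, feature, spec$transforms[[feature]])
  }
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor; check feature values", call. = FALSE)
  }
  stats::plogis(eta)
}

#' Surgical-risk surrogate score
#'
#' Serious-complication probability per patient:
#' `plogis(group baseline logit + covariate terms + gaussian noise)`. With
#' `noise_sd = 0` the score is deterministic, and with baseline-only specs it
#' equals the group baseline for every patient of that group.
#'
#' @param records data.frame with a `surgery` column in `{"PD", "DP"}`.
#' @param specs named list of [logistic_model_spec()] per group; defaults to
#'   [default_sc_specs()].
#' @param noise_sd non-negative logit-scale noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return numeric vector of probabilities aligned with `records`.
#' @export
sc_surrogate <- function(records, specs = default_sc_specs(), noise_sd = 0,
                         seed = 1L) {
  if (!"surgery" %in% names(records)) {
    stop("records must carry a 'surgery' column", call. = FALSE)
  }
  unknown <- setdiff(unique(records$surgery), names(specs))
  if (length(unknown) > 0) {
    stop("unknown surgery group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  n <- nrow(records)
  eta <- numeric(n)
  for (g in unique(records$surgery)) {
    idx <- records$surgery == g
    eta[idx] <- stats::qlogis(
      logistic_score(records[idx, , drop = FALSE], specs[[g]])
    )
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    eta <- eta + stats::rnorm(n, 0, noise_sd)
  }
  stats::plogis(eta)
}

#' Attach MP and SC risk scores to a cohort
#'
#' Adds the malignancy-probability column `mp` (nomogram surrogate) and the
#' surgical-risk column `sc` (serious-complication surrogate) to a cohort
#' table. Probabilities are carried in `[0, 1]`; conversion to percent happens
#' only when tables are written.
#'
#' @param cohort data.frame of patient records.
#' @param mp_spec [logistic_model_spec()] for malignancy probability.
#' @param sc_specs named list of per-group specs for surgical risk.
#' @param sc_noise_sd logit-scale noise of the surgical-risk surrogate.
#' @param seed integer seed for the surgical-risk noise.
#' @return `cohort` with `mp` and `sc` columns appended.
#' @export
score_cohort <- function(cohort, mp_spec = default_mp_spec(),
                         sc_specs = default_sc_specs(),
                         sc_noise_sd = 0.4, seed = 1L) {
  cohort$mp <- logistic_score(cohort, mp_spec)
  cohort$sc <- sc_surrogate(cohort, sc_specs, noise_sd = sc_noise_sd,
                            seed = substream_seed(seed, "sc_noise"))
  cohort
}

# Model-spec JSON serialization ----------------------------------------------

#' Read and write logistic model specs as JSON
#'
#' @param spec a [logistic_model_spec()].
#' @param path file path.
#' @return `read_model_spec` returns a [logistic_model_spec()];
#'   `write_model_spec` returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(
    list(intercept = spec$intercept,
         coefficients = as.list(spec$coefficients),
         transforms = as.list(spec$transforms)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- unlist(x$coefficients)
  tr <- unlist(x$transforms)
  logistic_model_spec(x$intercept,
                      if (is.null(cf)) numeric(0) else cf,
                      if (is.null(tr)) character(0) else tr)
}
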