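# Shared constants -----------------------------------------------------------

#' @keywords internal
clavien_levels <- function() c("none", "I", "II", "IIIa", "IIIb", "IV", "V")

#' @keywords internal
pathology_levels <- function() c("LGD", "IGD", "HGD", "invasive")

#' @keywords internal
severity_levels <- function() c("II", "IIIa", "IIIb", "IV")

#' Clavien-Dindo grades defining malignancy-independent "major" severity bands
#'
#' Pathology grades HGD and invasive carcinoma define a malignant lesion; every
#' other grade is benign for the purposes of the balance analysis.
#'
#' @param pathology character vector of pathology grades
#'   (`"LGD"`, `"IGD"`, `"HGD"`, `"invasive"`).
#' @return logical vector, `TRUE` where the grade is malignant.
#' @examples
#' is_malignant(c("LGD", "HGD", "invasive", "IGD"))
#' @export
is_malignant <- function(pathology) {
  bad <- setdiff(unique(pathology), pathology_levels())
  if (length(bad) > 0) {
    stop("unknown pathology grade(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pathology %in% c("HGD", "invasive")
}

# Complication rate sets ------------------------------------------------------

#' Graded complication exceedance rates for a surgery group
#'
#' A `complication_rates` object stores, for one surgery group (PD or DP), the
#' probability that a patient's postoperative Clavien-Dindo grade reaches or
#' exceeds each severity threshold II, IIIa, IIIb and IV (grade V is pooled
#' into the ">=IV" band). Exceedance rates must be weakly decreasing in
#' severity, so differencing adjacent thresholds yields a proper ordinal
#' category distribution.
#'
#' @param group surgery group, `"PD"` (pancreaticoduodenectomy) or `"DP"`
#'   (distal pancreatectomy).
#' @param rate_ge named numeric vector with entries `II`, `IIIa`, `IIIb`, `IV`;
#'   each in `[0, 1]`, weakly decreasing.
#' @return an object of class `complication_rates`.
#' @examples
#' complication_rates("PD", c(II = 0.433, IIIa = 0.181, IIIb = 0.067, IV = 0.024))
#' @seealso [default_rate_set()] for the bundled reference rates.
#' @export
complication_rates <- function(group, rate_ge) {
  group <- match.arg(group, c("PD", "DP"))
  if (!is.numeric(rate_ge) || is.null(names(rate_ge))) {
    stop("rate_ge must be a named numeric vector", call. = FALSE)
  }
  missing_lv <- setdiff(severity_levels(), names(rate_ge))
  if (length(missing_lv) > 0) {
    stop("rate_ge is missing severity threshold(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  rate_ge <- rate_ge[severity_levels()]
  if (any(!is.finite(rate_ge)) || any(rate_ge < 0) || any(rate_ge > 1)) {
    stop("rate_ge entries must be finite probabilities in [0, 1]", call. = FALSE)
  }
  if (any(diff(rate_ge) > 0)) {
    stop("rate_ge must be weakly decreasing in severity ",
         "(II >= IIIa >= IIIb >= IV); offending field: rate_ge", call. = FALSE)
  }
  structure(list(group = group, rate_ge = rate_ge), class = "complication_rates")
}

#' Reference complication rate sets
#'
#' Marginal Clavien-Dindo exceedance rates observed in a published reference
#' pancreatectomy cohort (464 PD and 293 DP patients): PD 43.3 / 18.1 / 6.7 /
#' 2.4 % and DP 30.4 / 8.5 / 3.4 / 2.0 % for grades >=II / >=IIIa / >=IIIb /
#' >=IV. These drive the default synthetic cohort and the bundled reference
#' balance worksheets.
#'
#' @param group `"PD"` or `"DP"`.
#' @return a [complication_rates()] object.
#' @export
default_rate_set <- function(group = c("PD", "DP")) {
  group <- match.arg(group)
  rates <- switch(group,
    PD = c(II = 0.433, IIIa = 0.181, IIIb = 0.067, IV = 0.024),
    DP = c(II = 0.304, IIIa = 0.085, IIIb = 0.034, IV = 0.020)
  )
  complication_rates(group, rates)
}

#' @export
print.complication_rates <- function(x, ...) {
  cat("Complication exceedance rates (", x$group, "):\n", sep = "")
  print(round(x$rate_ge, 4))
  invisible(x)
}

# Cohort configuration --------------------------------------------------------

default_feature_params <- function() {
  list(
    age          = list(dist = "norm_trunc", mean = 62, sd = 10, lower = 18, upper = 95),
    sex_male     = list(dist = "bernoulli", prob = 0.55),
    mpd_mm       = list(dist = "lnorm_trunc", meanlog = log(3), sdlog = 0.50,
                        lower = 0, upper = 10),
    cyst_mm      = list(dist = "lnorm_trunc", meanlog = log(28), sdlog = 0.45,
                        lower = 0, upper = 150),
    mural_nodule = list(dist = "bernoulli", prob = 0.35),
    ca19_9       = list(dist = "lnorm", meanlog = log(15), sdlog = 1.1),
    cea          = list(dist = "lnorm", meanlog = log(1.8), sdlog = 0.7)
  )
}

default_malignancy_coefs <- function() {
  c(intercept    = -6.0,
    age          = 0.02,
    sex_male     = 0.10,
    mpd_mm       = 0.25,
    cyst_mm      = 0.02,
    mural_nodule = 1.00,
    ca19_9       = 0.45,   # applied to log1p(ca19_9)
    cea          = 0.25)   # applied to log1p(cea)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles everything [generate_cohort()] needs: group sizes, feature
#' distribution parameters, the logistic coefficients of the latent malignancy
#' mechanism over the seven nomogram factors (age, sex, main pancreatic duct
#' diameter, cyst size, mural nodule, CA19-9, CEA), the per-group graded
#' complication rates, the logit-scale noise of the surgical-risk surrogate,
#' and the master seed. Given an identical config the generated cohort is
#' bit-reproducible.
#'
#' @param n_pd,n_dp number of pancreaticoduodenectomy / distal pancreatectomy
#'   patients (positive integers). Defaults 464 and 293 mirror the reference
#'   cohort sizes.
#' @param feature_params named list of per-feature distribution parameters;
#'   see `Details`.
#' @param malignancy_coefs named numeric vector with an `intercept` entry plus
#'   one coefficient per feature; `ca19_9` and `cea` coefficients act on the
#'   `log1p` scale.
#' @param rate_sets list with elements `PD` and `DP`, each a
#'   [complication_rates()] object.
#' @param sc_noise_sd logit-scale standard deviation of the surgical-risk
#'   surrogate (non-negative).
#' @param seed integer master seed; all generator substreams derive from it.
#'
#' @details
#' Feature distributions: age is truncated normal on `[18, 95]`; `mpd_mm` and
#' `cyst_mm` are truncated log-normal on `(0, 10]` and `(0, 150]` (the duct
#' bound encodes the <=10 mm eligibility rule of the branch/mixed-type
#' population); CA19-9 and CEA are log-normal; sex and mural nodule are
#' Bernoulli. All parameters are overridable through `feature_params`.
#'
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_pd = 50, n_dp = 30, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_pd = 464,
                          n_dp = 293,
                          feature_params = default_feature_params(),
                          malignancy_coefs = default_malignancy_coefs(),
                          rate_sets = list(PD = default_rate_set("PD"),
                                           DP = default_rate_set("DP")),
                          sc_noise_sd = 0.4,
                          seed = 1L) {
  if (!is.numeric(n_pd) || !is.numeric(n_dp) ||
      n_pd != round(n_pd) || n_dp != round(n_dp) || n_pd < 0 || n_dp < 0) {
    stop("configuration error: n_pd and n_dp must be non-negative integers",
         call. = FALSE)
  }
  if (n_pd + n_dp < 1) {
    stop("configuration error: n_pd + n_dp must be >= 1", call. = FALSE)
  }
  needed <- c("intercept", names(default_feature_params()))
  missing_cf <- setdiff(needed, names(malignancy_coefs))
  if (length(missing_cf) > 0) {
    stop("configuration error: malignancy_coefs missing ",
         paste(missing_cf, collapse = ", "), call. = FALSE)
  }
  for (g in c("PD", "DP")) {
    if (!inherits(rate_sets[[g]], "complication_rates")) {
      stop("configuration error: rate_sets$", g,
           " must be a complication_rates object", call. = FALSE)
    }
  }
  if (!is.numeric(sc_noise_sd) || sc_noise_sd < 0) {
    stop("configuration error: sc_noise_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(n_pd = as.integer(n_pd), n_dp = as.integer(n_dp),
         feature_params = feature_params,
         malignancy_coefs = malignancy_coefs,
         rate_sets = rate_sets,
         sc_noise_sd = sc_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n_pd:", x$n_pd, " n_dp:", x$n_dp, " seed:", x$seed, "\n")
  cat("  malignancy intercept:", x$malignancy_coefs[["intercept"]],
      " sc_noise_sd:", x$sc_noise_sd, "\n")
  invisible(x)
}

# Derive a named substream seed from the master seed so that adding a pipeline
# stage never perturbs the draws of earlier stages. Offsets are fixed per
# stage name; results stay below 2^31 - 1.
substream_seed <- function(seed, stream) {
  offsets <- c(features = 11L, pathology = 223L, complications_PD = 3511L,
               complications_DP = 4519L, sc_noise = 5657L)
  if (!stream %in% names(offsets)) {
    stop("unknown random substream: ", stream, call. = FALSE)
  }
  as.integer((as.numeric(seed) + offsets[[stream]]) %% .Machine$integer.max)
}
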