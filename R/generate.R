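# Synthetic cohort generation ------------------------------------------------

# Inverse-CDF draws from truncated distributions: deterministic one uniform per
# patient, so the draw count is independent of the truncation bounds.
draw_feature <- function(n, par) {
  u <- stats::runif(n)
  switch(par$dist,
    norm_trunc = {
      lo <- stats::pnorm(par$lower, par$mean, par$sd)
      hi <- stats::pnorm(par$upper, par$mean, par$sd)
      stats::qnorm(lo + u * (hi - lo), par$mean, par$sd)
    },
    lnorm_trunc = {
      lo <- stats::plnorm(par$lower, par$meanlog, par$sdlog)
      hi <- stats::plnorm(par$upper, par$meanlog, par$sdlog)
      stats::qlnorm(lo + u * (hi - lo), par$meanlog, par$sdlog)
    },
    lnorm = stats::qlnorm(u, par$meanlog, par$sdlog),
    bernoulli = as.integer(u < par$prob),
    stop("unknown feature distribution: ", par$dist, call. = FALSE)
  )
}

# Linear predictor of the latent malignancy mechanism; tumour markers enter on
# the log1p scale to tame their right skew.
malignancy_linpred <- function(cohort, coefs) {
  coefs[["intercept"]] +
    coefs[["age"]] * cohort$age +
    coefs[["sex_male"]] * as.numeric(cohort$sex == "male") +
    coefs[["mpd_mm"]] * cohort$mpd_mm +
    coefs[["cyst_mm"]] * cohort$cyst_mm +
    coefs[["mural_nodule"]] * as.numeric(cohort$mural_nodule) +
    coefs[["ca19_9"]] * log1p(cohort$ca19_9) +
    coefs[["cea"]] * log1p(cohort$cea)
}

#' Generate a synthetic branch/mixed-type IPMN surgical cohort
#'
#' Draws patient features from the configured distributions, assigns malignant
#' pathology (high-grade dysplasia or invasive carcinoma) from a Bernoulli
#' draw on the logistic latent probability over the seven nomogram factors,
#' and samples graded Clavien-Dindo complications per surgery group so that
#' the configured exceedance rates hold exactly in expectation. The latent
#' probability is retained in the `latent_p` column for oracle checks.
#'
#' Randomness flows through named substreams of the master seed (features,
#' pathology, per-group complications), so regenerating with the same config
#' is bit-reproducible and adding a downstream stage does not perturb earlier
#' draws.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` of class `ipmn_cohort` with columns `id`, `age`,
#'   `sex`, `mpd_mm`, `cyst_mm`, `mural_nodule`, `ca19_9`, `cea`, `surgery`,
#'   `pathology`, `clavien`, `malignant`, `latent_p`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pd = 30, n_dp = 20, seed = 7))
#' table(cohort$surgery, cohort$malignant)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config object", call. = FALSE)
  }
  n <- config$n_pd + config$n_dp
  surgery <- rep(c("PD", "DP"), times = c(config$n_pd, config$n_dp))

  set.seed(substream_seed(config$seed, "features"))
  fp <- config$feature_params
  cohort <- data.frame(
    id = sprintf("pt%05d", seq_len(n)),
    age = draw_feature(n, fp$age),
    sex = ifelse(draw_feature(n, fp$sex_male) == 1L, "male", "female"),
    mpd_mm = draw_feature(n, fp$mpd_mm),
    cyst_mm = draw_feature(n, fp$cyst_mm),
    mural_nodule = draw_feature(n, fp$mural_nodule) == 1L,
    ca19_9 = draw_feature(n, fp$ca19_9),
    cea = draw_feature(n, fp$cea),
    surgery = surgery,
    stringsAsFactors = FALSE
  )

  cohort$latent_p <- stats::plogis(malignancy_linpred(cohort, config$malignancy_coefs))

  set.seed(substream_seed(config$seed, "pathology"))
  malignant <- stats::rbinom(n, 1L, cohort$latent_p) == 1L
  # split each label into its two constituent histologic grades
  u_path <- stats::runif(n)
  cohort$pathology <- ifelse(malignant,
                             ifelse(u_path < 0.5, "HGD", "invasive"),
                             ifelse(u_path < 0.55, "LGD", "IGD"))
  cohort$malignant <- malignant

  cohort$clavien <- NA_character_
  for (g in c("PD", "DP")) {
    idx <- cohort$surgery == g
    if (any(idx)) {
      cohort$clavien[idx] <- assign_complications(
        cohort[idx, , drop = FALSE], config$rate_sets[[g]],
        seed = substream_seed(config$seed, paste0("complications_", g))
      )$clavien
    }
  }

  cohort <- cohort[, c("id", "age", "sex", "mpd_mm", "cyst_mm", "mural_nodule",
                       "ca19_9", "cea", "surgery", "pathology", "clavien",
                       "malignant", "latent_p")]
  class(cohort) <- c("ipmn_cohort", "data.frame")
  cohort
}

#' Sample graded Clavien-Dindo complications from exceedance rates
#'
#' Assigns each record an ordinal complication grade whose exceedance
#' probabilities equal the supplied rate set exactly: category probabilities
#' are differences of adjacent thresholds, mass below grade II absorbs the
#' remainder (split evenly between "none" and grade I, which leaves every
#' exceedance rate untouched), and grades IV and V are pooled as ">=IV" and
#' recorded as `"IV"`.
#'
#' @param records data.frame of patients (only the row count is used).
#' @param rate_set a [complication_rates()] object.
#' @param seed integer seed for the complication draw.
#' @return `records` with the `clavien` column (re)filled.
#' @export
assign_complications <- function(records, rate_set, seed) {
  if (!inherits(rate_set, "complication_rates")) {
    stop("rate_set must be a complication_rates object", call. = FALSE)
  }
  r <- rate_set$rate_ge
  # category masses: none, I, II, IIIa, IIIb, >=IV
  below <- 1 - r[["II"]]
  probs <- c(none = below / 2, I = below / 2,
             II = r[["II"]] - r[["IIIa"]],
             IIIa = r[["IIIa"]] - r[["IIIb"]],
             IIIb = r[["IIIb"]] - r[["IV"]],
             IV = r[["IV"]])
  if (any(probs < 0)) {
    stop("configuration error: differencing rate_ge yields a negative ",
         "category probability", call. = FALSE)
  }
  n <- nrow(records)
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  grade <- names(probs)[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
  records$clavien <- grade
  records
}

#' Empirical Clavien-Dindo exceedance rate
#'
#' Fraction of records whose complication grade reaches or exceeds the given
#' severity threshold, under the total order
#' none < I < II < IIIa < IIIb < IV < V.
#'
#' @param clavien character vector of Clavien-Dindo grades.
#' @param threshold one of `"II"`, `"IIIa"`, `"IIIb"`, `"IV"`.
#' @return a proportion in `[0, 1]`.
#' @export
clavien_exceedance <- function(clavien, threshold) {
  threshold <- match.arg(threshold, severity_levels())
  lv <- clavien_levels()
  bad <- setdiff(unique(clavien), lv)
  if (length(bad) > 0) {
    stop("unknown Clavien grade(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mean(match(clavien, lv) >= match(threshold, lv))
}
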