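test_that("logistic_score matches closed forms and is monotone", {
  ch <- generate_cohort(small_config(seed = 2))

  flat <- logistic_model_spec(0)
  expect_equal(logistic_score(ch, flat), rep(0.5, nrow(ch)))

  ind <- logistic_model_spec(0, c(mural_nodule = 1),
                             c(mural_nodule = "indicator"))
  scored <- logistic_score(ch, ind)
  expect_equal(scored[ch$mural_nodule], rep(plogis(1), sum(ch$mural_nodule)))
  expect_equal(scored[!ch$mural_nodule], rep(0.5, sum(!ch$mural_nodule)))

  # strictly increasing in a feature with positive coefficient
  a <- ch[1, ]
  b <- a
  b$cyst_mm <- a$cyst_mm + 5
  spec <- default_mp_spec()
  expect_gt(logistic_score(b, spec), logistic_score(a, spec))
})

test_that("vectorized scoring equals per-record brute-force recomputation", {
  ch <- generate_cohort(cohort_config(n_pd = 600, n_dp = 400, seed = 8))
  spec <- default_mp_spec()
  got <- logistic_score(ch, spec)
  # oracle: rebuild the linear predictor row by row, from the spec fields
  oracle <- vapply(seq_len(nrow(ch)), function(i) {
    r <- ch[i, ]
    eta <- spec$intercept +
      spec$coefficients[["age"]] * r$age +
      spec$coefficients[["sex"]] * (r$sex == "male") +
      spec$coefficients[["mpd_mm"]] * r$mpd_mm +
      spec$coefficients[["cyst_mm"]] * r$cyst_mm +
      spec$coefficients[["mural_nodule"]] * r$mural_nodule +
      spec$coefficients[["ca19_9"]] * log1p(r$ca19_9) +
      spec$coefficients[["cea"]] * log1p(r$cea)
    1 / (1 + exp(-eta))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-15)
  # order invariance
  perm <- sample(nrow(ch))
  expect_equal(logistic_score(ch[perm, ], spec), got[perm], tolerance = 1e-15)
})

test_that("missing data and malformed specs are hard errors", {
  ch <- generate_cohort(small_config(seed = 3))
  ch$ca19_9[4] <- NA
  expect_error(logistic_score(ch, default_mp_spec()), "missing data.*ca19_9")
  expect_error(logistic_model_spec(0, c(bmi = 1)), "unknown feature")
  expect_error(logistic_model_spec(0, c(age = 1), c(age = "sqrt")),
               "unknown transform")
})

test_that("surgical-risk surrogate reproduces its group baselines", {
  ch <- generate_cohort(small_config(seed = 4))
  sc <- sc_surrogate(ch, noise_sd = 0)
  # baseline-only specs: every patient sits at the group's minimal
  # serious-complication level (PD 12.2 %, DP 8.4 %)
  expect_equal(unique(sc[ch$surgery == "PD"]), 0.122)
  expect_equal(unique(sc[ch$surgery == "DP"]), 0.084)
  # deterministic at zero noise
  expect_identical(sc, sc_surrogate(ch, noise_sd = 0))
  # reproducible at fixed seed with noise
  expect_identical(sc_surrogate(ch, noise_sd = 0.4, seed = 7),
                   sc_surrogate(ch, noise_sd = 0.4, seed = 7))
  ch$surgery[1] <- "other"
  expect_error(sc_surrogate(ch), "unknown surgery group")
})

test_that("model specs round-trip through JSON", {
  spec <- default_mp_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$intercept, spec$intercept)
  expect_equal(back$coefficients, spec$coefficients)
  expect_equal(back$transforms, spec$transforms)
})
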