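test_that("latent malignancy probability follows the logistic mechanism", {
  coefs <- default_malignancy_coefs()
  coefs[] <- 0  # all-zero coefficients, zero intercept
  ch <- generate_cohort(cohort_config(n_pd = 20, n_dp = 10,
                                      malignancy_coefs = coefs, seed = 5))
  expect_equal(ch$latent_p, rep(0.5, 30))

  coefs[["intercept"]] <- -50  # essentially degenerate Bernoulli(0)
  ch0 <- generate_cohort(cohort_config(n_pd = 200, n_dp = 100,
                                       malignancy_coefs = coefs, seed = 5))
  expect_equal(sum(ch0$malignant), 0)
  expect_true(all(ch0$pathology %in% c("LGD", "IGD")))
})

test_that("generation is bit-reproducible and respects field invariants", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  expect_false(identical(a, generate_cohort(small_config(seed = 12))))

  expect_true(all(a$mpd_mm > 0 & a$mpd_mm <= 10))
  expect_true(all(a$cyst_mm > 0 & a$cyst_mm <= 150))
  expect_true(all(a$age >= 18 & a$age <= 95))
  expect_true(all(a$ca19_9 >= 0) && all(a$cea >= 0))
  expect_identical(a$malignant, a$pathology %in% c("HGD", "invasive"))
  expect_identical(a$surgery, rep(c("PD", "DP"), times = c(40, 30)))
})

test_that("invalid configurations fail with named errors", {
  expect_error(cohort_config(n_pd = -1), "n_pd")
  expect_error(cohort_config(n_pd = 0, n_dp = 0), "n_pd \\+ n_dp")
  expect_error(
    complication_rates("PD", c(II = 0.1, IIIa = 0.2, IIIb = 0.05, IV = 0.01)),
    "weakly decreasing")
  expect_error(complication_rates("PD", c(II = 1.2, IIIa = 0.2, IIIb = 0.05,
                                          IV = 0.01)), "\\[0, 1\\]")
  expect_error(complication_rates("PD", c(II = 0.4, IIIa = 0.2)), "IIIb")
})

test_that("degenerate rate sets pin every grade as expected", {
  recs <- data.frame(id = as.character(1:25))
  all_high <- complication_rates("PD", c(II = 1, IIIa = 1, IIIb = 1, IV = 1))
  expect_true(all(assign_complications(recs, all_high, 1)$clavien == "IV"))
  none <- complication_rates("DP", c(II = 0, IIIa = 0, IIIb = 0, IV = 0))
  expect_true(all(assign_complications(recs, none, 1)$clavien %in% c("none", "I")))
})

test_that("empirical exceedance rates recover the configured marginals", {
  # binomial sampling oracle: each empirical rate within 3 SE of its target
  n <- 20000
  recs <- data.frame(id = as.character(seq_len(n)))
  for (g in c("PD", "DP")) {
    rs <- default_rate_set(g)
    grades <- assign_complications(recs, rs, seed = 99)$clavien
    for (s in c("II", "IIIa", "IIIb", "IV")) {
      p <- rs$rate_ge[[s]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(clavien_exceedance(grades, s) - p), 3 * se)
    }
  }
})

test_that("a positive mural-nodule coefficient couples nodules to malignancy", {
  cfg <- cohort_config(n_pd = 20000, n_dp = 0, seed = 21)
  ch <- generate_cohort(cfg)
  rate_pos <- mean(ch$malignant[ch$mural_nodule])
  rate_neg <- mean(ch$malignant[!ch$mural_nodule])
  expect_gt(rate_pos, rate_neg)
})
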