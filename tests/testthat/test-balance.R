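test_that("count_errors reproduces hand counts and boundary behaviour", {
  toy <- toy_cohort()
  expect_equal(count_errors(toy$labels, toy$mp, 25), c(fp = 1L, fn = 1L))
  # cutoff below every score: nobody is missed, every benign is operated
  expect_equal(count_errors(toy$labels, toy$mp, 5), c(fp = 2L, fn = 0L))
  # cutoff above every score: nobody operated, every malignancy missed
  expect_equal(count_errors(toy$labels, toy$mp, 45), c(fp = 0L, fn = 2L))
  # a score exactly at the cutoff counts as operated (>= convention):
  # the benign 30 % patient is a false positive, not a true negative
  expect_equal(count_errors(toy$labels, toy$mp, 30), c(fp = 1L, fn = 1L))
  # and the conversion to percent is decimal-exact at the boundary
  expect_equal(count_errors(c(FALSE), c(0.29), 29), c(fp = 1L, fn = 0L))

  expect_error(count_errors(logical(0), numeric(0), 10), "empty")
  expect_error(count_errors(toy$labels, c(0.1, 0.2, 1.5, 0.3), 10), "\\[0, 1\\]")
  expect_error(count_errors(toy$labels, toy$mp, 0), "cutoff")
})

test_that("balance_product is the exact complication-weighted FP burden", {
  expect_equal(balance_product(274, 0.024), 6.576)
  expect_equal(balance_product(127, 0.304), 38.608)
  expect_equal(balance_product(0, 0.43), 0)
  expect_error(balance_product(-1, 0.1), "non-negative")
  expect_error(balance_product(3, 1.2), "\\[0, 1\\]")
})

test_that("build_balance_table tabulates a grid with exact weighted columns", {
  toy <- toy_cohort()
  half <- complication_rates("PD", c(II = 0.5, IIIa = 0.5, IIIb = 0.5, IV = 0.5))
  tab <- build_balance_table(toy$labels, toy$mp, 50, half)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$fp, 0L)   # no benign patient scores >= 50
  expect_equal(tab$fn, 2L)   # both malignant patients sit below 50
  expect_equal(tab$w_II, 0)

  # first-row guarantee: a cutoff below every score misses nothing
  ch <- random_scored_cohort(80, seed = 31)
  tab2 <- build_balance_table(ch$labels, ch$mp, c(0.5, 1:99),
                              default_rate_set("DP"))
  expect_equal(tab2$fn[1], 0L)
  # weighted columns reconstruct exactly from fp and the rate set
  rs <- attr(tab2, "rate_set")$rate_ge
  for (s in c("II", "IIIa", "IIIb", "IV")) {
    expect_identical(tab2[[paste0("w_", s)]], tab2$fp * rs[[s]])
  }
})

test_that("fp falls and fn rises across the grid on random cohorts", {
  for (seed in 1:100) {
    ch <- random_scored_cohort(60, seed = seed)
    tab <- build_balance_table(ch$labels, ch$mp, seq(5, 95, by = 5),
                               default_rate_set("PD"))
    expect_true(all(diff(tab$fp) <= 0))
    expect_true(all(diff(tab$fn) >= 0))
    expect_true(all(tab$fp + tab$fn <= length(ch$labels)))
  }
})

test_that("select_cutoff agrees with exhaustive evaluation on small cohorts", {
  for (seed in 1:60) {
    n <- sample(6:30, 1)
    ch <- random_scored_cohort(n, seed = 1000 + seed)
    rs <- default_rate_set(sample(c("PD", "DP"), 1))
    tab <- build_balance_table(ch$labels, ch$mp, 1:99, rs)
    for (s in c("II", "IIIa", "IIIb", "IV")) {
      expect_equal(as.numeric(select_cutoff(tab, s)),
                   cutoff_oracle(tab$cutoff, tab$fp, tab$fn, rs$rate_ge[[s]]))
    }
  }
})

test_that("ties break toward the lower cutoff and boundaries are flagged", {
  # two rows equidistant from equality: |2 - 0.5| at both
  rs <- complication_rates("PD", c(II = 0.5, IIIa = 0.5, IIIb = 0.5, IV = 0.5))
  tab <- balance_table(c(10, 20, 30), fp = c(5, 1, 1), fn = c(0, 2, 2), rs)
  sel <- select_cutoff(tab, "II")
  expect_equal(as.numeric(sel), 20)
  expect_false(attr(sel, "boundary"))

  # fn above fp*rate everywhere: the first grid point wins, flagged boundary
  tab2 <- balance_table(c(10, 20), fp = c(1, 0), fn = c(5, 9), rs)
  sel2 <- select_cutoff(tab2, "IIIa")
  expect_equal(as.numeric(sel2), 10)
  expect_true(attr(sel2, "boundary"))
})

test_that("the selected cutoff weakly increases with the complication rate", {
  for (seed in 1:40) {
    ch <- random_scored_cohort(120, seed = 2000 + seed)
    picks <- vapply(c(0.02, 0.07, 0.18, 0.43), function(r) {
      rs <- complication_rates("PD", c(II = r, IIIa = r, IIIb = r, IV = r))
      as.numeric(select_cutoff(build_balance_table(ch$labels, ch$mp, 1:99, rs),
                               "II"))
    }, numeric(1))
    expect_true(all(diff(picks) >= 0))
  }
})

test_that("balance tables round-trip through their TSV writer/reader", {
  ch <- random_scored_cohort(50, seed = 77)
  rs <- default_rate_set("DP")
  tab <- build_balance_table(ch$labels, ch$mp, seq(10, 90, 10), rs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_balance_table(tab, path)
  back <- read_balance_table(path, rs)
  expect_equal(back$cutoff, tab$cutoff)
  expect_equal(back$fp, tab$fp)
  expect_equal(back$fn, tab$fn)
  expect_equal(back$w_IIIa, tab$w_IIIa)
})
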