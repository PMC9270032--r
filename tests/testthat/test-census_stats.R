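test_that("line summaries report mean, CV% and n", {
  s <- line_summary(c(5, 5, 5), "brp", "f")
  expect_equal(s$mean_count, 5)
  expect_equal(s$cv_percent, 0)
  expect_equal(s$n_animals, 3L)

  s2 <- line_summary(c(9, 11))
  expect_equal(s2$mean_count, 10)
  expect_equal(s2$cv_percent, 100 * sqrt(2) / 10, tolerance = 1e-12) # 14.14

  expect_warning(s1 <- line_summary(10776), "single animal")
  expect_equal(s1$cv_percent, 0)
  expect_error(line_summary(numeric()), "non-empty")
})

test_that("sample-size-weighted pooling reproduces the published means", {
  fem <- list(
    line_summary_values(10776, 2.65, 6, "brp", "female"),
    line_summary_values(10097, 5.96, 5, "Syt1", "female"),
    line_summary_values(9971, 1.35, 5, "nSyb", "female")
  )
  expect_equal(round(weighted_mean_count(fem)), 10312)

  mal <- list(
    line_summary_values(9888, 3.15, 5, "brp", "male"),
    line_summary_values(9012, 3.8, 5, "Syt1", "male"),
    line_summary_values(9286, 5.38, 5, "nSyb", "male")
  )
  expect_equal(weighted_mean_count(mal), 9395.33, tolerance = 1e-5)

  expect_equal(weighted_mean_count(fem[1]), 10776)
  expect_error(weighted_mean_count(c(fem[1], mal[1])), "sexes")
  expect_true(
    weighted_mean_count(fem) >= min(vapply(fem, `[[`, 1, "mean_count")) &&
      weighted_mean_count(fem) <= max(vapply(fem, `[[`, 1, "mean_count"))
  )
})

test_that("the two percent-difference conventions match published values", {
  expect_equal(round(pct_diff_line(10776, 10097), 2), 6.72)
  expect_equal(round(pct_diff_line(10776, 9971), 2), 8.07)
  expect_equal(round(pct_diff_line(9888, 9012), 2), 9.72)
  expect_equal(pct_diff_line(7, 7), 0)

  expect_equal(round(pct_diff_sex(9396, 10312), 2), -9.75)
  expect_equal(round(pct_diff_sex(9888, 10776), 2), -8.98)
  expect_equal(round(pct_diff_sex(9012, 10097), 2), -12.04)
  expect_equal(round(pct_diff_sex(9286, 9971), 2), -7.38)
  expect_equal(round(pct_diff_sex(4015, 3860), 2), 3.86)

  expect_error(pct_diff_line(1, 0), "positive")
  expect_error(pct_diff_sex(0, 1), "positive")
})

test_that("the percent-difference antisymmetry identity holds", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 100, 20000)
    b <- runif(1, 100, 20000)
    p <- pct_diff_line(a, b)
    expect_equal(pct_diff_line(b, a), -p / (1 + p / 100), tolerance = 1e-9)
  }
})

test_that("expression fractions match published values", {
  expect_equal(fraction_of_reference(3860, 10312, digits = 0), 37)
  expect_equal(fraction_of_reference(3057, 9396, digits = 1), 32.5)
  expect_equal(fraction_of_reference(1737, 9396, digits = 1), 18.5)
  expect_equal(fraction_of_reference(0, 123), 0)
  expect_error(fraction_of_reference(1, 0), "positive")
})

test_that("one-way ANOVA + Tukey and the unpaired t-test behave classically", {
  r <- anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(r$F, 1.5, tolerance = 1e-12) # SSB = 1.5, MSW = 1
  # two groups: ANOVA p equals the two-sided pooled t-test p (F = t^2)
  t2 <- unpaired_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$p, t2$p, tolerance = 1e-12)
  expect_equal(r$F, t2$t^2, tolerance = 1e-12)

  same <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  tt <- unpaired_ttest(c(1, 2, 3), c(3, 4, 5))
  expect_equal(abs(tt$t), 2.449, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  swapped <- unpaired_ttest(c(3, 4, 5), c(1, 2, 3))
  expect_equal(swapped$t, -tt$t)
  expect_equal(swapped$p, tt$p)

  eq <- unpaired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  expect_error(anova_tukey(list(c(1, 2))), "2 groups")
  expect_error(unpaired_ttest(1, c(1, 2)), "n >= 2")
})

test_that("the full census report reproduces the published arithmetic", {
  rep <- census_report(cns_line_counts(), pooled = cns_pooled_counts())
  expect_equal(round(rep$pooled_neurons$female), 10312)
  expect_equal(rep$pooled_neurons$male, 9395.33, tolerance = 1e-5)

  lv <- rep$line_vs_line
  get_lv <- function(s, a, b) {
    round(lv$pct[lv$sex == s & lv$line_a == a & lv$line_b == b], 2)
  }
  expect_equal(get_lv("female", "brp", "Syt1"), 6.72)
  expect_equal(get_lv("female", "brp", "nSyb"), 8.07)
  expect_equal(get_lv("male", "brp", "Syt1"), 9.72)

  sd <- rep$sex_diff
  get_sd <- function(w) round(sd$pct[sd$what == w], 2)
  expect_equal(get_sd("all neurons"), -9.75)
  expect_equal(get_sd("brp"), -8.98)
  expect_equal(get_sd("Syt1"), -12.04)
  expect_equal(get_sd("nSyb"), -7.38)
  expect_equal(get_sd("glia"), 3.86)

  expect_equal(round(rep$glia_fraction$pct[rep$glia_fraction$sex == "female"]), 37)
  ch <- rep$channel
  expect_equal(round(ch$fraction_pct[ch$line == "Shab"], 1), 32.5)
  expect_equal(round(ch$fraction_pct[ch$line == "Shaw"], 1), 18.5)
  expect_equal(round(ch$vs_all_neurons_pct[ch$line == "Sh"], 1), -12.7)
  expect_equal(round(ch$vs_all_neurons_pct[ch$line == "Shal"], 1), -12.1)
})
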