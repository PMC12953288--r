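test_that("discordance summary matches a hand-enumerated toy cohort", {
  toy <- data.frame(hist_grade = c(0L, 0L, 2L, 3L),
                    pdff_grade = c(0L, 1L, 1L, 1L))
  s <- discordance_summary(toy)
  expect_equal(s$rate, 0.75)
  expect_equal(unname(s$by_direction[["mri_over"]]), 1L)
  expect_equal(unname(s$by_direction[["mri_under"]]), 2L)
  expect_equal(unname(s$by_magnitude[["1"]]), 2L)
  expect_equal(unname(s$by_magnitude[["2"]]), 1L)
  expect_equal(sum(s$crosstab), 4)
  expect_equal(unname(s$crosstab["0", "1"]), 1)
})

test_that("a perfectly concordant cohort has rate zero and diagonal cross-tab", {
  coh <- data.frame(hist_grade = rep(0:3, each = 5),
                    pdff_grade = rep(0:3, each = 5))
  s <- discordance_summary(coh)
  expect_equal(s$rate, 0)
  expect_equal(sum(diag(s$crosstab)), s$n)
  expect_error(discordance_summary(coh[0, ]), "empty")
})

test_that("cross-tab marginals equal independently computed grade distributions", {
  coh <- grade_cohort(generate_cohort(cohort_spec(n_patients = 355, seed = 14)))
  s <- discordance_summary(coh)
  expect_equal(unname(rowSums(s$crosstab)),
               unname(table(factor(coh$hist_grade, levels = 0:3))),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(s$crosstab)),
               unname(table(factor(coh$pdff_grade, levels = 0:3))),
               ignore_attr = TRUE)
  ci <- s$rate_ci
  expect_true(ci[1] < s$rate && s$rate < ci[2])
})

test_that("group comparisons dispatch the named tests correctly", {
  # duplicated data: identical groups, t-test p must be ~1
  x <- rnorm(40)
  coh <- data.frame(v = c(x, x), g = rep(c(FALSE, TRUE), each = 40))
  expect_gt(compare_groups(coh, "g", "v", test = "t")$p_value, 0.5)

  # 2x2 (10,0 / 0,10): exact hypergeometric two-sided p = 2 / choose(20, 10)
  coh2 <- data.frame(g = rep(c(FALSE, TRUE), each = 10),
                     v = rep(c("a", "b"), each = 10))
  res <- compare_groups(coh2, "g", "v", test = "fisher")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  expect_error(compare_groups(data.frame(v = 1:3, g = rep(TRUE, 3)), "g", "v"),
               "two nonempty groups")
})

test_that("planted stratum effect is detected by the stratified comparison", {
  set.seed(99)
  coh <- grade_cohort(generate_cohort(cohort_spec(n_patients = 400, seed = 6)))
  s0 <- coh$hist_grade == 0
  # plant a higher tiny-LD burden among discordant S0 patients
  coh$tiny_pct[s0 & coh$discordant] <- coh$tiny_pct[s0 & coh$discordant] + 3
  tab <- stratified_comparison(coh, variables = "tiny_pct")
  row <- tab[tab$stratum == 0 & tab$variable == "tiny_pct", ]
  expect_lt(row$p_value, 0.01)
  expect_gt(row$mean_discordant, row$mean_concordant)
})

test_that("univariable logit reproduces the 2x2 cross-product odds ratio", {
  counts <- c(a = 30, b = 12, c = 18, d = 25)  # exposed/outcome cells
  coh <- data.frame(
    x = rep(c(1, 1, 0, 0), counts),
    discordant = rep(c(TRUE, FALSE, TRUE, FALSE), counts)
  )
  res <- univariable_logit(coh, "x")
  or_closed <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  expect_equal(res$table$odds_ratio, unname(or_closed), tolerance = 1e-6)
})

test_that("univariable logit recovers a planted slope and flags separation", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n, sd = 2)
  y <- rbinom(n, 1, plogis(-0.3 + 0.25 * x)) == 1
  coh <- data.frame(x = x, discordant = y)
  res <- univariable_logit(coh, "x")
  expect_true(res$table$ci_low < exp(0.25) && exp(0.25) < res$table$ci_high)

  # independent predictor: OR ~ 1, CI covers 1
  coh$z <- rnorm(n)
  res0 <- univariable_logit(coh, "z")
  expect_true(res0$table$ci_low < 1 && 1 < res0$table$ci_high)
  expect_lt(abs(res0$table$odds_ratio - 1), 0.15)

  # perfectly separating predictor is flagged
  sep <- data.frame(x = c(1:20, 41:60),
                    discordant = rep(c(FALSE, TRUE), each = 20))
  expect_warning(rs <- univariable_logit(sep, "x"), "separation")
  expect_true(rs$separation)
})

test_that("multivariable entry, collinearity and direction rules behave as specified", {
  coh <- planted_outcome(generate_cohort(cohort_spec(n_patients = 355, seed = 50)),
                         seed = 150)
  fit <- multivariable_logit(coh,
                             candidates = c("tiny_pct", "small_pct", "large_pct",
                                            "total_pct"))
  # the sum variable never coexists with its components
  expect_true("total_pct" %in% fit$predictors_excluded_collinear)
  expect_false("total_pct" %in% fit$predictors_entered)
  tab <- fit$table
  expect_gt(tab$odds_ratio[tab$predictor == "tiny_pct"], 1)
  expect_gt(tab$odds_ratio[tab$predictor == "small_pct"], 1)
  expect_lt(tab$odds_ratio[tab$predictor == "large_pct"], 1)
  expect_true(all(tab$ci_low <= tab$odds_ratio & tab$odds_ratio <= tab$ci_high))

  # pure-noise candidates: nothing enters, forced covariates remain
  set.seed(77)
  coh$noise1 <- rnorm(nrow(coh)); coh$noise2 <- rnorm(nrow(coh))
  coh$discordant <- rbinom(nrow(coh), 1, 0.4) == 1
  fit0 <- multivariable_logit(coh, candidates = c("noise1", "noise2"))
  expect_length(fit0$predictors_entered, 0)
  expect_setequal(fit0$table$predictor, c("age", "sexmale"))
})

test_that("pairwise correlation screen drops the weaker of a collinear pair", {
  set.seed(12)
  n <- 800
  x <- rnorm(n)
  coh <- data.frame(
    age = round(runif(n, 30, 70)), sex = sample(c("female", "male"), n, TRUE),
    u = x, v = x + rnorm(n, sd = 0.1)  # |r| > 0.97
  )
  coh$discordant <- rbinom(n, 1, plogis(0.8 * x)) == 1
  fit <- multivariable_logit(coh, candidates = c("u", "v"),
                             sum_components = list())
  expect_length(intersect(c("u", "v"), fit$predictors_entered), 1)
  expect_length(fit$predictors_excluded_collinear, 1)
})

test_that("correlations match closed-form cases and the calibrated simulator", {
  coh <- data.frame(x = 1:20, y = 2 * (1:20) + 1)
  expect_equal(correlate(coh, "x", "y", "pearson")$coefficient, 1)
  coh$yrev <- rev(coh$x)
  expect_equal(correlate(coh, "x", "yrev", "spearman")$coefficient, -1)
  # any monotone transform has Spearman rho 1 with its argument
  coh$ymono <- exp(coh$x / 5)
  expect_equal(correlate(coh, "x", "ymono", "spearman")$coefficient, 1)
  expect_error(correlate(data.frame(x = c(1, 1, 1), y = 1:3), "x", "y"),
               "zero variance")

  sim <- generate_cohort(cohort_spec(n_patients = 355, seed = 4))
  r <- correlate(sim, "pdff_pct", "total_pct", "pearson")$coefficient
  expect_lt(abs(r - 0.89), 0.05)
})

test_that("stratified paired Wilcoxon handles shifts, nulls and degeneracy", {
  # planted +2% shift in one stratum
  set.seed(10)
  coh <- data.frame(hist_grade = rep(c(0L, 1L), each = 50))
  coh$total_pct <- rnorm(100, 10, 2)
  coh$pdff_pct <- coh$total_pct + rnorm(100, 0, 1) +
    ifelse(coh$hist_grade == 1L, 2, 0)
  res <- wilcoxon_paired_by_grade(coh)
  expect_lt(res$p_value[res$stratum == 1], 0.01)

  # degenerate stratum: identical pairs reported with p = 1
  cohd <- data.frame(hist_grade = 0L, total_pct = 1:10, pdff_pct = 1:10)
  resd <- wilcoxon_paired_by_grade(cohd)
  expect_equal(resd$status, "degenerate")
  expect_equal(resd$p_value, 1)

  # too-small stratum flagged, not computed
  cohs <- data.frame(hist_grade = 0L, total_pct = 1:3, pdff_pct = 4:6)
  expect_equal(wilcoxon_paired_by_grade(cohs)$status, "too_small")

  # null differences rarely significant
  ps <- vapply(1:40, function(s) {
    set.seed(s)
    cc <- data.frame(hist_grade = 0L, total_pct = rnorm(200),
                     pdff_pct = rnorm(200))
    cc$pdff_pct <- cc$total_pct + rnorm(200)  # symmetric zero-median noise
    wilcoxon_paired_by_grade(cc)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("quadratic fits recover exact curves and generator concavities", {
  x <- seq(-3, 3, by = 0.5)
  f <- quad_fit(x, x^2)
  expect_equal(unname(f$coefficients["a"]), 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$concavity, "up")

  fc <- quad_fit(x, rep(2, length(x)))
  expect_equal(unname(fc$coefficients["a"]), 0)
  expect_equal(fc$r_squared, 0)
  expect_equal(fc$concavity, "none")
  expect_error(quad_fit(rep(1, 10), rnorm(10)), "rank")

  coh <- generate_cohort(cohort_spec(n_patients = 355, seed = 30))
  up <- quad_fit(coh$total_pct, coh$large_pct)
  down <- quad_fit(coh$total_pct, coh$tiny_pct + coh$small_pct)
  expect_equal(up$concavity, "up")
  expect_equal(down$concavity, "down")
})

test_that("sample-size formula reproduces the worked values and its monotonicity", {
  expect_identical(required_sample_size(0.6, 0.05, 0.05), 369L)
  expect_identical(required_sample_size(0.5, 0.05, 0.05), 385L)
  expect_identical(required_sample_size(0.6, 0.10, 0.05), 93L)
  # decreasing in d; maximal at p = 0.5
  d <- c(0.02, 0.05, 0.1, 0.2)
  n <- vapply(d, function(di) required_sample_size(0.6, di), integer(1))
  expect_true(all(diff(n) < 0))
  p <- seq(0.1, 0.9, by = 0.1)
  np <- vapply(p, function(pi) required_sample_size(pi, 0.05), integer(1))
  expect_true(all(np <= np[p == 0.5]))
  expect_error(required_sample_size(1, 0.05), "prevalence")
  expect_error(required_sample_size(0.5, 1.2), "precision")
})
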