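test_that("pooled t test matches the closed-form hand computation", {
  r <- assoc_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-6)

  same <- assoc_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  far <- assoc_ttest(rnorm(20), rnorm(20) + 1e3)
  expect_lt(far$p_value, 1e-10)

  expect_error(assoc_ttest(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_error(assoc_ttest(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches the sum-of-squares hand computation", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6 (df 2), SSW = 6 (df 6), F = 3
  r <- assoc_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3, tolerance = 1e-12)
  expect_equal(r$df, c(2, 6))
  expect_equal(r$p_value, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  flat <- assoc_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  shifted <- assoc_anova(list(rnorm(10), rnorm(10), rnorm(10) + 100))
  expect_lt(shifted$p_value, 1e-10)

  # the grouping-vector interface agrees with the list interface
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(1:3, each = 3)
  expect_equal(assoc_anova(vals, g)$statistic, 3, tolerance = 1e-12)
})

test_that("chi-square test is Pearson without continuity correction", {
  r <- assoc_chisq(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)

  indep <- assoc_chisq(outer(c(30, 70), c(40, 60)) / 100)
  expect_equal(indep$statistic, 0, tolerance = 1e-12)
  expect_equal(indep$p_value, 1)

  tab <- rbind(c(12, 5, 9), c(4, 16, 2))
  perm <- tab[2:1, c(3, 1, 2)]
  expect_equal(assoc_chisq(tab)$statistic, assoc_chisq(perm)$statistic)
  expect_error(assoc_chisq(rbind(c(0, 0), c(1, 2))), "positive")
})

test_that("Pearson correlation handles exact and null relationships", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_corr(x, 2 * x)$estimate, 1)
  expect_equal(pearson_corr(x, -x)$estimate, -1)
  set.seed(31)
  r <- pearson_corr(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(r$estimate), 0.05)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("partial correlation reduces, errors and recovers as it should", {
  # orthogonal covariate: partial equals plain Pearson
  x <- c(1, 5, 3, 7, 9, 2, 8, 4)
  y <- c(2, 6, 1, 9, 7, 3, 9, 5)
  z <- rep(c(1, -1), 4)
  zo <- z - mean(z)
  xo <- x - sum(x * zo) / sum(zo^2) * zo   # force r_xz = 0
  yo <- y - sum(y * zo) / sum(zo^2) * zo
  expect_equal(partial_corr(xo, yo, z)$estimate,
               pearson_corr(xo, yo)$estimate, tolerance = 1e-12)

  expect_error(partial_corr(x, z, z), "collinear")

  # trivariate construction with known partial correlation 0.5
  set.seed(32)
  n <- 1e4
  zc <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(n)
  got <- partial_corr(0.8 * zc + e1, -0.6 * zc + e2, zc)
  expect_equal(got$estimate, 0.5, tolerance = 0.03)
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(33)
  for (i in 1:20) {
    n <- 30
    z <- rnorm(n)
    x <- 0.7 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    rx <- residuals(lm(x ~ z))
    ry <- residuals(lm(y ~ z))
    expect_equal(partial_corr(x, y, z)$estimate, cor(rx, ry),
                 tolerance = 1e-10)
  }
})

test_that("linear models recover exact and noisy generative slopes", {
  d <- data.frame(psad = seq(0.01, 0.3, length.out = 20), age = 60)
  d$tumor_volume <- 2 * d$psad
  fit <- suppressWarnings(tv_linear_model(d, "psad"))
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(34)
  n <- 1000
  d2 <- data.frame(psad = runif(n, 0.02, 0.3), age = rnorm(n, 60, 7))
  d2$tumor_volume <- 1.5 * d2$psad + rnorm(n, sd = 0.3)
  f2 <- tv_linear_model(d2, "psad")
  slope <- f2$coefficients[f2$coefficients$term == "psad", ]
  expect_lt(abs(slope$estimate - 1.5), 3 * slope$se)

  # age-adjusted form adds exactly one extra term
  f3 <- tv_linear_model(d2, "psad", adjust_age = TRUE)
  expect_equal(f3$coefficients$term, c("(Intercept)", "psad", "age"))

  # null predictor: slope near zero, p-values roughly uniform
  set.seed(35)
  ps <- replicate(200, {
    dn <- data.frame(psad = runif(50), tumor_volume = rnorm(50))
    fn <- tv_linear_model(dn, "psad")
    fn$coefficients$p[2]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("group summaries reproduce count percentages and edge cases", {
  df <- make_cohort_df(6, race_ethnicity = c("NHW", "NHW", "NHW", "NHB",
                                             "NHB", "HISPANIC_LATINO"),
                       psa = c(2, 4, 6, 3, 5, 7))
  d <- derive_all(as_cohort(df))
  s <- summarize_groups(d, "race_ethnicity")
  expect_equal(unname(s$group_n["All"]), 6)
  nhw_psa <- s$continuous[s$continuous$group == "NHW" &
                            s$continuous$variable == "psa", ]
  expect_equal(nhw_psa$mean, 4)
  expect_equal(nhw_psa$median, 4)
  expect_equal(nhw_psa$min, 2)
  expect_equal(nhw_psa$max, 6)
  # single-record group: mean = median = min = max
  hl <- s$continuous[s$continuous$group == "HISPANIC_LATINO" &
                       s$continuous$variable == "psa", ]
  expect_true(all(unlist(hl[c("mean", "median", "min", "max")]) == 7))
  # categorical percentages computed within the known denominator
  inst <- s$categorical[s$categorical$group == "All" &
                          s$categorical$variable == "institution", ]
  expect_equal(inst$percent[inst$level == "JHU"], 100)
})
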