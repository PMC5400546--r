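test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_preset("table1_default"), seed = 9)
  b <- generate_cohort(cohort_preset("table1_default"), seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_preset("table1_default"), seed = 10)
  expect_false(identical(a$psa, c2$psa))
  expect_error(generate_cohort(cohort_preset("table1_default")), "seed")
})

test_that("generated records honor the data-model invariants and envelopes", {
  cfg <- cohort_preset("table1_default")
  co <- generate_cohort(cfg, seed = 12)
  expect_equal(nrow(co), 589)
  expect_equal(unname(table(co$race_ethnicity)[c("NHW", "NHB",
                                                 "HISPANIC_LATINO",
                                                 "OTHER")]),
               c(390, 87, 78, 34), ignore_attr = TRUE)
  expect_true(all(co$age >= 36 & co$age <= 78))
  expect_true(all(co$psa >= 0.3 & co$psa <= 13))
  expect_true(all(co$tumor_volume >= 0.004 & co$tumor_volume <= 7.6))
  for (g in names(cfg$pw_range)) {
    pw <- co$prostate_weight[co$race_ethnicity == g]
    expect_true(all(pw >= cfg$pw_range[[g]][1] &
                      pw <= cfg$pw_range[[g]][2]))
  }
  expect_true(all(co$institution[co$race_ethnicity == "HISPANIC_LATINO"] ==
                    "UM"))
})

test_that("the deterministic limit reduces PSA to the structural equation", {
  cfg <- cohort_config(
    beta = c(NHW = 2, NHB = 2, HISPANIC_LATINO = 2, OTHER = 2),
    gamma = 0, noise_sdlog = 0,
    pw_median = c(NHW = 45, NHB = 45, HISPANIC_LATINO = 45, OTHER = 45),
    pw_sdlog = c(NHW = 0.2, NHB = 0.2, HISPANIC_LATINO = 0.2, OTHER = 0.2),
    pw_range = list(NHW = c(30, 70), NHB = c(30, 70),
                    HISPANIC_LATINO = c(30, 70), OTHER = c(30, 70)),
    tv_median = c(NHW = 0.35, NHB = 0.35, HISPANIC_LATINO = 0.35,
                  OTHER = 0.35),
    tv_range = c(0.05, 2))
  co <- generate_cohort(cfg, seed = 13)
  expect_equal(co$psa, cfg$alpha * co$prostate_weight + 2 * co$tumor_volume,
               tolerance = 1e-12)
})

test_that("zero-noise cohorts identify the production rates exactly", {
  cfg <- cohort_config(
    group_sizes = c(NHW = 300, NHB = 300, HISPANIC_LATINO = 0, OTHER = 0),
    gamma = 0, noise_sdlog = 0,
    pw_range = list(NHW = c(25, 100), NHB = c(25, 100),
                    HISPANIC_LATINO = c(25, 100), OTHER = c(25, 100)),
    tv_range = c(0.05, 3))
  est <- recover_parameters(generate_cohort(cfg, seed = 14))
  for (g in c("NHW", "NHB")) {
    row <- est[est$group == g, ]
    expect_equal(row$alpha_hat, cfg$alpha, tolerance = 1e-8)
    expect_equal(row$beta_hat, unname(cfg$beta[g]), tolerance = 1e-8)
  }
})

test_that("hemodilution ignored by recovery biases tumor rates low when BMI is high", {
  cfg <- cohort_config(
    group_sizes = c(NHW = 4000, NHB = 0, HISPANIC_LATINO = 0, OTHER = 0),
    noise_sdlog = 0.05)
  co <- generate_cohort(cfg, seed = 15)
  d <- derive_all(co)
  strata <- split(as.data.frame(d), d$bmi_category, drop = TRUE)
  fit_beta <- function(s) unname(coef(lm(psa ~ 0 + prostate_weight +
                                           tumor_volume,
                                         data = s))["tumor_volume"])
  expect_lt(fit_beta(strata$OBESE), fit_beta(strata$NORMAL))
})

test_that("generated medians land on the emulated cohort's printed values", {
  # 20x the study group sizes so the median sampling error (~1-4%) does not
  # mask the calibration being checked
  cfg <- cohort_config(group_sizes = c(NHW = 7800, NHB = 1740,
                                       HISPANIC_LATINO = 1560, OTHER = 680))
  co <- generate_cohort(cfg, seed = 16)
  targets <- list(
    NHW = c(psa = 4.4, pw = 44.9, tv = 0.35),
    NHB = c(psa = 4.4, pw = 51.5, tv = 0.51),
    HISPANIC_LATINO = c(psa = 4.5, pw = 42, tv = 0.35),
    OTHER = c(psa = 4.2, pw = 41, tv = 0.39))
  for (g in names(targets)) {
    sub <- co[co$race_ethnicity == g, ]
    got <- c(psa = median(sub$psa), pw = median(sub$prostate_weight),
             tv = median(sub$tumor_volume))
    expect_true(all(abs(got / targets[[g]] - 1) < 0.15),
                info = sprintf("%s medians: %s", g,
                               paste(round(got, 3), collapse = ", ")))
  }
  # NHB mean prostate weight sits on the printed 57.9 g scale
  expect_equal(mean(co$prostate_weight[co$race_ethnicity == "NHB"]), 57.9,
               tolerance = 0.15)
})

test_that("presets encode their intended race-effect structure", {
  def <- cohort_preset("table1_default")
  expect_equal(unname(def$group_sizes),
               c(390, 87, 78, 34))
  expect_equal(unname(def$beta["NHB"] / def$beta["NHW"]), 0.75)

  null <- cohort_preset("null_no_race_effect")
  expect_true(all(null$beta == null$beta[1]))
  expect_true(all(null$pw_median == null$pw_median[1]))

  strong <- cohort_preset("strong_effect")
  expect_equal(unname(strong$beta["NHB"] / strong$beta["NHW"]), 0.5)

  expect_error(cohort_preset("no_such_preset"))
})

test_that("configuration validation rejects infeasible parameters", {
  expect_error(cohort_config(group_sizes = c(NHW = -1, NHB = 87,
                                             HISPANIC_LATINO = 78,
                                             OTHER = 34)), ">= 0")
  expect_error(cohort_config(alpha = 0), "positive")
  expect_error(cohort_config(noise_sdlog = -0.1), ">= 0")
  expect_error(cohort_config(psa_range = c(13, 0.3)), "increasing")
  expect_error(cohort_config(group_sizes = c(NHW = 390, NHB = 87)),
               "group_sizes")
  # target median outside the truncation envelope is caught at generation
  bad <- cohort_config(pw_range = list(NHW = c(50, 165), NHB = c(24.5, 194),
                                       HISPANIC_LATINO = c(18, 97),
                                       OTHER = c(22, 146)))
  expect_error(generate_cohort(bad, seed = 1), "outside truncation range")
})
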