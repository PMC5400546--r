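test_that("ROC curves reproduce the canonical small examples", {
  expect_equal(build_roc(1:4, c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  # alternating labels on 1:4: pos {1,3} beats neg {2,4} in 1 of 4 pairs
  expect_equal(build_roc(1:4, c(TRUE, FALSE, TRUE, FALSE))$auc, 0.25)
  # ties split: 3 wins + 1 tie + 0 losses over 4 pairs -> 0.875
  expect_equal(build_roc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))$auc,
               0.875)
  expect_error(build_roc(1:3, c(TRUE, TRUE, TRUE)), "negative")
  expect_error(build_roc(1:3, c(FALSE, FALSE, FALSE)), "positive")
})

test_that("curves are monotone and span the two degenerate corners", {
  set.seed(20)
  for (i in 1:50) {
    inst <- random_roc_instance(max_n = 30)
    roc <- build_roc(inst$scores, inst$labels)
    p <- roc$points
    # threshold-ordered: sensitivity and FPR non-increasing
    expect_true(all(diff(p$sensitivity) <= 1e-12))
    expect_true(all(diff(p$fpr) <= 1e-12))
    expect_equal(p$sensitivity[1], 1)
    expect_equal(p$fpr[1], 1)
    expect_equal(p$sensitivity[nrow(p)], 0)
    expect_equal(p$fpr[nrow(p)], 0)
    expect_gte(roc$auc, 0)
    expect_lte(roc$auc, 1)
  }
})

test_that("trapezoidal AUC equals exhaustive pair counting on small data", {
  set.seed(21)
  for (i in 1:300) {
    inst <- random_roc_instance(max_n = 8)
    roc <- build_roc(inst$scores, inst$labels)
    expect_equal(roc$auc, concordance_oracle(inst$scores, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(22)
  for (i in 1:30) {
    inst <- random_roc_instance(max_n = 25)
    auc0 <- build_roc(inst$scores, inst$labels)$auc
    expect_equal(build_roc(exp(inst$scores), inst$labels)$auc, auc0)
    expect_equal(build_roc(3 * inst$scores + 11, inst$labels)$auc, auc0)
    expect_equal(roc_auc(build_roc(rank(inst$scores, ties.method = "min"),
                                   inst$labels)), auc0)
  }
})

test_that("upper-left cutoff matches exhaustive search on small instances", {
  set.seed(23)
  for (i in 1:300) {
    inst <- random_roc_instance(max_n = 10)
    got <- optimal_cutoff(build_roc(inst$scores, inst$labels))
    want <- upper_left_oracle(inst$scores, inst$labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sensitivity, want$sens)
    expect_equal(got$specificity, want$spec)
  }
})

test_that("upper-left cutoff picks the separating threshold when one exists", {
  roc <- build_roc(c(0.1, 0.2, 0.3, 0.4), c(FALSE, FALSE, TRUE, TRUE))
  opt <- optimal_cutoff(roc)
  expect_equal(opt$threshold, 0.3)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  # youden agrees here
  expect_equal(optimal_cutoff(roc, "youden")$threshold, 0.3)
})

test_that("confusion rates follow the score >= cutoff convention", {
  scores <- 1:4
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  c1 <- confusion_at_cutoff(scores, labels, 0.5)   # below min
  expect_equal(c1$sensitivity, 1)
  expect_equal(c1$specificity, 0)
  c2 <- confusion_at_cutoff(scores, labels, 5)     # above max
  expect_equal(c2$sensitivity, 0)
  expect_equal(c2$specificity, 1)
  expect_true(is.na(c2$ppv))                       # no predicted positives
  c3 <- confusion_at_cutoff(scores, labels, 3)
  expect_equal(c(c3$sensitivity, c3$specificity, c3$ppv, c3$npv),
               c(1, 1, 1, 1))

  set.seed(24)
  for (i in 1:30) {
    inst <- random_roc_instance(max_n = 20)
    cut <- sample(inst$scores, 1)
    cc <- confusion_at_cutoff(inst$scores, inst$labels, cut)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, length(inst$scores))
    if (!is.na(cc$ppv)) expect_equal(cc$ppv * (cc$tp + cc$fp), cc$tp)
    # PPV/NPV consistent with sens/spec and prevalence (Bayes identities)
    prev <- (cc$tp + cc$fn) / cc$n
    if (!is.na(cc$ppv)) {
      expect_equal(cc$ppv,
                   cc$sensitivity * prev /
                     (cc$sensitivity * prev +
                        (1 - cc$specificity) * (1 - prev)),
                   tolerance = 1e-12)
    }
  }
})

test_that("sensitivity at fixed specificity attains the target conservatively", {
  perfect <- build_roc(1:6, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sensitivity_at_fixed_specificity(perfect, 0.8)$sensitivity, 1)
  expect_equal(sensitivity_at_fixed_specificity(perfect, 0.99)$sensitivity, 1)

  # only the all-negative point reaches the target here
  one_neg <- build_roc(c(1, 2), c(TRUE, FALSE))
  res <- sensitivity_at_fixed_specificity(one_neg, 0.99)
  expect_equal(res$sensitivity, 0)

  got <- sensitivity_at_fixed_specificity(
    build_roc(1:10, rep(c(FALSE, TRUE), 5)), 0.6)
  expect_gte(got$specificity, 0.6)
})

test_that("under the null, sensitivity at 80% specificity is near 20%", {
  set.seed(25)
  sims <- replicate(2000, {
    scores <- rnorm(200)
    labels <- rep(c(TRUE, FALSE), 100)
    sensitivity_at_fixed_specificity(build_roc(scores, labels),
                                     0.80)$sensitivity
  })
  expect_lt(abs(mean(sims) - 0.20), 0.03)
})

test_that("the paired bootstrap comparison behaves under known structure", {
  set.seed(26)
  labels <- rep(c(TRUE, FALSE), 40)
  a <- rnorm(80) + labels
  # identical metrics: zero difference, p near 1
  same <- compare_sensitivity_bootstrap(a, a, labels, n_boot = 200, seed = 1)
  expect_equal(same$diff, 0)
  expect_gte(same$p_value, 0.99)
  # a monotone shift leaves ranks, hence the difference, unchanged
  shift <- compare_sensitivity_bootstrap(a, a + 100, labels, n_boot = 200,
                                         seed = 2)
  expect_equal(shift$diff, 0)
  # seeding makes the whole comparison reproducible
  again <- compare_sensitivity_bootstrap(a, a + 100, labels, n_boot = 200,
                                         seed = 2)
  expect_identical(shift$p_value, again$p_value)
  expect_identical(shift$ci, again$ci)
  expect_error(compare_sensitivity_bootstrap(a, a, labels, n_boot = 10),
               "seed")
})

test_that("bootstrap confidence intervals cover a known sensitivity gap", {
  # negatives U(0,1) for both metrics; positives shifted so the true
  # sensitivities at the 80% specificity threshold (0.8) are 0.50 and 0.65
  set.seed(27)
  n_pos <- 250
  n_neg <- 250
  covered <- logical(60)
  for (i in 1:60) {
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    a <- c(runif(n_pos, 0.45, 1.45), runif(n_neg))
    b <- c(runif(n_pos, 0.30, 1.30), runif(n_neg))
    res <- compare_sensitivity_bootstrap(a, b, labels, n_boot = 250,
                                         seed = 1000 + i)
    covered[i] <- res$ci[1] <= 0.15 && 0.15 <= res$ci[2]
  }
  expect_gte(mean(covered), 0.85)
})
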