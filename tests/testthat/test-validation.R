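test_that("Cohen's kappa reproduces hand-computed values", {
  ## identical sequences with >= 2 classes
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  ## binary perfect disagreement with balanced marginals
  expect_equal(cohen_kappa(c("a", "b", "a", "b"), c("b", "a", "b", "a")), -1)
  ## confusion table [[20,5],[10,15]]: kappa = (0.70 - 0.50) / 0.50 = 0.40
  ref <- c(rep("p", 25), rep("n", 25))
  pred <- c(rep("p", 20), rep("n", 5), rep("p", 10), rep("n", 15))
  expect_equal(cohen_kappa(ref, pred), 0.4, tolerance = 1e-12)
  expect_error(cohen_kappa(c("a", "b"), "a"), class = "somnostage_argument_error")
  ## degenerate marginals: both raters constant on the same label
  expect_equal(cohen_kappa(c("a", "a"), c("a", "a")), 1)
})

test_that("kappa matches the brute-force contingency formula", {
  set.seed(61)
  for (trial in 1:1000) {
    n <- sample(5:40, 1)
    k <- sample(2:4, 1)
    ref <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    want <- kappa_bruteforce(ref, pred)
    if (!is.finite(want)) next
    expect_equal(cohen_kappa(ref, pred), want, tolerance = 1e-12)
  }
})

test_that("agreement reports tie per-stage and overall accuracy to the confusion matrix", {
  set.seed(62)
  ref <- hypnogram(sample(c("W", "REM", "NREM"), 200, replace = TRUE), "s3")
  pred <- hypnogram(sample(c("W", "REM", "NREM"), 200, replace = TRUE), "s3")
  rep_ <- agreement_report(ref, pred)
  cm <- rep_$confusion_matrix
  expect_equal(sum(cm), 200)
  expect_equal(rep_$overall_accuracy, 100 * sum(diag(cm)) / sum(cm))
  ok <- !is.nan(rep_$per_stage_accuracy)
  expect_true(all(rep_$per_stage_accuracy[ok] >= 0 &
                  rep_$per_stage_accuracy[ok] <= 100))
  expect_equal(unname(rep_$per_stage_accuracy["W"]),
               100 * cm["W", "W"] / sum(cm["W", ]))
})

test_that("sleep summaries follow the epoch arithmetic", {
  ## 960 epochs with 816 sleep: SE = 85%, TST = 408 min
  h <- hypnogram(c(rep("S", 816), rep("W", 144)), "s2")
  s <- sleep_summary(h)
  expect_equal(s$SE, 85)
  expect_equal(s$TST, 408)
  expect_equal(s$time_in_bed, 480)

  ## all wake: SE 0, WASO 0
  s0 <- sleep_summary(hypnogram(rep("W", 10), "s2"))
  expect_equal(s0$SE, 0); expect_equal(s0$TST, 0); expect_equal(s0$WASO, 0)

  ## W W S W S: onset at the third epoch, one wake epoch after onset
  s1 <- sleep_summary(hypnogram(c("W", "W", "S", "W", "S"), "s2"))
  expect_equal(s1$WASO, 0.5)
  expect_equal(s1$SE, 40)

  ## the alternative onset rule waits for 3 consecutive sleep epochs
  h3 <- hypnogram(c("S", "W", "S", "S", "S", "W"), "s2")
  expect_equal(sleep_summary(h3, "first")$WASO, 1)
  expect_equal(sleep_summary(h3, "first3")$WASO, 0.5)

  expect_error(sleep_summary(hypnogram(c("W", "N2"), "raw")),
               class = "somnostage_argument_error")
})

test_that("TST + TWT equals time in bed for random hypnograms", {
  set.seed(63)
  for (trial in 1:50) {
    h <- hypnogram(sample(c("W", "S"), sample(1:500, 1), replace = TRUE), "s2")
    s <- sleep_summary(h)
    expect_equal(s$TST + s$TWT, s$time_in_bed)
    expect_gte(s$SE, 0); expect_lte(s$SE, 100)
    expect_lte(s$WASO, s$TWT)
  }
})

test_that("SE groups use half-open bins with boundaries in the upper group", {
  expect_equal(as.character(se_group(39.9)), "0-39")
  expect_equal(as.character(se_group(40)), "40-59")
  expect_equal(as.character(se_group(59.99)), "40-59")
  expect_equal(as.character(se_group(60)), "60-79")
  expect_equal(as.character(se_group(80)), ">=80")
  expect_equal(as.character(se_group(c(0, 100))), c("0-39", ">=80"))
  expect_error(se_group(101), class = "somnostage_argument_error")
  expect_error(se_group(-1), class = "somnostage_argument_error")
})

test_that("screening metrics reproduce the worked 2x2 example", {
  ## TP=10 FP=2 FN=3 TN=15 at threshold 60
  est <- c(rep(75, 10), rep(75, 2), rep(45, 3), rep(45, 15))
  psg <- c(rep(80, 10), rep(50, 2), rep(70, 3), rep(30, 15))
  r <- screening_metrics(est, psg, 60)
  expect_equal(r$sensitivity, 100 * 10 / 13, tolerance = 1e-9)
  expect_equal(r$specificity, 100 * 15 / 17, tolerance = 1e-9)
  expect_equal(r$PPV, 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(r$NPV, 100 * 15 / 18, tolerance = 1e-9)
  expect_equal(round(r$sensitivity, 1), 76.9)
  expect_equal(round(r$specificity, 1), 88.2)
})

test_that("perfect screening agreement yields perfect rates and AUC 1", {
  se <- c(30, 45, 55, 65, 75, 85, 95)
  for (thr in c(40, 60, 80)) {
    r <- screening_metrics(se, se, thr)
    expect_equal(r$sensitivity, 100)
    expect_equal(r$specificity, 100)
    expect_equal(r$PPV, 100); expect_equal(r$NPV, 100)
    expect_equal(r$kappa, 1)
    expect_equal(r$auc, 1)
  }
  expect_error(screening_metrics(se, se, 50), class = "somnostage_argument_error")
})

test_that("degenerate screening sides are reported as unavailable", {
  est <- c(85, 90, 95)
  psg <- c(85, 90, 95)                        # nobody below threshold 40
  r <- screening_metrics(est, psg, 40)
  expect_true(is.na(r$specificity))
  expect_true(is.na(r$auc))
})

test_that("the ROC sweep equals the Mann-Whitney formulation", {
  set.seed(64)
  for (trial in 1:200) {
    n <- sample(4:30, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(runif(n, 0, 10), sample(0:2, 1)))  # forces ties
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_mann_whitney(scores, labels), tolerance = 1e-12)
  }
})

test_that("the ROC sweep agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  got <- roc_curve(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("permuted screening labels give chance-level AUC", {
  set.seed(66)
  psg <- runif(20, 20, 95)
  aucs <- replicate(1000, {
    roc_curve(sample(psg), psg >= 60)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("correlation summaries behave on exact, shifted and independent data", {
  x <- c(60, 70, 80, 90, 55, 65)
  r1 <- correlation_summary(x, x)
  expect_equal(r1$r2, 1); expect_equal(r1$mean_diff, 0)
  r2 <- correlation_summary(x + 5, x)
  expect_equal(r2$r2, 1); expect_equal(r2$mean_diff, 5)
  set.seed(67)
  r3 <- correlation_summary(rnorm(100), rnorm(100))
  expect_lt(r3$r2, 0.1)
  expect_true(is.na(correlation_summary(rep(1, 5), 1:5)$r2))
  expect_error(correlation_summary(1:2, 1:2), class = "somnostage_argument_error")
})

test_that("leave-one-out cross validation tests every subject exactly once", {
  labels <- rep(c("W", "REM", "N1", "N2", "N3"), each = 10)
  cohort <- lapply(1:5, function(i) toy_subject(labels, seed = 70 + i))
  cv <- loocv(cohort, "s4")
  expect_equal(length(cv$folds), 5L)
  expect_equal(sort(vapply(cv$folds, `[[`, "", "subject")),
               sort(vapply(cohort, `[[`, "", "subject_id")))
  ## separable toy data: every fold perfect
  for (f in cv$folds) expect_equal(f$report$overall_accuracy, 100)
  expect_equal(cv$kappa_pooled, 1)

  ## shuffling the cohort leaves per-subject results unchanged
  cv2 <- loocv(rev(cohort), "s4")
  acc1 <- sapply(cv$folds, function(f) f$report$overall_accuracy)
  names(acc1) <- sapply(cv$folds, `[[`, "subject")
  acc2 <- sapply(cv2$folds, function(f) f$report$overall_accuracy)
  names(acc2) <- sapply(cv2$folds, `[[`, "subject")
  expect_equal(acc1[sort(names(acc1))], acc2[sort(names(acc2))])

  expect_error(loocv(cohort[1:2], "s2"), class = "somnostage_argument_error")
})

test_that("folds whose training set lacks a class are flagged and skipped", {
  ## N3 appears only in subject 1: its fold cannot be trained
  with_n3 <- toy_subject(rep(c("W", "REM", "N1", "N2", "N3"), each = 8), seed = 81)
  no_n3 <- lapply(2:4, function(i)
    toy_subject(rep(c("W", "REM", "N1", "N2"), each = 10), seed = 80 + i))
  cohort <- c(list(with_n3), no_n3)
  expect_warning(cv <- loocv(cohort, "s4"), "skipped")
  expect_equal(length(cv$folds), 3L)
  expect_equal(cv$skipped_folds, with_n3$subject_id)
})
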