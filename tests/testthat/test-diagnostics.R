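test_that("confusion matrices cross-tabulate and sideline unscorable calls", {
  truth <- rep(c("male", "female"), each = 5)
  perfect <- confusion(truth, truth, positive = "male")
  expect_equal(c(perfect$fp, perfect$fn), c(0, 0))
  expect_equal(c(perfect$tp, perfect$tn), c(5, 5))

  # the combined-index row: 91/5 correct/incorrect males, 101/7 females
  truth2 <- c(rep("male", 96), rep("female", 108))
  calls2 <- c(rep("male", 91), rep("female", 5), rep("female", 101),
              rep("male", 7))
  cm <- confusion(truth2, calls2, positive = "male")
  expect_equal(list(cm$tp, cm$fn, cm$tn, cm$fp), list(91L, 5L, 101L, 7L))

  allna <- confusion(truth, rep("unclassified", 10), positive = "male")
  expect_equal(allna$tp + allna$fp + allna$fn + allna$tn, 0)
  expect_equal(allna$n_excluded, 10)

  expect_error(confusion(truth, truth[-1], positive = "male"), "equal length")
})

test_that("accuracy and kappa match the published sex-cohort values", {
  gsd <- accuracy_kappa(tab_gsd())
  expect_equal(gsd$accuracy, 0.941, tolerance = 5e-4)
  expect_equal(gsd$kappa, 0.882, tolerance = 5e-4)
  sry <- accuracy_kappa(tab_sry())
  expect_equal(sry$kappa, 0.861, tolerance = 5e-4)

  ident <- confusion_from_counts(tp = 7, fp = 0, fn = 0, tn = 13)
  expect_equal(accuracy_kappa(ident)$kappa, 1)

  # independent labels: kappa near zero (permutation-style null)
  set.seed(12)
  a <- sample(c("x", "y"), 10000, replace = TRUE)
  b <- sample(c("x", "y"), 10000, replace = TRUE)
  expect_lt(abs(accuracy_kappa(confusion(a, b, "x"))$kappa), 0.05)

  degen <- confusion_from_counts(tp = 10, fp = 0, fn = 0, tn = 0)
  expect_false(accuracy_kappa(degen)$kappa_defined)
})

test_that("kappa is transpose-invariant and OR tracks the test polarity", {
  cm <- confusion_from_counts(tp = 40, fp = 9, fn = 6, tn = 70)
  tr <- confusion_from_counts(tp = 40, fp = 6, fn = 9, tn = 70)
  expect_equal(accuracy_kappa(cm)$kappa, accuracy_kappa(tr)$kappa)

  # relabelling which class is positive leaves the OR unchanged ...
  relabel <- confusion_from_counts(tp = 70, fp = 6, fn = 9, tn = 40)
  expect_equal(odds_ratio(cm)$or, odds_ratio(relabel)$or, tolerance = 1e-12)
  # ... while inverting the test's calls inverts it
  flipped <- confusion_from_counts(tp = 6, fp = 70, fn = 40, tn = 9)
  expect_equal(odds_ratio(cm)$or, 1 / odds_ratio(flipped)$or, tolerance = 1e-12)
})

test_that("odds ratios with Woolf intervals match the published rows", {
  sry <- odds_ratio(tab_sry())
  expect_equal(sry$or, 683, tolerance = 5e-4)
  expect_equal(sry$lo, 88, tolerance = 0.01)
  expect_equal(sry$hi, 5328, tolerance = 0.01)
  expect_lt(sry$p, 0.001)

  expect_equal(odds_ratio(tab_gsd())$or, 262.6, tolerance = 1e-3)

  sym <- confusion_from_counts(tp = 5, fp = 5, fn = 5, tn = 5)
  expect_equal(odds_ratio(sym)$or, 1)

  zero <- confusion_from_counts(tp = 5, fp = 0, fn = 5, tn = 5)
  expect_error(odds_ratio(zero), "zero cell")
  expect_true(odds_ratio(zero, haldane = TRUE)$corrected)
})

test_that("the rank AUC equals the all-pairs oracle and external checks", {
  scores <- c(1, 2, 3, 10, 11)
  labels <- c("pos", "pos", "pos", "neg", "neg")
  expect_equal(roc_auc(scores, labels, "pos", direction = "low")$auc, 1)

  brute_auc <- function(s, l, positive) {
    ps <- s[l == positive]; ns <- s[l != positive]
    g <- outer(ps, ns, function(a, b) (a < b) + 0.5 * (a == b))
    mean(g)  # low scores mark the positive class
  }
  set.seed(33)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n0 <- sample(3:40, 1)
    s <- c(round(stats::rnorm(n1, 0, 2), 1), round(stats::rnorm(n0, 1, 2), 1))
    l <- c(rep("pos", n1), rep("neg", n0))
    expect_equal(roc_auc(s, l, "pos", "low")$auc, brute_auc(s, l, "pos"),
                 tolerance = 1e-12)
  }

  # cross-checks against independent implementations
  s <- c(4.2, 3.1, 5.0, 2.2, 4.9, 3.8, 5.6, 2.9, 3.3, 6.0)
  l <- rep(c("pos", "neg"), 5)
  mine <- roc_auc(s, l, "pos", "low")
  w <- stats::wilcox.test(s[l == "neg"], s[l == "pos"])
  expect_equal(mine$auc, unname(w$statistic) / 25, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::roc(l, s, levels = c("neg", "pos"), direction = ">",
                    quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }

  expect_error(roc_auc(1:5, rep("pos", 5), "pos"), "both classes")
})

test_that("Youden search returns the midpoint cutoff the oracle finds", {
  scores <- c(1, 2, 3, 10, 11)
  labels <- c(rep("pos", 3), rep("neg", 2))
  opt <- youden_optimal_cutoff(scores, labels, "pos", direction = "low")
  expect_equal(opt$cutoff, 6.5)
  expect_equal(opt$j, 1)

  brute <- function(s, l, positive) {
    su <- sort(unique(s))
    cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
    js <- vapply(cand, function(ct) {
      sens <- mean(s[l == positive] <= ct)
      spec <- mean(s[l != positive] > ct)
      sens + spec - 1
    }, numeric(1))
    max(js)
  }
  set.seed(44)
  for (i in 1:20) {
    s <- round(stats::rnorm(30, 0, 2), 1)
    l <- sample(c("pos", "neg"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(l)) < 2) next
    expect_equal(youden_optimal_cutoff(s, l, "pos", "low")$j, brute(s, l, "pos"),
                 tolerance = 1e-12)
  }
})

test_that("Youden J from the trisomy operating points matches the reports", {
  # TTC3: sensitivity 12/13, specificity 26/27
  t21 <- sens_spec(confusion_from_counts(tp = 12, fn = 1, tn = 26, fp = 1))
  expect_equal(t21$youden_j, 0.886, tolerance = 5e-4)
  expect_equal(t21$sensitivity, 0.923, tolerance = 5e-4)
  expect_equal(t21$specificity, 0.963, tolerance = 5e-4)
  # RPL17: 8/9 and 31/34
  t18 <- sens_spec(confusion_from_counts(tp = 8, fn = 1, tn = 31, fp = 3))
  expect_equal(t18$youden_j, 0.801, tolerance = 5e-4)
  # implied accuracies and agreement
  expect_equal(accuracy_kappa(confusion_from_counts(12, 1, 1, 26))$accuracy,
               0.95, tolerance = 1e-9)
  ak18 <- accuracy_kappa(confusion_from_counts(8, 3, 1, 31))
  expect_equal(ak18$accuracy, 39 / 43, tolerance = 1e-9)
  expect_equal(ak18$kappa, 0.742, tolerance = 5e-3)  # printed as 0.742
  expect_equal(ak18$kappa, 490 / 662, tolerance = 1e-9)
})

test_that("ADO/FA arithmetic reproduces every printed per-locus rate", {
  mk <- function(n_carrier, miss, n_non, spur) {
    data.frame(embryo_id = sprintf("E%04d", seq_len(n_carrier + n_non)),
               locus = "L",
               present = rep(c(TRUE, FALSE), c(n_carrier, n_non)),
               detected = c(rep(c(FALSE, TRUE), c(miss, n_carrier - miss)),
                            rep(c(TRUE, FALSE), c(spur, n_non - spur))))
  }
  sry <- ado_fa_rates(mk(96, 13, 108, 1), locus = "L")
  expect_equal(round(100 * sry$ado, 1), 13.5)
  expect_equal(round(100 * sry$fa, 1), 0.5)      # 1/204
  dys <- ado_fa_rates(mk(96, 5, 108, 7), locus = "L")
  expect_equal(round(100 * dys$ado, 1), 5.2)
  expect_equal(round(100 * dys$fa, 1), 3.4)      # 7/204
  amel <- ado_fa_rates(mk(50, 1, 78, 8), locus = "L")
  expect_equal(round(100 * amel$ado, 1), 2.0)
  expect_equal(100 * amel$fa, 6.25)              # 8/128; printed as 6.3

  clean <- ado_fa_rates(mk(10, 0, 10, 0), locus = "L")
  expect_equal(c(clean$ado, clean$fa), c(0, 0))

  none <- ado_fa_rates(mk(0, 0, 10, 2), locus = "L")
  expect_false(none$ado_defined)
  expect_true(is.na(none$ado))
})

test_that("diagnostic summaries assemble all statistics coherently", {
  set.seed(55)
  truth <- rep(c("case", "control"), c(40, 60))
  score <- c(stats::rnorm(40, 1), stats::rnorm(60, 3))
  calls <- ifelse(score <= 2, "case", "control")
  ds <- diagnostic_summary(truth, calls, "case", scores = score,
                           direction = "low")
  expect_s3_class(ds, "diagnostic_summary")
  expect_equal(ds$youden_j, ds$sensitivity + ds$specificity - 1)
  expect_true(ds$auc$lo <= ds$auc$auc && ds$auc$auc <= ds$auc$hi)
  expect_output(print(ds), "accuracy")
})
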