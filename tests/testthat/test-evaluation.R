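test_that("precision-recall points enumerate distinct thresholds", {
  pr <- precision_recall_points(c(0.9, 0.8, 0.7), c(1, 0, 1))
  expect_equal(pr$threshold, c(0.9, 0.8, 0.7))
  expect_equal(pr$recall, c(0.5, 0.5, 1.0))
  expect_equal(pr$precision, c(1.0, 0.5, 2 / 3))

  # perfect separation reaches the (1, 1) corner
  pr <- precision_recall_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(pr$recall == 1 & pr$precision == 1))

  # all-identical scores collapse to a single point at the prevalence
  pr <- precision_recall_points(rep(0.4, 10), rep(c(1, 0), c(3, 7)))
  expect_equal(nrow(pr), 1)
  expect_equal(pr$recall, 1.0)
  expect_equal(pr$precision, 0.3)

  expect_error(precision_recall_points(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("average precision is the step-wise integral", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1.0 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
})

test_that("average precision equals a brute-force oracle on random data", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[sample(n, 1)] <- 1
    probs <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(average_precision(probs, y), ap_oracle(probs, y),
                 tolerance = 1e-12)
  }
})

test_that("average precision is invariant to monotone score transforms", {
  set.seed(13)
  probs <- runif(60)
  y <- rbinom(60, 1, 0.75)
  base <- average_precision(probs, y)
  expect_equal(average_precision(probs^3, y), base, tolerance = 1e-12)
  expect_equal(average_precision(plogis(7 * probs - 2), y), base,
               tolerance = 1e-12)
})

test_that("confusion matrices count and normalize correctly", {
  cm <- confusion_at_threshold(c(0.8, 0.6), c("SMAD3", "SMAD2"))
  expect_equal(unname(diag(cm$counts)), c(1L, 1L))
  expect_equal(unname(cm$recalls), c(1.0, 1.0))

  # probability exactly at the threshold goes to the positive class
  cm <- confusion_at_threshold(0.75, "SMAD3", threshold = 0.75)
  expect_equal(cm$counts["SMAD3", "SMAD3"], 1L)

  # counts are conserved and rows normalize, vs a direct tally
  set.seed(14)
  probs <- runif(40)
  labels <- sample(c("SMAD2", "SMAD3"), 40, TRUE)
  for (thr in c(0.25, 0.5, 0.75)) {
    cm <- confusion_at_threshold(probs, labels, thr)
    expect_equal(sum(cm$counts), 40)
    expect_equal(unname(rowSums(cm$normalized)), c(1, 1))
    expect_equal(cm$counts["SMAD2", "SMAD3"],
                 sum(labels == "SMAD2" & probs >= thr))
    expect_equal(cm$counts["SMAD3", "SMAD2"],
                 sum(labels == "SMAD3" & probs < thr))
  }
})

test_that("the ensemble-size ablation enumerates all subsets", {
  # hand-fixed member predictions, M = 3: check all 7 subsets by hand
  y <- c(1, 1, 0, 1, 0, 0)
  P <- cbind(c(.9, .8, .7, .6, .4, .2),
             c(.6, .9, .2, .7, .5, .1),
             c(.5, .4, .6, .9, .3, .2))
  tab <- smaddeconv:::ablate_matrix(P, y)
  expect_equal(tab$n_subsets, choose(3, 1:3))
  singles <- apply(P, 2, average_precision, labels = y)
  expect_equal(tab$mean_aupr[1], mean(singles))
  expect_equal(tab$sd_aupr[1], sd(singles))
  pairs <- combn(3, 2, function(s) average_precision(rowMeans(P[, s]), y))
  expect_equal(tab$mean_aupr[2], mean(pairs))
  expect_equal(tab$sd_aupr[2], sd(pairs))
  expect_equal(tab$mean_aupr[3], average_precision(rowMeans(P), y))
  expect_equal(tab$sd_aupr[3], 0)

  # on a real (tiny) ensemble the n = M row equals the full-ensemble AUPR
  fix <- tiny_ensemble()
  full <- ablate_ensemble_size(fix$ens, fix$enc)
  expect_equal(full$mean_aupr[nrow(full)],
               average_precision(predict_ensemble(fix$ens, fix$enc),
                                 fix$enc$labels))
  expect_error(smaddeconv:::ablate_matrix(matrix(0.5, 2, 13), c(0, 1)),
               "infeasible")
})

test_that("label-permutation null AUPR concentrates at the prevalence", {
  set.seed(15)
  n <- 400
  probs <- runif(n)
  y <- rep(c(1, 0), c(300, 100))
  auprs <- replicate(30, average_precision(probs, sample(y)))
  se <- sd(auprs) / sqrt(length(auprs))
  expect_lt(abs(mean(auprs) - 0.75), 3 * se + 0.01)
})

test_that("the GC class comparison is a Welch t-test", {
  # identical groups: zero mean difference, p = 1
  seqs <- c("ATGC", "GGCC", "AATT", "ATGC", "GGCC", "AATT")
  labels <- rep(c("SMAD2", "SMAD3"), each = 3)
  res <- gc_class_test(seqs, labels)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  # strongly separated GC distributions are detected
  set.seed(16)
  seqs <- c(vapply(1:200, function(i) random_seq(100, 0.7), ""),
            vapply(1:200, function(i) random_seq(100, 0.3), ""))
  labels <- rep(c("SMAD2", "SMAD3"), each = 200)
  res <- gc_class_test(seqs, labels)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$gc_mean_smad2, res$gc_mean_smad3)

  # 3 vs 3 values match the textbook Welch formula
  g2 <- c("GGCA", "GCAT", "GGGC")   # GC 0.75, 0.5, 1.0
  g3 <- c("GCAT", "ACAT", "GCTA")   # GC 0.5, 0.25, 0.5
  res <- gc_class_test(c(g2, g3), rep(c("SMAD2", "SMAD3"), each = 3))
  x2 <- c(0.75, 0.5, 1.0); x3 <- c(0.5, 0.25, 0.5)
  t_manual <- (mean(x2) - mean(x3)) /
    sqrt(var(x2) / 3 + var(x3) / 3)
  expect_equal(res$t_statistic, t_manual)

  # zero variance in both groups: flagged, not an error
  res <- gc_class_test(c("GC", "GC", "AT", "AT"),
                       c("SMAD2", "SMAD2", "SMAD3", "SMAD3"))
  expect_true(is.nan(res$p_value))
  expect_error(gc_class_test(c("GC", "AT"), c("SMAD2", "SMAD3")),
               "at least 2")
})

test_that("evaluation reports bundle AUPR and confusion consistently", {
  set.seed(17)
  probs <- runif(30)
  labels <- sample(c("SMAD2", "SMAD3"), 30, TRUE)
  ev <- evaluate_predictions(probs, labels)
  expect_s3_class(ev, "smad_eval")
  expect_equal(ev$aupr, average_precision(probs, labels))
  expect_equal(ev$confusion$counts,
               confusion_at_threshold(probs, labels, 0.75)$counts)
  expect_output(print(ev), "AUPR")
})
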