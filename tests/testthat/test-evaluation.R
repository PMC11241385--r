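test_that("confusion matrix equals a brute-force tally", {
  perfect <- confusionTable(rep(gradeLevels(), each = 4),
                            rep(gradeLevels(), each = 4))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(diag(perfect), c(Normal = 4L, Moderate = 4L,
                                Intensive = 4L))
  single <- confusionTable("Normal", "Intensive")
  expect_equal(single["Normal", "Intensive"], 1L)
  expect_equal(sum(single), 1L)
  set.seed(61)
  for (r in 1:100) {
    n <- sample(3:20, 1)
    truth <- sample(gradeLevels(), n, TRUE)
    pred <- sample(gradeLevels(), n, TRUE)
    expect_identical(confusionTable(truth, pred),
                     naiveConfusion(truth, pred, gradeLevels()))
  }
  expect_error(confusionTable("Normal", "Weird"), "unknown label")
})

test_that("one-vs-rest counts partition the grand total", {
  diagM <- confusionTable(rep(gradeLevels(), 3), rep(gradeLevels(), 3))
  for (cl in gradeLevels()) {
    ct <- ovrCounts(diagM, cl)
    expect_equal(unname(ct[c("FP", "FN")]), c(0L, 0L))
  }
  set.seed(62)
  for (r in 1:20) {
    m <- matrix(sample(0:9, 9, TRUE), 3,
                dimnames = list(truth = gradeLevels(),
                                predicted = gradeLevels()))
    for (cl in 1:3) {
      ct <- ovrCounts(m, cl)
      expect_equal(sum(ct), sum(m))
      expect_equal(unname(ct["TP"] + ct["FN"]), sum(m[cl, ]))
      expect_equal(unname(ct["TP"] + ct["FP"]), sum(m[, cl]))
    }
  }
})

test_that("metric formulas match their definitions", {
  ## harmonic mean of equals is the value itself
  expect_equal(fMeasure(0.8, 0.8), 0.8)
  expect_equal(fMeasure(0.90, 0.925), 2 * 0.90 * 0.925 / (0.90 + 0.925))
  ## harmonic <= geometric <= arithmetic for random precision/recall
  set.seed(63)
  for (r in 1:50) {
    p <- runif(1, 0.01, 1); s <- runif(1, 0.01, 1)
    f <- fMeasure(p, s)
    expect_lte(f, sqrt(p * s) + 1e-12)
    expect_lte(sqrt(p * s), (p + s) / 2 + 1e-12)
  }
})

test_that("zero denominators yield 0 with a warning", {
  ## nothing predicted Normal -> precision denominator 0
  m <- confusionTable(c("Normal", "Moderate"), c("Moderate", "Moderate"))
  expect_warning(cm <- classMetrics(m), "zero denominator")
  expect_equal(cm["Normal", "precision"], 0)
  expect_true(all(as.matrix(cm) >= 0 & as.matrix(cm) <= 1))
})

test_that("rank-sum AUC equals exhaustive pair counting", {
  ## perfect separation
  sc <- c(0.9, 0.8, 0.2, 0.1)
  truth <- c("Normal", "Normal", "Moderate", "Intensive")
  expect_equal(rocAucOvr(sc, truth, "Normal"), 1)
  ## all-tied scores give 0.5 under midranks
  expect_equal(rocAucOvr(rep(0.5, 6),
                         rep(c("Normal", "Moderate"), 3), "Normal"), 0.5)
  set.seed(64)
  for (r in 1:100) {
    n <- sample(8:40, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    truth <- sample(c("Normal", "Moderate"), n, TRUE, prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    expect_equal(rocAucOvr(scores, truth, "Normal"),
                 allPairsAuc(scores, truth == "Normal"),
                 tolerance = 1e-12)
  }
  expect_warning(a <- rocAucOvr(runif(3), rep("Moderate", 3), "Normal"),
                 "absent")
  expect_true(is.na(a))
})

test_that("rank-sum AUC agrees with an independent library route", {
  skip_if_not_installed("pROC")
  set.seed(65)
  scores <- runif(60)
  truth <- sample(c("Normal", "Moderate"), 60, TRUE)
  ours <- rocAucOvr(scores, truth, "Normal")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth == "Normal"), predictor = scores,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("macro summary is the unweighted mean across classes", {
  pc <- data.frame(precision = c(0.90, 0.85, 0.88),
                   sensitivity = c(0.925, 0.875, 0.875))
  ov <- macroSummary(pc)
  expect_equal(unname(ov["precision"]), mean(c(0.90, 0.85, 0.88)))
  expect_equal(unname(ov["sensitivity"]), mean(c(0.925, 0.875, 0.875)))
  same <- data.frame(accuracy = rep(0.7, 3))
  expect_equal(unname(macroSummary(same)["accuracy"]), 0.7)
})

test_that("evaluation reports assemble counts, metrics and AUC", {
  set.seed(66)
  truth <- sample(gradeLevels(), 30, TRUE)
  probs <- matrix(runif(90), 30, 3,
                  dimnames = list(NULL, gradeLevels()))
  probs <- probs / rowSums(probs)
  pred <- gradeLevels()[max.col(probs, ties.method = "first")]
  rep <- suppressWarnings(evaluationReport(truth, pred, probs))
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(sum(rep@confusion), 30)
  expect_equal(rownames(rep@perClass), gradeLevels())
  expect_true("auc" %in% colnames(rep@perClass))
  expect_equal(unname(rep@overall),
               unname(colMeans(as.matrix(rep@perClass))))
})

test_that("cross-validation aggregation matches hand arithmetic", {
  mkReport <- function(acc) {
    pc <- data.frame(sensitivity = acc, accuracy = acc,
                     row.names = gradeLevels())
    new("EvaluationReport",
        confusion = matrix(0L, 3, 3,
                           dimnames = list(truth = gradeLevels(),
                                           predicted = gradeLevels())),
        perClass = pc, overall = macroSummary(pc))
  }
  same <- cvAggregate(list(mkReport(c(0.8, 0.8, 0.8)),
                           mkReport(c(0.8, 0.8, 0.8))))
  expect_true(all(as.matrix(same$sd) == 0))
  two <- cvAggregate(list(mkReport(c(0.80, 0.90, 0.70)),
                          mkReport(c(0.90, 0.80, 0.90))))
  expect_equal(two$mean["Normal", "accuracy"], 0.85)
  expect_equal(two$sd["Normal", "accuracy"], sd(c(0.80, 0.90)))
  ## the Overall mean is the mean of per-class means, and its sd is the
  ## across-fold sd of the fold macro values
  expect_equal(two$mean["Overall", "accuracy"],
               mean(c(0.85, 0.85, 0.80)))
  expect_equal(two$sd["Overall", "accuracy"],
               sd(c(mean(c(0.80, 0.90, 0.70)), mean(c(0.90, 0.80, 0.90)))))
  expect_error(cvAggregate(list(mkReport(c(0.8, 0.8, 0.8)))), "2 folds")
})

test_that("micro accuracy is invariant under class permutation", {
  set.seed(67)
  m <- matrix(sample(0:9, 9, TRUE), 3,
              dimnames = list(truth = gradeLevels(),
                              predicted = gradeLevels()))
  perm <- c(3, 1, 2)
  mp <- m[perm, perm]
  expect_equal(sum(diag(m)) / sum(m), sum(diag(mp)) / sum(mp))
})
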