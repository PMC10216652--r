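test_that("one-vs-rest confusion counts match hand enumeration", {
  # y_true=[0,0,1,1,2], y_pred=[0,1,1,1,2]: class 1 -> TP=2 FP=1 FN=0 TN=2
  cc <- confusionCounts(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2), 3,
                        zeroBased = TRUE)
  expect_equal(unname(cc@counts["class2", ]), c(2L, 1L, 0L, 2L))
  expect_equal(unname(cc@counts["class1", ]), c(1L, 0L, 1L, 3L))
  # per-class counts always sum to n
  expect_true(all(rowSums(cc@counts) == 5L))
  # perfect prediction: no FP/FN anywhere
  cp <- confusionCounts(1:3, 1:3, 3)
  expect_true(all(cp@counts[, c("FP", "FN")] == 0L))
  expect_error(confusionCounts(1:3, 1:2, 3), "equal length")
  expect_error(confusionCounts(1:3, c(1, 2, 9), 3), "out of range")
})

test_that("metrics reproduce the hand-computed example exactly", {
  cc <- new("ConfusionCounts",
            counts = matrix(c(3L, 1L, 2L, 4L), 1,
                            dimnames = list("class1",
                                            c("TP", "FP", "FN", "TN"))),
            nSamples = 10L)
  r <- classificationMetrics(cc)
  pc <- perClassMetrics(r)
  expect_equal(pc$accuracy, 0.7)
  expect_equal(pc$precision, 0.75)
  expect_equal(pc$recall, 0.6)
  expect_equal(pc$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(pc$f1, 3), 0.667)
})

test_that("perfect predictions score 1 everywhere, degenerate counts 0", {
  r <- evaluatePredictions(rep(1:3, 5), rep(1:3, 5), 3)
  expect_equal(unname(macroMetrics(r)), rep(1, 4))
  expect_equal(r@accuracy, 1)
  # TP = FP = 0: precision 0 by convention, with a warning, never NaN
  cc <- new("ConfusionCounts",
            counts = matrix(c(0L, 0L, 2L, 8L), 1,
                            dimnames = list("class1",
                                            c("TP", "FP", "FN", "TN"))),
            nSamples = 10L)
  # several one-vs-rest ratios degenerate at once; each warns
  expect_warning(expect_warning(classificationMetrics(cc),
                                "zero denominator"))
  r0 <- suppressWarnings(classificationMetrics(cc))
  expect_equal(perClassMetrics(r0)$precision, 0)
  expect_equal(perClassMetrics(r0)$f1, 0)
  expect_false(any(is.nan(unlist(perClassMetrics(r0)))))
})

test_that("macro metrics are invariant to class relabeling", {
  set.seed(1)
  yt <- sample(1:3, 200, replace = TRUE)
  yp <- ifelse(runif(200) < 0.7, yt, sample(1:3, 200, replace = TRUE))
  r1 <- evaluatePredictions(yt, yp, 3)
  perm <- c(3L, 1L, 2L)
  r2 <- evaluatePredictions(perm[yt], perm[yp], 3)
  expect_equal(macroMetrics(r1), macroMetrics(r2), tolerance = 1e-12)
  # pooled accuracy equals the fraction of exact matches
  expect_equal(r1@accuracy, mean(yt == yp))
})

test_that("record-wise folds partition 3064 records into near-equal tests", {
  plan <- crossvalSplit(seq_len(3064), k = 10, seed = 1)
  sizes <- vapply(cvFolds(plan), function(f) length(f$test), integer(1))
  expect_true(all(sizes %in% c(306L, 307L)))
  tests <- unlist(lapply(cvFolds(plan), `[[`, "test"))
  expect_equal(sort(tests), seq_len(3064))          # disjoint + exhaustive
  for (f in cvFolds(plan))
    expect_length(intersect(f$train, f$test), 0L)
  # determinism
  plan2 <- crossvalSplit(seq_len(3064), k = 10, seed = 1)
  expect_identical(cvFolds(plan), cvFolds(plan2))
})

test_that("subject-wise folds never split a subject across test sets", {
  subj <- c("A", "A", "A", "B", "B", "C", "C", "D", "E", "F")
  plan <- crossvalSplit(seq_along(subj), subj, k = 3, mode = "subject",
                        seed = 2)
  for (f in cvFolds(plan)) {
    testSubj <- subj[f$test]
    trainSubj <- subj[f$train]
    expect_length(intersect(testSubj, trainSubj), 0L)
  }
  tests <- unlist(lapply(cvFolds(plan), `[[`, "test"))
  expect_equal(sort(tests), seq_along(subj))
  expect_error(crossvalSplit(1:5, k = 10), "exceeds")
  expect_error(crossvalSplit(1:10, subj, k = 7, mode = "subject"), "exceeds")
  expect_error(crossvalSplit(1:10, NULL, k = 2, mode = "subject"),
               "requires subjectIds")
})
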