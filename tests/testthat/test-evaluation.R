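test_that("confusion matrix counts the four cells correctly", {
  cm <- confusionMatrixFromLabels(rep(1, 10), rep(1, 10))
  expect_equal(confusionCounts(cm), c(TP = 10L, TN = 0L, FP = 0L, FN = 0L))
  yt <- c(rep(1, 6), rep(-1, 4))
  cm2 <- confusionMatrixFromLabels(yt, -yt)
  expect_equal(confusionCounts(cm2), c(TP = 0L, TN = 0L, FP = 4L, FN = 6L))
  set.seed(1)
  a <- sample(c(-1, 1), 50, TRUE); b <- sample(c(-1, 1), 50, TRUE)
  cm3 <- confusionCounts(confusionMatrixFromLabels(a, b))
  brute <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in 1:50) {
    cell <- if (a[i] == 1 && b[i] == 1) "TP" else if (a[i] == -1 && b[i] == -1)
      "TN" else if (a[i] == -1 && b[i] == 1) "FP" else "FN"
    brute[cell] <- brute[cell] + 1L
  }
  expect_equal(cm3, brute)
  expect_error(confusionMatrixFromLabels(c(1, 0), c(1, 1)), "labels")
  expect_error(confusionMatrixFromLabels(c(1, 1), c(1, 1, 1)), "length")
})

test_that("diagnostic metrics implement the five percentage formulas", {
  sym <- methods::new("ConfusionMatrix", TP = 25L, TN = 25L, FP = 25L, FN = 25L)
  expect_equal(unname(diagnosticMetrics(sym)), rep(50, 5))
  m <- diagnosticMetrics(methods::new("ConfusionMatrix",
                                      TP = 50L, TN = 40L, FP = 10L, FN = 0L))
  expect_equal(unname(m), c(90, 100, 80, 100 * 50 / 60, 100))
  # FN = 0 forces SE = 100 and NPV = 100 whenever TN > 0
  expect_equal(unname(m[c("SE", "NPV")]), c(100, 100))
  # zero denominators are NA, never 0 or 100
  noNeg <- diagnosticMetrics(methods::new("ConfusionMatrix",
                                          TP = 5L, TN = 0L, FP = 0L, FN = 0L))
  expect_true(is.na(noNeg["SP"]))
  expect_true(is.na(noNeg["NPV"]))
  expect_error(diagnosticMetrics(methods::new("ConfusionMatrix",
                                              TP = 0L, TN = 0L, FP = 0L, FN = 0L)),
               "empty")
})

test_that("accuracy is the prevalence-weighted mean of SE and SP", {
  set.seed(2)
  for (rep in 1:10) {
    cm <- methods::new("ConfusionMatrix", TP = sample(0:30, 1), TN = sample(0:30, 1),
                       FP = sample(1:30, 1), FN = sample(1:30, 1))
    met <- diagnosticMetrics(cm)
    P <- cm@TP + cm@FN; N <- cm@TN + cm@FP
    expect_equal(met[["AC"]] * (P + N), met[["SE"]] * P + met[["SP"]] * N)
  }
})

test_that("random over-sampling balances a 70/100 dataset with 30 replicas", {
  X <- matrix(seq_len(170 * 2), 170)
  y <- c(rep(1, 70), rep(-1, 100))
  os <- randomOversample(X, y, seed = 3)
  expect_length(os$replicatedFrom, 30L)
  expect_true(all(os$replicatedFrom <= 70))
  expect_equal(sum(os$labels == 1), 100)
  expect_equal(sum(os$labels == -1), 100)
  expect_identical(os$features[1:170, ], X)
  # replicas are copies of minority rows
  expect_identical(os$features[171:200, ], X[os$replicatedFrom, ])
  # balanced input untouched; forced replication with a single minority row
  bal <- randomOversample(X[1:140, ], rep(c(1, -1), each = 70), seed = 3)
  expect_length(bal$replicatedFrom, 0L)
  tiny <- randomOversample(matrix(1:12, 6), c(1, rep(-1, 5)), seed = 4)
  expect_equal(tiny$replicatedFrom, rep(1L, 4))
  expect_error(randomOversample(X, rep(1, 170)), "both classes")
  # deterministic under a fixed seed
  expect_identical(randomOversample(X, y, seed = 9)$replicatedFrom,
                   randomOversample(X, y, seed = 9)$replicatedFrom)
})

test_that("stratified k-fold assignments satisfy the size invariants", {
  y <- c(rep(1, 40), rep(-1, 60))
  f <- kfoldSplit(y, 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  expect_equal(as.integer(table(f[y == 1])), rep(4L, 10))
  expect_equal(as.integer(table(f[y == -1])), rep(6L, 10))
  expect_length(f, 100L)
  # uneven n: fold sizes differ by at most one, per class and overall
  y2 <- c(rep(1, 41), rep(-1, 62))
  f2 <- kfoldSplit(y2, 10, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  expect_lte(diff(range(table(f2[y2 == 1]))), 1)
  f3 <- kfoldSplit(y2, 10, seed = 2, stratified = FALSE)
  expect_lte(diff(range(table(f3))), 1)
  expect_error(kfoldSplit(y, 101, seed = 1), "k must")
  expect_identical(kfoldSplit(y, 10, seed = 5), kfoldSplit(y, 10, seed = 5))
})

test_that("cross-validation recovers perfectly separable features", {
  set.seed(4)
  X <- cbind(rep(c(2, -2), each = 60) + rnorm(120, sd = 0.1),
             matrix(rnorm(240), 120))
  y <- sign(X[, 1])
  for (kind in c("gab", "knn", "svm")) {
    cv <- crossValidate(X, y, kind, k = 10, seed = 1,
                        classifierArgs = if (kind == "gab") list(M = 10) else list())
    expect_equal(unname(cv$metrics["AC"]), 100)
    tot <- sum(confusionCounts(cv$confusion))
    expect_equal(tot, 120)
  }
})

test_that("cross-validation is deterministic and pools fold confusions", {
  set.seed(5)
  X <- matrix(rnorm(80 * 5), 80)
  y <- rep(c(1, -1), 40)
  a <- crossValidate(X, y, "gab", k = 5, seed = 3, classifierArgs = list(M = 5))
  b <- crossValidate(X, y, "gab", k = 5, seed = 3, classifierArgs = list(M = 5))
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$metrics, b$metrics)
  pooled <- Reduce(`+`, lapply(a$perFold, function(f) f$confusion))
  expect_equal(unname(pooled), unname(confusionCounts(a$confusion)))
  expect_equal(sum(pooled), 80)
})

test_that("replicate-first over-samples before splitting, default mode within folds", {
  set.seed(6)
  X <- matrix(rnorm(60 * 3), 60)
  y <- c(rep(1, 20), rep(-1, 40))
  cvDefault <- crossValidate(X, y, "knn", k = 5, seed = 2)
  expect_equal(sum(confusionCounts(cvDefault$confusion)), 60)
  cvFirst <- crossValidate(X, y, "knn", k = 5, seed = 2, replicateFirst = TRUE)
  # the replicated rows are evaluated too when balancing precedes the split
  expect_equal(sum(confusionCounts(cvFirst$confusion)), 80)
  # test folds are disjoint from training folds (the leakage guard of the
  # default mode: over-sampling only ever draws from training indices)
  f <- kfoldSplit(y, 5, seed = 2)
  for (k in 1:5) expect_length(intersect(which(f == k), which(f != k)), 0L)
})
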