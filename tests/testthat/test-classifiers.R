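# brute-force WLS stump search used as the independent oracle
bruteStump <- function(X, y, w) {
  best <- list(err = sum(w * (y - sum(w * y) / sum(w))^2))
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (thr in (head(xs, -1) + tail(xs, -1)) / 2) {
      L <- X[, j] < thr
      a <- sum(w[L] * y[L]) / sum(w[L])
      b <- sum(w[!L] * y[!L]) / sum(w[!L])
      err <- sum(w * (y - ifelse(L, a, b))^2)
      if (err < best$err - 1e-12) best <- list(err = err, j = j, thr = thr)
    }
  }
  best
}

stumpError <- function(st, X, y, w) {
  f <- ifelse(X[, st@featureIndex] < st@threshold, st@leftValue, st@rightValue)
  sum(w * (y - f)^2)
}

test_that("the WLS stump solves tiny problems exactly", {
  st <- fitStumpWLS(matrix(c(0, 1), 2), c(-1, 1), c(0.5, 0.5))
  expect_gt(st@threshold, 0); expect_lt(st@threshold, 1)
  expect_equal(st@leftValue, -1)
  expect_equal(st@rightValue, 1)
  allPos <- fitStumpWLS(matrix(c(0, 1, 2), 3), c(1, 1, 1), rep(1 / 3, 3))
  expect_equal(allPos@leftValue, 1)
  expect_equal(allPos@rightValue, 1)
  # identical rows degenerate to the weighted mean label
  deg <- fitStumpWLS(matrix(1, 4, 2), c(1, 1, -1, 1), rep(0.25, 4))
  expect_equal(deg@leftValue, 0.5)
  expect_equal(deg@rightValue, 0.5)
})

test_that("the stump search matches exhaustive brute force on random data", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    X <- matrix(sample(0:6, n * 3, TRUE), n, 3)
    y <- sample(c(-1, 1), n, TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    w <- runif(n); w <- w / sum(w)
    st <- fitStumpWLS(X, y, w)
    expect_equal(stumpError(st, X, y, w), bruteStump(X, y, w)$err,
                 tolerance = 1e-10)
  }
})

test_that("Gentle AdaBoost reproduces the boosting loop exactly", {
  set.seed(7)
  X <- matrix(rnorm(30), 15, 2)
  y <- sample(c(-1, 1), 15, TRUE); y[1:2] <- c(-1, 1)
  model <- gabTrain(X, y, M = 2)
  # round 1: stump on uniform weights
  w1 <- rep(1 / 15, 15)
  s1 <- fitStumpWLS(X, y, w1)
  expect_equal(model@stumps[[1]], s1)
  # weight update per the algorithm, then renormalization to sum 1
  f1 <- ifelse(X[, s1@featureIndex] < s1@threshold, s1@leftValue, s1@rightValue)
  w2 <- w1 * exp(-y * f1)
  w2 <- w2 / sum(w2)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_equal(model@stumps[[2]], fitStumpWLS(X, y, w2))
})

test_that("one round separates 1-D separable data; M = 1 equals a single stump", {
  set.seed(8)
  x <- c(runif(10, -2, -0.1), runif(10, 0.1, 2))
  y <- ifelse(x > 0, 1, -1)
  X <- matrix(x, 20)
  model <- gabTrain(X, y, M = 1)
  expect_equal(gabPredict(model, X)$labels, y)
  st <- fitStumpWLS(X, y, rep(1 / 20, 20))
  expect_equal(sign(gabPredict(model, X)$scores),
               sign(ifelse(x < st@threshold, st@leftValue, st@rightValue)))
})

test_that("the exponential loss is non-increasing across boosting rounds", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3)
  y <- sample(c(-1, 1), 20, TRUE); y[1:2] <- c(-1, 1)
  model <- gabTrain(X, y, M = 12)
  Fm <- rep(0, 20)
  losses <- vapply(model@stumps, function(st) {
    Fm <<- Fm + ifelse(X[, st@featureIndex] < st@threshold,
                       st@leftValue, st@rightValue)
    mean(exp(-y * Fm))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("GAB prediction contract: signs, ties and dimension checks", {
  st <- methods::new("Stump", featureIndex = 1L, threshold = 0.5,
                     leftValue = -1, rightValue = 1)
  one <- methods::new("GABEnsemble", stumps = list(st), M = 1L,
                      featureCount = 1L)
  X <- matrix(c(0, 1), 2)
  expect_equal(gabPredict(one, X)$labels, c(-1, 1))
  five <- methods::new("GABEnsemble", stumps = rep(list(st), 5), M = 5L,
                       featureCount = 1L)
  expect_equal(gabPredict(five, X)$labels, gabPredict(one, X)$labels)
  expect_equal(gabPredict(five, X)$scores, 5 * gabPredict(one, X)$scores)
  expect_equal(predictLabels(one, X), c(-1, 1))
  expect_error(gabPredict(one, matrix(0, 2, 3)), "dimension mismatch")
  # zero score maps to +1
  zero <- methods::new("Stump", featureIndex = 1L, threshold = 0.5,
                       leftValue = 0, rightValue = 0)
  zens <- methods::new("GABEnsemble", stumps = list(zero), M = 1L,
                       featureCount = 1L)
  expect_equal(gabPredict(zens, X)$labels, c(1, 1))
})

test_that("single-class training warns and returns a constant ensemble", {
  expect_warning(m <- gabTrain(matrix(rnorm(10), 5), rep(1, 5), M = 10),
                 "single-class")
  expect_equal(m@M, 1L)
  expect_equal(predictLabels(m, matrix(rnorm(6), 3, 2)), rep(1, 3))
})

test_that("Euclidean distance follows the coordinate-wise formula", {
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(1:7, 1:7), 0)
  set.seed(10)
  x <- rnorm(10); y <- rnorm(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (x[i] - y[i])^2
  expect_equal(euclideanDistance(x, y), sqrt(acc))
  expect_error(euclideanDistance(1:3, 1:4), "lengths differ")
})

test_that("kNN majority vote, tie rules and limit cases", {
  X <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5), c(10, 10))
  y <- c(1, 1, -1, -1, -1)
  expect_equal(knnPredict(knnModel(X, y, k = 1), c(0, 0)), 1)
  expect_equal(knnPredict(knnModel(X, y, k = 3), c(0.05, 0)), 1)   # votes +1,+1,-1
  # k = n: global majority regardless of query
  expect_equal(knnPredict(knnModel(X, y, k = 5), c(0, 0)), -1)
  # distance tie at the k-th position resolved by lower training index
  Xt <- rbind(c(0, 1), c(0, -1), c(0, 1))
  mt <- knnModel(Xt, c(1, -1, -1), k = 2)
  # neighbours of origin-adjacent query: rows 1 and 2 tie after the nearest;
  # with k = 2 the vote is (row1, row2) = (+1, -1), tie -> nearest label
  expect_equal(knnPredict(mt, c(0, 0.9)), 1)
  # 1-NN self-prediction is perfect on distinct rows
  set.seed(11)
  Xs <- matrix(rnorm(40), 10, 4)
  ys <- sample(c(-1, 1), 10, TRUE)
  expect_equal(knnPredict(knnModel(Xs, ys, k = 1), Xs), ys)
  expect_error(knnModel(matrix(1, 2, 2), c(1, -1), k = 3), "k must be")
  expect_error(knnModel(matrix(c(1, NA, 2, 3), 2), c(1, -1), 1), "missing")
})

test_that("RBF SVM separates clouds and honours the decision contract", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40), 20) + 5, matrix(rnorm(40), 20) - 5)
  y <- rep(c(1, -1), each = 20)
  m <- svmTrainRBF(X, y)
  expect_equal(predictLabels(m, X), y)
  expect_true(all(is.finite(decisionScores(m, X))))
  # duplicating every sample leaves the decision unchanged on a probe grid
  m2 <- svmTrainRBF(rbind(X, X), c(y, y), gamma = m@gamma)
  probe <- as.matrix(expand.grid(seq(-6, 6, 3), seq(-6, 6, 3)))
  expect_equal(predictLabels(m, probe), predictLabels(m2, probe))
  # heavy regularization cannot beat the unregularized fit on training data
  mW <- svmTrainRBF(X, y, C = 1e-6)
  expect_lte(mean(predictLabels(mW, X) == y), mean(predictLabels(m, X) == y))
  # appending a zero-variance feature changes nothing
  m3 <- svmTrainRBF(cbind(X, 0), y, gamma = m@gamma)
  expect_equal(predictLabels(m3, cbind(probe, 0)), predictLabels(m, probe))
  expect_error(svmTrainRBF(X, rep(1, 40)), "both classes")
  expect_error(svmPredictLabels(m, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("all three classifiers share the predict contract on separable data", {
  set.seed(13)
  X <- matrix(rnorm(60), 30, 2)
  y <- ifelse(X[, 1] > 0, 1, -1)
  X[, 1] <- X[, 1] + 2 * y
  for (kind in c("gab", "knn", "svm")) {
    model <- dermaCAD:::.trainClassifier(kind, X, y,
                                         if (kind == "knn") list(k = 1L) else list())
    expect_true(all(predictLabels(model, X) %in% c(-1, 1)))
    expect_equal(mean(predictLabels(model, X) == y), 1)
  }
})
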