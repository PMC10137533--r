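## ---------------------------------------------------------------------------
## Gentle AdaBoost with weighted-least-squares regression stumps
## ---------------------------------------------------------------------------

## Exhaustive weighted-least-squares stump search over presorted features.
## For labels y in {-1, +1} and weights w, the WLS-optimal responses in each
## region are the weighted means of y there, and minimizing the weighted
## squared error is equivalent to maximizing Sl^2/Wl + Sr^2/Wr where Sl, Wl
## are the weighted label sum and weight mass left of the cut.
.fitStumpSorted <- function(Xs, ord, y, w, n, F) {
  wy <- w * y
  sumW <- sum(w)
  sumS <- sum(wy)
  meanY <- sumS / sumW
  if (n < 2L)
    return(methods::new("Stump", featureIndex = 1L, threshold = -Inf,
                        leftValue = .clamp(meanY, -1, 1),
                        rightValue = .clamp(meanY, -1, 1)))
  W <- matrix(w[ord], n, F)
  WY <- matrix(wy[ord], n, F)
  cumW <- .colCumsum(W)[seq_len(n - 1L), , drop = FALSE]
  cumS <- .colCumsum(WY)[seq_len(n - 1L), , drop = FALSE]
  Wr <- sumW - cumW
  Sr <- sumS - cumS
  gain <- ifelse(cumW > 0, cumS^2 / cumW, 0) + ifelse(Wr > 0, Sr^2 / Wr, 0)
  valid <- Xs[-1L, , drop = FALSE] > Xs[-n, , drop = FALSE]
  gain[!valid] <- -Inf
  best <- which.max(gain)          # column-major: lowest threshold, then feature
  baseline <- sumS^2 / sumW
  if (!length(best) || gain[best] <= baseline + 1e-12)
    return(methods::new("Stump", featureIndex = 1L, threshold = -Inf,
                        leftValue = .clamp(meanY, -1, 1),
                        rightValue = .clamp(meanY, -1, 1)))
  t <- ((best - 1L) %% (n - 1L)) + 1L
  j <- ((best - 1L) %/% (n - 1L)) + 1L
  thr <- (Xs[t, j] + Xs[t + 1L, j]) / 2
  a <- if (cumW[t, j] > 0) cumS[t, j] / cumW[t, j] else meanY
  b <- if (Wr[t, j] > 0) Sr[t, j] / Wr[t, j] else meanY
  methods::new("Stump", featureIndex = as.integer(j), threshold = thr,
               leftValue = .clamp(a, -1, 1), rightValue = .clamp(b, -1, 1))
}

.sortFeatures <- function(X) {
  n <- nrow(X); F <- ncol(X)
  ord <- matrix(0L, n, F)
  for (j in seq_len(F)) ord[, j] <- order(X[, j])
  Xs <- matrix(X[as.vector(ord) + rep((seq_len(F) - 1L) * n, each = n)], n, F)
  list(ord = ord, Xs = Xs)
}

#' Fit a regression stump by weighted least squares
#'
#' Searches all (feature, threshold-between-consecutive-sorted-values)
#' candidates for the stump minimizing the weighted squared error
#' sum_i w_i (y_i - f(x_i))^2; the response on each side of the cut is the
#' weighted mean of the labels there, the weighted class-probability
#' difference P_w(y = +1) - P_w(y = -1) of the region. Ties are broken by
#' lowest feature index, then lowest threshold. If no split improves on the
#' constant fit (e.g. all rows identical) a degenerate stump with both
#' responses equal to the weighted mean label is returned.
#'
#' @param X samples x features numeric matrix (>= 2 rows).
#' @param y labels in {-1, +1}.
#' @param w non-negative weights summing to 1.
#' @return a \linkS4class{Stump}.
#' @export
fitStumpWLS <- function(X, y, w) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least two samples")
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  s <- .sortFeatures(X)
  .fitStumpSorted(s$Xs, s$ord, y, w, nrow(X), ncol(X))
}

.stumpResponse <- function(stump, X) {
  ifelse(X[, stump@featureIndex] < stump@threshold,
         stump@leftValue, stump@rightValue)
}

#' Train a Gentle AdaBoost ensemble
#'
#' Boosting of weighted-least-squares regression stumps: weights start at
#' 1/N; each round fits a stump on the current weights, adds its response to
#' the ensemble score, reweights with w_i <- w_i exp(-y_i f_m(x_i)) and
#' renormalizes so the weights sum to 1.
#'
#' @param X samples x features numeric matrix.
#' @param y labels in {-1, +1}.
#' @param M boosting rounds (default 100).
#' @return a \linkS4class{GABEnsemble}.
#' @export
gabTrain <- function(X, y, M = 100L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  n <- nrow(X)
  if (length(unique(y)) < 2L) {
    warning("single-class training labels: returning a constant ensemble")
    stump <- methods::new("Stump", featureIndex = 1L, threshold = -Inf,
                          leftValue = y[1], rightValue = y[1])
    return(methods::new("GABEnsemble", stumps = list(stump), M = 1L,
                        featureCount = ncol(X)))
  }
  s <- .sortFeatures(X)
  w <- rep(1 / n, n)
  stumps <- vector("list", M)
  for (m in seq_len(M)) {
    stump <- .fitStumpSorted(s$Xs, s$ord, y, w, n, ncol(X))
    stumps[[m]] <- stump
    f <- .stumpResponse(stump, X)
    w <- w * exp(-y * f)
    w <- w / sum(w)
  }
  methods::new("GABEnsemble", stumps = stumps, M = M,
               featureCount = ncol(X))
}

#' Predict with a Gentle AdaBoost ensemble
#'
#' @param model a \linkS4class{GABEnsemble}.
#' @param X samples x features matrix with the training dimensionality.
#' @return list with \code{labels} (sign of the score, 0 mapping to +1) and
#'   \code{scores} (summed stump responses).
#' @export
gabPredict <- function(model, X) {
  stopifnot(is(model, "GABEnsemble"))
  X <- .asMatrix(X, model@featureCount)
  scores <- rep(0, nrow(X))
  for (stump in model@stumps) scores <- scores + .stumpResponse(stump, X)
  list(labels = ifelse(scores >= 0, 1, -1), scores = scores)
}

setMethod("predictLabels", "GABEnsemble", function(object, newdata)
  gabPredict(object, newdata)$labels)

setMethod("decisionScores", "GABEnsemble", function(object, newdata)
  gabPredict(object, newdata)$scores)

## ---------------------------------------------------------------------------
## k-nearest neighbours
## ---------------------------------------------------------------------------

#' Euclidean distance between two feature vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar, zero iff x equals y.
#' @export
euclideanDistance <- function(x, y) {
  if (length(x) != length(y)) stop("vector lengths differ")
  sqrt(sum((x - y)^2))
}

#' Construct a k-nearest-neighbour model
#'
#' Stores the training samples and labels as given (no internal
#' normalization); prediction is by majority vote of the k nearest stored
#' samples in Euclidean distance.
#'
#' @param X samples x features numeric matrix without missing values.
#' @param y labels in {-1, +1}.
#' @param k neighbour count (default 5).
#' @return a \linkS4class{KNNModel}.
#' @export
knnModel <- function(X, y, k = 5L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  methods::new("KNNModel", X = X, y = as.numeric(y), k = as.integer(k))
}

#' Predict with a k-nearest-neighbour model
#'
#' Distance ties at the k-th position are broken by lower training index;
#' vote ties by the label of the single nearest neighbour.
#'
#' @param model a \linkS4class{KNNModel}.
#' @param X query matrix or single feature vector.
#' @return numeric labels in {-1, +1}.
#' @export
knnPredict <- function(model, X) {
  stopifnot(is(model, "KNNModel"))
  X <- .asMatrix(X, ncol(model@X))
  tr <- model@X
  trNorm <- rowSums(tr^2)
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- trNorm - 2 * as.vector(tr %*% X[i, ]) + sum(X[i, ]^2)
    ord <- order(d2, seq_along(d2))
    nn <- ord[seq_len(model@k)]
    vote <- sum(model@y[nn])
    if (vote > 0) 1 else if (vote < 0) -1 else model@y[ord[1L]]
  }, numeric(1))
}

setMethod("predictLabels", "KNNModel", function(object, newdata)
  knnPredict(object, newdata))

setMethod("decisionScores", "KNNModel", function(object, newdata) {
  newdata <- .asMatrix(newdata, ncol(object@X))
  tr <- object@X
  trNorm <- rowSums(tr^2)
  vapply(seq_len(nrow(newdata)), function(i) {
    d2 <- trNorm - 2 * as.vector(tr %*% newdata[i, ]) + sum(newdata[i, ]^2)
    ord <- order(d2, seq_along(d2))
    sum(object@y[ord[seq_len(object@k)]]) / object@k
  }, numeric(1))
})

## ---------------------------------------------------------------------------
## RBF support vector machine
## ---------------------------------------------------------------------------

#' Train a soft-margin SVM with Gaussian RBF kernel
#'
#' Maximizes the margin of the separating hyperplane in the kernel-induced
#' feature space; the optimization is delegated to the libsvm solver in
#' \pkg{e1071}. The decision function has the kernel-expansion form
#' sign(sum_i alpha_i y_i k(x_i, x) + b) with
#' k(x, x') = exp(-gamma ||x - x'||^2).
#'
#' @param X samples x features numeric matrix.
#' @param y labels in {-1, +1}; both classes must be present.
#' @param C soft-margin penalty (default 1).
#' @param gamma kernel width; default 1 / (d x mean feature variance), or
#'   1/d when the features are constant.
#' @return an \linkS4class{SVMModel}.
#' @export
svmTrainRBF <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  d <- ncol(X)
  if (is.null(gamma)) {
    mv <- mean(apply(X, 2L, stats::var))
    gamma <- if (is.finite(mv) && mv > 0) 1 / (d * mv) else 1 / d
  }
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)), scale = FALSE,
                    kernel = "radial", cost = C, gamma = gamma)
  methods::new("SVMModel", fit = fit, cost = C, gamma = gamma,
               featureCount = as.integer(d))
}

.svmScores <- function(object, newdata) {
  newdata <- .asMatrix(newdata, object@featureCount)
  fit <- object@fit
  if (inherits(fit, "svm")) {
    pr <- stats::predict(fit, newdata, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    negFirst <- strsplit(colnames(dv)[1], "/")[[1]][1] == "-1"
    return(as.vector(dv) * (if (negFirst) -1 else 1))
  }
  ## deserialized kernel expansion: sum_i alpha_i y_i k(x_i, x) - rho
  sv <- fit$sv
  d2 <- outer(rowSums(sv^2), rowSums(newdata^2), `+`) -
    2 * sv %*% t(newdata)
  raw <- as.vector(crossprod(exp(-object@gamma * d2), fit$coefs)) - fit$rho
  raw * fit$flip
}

#' Predict with an RBF SVM model
#'
#' @param model an \linkS4class{SVMModel}.
#' @param X query matrix or single feature vector.
#' @return numeric labels in {-1, +1}; a zero decision value maps to +1.
#' @export
svmPredictLabels <- function(model, X) {
  stopifnot(is(model, "SVMModel"))
  ifelse(.svmScores(model, X) >= 0, 1, -1)
}

setMethod("predictLabels", "SVMModel", function(object, newdata)
  svmPredictLabels(object, newdata))

setMethod("decisionScores", "SVMModel", function(object, newdata)
  .svmScores(object, newdata))

## Train any of the three classifiers through one interface.
.trainClassifier <- function(kind, X, y, args = list()) {
  switch(kind,
         gab = do.call(gabTrain, c(list(X = X, y = y), args)),
         knn = do.call(knnModel, c(list(X = X, y = y), args)),
         svm = do.call(svmTrainRBF, c(list(X = X, y = y), args)),
         stop("unknown classifier kind: ", kind))
}
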