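#' Binary confusion matrix from label vectors
#'
#' @param yTrue,yPred equal-length label vectors in {-1, +1}; +1 = melanoma.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrixFromLabels <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  if (!all(c(yTrue, yPred) %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  methods::new("ConfusionMatrix",
               TP = sum(yTrue == 1 & yPred == 1),
               TN = sum(yTrue == -1 & yPred == -1),
               FP = sum(yTrue == -1 & yPred == 1),
               FN = sum(yTrue == 1 & yPred == -1))
}

#' Diagnostic performance statistics
#'
#' The five standard ratios, reported as percentages:
#' AC = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN), SP = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), each x 100. A ratio with a zero
#' denominator is undefined and reported as NA, never as 0 or 100.
#'
#' @param cm a \linkS4class{ConfusionMatrix} with at least one counted
#'   sample.
#' @return named numeric vector AC, SE, SP, PPV, NPV in \[0, 100\].
#' @export
diagnosticMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@TP; tn <- cm@TN; fp <- cm@FP; fn <- cm@FN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(AC = 100 * (tp + tn) / total,
    SE = ratio(tp, tp + fn),
    SP = ratio(tn, tn + fp),
    PPV = ratio(tp, tp + fp),
    NPV = ratio(tn, tn + fn))
}

#' Balance classes by random over-sampling
#'
#' Rows of the minority class are sampled with replacement (seeded) and
#' appended until the class counts are equal; majority rows are untouched.
#' With 70 melanomas and 100 nevi this appends exactly 30 replicated
#' melanoma rows.
#'
#' @param features samples x features matrix.
#' @param labels labels in {-1, +1}; both classes must be present.
#' @param seed RNG seed for the replication draw.
#' @return list with the augmented \code{features}, \code{labels} and the
#'   indices of the source rows of the appended replicas
#'   (\code{replicatedFrom}).
#' @export
randomOversample <- function(features, labels, seed = 1L) {
  n1 <- sum(labels == 1); n0 <- sum(labels == -1)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0)
    return(list(features = features, labels = labels,
                replicatedFrom = integer(0)))
  minority <- if (n1 < n0) 1 else -1
  need <- abs(n1 - n0)
  pool <- which(labels == minority)
  extra <- withSeed(seed, sample(pool, need, replace = TRUE))
  list(features = rbind(features, features[extra, , drop = FALSE]),
       labels = c(labels, labels[extra]),
       replicatedFrom = extra)
}

#' Seeded (stratified) k-fold assignment
#'
#' Samples are shuffled with a seeded permutation and dealt round-robin into
#' k folds; with stratification (the default) the shuffle and deal happen
#' within each class, with the spill-over positions rotated across classes
#' so overall fold sizes still differ by at most one.
#'
#' @param labels label vector (defines n and, when stratified, the classes).
#' @param k fold count (2 <= k <= n; default 10).
#' @param seed RNG seed.
#' @param stratified balance class counts across folds (default TRUE).
#' @return integer vector of fold ids in \[1, k\], one per sample.
#' @export
kfoldSplit <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n")
  fold <- integer(n)
  withSeed(seed, {
    if (stratified) {
      start <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- (start + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      fold[idx] <- ((seq_len(n) - 1L) %% k) + 1L
    }
  })
  fold
}

#' Cross-validated evaluation of a descriptor/classifier pipeline
#'
#' Runs seeded stratified k-fold cross-validation. Per fold: the variance
#' feature filter is fitted on the nine training folds only, random
#' over-sampling balances the training folds only (default; with
#' \code{replicateFirst = TRUE} the whole dataset is over-sampled before
#' splitting, which lets replicated rows leak across folds), the classifier
#' is trained and the held-out fold predicted. Fold confusion matrices are
#' pooled into one report.
#'
#' @param features samples x features matrix (dense, or a \pkg{Matrix}
#'   sparse matrix as produced for the 24-neighbour LBP descriptor).
#' @param labels labels in {-1, +1}.
#' @param classifier \code{"gab"}, \code{"knn"} or \code{"svm"}.
#' @param k fold count (default 10).
#' @param seed RNG seed driving the fold split and over-sampling.
#' @param nFeatures features kept by the variance filter (default: all
#'   non-constant features, capped at 4096).
#' @param oversample balance training classes by random over-sampling
#'   (default TRUE).
#' @param replicateFirst over-sample the full dataset before splitting
#'   (default FALSE; leaks replicas across folds, kept for comparability
#'   with protocols that balance before splitting).
#' @param classifierArgs list of extra arguments for the classifier
#'   constructor (e.g. \code{list(M = 100)} or \code{list(k = 5)}).
#' @return list with \code{metrics} (named percentages), \code{confusion}
#'   (pooled \linkS4class{ConfusionMatrix}), \code{perFold} (list of fold
#'   reports), \code{predictions}, and a \code{config} echo.
#' @export
crossValidate <- function(features, labels, classifier = c("gab", "knn", "svm"),
                          k = 10L, seed = 1L, nFeatures = NULL,
                          oversample = TRUE, replicateFirst = FALSE,
                          classifierArgs = list()) {
  classifier <- match.arg(classifier)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (isTRUE(replicateFirst) && oversample) {
    os <- randomOversample(features, labels, seed = deriveSeed(seed, 0L))
    features <- os$features
    labels <- os$labels
  }
  n <- length(labels)
  fold <- kfoldSplit(labels, k, seed = seed, stratified = TRUE)
  if (is.null(nFeatures)) nFeatures <- min(ncol(features), 4096L)
  pred <- numeric(n)
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    trainIdx <- which(fold != f)
    sel <- selectFeatures(features[trainIdx, , drop = FALSE],
                          min(nFeatures, ncol(features)))
    Xtr <- as.matrix(features[trainIdx, sel, drop = FALSE])
    Xte <- as.matrix(features[testIdx, sel, drop = FALSE])
    ytr <- labels[trainIdx]
    if (oversample && !replicateFirst) {
      os <- randomOversample(Xtr, ytr, seed = deriveSeed(seed, f))
      Xtr <- os$features
      ytr <- os$labels
    }
    model <- .trainClassifier(classifier, Xtr, ytr, classifierArgs)
    yhat <- predictLabels(model, Xte)
    pred[testIdx] <- yhat
    cmF <- confusionMatrixFromLabels(labels[testIdx], yhat)
    perFold[[f]] <- list(fold = f, confusion = confusionCounts(cmF),
                         metrics = diagnosticMetrics(cmF))
  }
  cm <- confusionMatrixFromLabels(labels, pred)
  list(metrics = diagnosticMetrics(cm),
       confusion = cm,
       perFold = perFold,
       predictions = pred,
       config = list(classifier = classifier, k = k, seed = seed,
                     nFeatures = nFeatures, oversample = oversample,
                     replicateFirst = replicateFirst,
                     classifierArgs = classifierArgs))
}
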