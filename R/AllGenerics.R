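#' Predict class labels from a fitted classifier
#'
#' All three classifiers (Gentle AdaBoost, kNN, SVM) share this contract:
#' given a feature matrix with the training dimensionality, return labels in
#' {-1, +1} (+1 = melanoma). A decision score of exactly zero maps to +1,
#' the safety-first direction for a diagnostic tool.
#'
#' @param object a fitted \linkS4class{GABEnsemble}, \linkS4class{KNNModel}
#'   or \linkS4class{SVMModel}.
#' @param newdata numeric matrix (samples x features) or a single feature
#'   vector.
#' @return numeric vector of labels in {-1, +1}.
#' @export
setGeneric("predictLabels", function(object, newdata) standardGeneric("predictLabels"))

#' Real-valued decision scores from a fitted classifier
#'
#' The quantity whose sign \code{\link{predictLabels}} takes: the summed
#' stump responses for Gentle AdaBoost, the signed kernel expansion
#' sum_i alpha_i y_i k(x_i, x) + b for the SVM, and the signed neighbour
#' vote margin for kNN.
#'
#' @inheritParams predictLabels
#' @return numeric vector of finite scores.
#' @export
setGeneric("decisionScores", function(object, newdata) standardGeneric("decisionScores"))

.asMatrix <- function(newdata, d) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != d)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 d, ncol(newdata)), call. = FALSE)
  storage.mode(newdata) <- "double"
  newdata
}
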