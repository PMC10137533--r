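#' @import methods
NULL

#' Sparse histogram over a large integer code space
#'
#' Holds the nonzero bins of a descriptor histogram whose domain is too large
#' to store densely (the 24-neighbour LBP extension has a code space of
#' 2^24 = 16,777,216 bins, of which a 150x150 image can occupy at most
#' 146x146 = 21,316).
#'
#' @slot codes numeric vector of integer codes in \[0, domainSize).
#' @slot counts non-negative counts, one per code.
#' @slot domainSize total number of possible codes (2^P).
#' @export
setClass("SparseHistogram",
  representation(codes = "numeric", counts = "numeric", domainSize = "numeric"),
  validity = function(object) {
    if (length(object@codes) != length(object@counts))
      return("codes and counts must have equal length")
    if (anyDuplicated(object@codes)) return("codes must be unique")
    if (length(object@codes) && (min(object@codes) < 0 ||
        max(object@codes) >= object@domainSize))
      return("codes must lie in [0, domainSize)")
    if (length(object@counts) && min(object@counts) < 0)
      return("counts must be non-negative")
    TRUE
  }
)

#' Single-feature regression stump
#'
#' The weak learner used by Gentle AdaBoost: a threshold on one feature with
#' a real-valued response per side, fit by weighted least squares. With
#' labels in {-1, +1} each response is the weighted mean of the labels in its
#' region, i.e. the weighted class-probability difference
#' P_w(y = +1 | region) - P_w(y = -1 | region), and so lies in \[-1, 1\].
#'
#' @slot featureIndex column of the feature matrix the stump splits on.
#' @slot threshold split point; rows with feature < threshold go left.
#' @slot leftValue,rightValue real responses in \[-1, 1\].
#' @export
setClass("Stump",
  representation(featureIndex = "integer", threshold = "numeric",
                 leftValue = "numeric", rightValue = "numeric"),
  validity = function(object) {
    if (!is.finite(object@leftValue) || !is.finite(object@rightValue))
      return("stump responses must be finite")
    if (abs(object@leftValue) > 1 + 1e-9 || abs(object@rightValue) > 1 + 1e-9)
      return("stump responses must lie in [-1, 1]")
    TRUE
  }
)

#' Gentle AdaBoost ensemble
#'
#' An ordered list of regression stumps; the decision score of a sample is
#' the sum of stump responses and the predicted label its sign (ties to +1,
#' the melanoma class).
#'
#' @slot stumps list of \linkS4class{Stump} objects.
#' @slot M number of boosting rounds (length of stumps).
#' @slot featureCount training feature dimension.
#' @export
setClass("GABEnsemble",
  representation(stumps = "list", M = "integer", featureCount = "integer"),
  validity = function(object) {
    if (object@M < 1L) return("M must be >= 1")
    if (length(object@stumps) != object@M) return("length(stumps) must equal M")
    if (!all(vapply(object@stumps, is, logical(1), "Stump")))
      return("stumps must all be Stump objects")
    TRUE
  }
)

#' k-nearest-neighbour model
#'
#' Stores the training matrix and labels; prediction is the majority label
#' of the k training samples nearest in Euclidean distance.
#'
#' @slot X numeric training matrix (samples x features), no missing values.
#' @slot y labels in {-1, +1}.
#' @slot k neighbour count.
#' @export
setClass("KNNModel",
  representation(X = "matrix", y = "numeric", k = "integer"),
  validity = function(object) {
    if (anyNA(object@X) || !is.numeric(object@X))
      return("missing or non-numeric training data is not allowed")
    if (length(object@y) != nrow(object@X))
      return("label count must equal row count")
    if (!all(object@y %in% c(-1, 1))) return("labels must be in {-1, +1}")
    if (object@k < 1L || object@k > nrow(object@X))
      return("k must be in [1, number of training samples]")
    TRUE
  }
)

#' Support-vector-machine model (RBF kernel)
#'
#' Wraps a fitted soft-margin SVM with Gaussian radial-basis-function kernel
#' k(x, x') = exp(-gamma ||x - x'||^2). The decision function is
#' f(x) = sign(sum_i alpha_i y_i k(x_i, x) + b), with a zero decision value
#' mapped to +1 (melanoma).
#'
#' @slot fit the underlying fitted solver object.
#' @slot cost soft-margin penalty C.
#' @slot gamma RBF kernel width.
#' @slot featureCount expected input dimension.
#' @export
setClass("SVMModel",
  representation(fit = "ANY", cost = "numeric", gamma = "numeric",
                 featureCount = "integer"))

#' Binary confusion matrix
#'
#' Counts over a melanoma-positive binary problem: TP = true +1 predicted +1,
#' TN = true -1 predicted -1, FP = true -1 predicted +1, FN = true +1
#' predicted -1.
#'
#' @slot TP,TN,FP,FN non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(TP = "integer", TN = "integer", FP = "integer", FN = "integer"),
  validity = function(object) {
    v <- c(object@TP, object@TN, object@FP, object@FN)
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
  }
)

#' Labelled synthetic lesion sample
#'
#' One generated skin-lesion image with its ground-truth lesion mask (frozen
#' before hair strokes and impulse noise are painted) and its class label.
#'
#' @slot image height x width x 3 RGB array of 8-bit intensities.
#' @slot mask logical matrix, TRUE = lesion, same height/width as the image.
#' @slot label +1 (melanoma) or -1 (nevus).
#' @export
setClass("LabeledSample",
  representation(image = "array", mask = "matrix", label = "numeric"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) return("image must be height x width x 3")
    if (!identical(dim(object@mask), d[1:2]))
      return("mask and image dimensions must agree")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!object@label %in% c(-1, 1)) return("label must be +1 or -1")
    TRUE
  }
)

setMethod("show", "SparseHistogram", function(object) {
  cat(sprintf("SparseHistogram: %d nonzero bins over a domain of %s codes (total count %s)\n",
      length(object@codes), format(object@domainSize, big.mark = ","),
      format(sum(object@counts), big.mark = ",")))
})

setMethod("show", "GABEnsemble", function(object) {
  cat(sprintf("GABEnsemble: Gentle AdaBoost with %d regression stumps\n", object@M))
  feats <- vapply(object@stumps, function(s) s@featureIndex, integer(1))
  cat(sprintf("  distinct features used: %d\n", length(unique(feats))))
})

setMethod("show", "KNNModel", function(object) {
  cat(sprintf("KNNModel: k = %d over %d stored samples x %d features\n",
      object@k, nrow(object@X), ncol(object@X)))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel: RBF kernel, C = %g, gamma = %g, %d features\n",
      object@cost, object@gamma, object@featureCount))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive = melanoma)\n")
  m <- matrix(c(object@TP, object@FP, object@FN, object@TN), 2, 2,
              dimnames = list(true = c("+1", "-1"), predicted = c("+1", "-1")))
  print(m)
})

setMethod("show", "LabeledSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledSample: %dx%d RGB image, label %+d, lesion area %d px\n",
      d[1], d[2], as.integer(object@label), sum(object@mask)))
})

## Accessors ----------------------------------------------------------------

#' @describeIn SparseHistogram-class domain size (number of possible codes).
#' @param x a SparseHistogram.
#' @export
domainSize <- function(x) {
  stopifnot(is(x, "SparseHistogram"))
  x@domainSize
}

#' @describeIn SparseHistogram-class nonzero codes and counts as a data frame.
#' @export
histCounts <- function(x) {
  stopifnot(is(x, "SparseHistogram"))
  o <- order(x@codes)
  data.frame(code = x@codes[o], count = x@counts[o])
}

#' @describeIn ConfusionMatrix-class counts as a named integer vector.
#' @param cm a ConfusionMatrix.
#' @export
confusionCounts <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  c(TP = cm@TP, TN = cm@TN, FP = cm@FP, FN = cm@FN)
}

#' @describeIn LabeledSample-class the RGB pixel array.
#' @param x a LabeledSample.
#' @export
sampleImage <- function(x) { stopifnot(is(x, "LabeledSample")); x@image }

#' @describeIn LabeledSample-class the ground-truth lesion mask.
#' @export
sampleMask <- function(x) { stopifnot(is(x, "LabeledSample")); x@mask }

#' @describeIn LabeledSample-class the class label (+1 melanoma, -1 nevus).
#' @export
sampleLabel <- function(x) { stopifnot(is(x, "LabeledSample")); x@label }
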