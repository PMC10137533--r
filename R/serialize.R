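## Versioned JSON container for trained models: regression-stump lists for
## Gentle AdaBoost, the stored samples for kNN, and the kernel expansion
## (support vectors, signed dual coefficients, offset, gamma) for the SVM.

#' Serialize a trained classifier to JSON
#'
#' @param model a \linkS4class{GABEnsemble}, \linkS4class{KNNModel} or
#'   \linkS4class{SVMModel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  obj <- if (is(model, "GABEnsemble")) {
    list(format = "dermaCAD-model", version = 1L, type = "gab",
         featureCount = model@featureCount,
         stumps = lapply(model@stumps, function(s)
           list(featureIndex = s@featureIndex, threshold = s@threshold,
                leftValue = s@leftValue, rightValue = s@rightValue)))
  } else if (is(model, "KNNModel")) {
    list(format = "dermaCAD-model", version = 1L, type = "knn",
         k = model@k, labels = model@y, train = model@X)
  } else if (is(model, "SVMModel")) {
    fit <- model@fit
    sv <- if (inherits(fit, "svm")) as.matrix(fit$SV) else fit$sv
    coefs <- if (inherits(fit, "svm")) as.numeric(fit$coefs) else fit$coefs
    rho <- if (inherits(fit, "svm")) as.numeric(fit$rho) else fit$rho
    flip <- if (inherits(fit, "svm")) {
      if (fit$levels[fit$labels[1]] == "-1") -1 else 1
    } else fit$flip
    list(format = "dermaCAD-model", version = 1L, type = "svm",
         gamma = model@gamma, cost = model@cost,
         featureCount = model@featureCount,
         sv = sv, coefs = coefs, rho = rho, flip = flip)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a classifier serialized by \code{writeModelJSON}
#'
#' @param path JSON model file.
#' @return a model object honouring the \code{\link{predictLabels}} contract.
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dermaCAD-model"))
    stop("not a dermaCAD model file")
  switch(obj$type,
    gab = {
      stumps <- lapply(seq_len(nrow(obj$stumps)), function(i)
        methods::new("Stump",
                     featureIndex = as.integer(obj$stumps$featureIndex[i]),
                     threshold = obj$stumps$threshold[i],
                     leftValue = obj$stumps$leftValue[i],
                     rightValue = obj$stumps$rightValue[i]))
      methods::new("GABEnsemble", stumps = stumps, M = length(stumps),
                   featureCount = as.integer(obj$featureCount))
    },
    knn = knnModel(obj$train, obj$labels, k = obj$k),
    svm = methods::new("SVMModel",
                       fit = list(sv = as.matrix(obj$sv),
                                  coefs = as.numeric(obj$coefs),
                                  rho = obj$rho, flip = obj$flip),
                       cost = obj$cost, gamma = obj$gamma,
                       featureCount = as.integer(obj$featureCount)),
    stop("unknown model type: ", obj$type))
}
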