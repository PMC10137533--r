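#' Pipeline configuration
#'
#' A flat, validated key-value configuration covering every stage of the
#' CAD pipeline; all defaults are echoed into run reports so omitted keys
#' stay auditable.
#'
#' @param side standard image side in pixels (default 150).
#' @param medianWindow odd median-filter window (default 5).
#' @param seRadius bottom-hat disk radius for hair removal (default 5).
#' @param hairThreshold hair-detection threshold (default 30).
#' @param fusion mask fusion rule: majority, union or intersection.
#' @param openRadius opening disk radius (default 3).
#' @param ocRadius open-close disk radius (default 2).
#' @param maxIter open-close iterations (default 5).
#' @param minFraction size-filter cutoff (default 0.05).
#' @param descriptor lbp, nlbp, hog or cshog (default nlbp).
#' @param masked restrict descriptors to the segmented lesion (default
#'   FALSE).
#' @param nFeatures variance-filter feature count (default 4096).
#' @param classifier gab, knn or svm (default gab).
#' @param classifierArgs extra classifier arguments (default empty).
#' @param k cross-validation folds (default 10).
#' @param seed RNG seed (default 1).
#' @param oversample balance training classes (default TRUE).
#' @param replicateFirst over-sample before splitting (default FALSE).
#' @param segment run the segmentation stage and keep its artifacts
#'   (default TRUE; forced TRUE when \code{masked}).
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(side = 150L, medianWindow = 5L, seRadius = 5,
                           hairThreshold = 30, fusion = "majority",
                           openRadius = 3, ocRadius = 2, maxIter = 5L,
                           minFraction = 0.05, descriptor = "nlbp",
                           masked = FALSE, nFeatures = 4096L,
                           classifier = "gab", classifierArgs = list(),
                           k = 10L, seed = 1L, oversample = TRUE,
                           replicateFirst = FALSE, segment = TRUE) {
  cfg <- list(side = as.integer(side), medianWindow = as.integer(medianWindow),
              seRadius = seRadius, hairThreshold = hairThreshold,
              fusion = fusion, openRadius = openRadius, ocRadius = ocRadius,
              maxIter = as.integer(maxIter), minFraction = minFraction,
              descriptor = descriptor, masked = masked,
              nFeatures = as.integer(nFeatures), classifier = classifier,
              classifierArgs = classifierArgs, k = as.integer(k),
              seed = as.integer(seed), oversample = oversample,
              replicateFirst = replicateFirst, segment = segment || masked)
  if (cfg$side < 8L) stop("side must be >= 8")
  if (cfg$medianWindow %% 2L == 0L || cfg$medianWindow < 3L)
    stop("medianWindow must be odd and >= 3")
  if (cfg$seRadius < 1 || cfg$openRadius < 1 || cfg$ocRadius < 1)
    stop("structuring element radii must be >= 1")
  if (!cfg$fusion %in% c("majority", "union", "intersection"))
    stop("unknown fusion rule")
  if (cfg$minFraction < 0 || cfg$minFraction >= 1)
    stop("minFraction must lie in [0, 1)")
  if (!cfg$descriptor %in% c("lbp", "nlbp", "hog", "cshog"))
    stop("unknown descriptor kind")
  if (!cfg$classifier %in% c("gab", "knn", "svm"))
    stop("unknown classifier kind")
  if (cfg$k < 2L) stop("k must be >= 2")
  if (cfg$maxIter < 1L) stop("maxIter must be >= 1")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full CAD pipeline on a dataset
#'
#' Preprocess, segment, extract and evaluate: every image is resized, median
#' filtered and hair-cleaned; the lesion is segmented (when enabled) and the
#' chosen descriptor extracted from the preprocessed grayscale image; the
#' chosen classifier is evaluated by stratified k-fold cross-validation with
#' over-sampling of the training folds. When \code{outDir} is given, all
#' intermediate artifacts (preprocessed images, masks, contours, the feature
#' table and the JSON report with the full configuration echo) are written
#' under it; reruns with an identical configuration and seed are
#' byte-identical.
#'
#' @param samples list of \linkS4class{LabeledSample}, or the path of a CSV
#'   manifest (see \code{\link{readDataset}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional run directory for artifacts.
#' @return the evaluation report of \code{\link{crossValidate}}, extended
#'   with the configuration echo and per-sample segmentation IoU against
#'   ground truth where masks are available.
#' @export
runPipeline <- function(samples, config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(samples)) samples <- readDataset(samples)
  if (!length(samples)) stop("empty dataset")
  labels <- sampleLabels(samples)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  segIoU <- rep(NA_real_, length(samples))
  stage <- function(i, what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("sample %d, stage '%s': %s", i, what, conditionMessage(e)),
           call. = FALSE))
  }
  if (config$segment) {
    for (i in seq_along(samples)) {
      prgb <- stage(i, "preprocess",
                    preprocessImage(sampleImage(samples[[i]]), config$side,
                                    config$medianWindow, config$seRadius,
                                    config$hairThreshold))
      seg <- stage(i, "segment",
                   segmentLesion(prgb, config$fusion, config$openRadius,
                                 config$ocRadius, config$maxIter,
                                 config$minFraction))
      gt <- sampleMask(samples[[i]])
      if (any(gt)) {
        gtStd <- .resizeGray(gt * 1, config$side) > 0.5
        segIoU[i] <- maskIoU(seg$mask, gtStd)
      }
      if (!is.null(outDir)) {
        writeLesionImage(prgb, file.path(outDir, sprintf("preprocessed_%03d.png", i)))
        writeMaskPNG(seg$mask, file.path(outDir, sprintf("mask_%03d.png", i)))
        utils::write.csv(as.data.frame(seg$contour),
                         file.path(outDir, sprintf("contour_%03d.csv", i)),
                         row.names = FALSE)
      }
    }
  }

  features <- featureMatrix(samples, config$descriptor, preprocess = TRUE,
                            side = config$side,
                            medianWindow = config$medianWindow,
                            seRadius = config$seRadius,
                            hairThreshold = config$hairThreshold,
                            masked = config$masked)
  report <- crossValidate(features, labels, classifier = config$classifier,
                          k = config$k, seed = config$seed,
                          nFeatures = min(config$nFeatures, ncol(features)),
                          oversample = config$oversample,
                          replicateFirst = config$replicateFirst,
                          classifierArgs = config$classifierArgs)
  report$config <- unclass(config)
  report$segmentationIoU <- segIoU
  if (!is.null(outDir)) {
    if (config$descriptor == "nlbp") {
      Matrix::writeMM(methods::as(features, "generalMatrix"),
                      file.path(outDir, "features.mtx"))
    } else {
      utils::write.csv(as.data.frame(features),
                       file.path(outDir, "features.csv"), row.names = FALSE)
    }
    json <- list(config = unclass(config),
                 confusion = as.list(confusionCounts(report$confusion)),
                 metrics = as.list(report$metrics),
                 perFold = lapply(report$perFold, function(f)
                   list(fold = f$fold, confusion = as.list(f$confusion),
                        metrics = as.list(f$metrics))),
                 segmentationIoU = segIoU)
    jsonlite::write_json(json, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}
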