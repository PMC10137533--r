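#' Extract one lesion descriptor from a grayscale image
#'
#' @param image grayscale matrix.
#' @param kind \code{"lbp"} (256-bin histogram), \code{"nlbp"} (sparse
#'   24-neighbour histogram), \code{"hog"} (8-pixel cells) or \code{"cshog"}
#'   (2-pixel cells).
#' @param lbp,hog optional parameter overrides (\code{\link{lbpParams}},
#'   \code{\link{hogParams}}).
#' @return numeric descriptor vector, or a \linkS4class{SparseHistogram} for
#'   \code{"nlbp"}.
#' @export
extractDescriptor <- function(image, kind = c("lbp", "nlbp", "hog", "cshog"),
                              lbp = lbpParams(), hog = hogParams()) {
  kind <- match.arg(kind)
  switch(kind,
         lbp = lbpHistogram(image, lbp),
         nlbp = nlbpHistogram(image),
         hog = hogDescriptor(image, hog),
         cshog = csHogDescriptor(image))
}

.toGrayInput <- function(x) {
  if (is(x, "LabeledSample")) x <- sampleImage(x)
  if (.isRGB(x)) toGrayscale(x) else x
}

#' Build the descriptor matrix of a dataset
#'
#' Converts every sample to grayscale, optionally preprocesses it (resize to
#' the standard side, median filter, hair removal), extracts the chosen
#' descriptor and stacks the results into a samples x features matrix. The
#' sparse 24-neighbour LBP histograms are assembled into a \pkg{Matrix}
#' sparse matrix over the codes observed anywhere in the dataset (an
#' injective re-indexing of the fixed 2^24 code space; columns are named by
#' code).
#'
#' @param samples list of \linkS4class{LabeledSample}, RGB arrays or
#'   grayscale matrices.
#' @param kind descriptor kind, as \code{\link{extractDescriptor}}.
#' @param preprocess apply \code{\link{preprocessImage}} (default TRUE).
#' @param side standard image side (default 150).
#' @param medianWindow,seRadius,hairThreshold preprocessing parameters.
#' @param masked zero all pixels outside the segmented lesion before
#'   descriptor extraction (default FALSE: whole preprocessed image).
#' @return numeric matrix, or \code{dgCMatrix} for \code{"nlbp"}.
#' @export
featureMatrix <- function(samples, kind = c("lbp", "nlbp", "hog", "cshog"),
                          preprocess = TRUE, side = 150L, medianWindow = 5L,
                          seRadius = 5, hairThreshold = 30, masked = FALSE) {
  kind <- match.arg(kind)
  grays <- lapply(samples, function(s) {
    g <- .toGrayInput(s)
    if (preprocess)
      g <- preprocessImage(g, side, medianWindow, seRadius, hairThreshold)
    else
      g <- round(.clamp(resizeImage(g, side), 0, 255))
    if (masked) {
      rgb <- if (is(s, "LabeledSample")) sampleImage(s) else s
      if (!.isRGB(rgb))
        stop("masked extraction needs RGB input for segmentation")
      prgb <- preprocessImage(rgb, side, medianWindow, seRadius, hairThreshold)
      g[!segmentLesion(prgb)$mask] <- 0
    }
    g
  })
  if (kind == "nlbp") {
    hists <- lapply(grays, nlbpHistogram)
    allCodes <- sort(unique(unlist(lapply(hists, function(h) h@codes))))
    trip <- do.call(rbind, lapply(seq_along(hists), function(i)
      cbind(i = i, j = match(hists[[i]]@codes, allCodes),
            x = hists[[i]]@counts)))
    m <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                              dims = c(length(hists), length(allCodes)))
    colnames(m) <- format(allCodes, scientific = FALSE, trim = TRUE)
    return(m)
  }
  do.call(rbind, lapply(grays, function(g)
    as.numeric(extractDescriptor(g, kind))))
}
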