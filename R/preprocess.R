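#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luminance: 0.299 R + 0.587 G + 0.114 B, rounded to the
#' nearest integer.
#'
#' @param image height x width x 3 numeric array of 8-bit intensities.
#' @return numeric matrix of 8-bit gray levels.
#' @export
toGrayscale <- function(image) {
  .assertRGB(image)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

.resizeGray <- function(m, side) {
  sr <- .clamp((seq_len(side) - 0.5) * nrow(m) / side + 0.5, 1, nrow(m))
  sc <- .clamp((seq_len(side) - 0.5) * ncol(m) / side + 0.5, 1, ncol(m))
  r0 <- pmin(floor(sr), nrow(m) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(sc), ncol(m) - 1L); c0 <- pmax(c0, 1L)
  fr <- sr - r0; fc <- sc - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]; d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, side, side); wc <- matrix(fc, side, side, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * cc + wr * wc * d
}

#' Resize an image to a square standard size
#'
#' Bilinear resampling with pixel-centre alignment; the default side of 150
#' pixels gives every lesion image a uniform size before feature extraction.
#'
#' @param image grayscale matrix or RGB array.
#' @param side output pixels per side (>= 8; default 150).
#' @return an image of the same type, side x side. Values are real; round
#'   before 8-bit export.
#' @export
resizeImage <- function(image, side = 150L) {
  if (side < 8L) stop("side must be >= 8")
  side <- as.integer(side)
  if (.isRGB(image)) {
    out <- array(0, dim = c(side, side, 3L))
    for (ch in 1:3) out[, , ch] <- .resizeGray(image[, , ch], side)
    return(out)
  }
  .assertGray(image)
  .resizeGray(image, side)
}

#' Median filter for impulse-noise suppression
#'
#' Replaces every pixel by the median of the odd-sided square window centred
#' on it; out-of-frame neighbours take the replicated edge value. Removes
#' salt-and-pepper noise while retaining edges.
#'
#' @param image grayscale matrix.
#' @param window odd window side (>= 3; default 5).
#' @return filtered matrix of the same size.
#' @export
medianFilterImage <- function(image, window = 5L) {
  .assertGray(image)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  off <- .squareOffsets(h)
  a <- vapply(seq_len(nrow(off)),
              function(k) as.vector(shiftReplicate(image, off[k, 1], off[k, 2])),
              numeric(length(image)))
  mid <- (ncol(a) + 1L) %/% 2L
  med <- apply(a, 1L, function(v) sort.int(v, partial = mid)[mid])
  matrix(med, nrow(image), ncol(image))
}

#' Bottom-hat transform
#'
#' Morphological closing with a flat disk minus the image. Non-negative
#' everywhere, and large exactly over thin dark structures (hairs) narrower
#' than the structuring element.
#'
#' @param image grayscale matrix.
#' @param seRadius disk radius in pixels (default 5); must be smaller than
#'   half the shorter image side.
#' @return non-negative matrix of the same size.
#' @export
bottomHat <- function(image, seRadius = 5) {
  .assertGray(image)
  if (seRadius >= min(dim(image)) / 2) stop("structuring element too large for image")
  off <- diskOffsets(seRadius)
  grayClose(image, off) - image
}

#' Hair-artifact removal
#'
#' Pixels whose bottom-hat response exceeds \code{hairThreshold} form the
#' hair mask (dilated by one pixel); each is replaced by the median of the
#' non-hair pixels in a growing window (5, 7, 9, ...) around it. All other
#' pixels are untouched. If the detected mask covers more than half the
#' image the threshold is considered degenerate: a warning is raised and the
#' image returned unmodified.
#'
#' @param image grayscale matrix.
#' @param seRadius disk radius of the bottom-hat structuring element
#'   (default 5; hairs are 1 to 3 pixels thin).
#' @param hairThreshold bottom-hat response above which a pixel counts as
#'   hair (default 30).
#' @return matrix with hair pixels inpainted.
#' @export
removeHair <- function(image, seRadius = 5, hairThreshold = 30) {
  .assertGray(image)
  bh <- bottomHat(image, seRadius)
  hair <- bh > hairThreshold
  if (!any(hair)) return(image)
  hair <- binaryDilate(hair, .squareOffsets(1L))
  if (mean(hair) > 0.5) {
    warning("hair mask covers more than 50% of the image; returning input unmodified")
    return(image)
  }
  out <- image
  n <- nrow(image); m <- ncol(image)
  idx <- which(hair)
  rs <- ((idx - 1L) %% n) + 1L
  cs <- ((idx - 1L) %/% n) + 1L
  for (i in seq_along(idx)) {
    h <- 2L
    repeat {
      r1 <- max(1L, rs[i] - h); r2 <- min(n, rs[i] + h)
      c1 <- max(1L, cs[i] - h); c2 <- min(m, cs[i] + h)
      vals <- image[r1:r2, c1:c2][!hair[r1:r2, c1:c2]]
      if (length(vals)) break
      h <- h + 1L
    }
    out[idx[i]] <- stats::median(vals)
  }
  out
}

#' Full image preprocessing
#'
#' Resize to the standard side, median filter, then bottom-hat based hair
#' removal; applied per channel for RGB input so the cleaned planes can feed
#' per-channel segmentation.
#'
#' @param image grayscale matrix or RGB array.
#' @param side standard side in pixels (default 150).
#' @param medianWindow odd median-filter window (default 5).
#' @param seRadius bottom-hat disk radius (default 5).
#' @param hairThreshold hair-detection threshold (default 30).
#' @return preprocessed image of the same type, rounded to integer levels.
#' @export
preprocessImage <- function(image, side = 150L, medianWindow = 5L,
                            seRadius = 5, hairThreshold = 30) {
  img <- resizeImage(image, side)
  img <- round(.clamp(img, 0, 255))
  one <- function(m) removeHair(medianFilterImage(m, medianWindow),
                                seRadius, hairThreshold)
  if (.isRGB(img)) {
    for (ch in 1:3) img[, , ch] <- one(img[, , ch])
    img
  } else one(img)
}
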