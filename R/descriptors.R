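## Neighbourhood offsets of the square LBP rings, in raster order
## (row-major, top-left to bottom-right, centre excluded).
.ringOffsets <- function(radius) {
  g <- expand.grid(dc = -radius:radius, dr = -radius:radius)
  g <- g[!(g$dr == 0 & g$dc == 0), c("dr", "dc")]
  g <- g[order(g$dr, g$dc), ]
  as.matrix(g)
}

#' LBP parameter set
#'
#' @param P neighbour count (> 1). The square kind supports P = 8 (3x3 ring)
#'   and P = 24 (5x5 ring).
#' @param R neighbourhood radius in pixels (>= 1); implied by P for the
#'   square kind (1 for P = 8, 2 for P = 24).
#' @param neighborhoodKind \code{"square"} (default; the classic square
#'   mask) or \code{"circular"} (P points on a circle of radius R, sampled
#'   with bilinear interpolation).
#' @return validated list of class \code{"LBPParams"}.
#' @export
lbpParams <- function(P = 8L, R = 1L, neighborhoodKind = c("square", "circular")) {
  neighborhoodKind <- match.arg(neighborhoodKind)
  P <- as.integer(P)
  if (P <= 1L) stop("P must be > 1")
  if (neighborhoodKind == "square") {
    if (!P %in% c(8L, 24L)) stop("square neighbourhoods support P = 8 or P = 24")
    R <- if (P == 8L) 1L else 2L
  }
  if (R < 1) stop("R must be >= 1")
  structure(list(P = P, R = R, neighborhoodKind = neighborhoodKind),
            class = "LBPParams")
}

#' Local binary pattern code of one pixel
#'
#' code = sum over p of s(g_p - g_c) 2^p, where s(x) = 1 for x >= 0 and 0
#' otherwise; equal neighbour and centre therefore sets the bit.
#'
#' @param center gray value g_c of the centre pixel.
#' @param neighbors ordered gray values g_0, ..., g_(P-1).
#' @return integer code in \[0, 2^P) (as a double, exact up to P = 52).
#' @export
lbpCode <- function(center, neighbors) {
  bits <- as.numeric(neighbors >= center)
  sum(bits * 2^(seq_along(neighbors) - 1))
}

## Code image over interior pixels (border of width R excluded), vectorized
## one bit-plane at a time.
.lbpCodes <- function(image, params) {
  h <- nrow(image); w <- ncol(image); R <- params$R
  if (h <= 2 * R + 1 || w <= 2 * R + 1)
    stop(sprintf("image must exceed %d pixels per side", 2 * R + 1))
  ri <- (R + 1):(h - R); ci <- (R + 1):(w - R)
  centre <- image[ri, ci, drop = FALSE]
  codes <- matrix(0, length(ri), length(ci))
  if (params$neighborhoodKind == "square") {
    off <- .ringOffsets(R)
    for (p in seq_len(nrow(off))) {
      nb <- image[ri + off[p, 1], ci + off[p, 2], drop = FALSE]
      codes <- codes + (nb >= centre) * 2^(p - 1)
    }
  } else {
    rows <- matrix(ri, length(ri), length(ci))
    cols <- matrix(ci, length(ri), length(ci), byrow = TRUE)
    for (p in seq_len(params$P)) {
      a <- 2 * pi * (p - 1) / params$P
      dr <- -R * sin(a); dc <- R * cos(a)
      sr <- rows + dr; sc <- cols + dc
      r0 <- floor(sr + 1e-9); c0 <- floor(sc + 1e-9)
      fr <- sr - r0; fc <- sc - c0
      fr[abs(fr) < 1e-9] <- 0; fc[abs(fc) < 1e-9] <- 0
      r0 <- .clamp(r0, 1, h - 1); c0 <- .clamp(c0, 1, w - 1)
      nb <- (1 - fr) * (1 - fc) * image[cbind(c(r0), c(c0))] +
            fr * (1 - fc) * image[cbind(c(r0 + 1), c(c0))] +
            (1 - fr) * fc * image[cbind(c(r0), c(c0 + 1))] +
            fr * fc * image[cbind(c(r0 + 1), c(c0 + 1))]
      codes <- codes + (matrix(nb, nrow(rows)) >= centre - 1e-9) * 2^(p - 1)
    }
  }
  codes
}

#' LBP histogram descriptor
#'
#' Codes are computed at every pixel whose full neighbourhood lies inside
#' the image (a border of width R is excluded) and accumulated into a raw
#' count histogram of length 2^P; 256 bins for the classic 8-neighbour
#' operator.
#'
#' @param image grayscale matrix, larger than 2R+1 per side.
#' @param params \code{\link{lbpParams}}; dense histograms require P <= 16
#'   (use \code{\link{nlbpHistogram}} for the 24-neighbour code space).
#' @return numeric count vector of length 2^P with attribute
#'   \code{kind = "LBP"}.
#' @export
lbpHistogram <- function(image, params = lbpParams()) {
  .assertGray(image)
  if (params$P > 16L)
    stop("dense histograms are limited to P <= 16; use nlbpHistogram()")
  codes <- .lbpCodes(image, params)
  out <- tabulate(as.integer(codes) + 1L, nbins = 2^params$P)
  structure(as.numeric(out), kind = "LBP", params = params)
}

#' 24-neighbour LBP (N-LBP) sparse histogram
#'
#' Extends the LBP neighbourhood from 8 to 24 pixels (the 5x5 square ring,
#' raster bit order, border of width 2 excluded), giving a code space of
#' 2^24 = 16,777,216 bins. Only the nonzero bins are stored: a 150x150
#' image codes at most 146 x 146 = 21,316 pixels.
#'
#' @param image grayscale matrix, at least 6x6.
#' @return a \linkS4class{SparseHistogram} with domain size 2^24.
#' @export
nlbpHistogram <- function(image) {
  .assertGray(image)
  codes <- .lbpCodes(image, lbpParams(P = 24L))
  tab <- table(as.vector(codes))
  methods::new("SparseHistogram",
               codes = as.numeric(names(tab)),
               counts = as.numeric(tab),
               domainSize = 2^24)
}

#' Central-difference image gradients
#'
#' Gx(x, y) = I(x+1, y) - I(x-1, y) along columns and
#' Gy(x, y) = I(x, y+1) - I(x, y-1) along rows, with edge replication at the
#' border.
#'
#' @param image grayscale matrix, at least 3x3.
#' @return list with matrices \code{gx} and \code{gy}.
#' @export
imageGradients <- function(image) {
  .assertGray(image)
  list(gx = shiftReplicate(image, 0L, 1L) - shiftReplicate(image, 0L, -1L),
       gy = shiftReplicate(image, 1L, 0L) - shiftReplicate(image, -1L, 0L))
}

#' Gradient magnitude and orientation
#'
#' m = sqrt(Gx^2 + Gy^2); theta from the two-argument arctangent in degrees,
#' folded to \[0, 180) in unsigned mode (\[0, 360) when signed). Where the
#' magnitude is zero the orientation is defined as 0.
#'
#' @param gx,gy gradient fields of equal dimensions.
#' @param signed use the full \[0, 360) orientation circle (default FALSE).
#' @return list with matrices \code{magnitude} and \code{orientation}.
#' @export
gradientPolar <- function(gx, gy, signed = FALSE) {
  stopifnot(identical(dim(gx), dim(gy)))
  m <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx) * 180 / pi
  th <- th %% (if (signed) 360 else 180)
  th[m == 0] <- 0
  list(magnitude = m, orientation = th)
}

#' HOG parameter set
#'
#' @param cellSize pixels per cell side (8 for the standard descriptor, 2
#'   for the small-cell CS-HOG variant).
#' @param nBins orientation bins (default 9).
#' @param blockSize cells per block side (default 2).
#' @param blockStride block stride in cells (default 1).
#' @param signed signed orientation circle (default FALSE: \[0, 180)).
#' @param normEpsilon block-normalization constant (default 1e-6).
#' @return validated list of class \code{"HOGParams"}.
#' @export
hogParams <- function(cellSize = 8L, nBins = 9L, blockSize = 2L,
                      blockStride = 1L, signed = FALSE, normEpsilon = 1e-6) {
  if (cellSize < 1 || nBins < 2 || blockSize < 1 || blockStride < 1)
    stop("invalid HOG parameters")
  structure(list(cellSize = as.integer(cellSize), nBins = as.integer(nBins),
                 blockSize = as.integer(blockSize),
                 blockStride = as.integer(blockStride),
                 signed = signed, normEpsilon = normEpsilon),
            class = "HOGParams")
}

## Per-cell magnitude-weighted orientation histograms with linear soft
## binning between the two nearest bin centres (centres at i * binWidth,
## wrap-around at the top of the orientation range).
.cellHistograms <- function(image, params) {
  cell <- params$cellSize
  nCy <- nrow(image) %/% cell
  nCx <- ncol(image) %/% cell
  img <- image[seq_len(nCy * cell), seq_len(nCx * cell), drop = FALSE]
  g <- imageGradients(img)
  pol <- gradientPolar(g$gx, g$gy, signed = params$signed)
  nb <- params$nBins
  binWidth <- (if (params$signed) 360 else 180) / nb
  t <- pol$orientation / binWidth
  b0 <- floor(t)
  frac <- t - b0
  bin0 <- b0 %% nb
  bin1 <- (b0 + 1) %% nb
  rowc <- (row(img) - 1L) %/% cell
  colc <- (col(img) - 1L) %/% cell
  cellId <- rowc + colc * nCy
  acc <- numeric(nCy * nCx * nb)
  idx <- c(cellId * nb + bin0, cellId * nb + bin1) + 1
  wgt <- c((1 - frac) * pol$magnitude, frac * pol$magnitude)
  s <- rowsum(wgt, idx)
  acc[as.integer(rownames(s))] <- s
  list(hist = array(acc, dim = c(nb, nCy, nCx)), nCy = nCy, nCx = nCx)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' The image is cropped (top-left anchored) to the largest multiple of the
#' cell size, per-cell magnitude-weighted orientation histograms are built
#' with linear soft binning across the two nearest orientation bins, blocks
#' of blockSize x blockSize cells (stride blockStride) are L2-normalized
#' with \code{normEpsilon}, and the normalized block vectors are
#' concatenated.
#'
#' @param image grayscale matrix at least cellSize x blockSize per side.
#' @param params \code{\link{hogParams}}.
#' @return numeric descriptor of length
#'   nBlocksY x nBlocksX x blockSize^2 x nBins with attribute
#'   \code{kind = "HOG"}.
#' @export
hogDescriptor <- function(image, params = hogParams()) {
  .assertGray(image)
  bs <- params$blockSize
  if (min(dim(image)) < params$cellSize * bs)
    stop("image smaller than one block")
  ch <- .cellHistograms(image, params)
  stride <- params$blockStride
  bys <- seq(1L, ch$nCy - bs + 1L, by = stride)
  bxs <- seq(1L, ch$nCx - bs + 1L, by = stride)
  nb <- params$nBins
  blockLen <- bs * bs * nb
  out <- numeric(length(bys) * length(bxs) * blockLen)
  eps2 <- params$normEpsilon^2
  k <- 0L
  for (bx in bxs) for (by in bys) {
    v <- as.vector(ch$hist[, by:(by + bs - 1L), bx:(bx + bs - 1L)])
    out[(k * blockLen + 1L):((k + 1L) * blockLen)] <- v / sqrt(sum(v * v) + eps2)
    k <- k + 1L
  }
  structure(out, kind = if (params$cellSize == 2L) "CSHOG" else "HOG",
            params = params)
}

#' Small-cell HOG (CS-HOG) descriptor
#'
#' The HOG descriptor with the cell size reduced to 2x2 pixels (all other
#' parameters at their defaults), trading compactness for finer spatial
#' resolution of gradient structure.
#'
#' @param image grayscale matrix.
#' @return numeric descriptor, as \code{\link{hogDescriptor}}.
#' @export
csHogDescriptor <- function(image) hogDescriptor(image, hogParams(cellSize = 2L))

#' Variance-based feature selection
#'
#' Drops zero-variance features (variances computed on the training rows
#' only), then keeps the k features with the largest training variance. A
#' deliberately simple, documented filter standing in for an unspecified
#' selection step; the returned indices must be applied identically to
#' training and test rows.
#'
#' @param trainMatrix samples x features matrix (dense or \pkg{Matrix}
#'   sparse).
#' @param k number of features to keep.
#' @return sorted ascending integer vector of column indices.
#' @export
selectFeatures <- function(trainMatrix, k) {
  n <- nrow(trainMatrix)
  if (k > ncol(trainMatrix)) stop("k exceeds the feature count")
  if (n < 2L) stop("need at least two training rows")
  mu <- Matrix::colMeans(trainMatrix)
  ex2 <- Matrix::colMeans(trainMatrix^2)
  v <- pmax(ex2 - mu^2, 0) * n / (n - 1)
  keep <- which(v > 1e-12)
  if (!length(keep)) stop("all features have zero variance")
  if (k > length(keep)) {
    warning(sprintf("only %d non-constant features available; returning all of them",
                    length(keep)))
    k <- length(keep)
  }
  sel <- keep[order(-v[keep], keep)][seq_len(k)]
  sort(sel)
}
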