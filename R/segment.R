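#' Otsu threshold of a gray channel
#'
#' Exhaustive search over the 256-bin intensity histogram for the cut that
#' maximizes the between-class variance. The returned value t is a cut:
#' pixels with value < t fall in the lower (lesion) class. Ties are broken
#' toward the smaller cut.
#'
#' @param channel numeric matrix of 8-bit intensities.
#' @return integer cut in \[1, 255\].
#' @export
otsuThreshold <- function(channel) {
  v <- as.integer(round(.clamp(channel, 0, 255)))
  if (length(unique(v)) < 2L)
    stop("constant channel: no separable classes for Otsu thresholding")
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  lev <- 0:255
  cumN <- cumsum(counts)
  cumS <- cumsum(counts * lev)
  n0 <- cumN[1:255]            # pixels with value < c, for cuts c = 1..255
  s0 <- cumS[1:255]
  n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- ifelse(valid, s0 / n0, 0)
  mu1 <- ifelse(valid, (cumS[256] - s0) / n1, 0)
  sigma <- ifelse(valid, (n0 / n) * (n1 / n) * (mu0 - mu1)^2, -Inf)
  which.max(sigma)             # first maximum = smallest cut
}

#' Per-channel Otsu lesion masks
#'
#' Applies Otsu thresholding to the R, G and B planes individually; the
#' darker side of each threshold is lesion (pigmented lesions are darker
#' than the surrounding skin).
#'
#' @param image RGB array.
#' @return list of three logical masks (R, G, B).
#' @export
channelMasks <- function(image) {
  .assertRGB(image)
  lapply(1:3, function(ch) {
    t <- otsuThreshold(image[, , ch])
    image[, , ch] < t
  })
}

#' Fuse per-channel masks into one lesion mask
#'
#' @param masks list of three logical masks of equal dimensions.
#' @param rule \code{"majority"} (pixel true in >= 2 of 3 masks, the
#'   default), \code{"union"} or \code{"intersection"}.
#' @return fused logical mask.
#' @export
fuseMasks <- function(masks, rule = c("majority", "union", "intersection")) {
  rule <- match.arg(rule)
  stopifnot(length(masks) == 3L)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    stop("mask dimensions must agree")
  s <- masks[[1]] + masks[[2]] + masks[[3]]
  switch(rule,
         majority = s >= 2,
         union = s >= 1,
         intersection = s >= 3)
}

#' Morphological opening of a binary mask
#'
#' Erosion then dilation with a flat disk; removes blobs that cannot contain
#' the structuring element.
#'
#' @param mask logical matrix.
#' @param seRadius disk radius (default 3).
#' @return opened logical mask.
#' @export
morphologicalOpen <- function(mask, seRadius = 3) {
  binaryOpen(mask, diskOffsets(seRadius))
}

.binaryMedian <- function(mask, window) {
  h <- (window - 1L) %/% 2L
  boxSum(mask * 1, h) > (window * window) / 2
}

#' Iterative median smoothing of a binary mask
#'
#' Three successive binary median (window-majority) filters with gradually
#' decreasing windows 7x7, 5x5 and 3x3; smooths the boundary and fills
#' small holes.
#'
#' @param mask logical matrix.
#' @return smoothed logical mask.
#' @export
iterativeMedianSmooth <- function(mask) {
  for (w in c(7L, 5L, 3L)) mask <- .binaryMedian(mask, w)
  mask
}

#' Iterated open-close filter
#'
#' Alternates morphological opening and closing with the same disk until the
#' mask stops changing or \code{maxIter} passes are done; removes small
#' specks and fills small holes adaptively.
#'
#' @param mask logical matrix.
#' @param seRadius disk radius (default 2).
#' @param maxIter maximum passes (default 5).
#' @return filtered logical mask.
#' @export
openCloseFilter <- function(mask, seRadius = 2, maxIter = 5L) {
  stopifnot(maxIter >= 1L)
  off <- diskOffsets(seRadius)
  for (i in seq_len(maxIter)) {
    new <- binaryClose(binaryOpen(mask, off), off)
    if (identical(new, mask)) return(new)
    mask <- new
  }
  mask
}

#' Remove small connected components
#'
#' Deletes 8-connected components whose pixel area is below
#' \code{minFraction} of the image area; components at or above the cutoff
#' are retained.
#'
#' @param mask logical matrix.
#' @param minFraction area cutoff as a fraction of height x width
#'   (default 0.05).
#' @return filtered logical mask.
#' @export
sizeFilter <- function(mask, minFraction = 0.05) {
  stopifnot(minFraction >= 0, minFraction < 1)
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minFraction * length(mask))
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(NULL)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

## Clockwise Moore-neighbourhood directions: N, NE, E, SE, S, SW, W, NW.
.mooreDirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                    c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

.dirIndex <- function(d) {
  for (k in 1:8) if (all(.mooreDirs[k, ] == d)) return(k)
  stop("not a Moore direction")
}

#' Trace the boundary contour of a lesion mask
#'
#' Moore-neighbour boundary tracing of the largest 8-connected component,
#' returning the closed boundary as (row, col) pixel coordinates ordered
#' counterclockwise, starting from the topmost-then-leftmost boundary pixel.
#' A single-pixel component yields a one-point contour flagged with
#' \code{attr(, "degenerate")}.
#'
#' @param mask logical matrix with at least one TRUE pixel.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
traceContour <- function(mask) {
  comp <- .largestComponent(mask)
  if (is.null(comp)) stop("no lesion found: mask is empty")
  h <- nrow(comp); w <- ncol(comp)
  idx <- which(comp)
  rs <- ((idx - 1L) %% h) + 1L
  cs <- ((idx - 1L) %/% h) + 1L
  topRow <- min(rs)
  start <- c(topRow, min(cs[rs == topRow]))
  if (length(idx) == 1L) {
    out <- matrix(start, 1L, 2L, dimnames = list(NULL, c("row", "col")))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  inside <- function(p) p[1] >= 1L && p[1] <= h && p[2] >= 1L && p[2] <= w && comp[p[1], p[2]]
  pts <- list(start)
  cur <- start
  backDir <- 7L                      # backtrack points West of the start pixel
  startBack <- backDir
  maxSteps <- 8L * length(idx) + 8L
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > maxSteps) stop("contour tracing failed to close")
    found <- FALSE
    for (k in 1:8) {
      d <- ((backDir - 1L + k) %% 8L) + 1L
      q <- cur + .mooreDirs[d, ]
      if (inside(q)) {
        bprev <- cur + .mooreDirs[((d - 2L) %% 8L) + 1L, ]   # last false neighbour
        backDir <- .dirIndex(bprev - q)
        cur <- q
        found <- TRUE
        break
      }
    }
    if (!found) break                # isolated pixel (cannot happen here)
    if (all(cur == start) && backDir == startBack) break
    pts[[length(pts) + 1L]] <- cur
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("row", "col")
  ## enforce counterclockwise orientation (positive shoelace area in a
  ## y-up frame, i.e. using (col, -row))
  x <- out[, "col"]; y <- -out[, "row"]
  n <- nrow(out)
  a2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  if (a2 < 0) out <- out[c(1L, n:2L), , drop = FALSE]
  out
}

#' Full lesion segmentation
#'
#' Composition of the segmentation chain on a preprocessed RGB image:
#' per-channel Otsu masks, mask fusion, morphological opening, iterative
#' median smoothing, iterated open-close filtering, size filtering, then
#' boundary tracing of the largest surviving component.
#'
#' @param image preprocessed RGB array.
#' @param fusion mask fusion rule (default "majority").
#' @param openRadius disk radius of the opening (default 3).
#' @param ocRadius disk radius of the open-close filter (default 2).
#' @param maxIter open-close iterations (default 5).
#' @param minFraction size-filter cutoff (default 0.05).
#' @return list with elements \code{mask} (logical matrix of the lesion) and
#'   \code{contour} (ordered boundary coordinates).
#' @export
segmentLesion <- function(image, fusion = "majority", openRadius = 3,
                          ocRadius = 2, maxIter = 5L, minFraction = 0.05) {
  .assertRGB(image)
  masks <- tryCatch(channelMasks(image),
                    error = function(e) stop("no lesion found: ", conditionMessage(e),
                                             call. = FALSE))
  m <- fuseMasks(masks, fusion)
  m <- morphologicalOpen(m, openRadius)
  m <- iterativeMedianSmooth(m)
  m <- openCloseFilter(m, ocRadius, maxIter)
  m <- sizeFilter(m, minFraction)
  if (!any(m)) stop("no lesion found: every component was filtered out", call. = FALSE)
  lesion <- .largestComponent(m)
  list(mask = lesion, contour = traceContour(lesion))
}
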