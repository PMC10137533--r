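#' Parameters for the synthetic lesion-image generator
#'
#' Controls the generator that emulates small clinical skin-lesion
#' photographs: a single roughly elliptical pigmented lesion, darker than
#' the surrounding skin, optionally crossed by thin dark hair strokes and
#' corrupted by impulsive salt-and-pepper noise. Class differences are
#' carried by two knobs: melanomas get irregular borders and strong
#' intra-lesion texture, nevi smooth borders and mild texture.
#'
#' @param imageSize pixels per side of the square image (default 150).
#' @param lesionRadiusRange range of the lesion semi-axes as a fraction of
#'   the image side (default 0.15 to 0.35).
#' @param borderIrregularity named amplitude of the radial border
#'   perturbation, as a fraction of the radius, per class
#'   (melanoma 0.3, nevus 0.05).
#' @param lesionMean,skinMean mean 8-bit intensities of lesion and skin
#'   (defaults 70 and 180).
#' @param textureSdLesion named per-class SD of the lesion intensity noise
#'   (melanoma 30, nevus 8).
#' @param textureSdSkin SD of the skin intensity noise (default 5).
#' @param nHairs integer range of hair-stroke counts (default 0 to 8).
#' @param hairWidth range of stroke widths in pixels (default 1 to 3).
#' @param hairIntensity 8-bit intensity of hair strokes (default 30).
#' @param saltPepperFraction fraction of pixels replaced by 0 or 255
#'   (default 0.01, at most 0.2).
#' @param seed default RNG seed used when none is passed to
#'   \code{\link{generateLesionImage}}.
#' @return A validated list of class \code{"SyntheticParams"}.
#' @export
syntheticParams <- function(imageSize = 150L,
                            lesionRadiusRange = c(0.15, 0.35),
                            borderIrregularity = c(melanoma = 0.3, nevus = 0.05),
                            lesionMean = 70,
                            skinMean = 180,
                            textureSdLesion = c(melanoma = 30, nevus = 8),
                            textureSdSkin = 5,
                            nHairs = c(0L, 8L),
                            hairWidth = c(1, 3),
                            hairIntensity = 30,
                            saltPepperFraction = 0.01,
                            seed = 1L) {
  p <- list(imageSize = as.integer(imageSize),
            lesionRadiusRange = as.numeric(lesionRadiusRange),
            borderIrregularity = borderIrregularity,
            lesionMean = lesionMean, skinMean = skinMean,
            textureSdLesion = textureSdLesion, textureSdSkin = textureSdSkin,
            nHairs = as.integer(nHairs), hairWidth = as.numeric(hairWidth),
            hairIntensity = hairIntensity,
            saltPepperFraction = saltPepperFraction, seed = as.integer(seed))
  if (p$imageSize < 16L) stop("imageSize must be >= 16")
  rr <- p$lesionRadiusRange
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] <= 0 || rr[2] >= 0.5)
    stop("lesionRadiusRange must lie within (0, 0.5)")
  lv <- c(p$lesionMean, p$skinMean, p$hairIntensity)
  if (any(lv < 0 | lv > 255)) stop("intensity levels must lie in [0, 255]")
  if (p$saltPepperFraction < 0 || p$saltPepperFraction > 0.2)
    stop("saltPepperFraction must lie in [0, 0.2]")
  if (!all(c("melanoma", "nevus") %in% names(p$borderIrregularity)) ||
      !all(c("melanoma", "nevus") %in% names(p$textureSdLesion)))
    stop("borderIrregularity and textureSdLesion need 'melanoma' and 'nevus' entries")
  class(p) <- "SyntheticParams"
  p
}

.classKey <- function(label) if (label > 0) "melanoma" else "nevus"

## Spatially correlated Gaussian texture field: white noise smoothed with a
## separable Gaussian kernel (pigmented-lesion texture is blotchy at a
## supra-pixel scale, not independent per pixel), then rescaled to the
## requested intensity SD.
.smoothNoise <- function(size, sd, sigma = 1.5) {
  if (sd <= 0) return(matrix(0, size, size))
  f <- matrix(stats::rnorm(size * size), size, size)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  g <- matrix(0, size, size)
  for (i in seq_along(k)) g <- g + k[i] * shiftReplicate(f, i - r - 1L, 0L)
  out <- matrix(0, size, size)
  for (i in seq_along(k)) out <- out + k[i] * shiftReplicate(g, 0L, i - r - 1L)
  out / stats::sd(out) * sd
}

## Blend an anti-aliased curved stroke into every channel of an RGB array.
.drawHair <- function(img, intensity, width, size) {
  p0 <- stats::runif(2, 1, size)
  ang <- stats::runif(1, 0, 2 * pi)
  dirv <- c(cos(ang), sin(ang))
  perp <- c(-dirv[2], dirv[1])
  len <- stats::runif(1, 0.4, 1.2) * size
  curv <- stats::runif(1, -0.15, 0.15) * len
  tt <- seq(0, 1, length.out = 24)
  pts <- cbind(p0[1] + tt * len * dirv[1] + sin(tt * pi) * curv * perp[1],
               p0[2] + tt * len * dirv[2] + sin(tt * pi) * curv * perp[2])
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dmin <- matrix(Inf, size, size)
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    if (ab2 == 0) next
    t <- .clamp(((rows - a[1]) * ab[1] + (cols - a[2]) * ab[2]) / ab2, 0, 1)
    dx <- rows - (a[1] + t * ab[1])
    dy <- cols - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  alpha <- .clamp(width / 2 + 0.5 - dmin, 0, 1)
  for (ch in 1:3) img[, , ch] <- alpha * intensity + (1 - alpha) * img[, , ch]
  img
}

#' Generate one synthetic labelled lesion sample
#'
#' Draws an elliptical lesion with a per-angle radial border perturbation,
#' fills lesion and skin with spatially correlated Gaussian texture of
#' class-dependent amplitude (correlation length about 1.5 px), freezes the
#' ground-truth mask, then paints anti-aliased hair strokes and finally
#' salt-and-pepper impulse noise. Identical seed, parameters and label
#' reproduce an identical sample.
#'
#' @param params a \code{\link{syntheticParams}} object.
#' @param label +1 (melanoma) or -1 (nevus).
#' @param seed RNG seed; defaults to \code{params$seed}.
#' @return A \linkS4class{LabeledSample}.
#' @export
generateLesionImage <- function(params = syntheticParams(), label = 1,
                                seed = params$seed) {
  stopifnot(inherits(params, "SyntheticParams"), label %in% c(-1, 1))
  size <- params$imageSize
  key <- .classKey(label)
  bi <- unname(params$borderIrregularity[key])
  rmax <- params$lesionRadiusRange[2]
  if (rmax * (1 + bi) >= 0.5)
    stop("lesion radius range forces the lesion outside the image frame")
  withSeed(seed, {
    ra <- stats::runif(1, params$lesionRadiusRange[1], rmax) * size
    rb <- stats::runif(1, params$lesionRadiusRange[1], rmax) * size
    ang <- stats::runif(1, 0, pi)
    maxExtent <- max(ra, rb) * (1 + bi)
    jit <- min(3, max(0, size / 2 - maxExtent - 2))
    center <- (size + 1) / 2 + stats::runif(2, -jit, jit)
    noiseFun <- if (bi > 0) {
      k <- 2:6
      amp <- stats::rnorm(length(k)) / k
      phase <- stats::runif(length(k), 0, 2 * pi)
      grid <- seq(0, 2 * pi, length.out = 1024)
      peak <- max(abs(colSums(amp * sin(outer(k, grid) + phase))))
      function(theta) colSums(amp * sin(outer(k, theta) + phase)) / max(peak, 1e-12)
    } else function(theta) rep(0, length(theta))

    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    x <- cols - center[2]; y <- rows - center[1]
    u <- x * cos(ang) + y * sin(ang)
    v <- -x * sin(ang) + y * cos(ang)
    e <- sqrt((u / ra)^2 + (v / rb)^2)
    theta <- atan2(v / rb, u / ra)
    mask <- e <= 1 + bi * noiseFun(as.vector(theta))

    sdL <- unname(params$textureSdLesion[key])
    base <- params$skinMean + .smoothNoise(size, params$textureSdSkin)
    lesionField <- .smoothNoise(size, sdL)
    base[mask] <- params$lesionMean + lesionField[mask]

    img <- array(0, dim = c(size, size, 3L))
    img[, , 1] <- base + 8
    img[, , 2] <- base
    img[, , 3] <- base - 8

    nh <- if (params$nHairs[1] == params$nHairs[2]) params$nHairs[1] else
      sample(params$nHairs[1]:params$nHairs[2], 1L)
    if (nh > 0) for (i in seq_len(nh)) {
      w <- stats::runif(1, params$hairWidth[1], params$hairWidth[2])
      img <- .drawHair(img, params$hairIntensity, w, size)
    }

    if (params$saltPepperFraction > 0) {
      npx <- round(params$saltPepperFraction * size * size)
      if (npx > 0) {
        idx <- sample.int(size * size, npx)
        val <- ifelse(stats::runif(npx) < 0.5, 0, 255)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[idx] <- val
          img[, , ch] <- plane
        }
      }
    }

    img <- round(.clamp(img, 0, 255))
    methods::new("LabeledSample", image = img, mask = mask, label = as.numeric(label))
  })
}

#' Generate a seeded dataset of synthetic lesion samples
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' the dataset is reproducible and samples are independent of the requested
#' counts of the other class.
#'
#' @param nMelanoma,nNevus non-negative sample counts per class.
#' @param params a \code{\link{syntheticParams}} object.
#' @param seed master RNG seed.
#' @return A list of \linkS4class{LabeledSample}; melanomas (+1) first.
#' @export
generateDataset <- function(nMelanoma, nNevus, params = syntheticParams(),
                            seed = params$seed) {
  stopifnot(nMelanoma >= 0, nNevus >= 0)
  labels <- c(rep(1, nMelanoma), rep(-1, nNevus))
  lapply(seq_along(labels), function(i)
    generateLesionImage(params, labels[i], seed = deriveSeed(seed, i)))
}

#' Labels of a list of samples
#' @param samples list of \linkS4class{LabeledSample}.
#' @return numeric vector of +1/-1 labels.
#' @export
sampleLabels <- function(samples) vapply(samples, sampleLabel, numeric(1))
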