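## Low-level pixel utilities shared by the preprocessing, segmentation and
## descriptor stages. All neighbourhood operations use edge replication at
## the image border and operate on plain numeric matrices (rows = image
## rows, columns = image columns).

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.isGray <- function(img) is.matrix(img) && is.numeric(img)

.isRGB <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

.assertGray <- function(img) {
  if (!.isGray(img)) stop("expected a grayscale image (numeric matrix)", call. = FALSE)
  if (nrow(img) < 3L || ncol(img) < 3L) stop("image dimensions must be >= 3", call. = FALSE)
  invisible(img)
}

.assertRGB <- function(img) {
  if (!.isRGB(img)) stop("expected an RGB image (height x width x 3 array)", call. = FALSE)
  if (dim(img)[1] < 3L || dim(img)[2] < 3L) stop("image dimensions must be >= 3", call. = FALSE)
  invisible(img)
}

## Shift a matrix by (dr, dc) with edge replication:
## out[i, j] = m[clamp(i + dr), clamp(j + dc)].
shiftReplicate <- function(m, dr, dc) {
  ri <- .clamp(seq_len(nrow(m)) + dr, 1L, nrow(m))
  ci <- .clamp(seq_len(ncol(m)) + dc, 1L, ncol(m))
  m[ri, ci, drop = FALSE]
}

## Offsets (dr, dc) of a flat disk structuring element: dr^2 + dc^2 <= r^2.
diskOffsets <- function(radius) {
  if (radius < 1) stop("structuring element radius must be >= 1", call. = FALSE)
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

.squareOffsets <- function(halfwidth) {
  g <- expand.grid(dr = -halfwidth:halfwidth, dc = -halfwidth:halfwidth)
  as.matrix(g)
}

## Grayscale erosion / dilation: min / max over the structuring element,
## with edge replication outside the frame.
grayErode <- function(img, offsets) {
  out <- shiftReplicate(img, offsets[1, 1], offsets[1, 2])
  for (k in seq_len(nrow(offsets))[-1])
    out <- pmin(out, shiftReplicate(img, offsets[k, 1], offsets[k, 2]))
  out
}

grayDilate <- function(img, offsets) {
  out <- shiftReplicate(img, offsets[1, 1], offsets[1, 2])
  for (k in seq_len(nrow(offsets))[-1])
    out <- pmax(out, shiftReplicate(img, offsets[k, 1], offsets[k, 2]))
  out
}

grayClose <- function(img, offsets) grayErode(grayDilate(img, offsets), offsets)

binaryErode <- function(mask, offsets) grayErode(mask * 1, offsets) > 0.5

binaryDilate <- function(mask, offsets) grayDilate(mask * 1, offsets) > 0.5

binaryOpen <- function(mask, offsets) binaryDilate(binaryErode(mask, offsets), offsets)

binaryClose <- function(mask, offsets) binaryErode(binaryDilate(mask, offsets), offsets)

## Column-wise cumulative sums without per-column loops.
.colCumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  if (ncol(m) > 1L) {
    adj <- c(0, cs[nrow(m), -ncol(m)])
    cs <- sweep(cs, 2L, adj)
  }
  cs
}

## Sum over a (2h+1) x (2h+1) window centred at each pixel, edge replicated,
## computed with an integral image.
boxSum <- function(m, halfwidth) {
  h <- halfwidth
  ri <- .clamp(seq(1L - h, nrow(m) + h), 1L, nrow(m))
  ci <- .clamp(seq(1L - h, ncol(m) + h), 1L, ncol(m))
  p <- m[ri, ci, drop = FALSE]
  ii <- rbind(0, .colCumsum(p))
  ii <- cbind(0, t(.colCumsum(t(ii))))
  n <- nrow(m); k <- ncol(m); w <- 2L * h + 1L
  ii[(1L + w):(n + w), (1L + w):(k + w), drop = FALSE] -
    ii[1:n, (1L + w):(k + w), drop = FALSE] -
    ii[(1L + w):(n + w), 1:k, drop = FALSE] +
    ii[1:n, 1:k, drop = FALSE]
}

## Connected-component labelling (default 8-connectivity) by breadth-first
## search over linear pixel indices.
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  todo <- which(mask)
  visited <- !mask
  cur <- 0L
  for (seed in todo) {
    if (visited[seed]) next
    cur <- cur + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; ccc <- cc + dc[k]
        ok <- rr >= 1L & rr <= h & ccc >= 1L & ccc <= w
        j <- (ccc[ok] - 1L) * h + rr[ok]
        j <- j[!visited[j]]
        if (length(j)) {
          j <- unique(j)
          visited[j] <- TRUE
          lab[j] <- cur
          nxt <- c(nxt, j)
        }
      }
      frontier <- nxt
    }
  }
  lab
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return A number in \[0, 1\]; 1 when both masks are empty.
#' @export
maskIoU <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-sample seed derived from a master seed; exact in double
## arithmetic and always below 2^31.
deriveSeed <- function(master, index) {
  s <- as.numeric(master) %% 2147483647
  s <- (s * 16807) %% 2147483647
  s <- (s + as.numeric(index) * 2654435 + 7919) %% 2147483647
  s <- (s * 16807) %% 2147483647
  as.integer(s %% 2147483647)
}
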