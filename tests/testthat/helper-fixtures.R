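# Brute-force oracles and small fixtures used across the suite. Every oracle
# is an independent, direct realization of the defining formula (double
# loops, exhaustive search), kept free of the package's vectorized code
# paths.

randGray <- function(n, m = n, seed = 1, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, n * m, replace = TRUE), n, m)
}

randMask <- function(n, m = n, seed = 1, p = 0.5) {
  set.seed(seed)
  matrix(runif(n * m) < p, n, m)
}

# edge-replicated pixel lookup
.at <- function(img, r, c) {
  img[min(max(r, 1), nrow(img)), min(max(c, 1), ncol(img))]
}

bruteMedianFilter <- function(img, window) {
  h <- (window - 1) / 2
  out <- img
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    v <- c()
    for (dr in -h:h) for (dc in -h:h) v <- c(v, .at(img, r + dr, c + dc))
    out[r, c] <- sort(v)[(length(v) + 1) / 2]
  }
  out
}

# grayscale closing with a disk: max then min over the disk window,
# edge replicated
bruteClose <- function(img, radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  slide <- function(im, f) {
    out <- im
    for (r in seq_len(nrow(im))) for (c in seq_len(ncol(im))) {
      v <- mapply(function(dr, dc) .at(im, r + dr, c + dc), off$dr, off$dc)
      out[r, c] <- f(v)
    }
    out
  }
  slide(slide(img, max), min)
}

bruteOtsu <- function(img) {
  v <- as.integer(round(img))
  best <- -Inf; bestCut <- NA
  n <- length(v)
  for (cut in 1:255) {
    lo <- v[v < cut]; hi <- v[v >= cut]
    if (!length(lo) || !length(hi)) next
    s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; bestCut <- cut }
  }
  bestCut
}

bruteBinaryMajority <- function(mask, window) {
  h <- (window - 1) / 2
  out <- mask
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    v <- 0
    for (dr in -h:h) for (dc in -h:h) v <- v + .at(mask, r + dr, c + dc)
    out[r, c] <- v > window^2 / 2
  }
  out
}

# stack-based flood fill, 8-connectivity
bruteLabel <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1) %% nrow(mask) + 1; c <- (p - 1) %/% nrow(mask) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          q <- (cc - 1) * nrow(mask) + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
        }
      }
    }
  }
  lab
}

# per-pixel double-loop LBP histogram; offsets in raster order over the
# square ring of the given radius
bruteLBPCodes <- function(img, radius) {
  off <- expand.grid(dc = -radius:radius, dr = -radius:radius)
  off <- off[!(off$dr == 0 & off$dc == 0), c("dr", "dc")]
  off <- off[order(off$dr, off$dc), ]
  codes <- c()
  for (r in (radius + 1):(nrow(img) - radius))
    for (c in (radius + 1):(ncol(img) - radius)) {
      code <- 0
      for (p in seq_len(nrow(off))) {
        g <- img[r + off$dr[p], c + off$dc[p]]
        if (g >= img[r, c]) code <- code + 2^(p - 1)
      }
      codes <- c(codes, code)
    }
  codes
}

# parameters that switch off all stochastic corruption
cleanParams <- function(...) {
  syntheticParams(nHairs = c(0L, 0L), saltPepperFraction = 0, ...)
}

flatParams <- function() {
  syntheticParams(nHairs = c(0L, 0L), saltPepperFraction = 0,
                  borderIrregularity = c(melanoma = 0, nevus = 0),
                  textureSdLesion = c(melanoma = 0, nevus = 0),
                  textureSdSkin = 0)
}
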