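test_that("Otsu threshold separates bimodal data and matches exhaustive search", {
  img <- matrix(c(rep(10, 128), rep(200, 128)), 16)
  t <- otsuThreshold(img)
  expect_gte(t, 11)
  expect_lte(t, 200)
  expect_identical(unname(table(img < t)), unname(table(img >= 135)))
  for (seed in 1:5) {
    r <- randGray(16, seed = seed)
    expect_equal(otsuThreshold(r), bruteOtsu(r))
  }
  bw <- matrix(c(rep(0, 40), rep(255, 60)), 10)
  t2 <- otsuThreshold(bw)
  expect_identical(bw < t2, bw == 0)
  expect_error(otsuThreshold(matrix(7, 5, 5)), "constant")
})

test_that("per-channel masks recover a noise-free ellipse", {
  s <- generateLesionImage(flatParams(), 1, seed = 11)
  masks <- channelMasks(sampleImage(s))
  for (m in masks) expect_identical(m, sampleMask(s))
  # channel-wise identical image -> identical masks
  g <- randGray(20, seed = 3)
  rgb <- array(rep(g, 3), c(20, 20, 3))
  masks2 <- channelMasks(rgb)
  expect_identical(masks2[[1]], masks2[[2]])
  expect_identical(masks2[[2]], masks2[[3]])
  # default (noisy, hairy) melanoma still overlaps ground truth well
  s2 <- generateLesionImage(syntheticParams(), 1, seed = 12)
  prep <- preprocessImage(sampleImage(s2))
  for (m in channelMasks(prep)) expect_gte(maskIoU(m, sampleMask(s2)), 0.7)
})

test_that("mask fusion is a per-pixel majority vote", {
  m <- randMask(8, seed = 1)
  expect_identical(fuseMasks(list(m, m, m)), m)
  allT <- matrix(TRUE, 8, 8); allF <- matrix(FALSE, 8, 8)
  expect_identical(fuseMasks(list(allT, allT, allF)), allT)
  a <- randMask(8, seed = 2); b <- randMask(8, seed = 3); c <- randMask(8, seed = 4)
  votes <- a + b + c
  expect_identical(fuseMasks(list(a, b, c)), votes >= 2)
  expect_identical(fuseMasks(list(a, b, c), "union"), votes >= 1)
  expect_identical(fuseMasks(list(a, b, c), "intersection"), votes == 3)
  # permutation invariance
  expect_identical(fuseMasks(list(a, b, c)), fuseMasks(list(c, a, b)))
  expect_error(fuseMasks(list(a, b, randMask(9, seed = 5))), "dimensions")
})

test_that("morphological opening removes specks and keeps large disks", {
  disk <- (row(matrix(0, 31, 31)) - 16)^2 + (col(matrix(0, 31, 31)) - 16)^2 <= 100
  expect_gte(maskIoU(morphologicalOpen(disk, 3), disk), 0.95)
  speck <- matrix(FALSE, 15, 15); speck[8, 8] <- TRUE
  expect_false(any(morphologicalOpen(speck, 2)))
  allT <- matrix(TRUE, 12, 12)
  expect_true(all(morphologicalOpen(allT, 3)))
})

test_that("iterative median smoothing fills holes and matches brute force", {
  allT <- matrix(TRUE, 20, 20)
  expect_true(all(iterativeMedianSmooth(allT)))
  sq <- matrix(TRUE, 30, 30)
  set.seed(6)
  sq[sample(900, 20)] <- FALSE
  expect_true(all(iterativeMedianSmooth(sq)))
  m <- randMask(12, seed = 7)
  expect_identical(iterativeMedianSmooth(m),
                   bruteBinaryMajority(bruteBinaryMajority(
                     bruteBinaryMajority(m, 7), 5), 3))
})

test_that("open-close filter reaches a fixed point and repairs specks/holes", {
  allF <- matrix(FALSE, 10, 10)
  expect_identical(openCloseFilter(allF, 2), allF)
  blob <- (row(matrix(0, 40, 40)) - 20)^2 + (col(matrix(0, 40, 40)) - 20)^2 <= 144
  m <- blob
  m[20, 20] <- FALSE      # 1-px hole inside the blob
  m[3, 3] <- TRUE         # 1-px speck far away
  out <- openCloseFilter(m, 2)
  expect_false(out[3, 3])
  expect_true(out[20, 20])
  stable <- openCloseFilter(blob, 2)
  expect_identical(openCloseFilter(stable, 2), stable)
})

test_that("size filter drops components under the 5% area cutoff", {
  m <- matrix(FALSE, 150, 150)
  m[10:54, 10:34] <- TRUE            # 45 x 25 = 1125 px = 5.0%
  m[100:129, 100:129] <- TRUE        # 30 x 30 =  900 px = 4.0%
  out <- sizeFilter(m, 0.05)
  expect_true(all(out[10:54, 10:34]))
  expect_false(any(out[100:129, 100:129]))
  # idempotence and the empty case
  expect_identical(sizeFilter(out, 0.05), out)
  empty <- matrix(FALSE, 20, 20)
  expect_identical(sizeFilter(empty), empty)
  # random blobs against the flood-fill oracle
  for (seed in 1:3) {
    rm <- randMask(40, seed = seed, p = 0.35)
    lab <- bruteLabel(rm)
    areas <- tabulate(lab[lab > 0])
    keepLab <- which(areas >= 0.02 * length(rm))
    expect_identical(sizeFilter(rm, 0.02), rm & matrix(lab %in% keepLab, 40, 40))
  }
})

test_that("contour tracing returns ordered closed boundaries", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  ct <- traceContour(sq)
  expect_equal(nrow(ct), 8L)
  expect_setequal(paste(ct[, 1], ct[, 2]),
                  paste(c(2, 2, 2, 3, 3, 4, 4, 4), c(2, 3, 4, 2, 4, 2, 3, 4)))
  expect_equal(ct[1, ], c(row = 2, col = 2))
  # consecutive points (and the closing step) are 8-connected
  nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
  expect_true(all(pmax(abs(nxt[, 1] - ct[, 1]), abs(nxt[, 2] - ct[, 2])) == 1))
  # counterclockwise orientation in a y-up frame
  x <- ct[, 2]; y <- -ct[, 1]; n <- nrow(ct)
  expect_gt(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y), 0)
  single <- matrix(FALSE, 4, 4); single[2, 3] <- TRUE
  cs <- traceContour(single)
  expect_equal(nrow(cs), 1L)
  expect_true(isTRUE(attr(cs, "degenerate")))
  r <- 20
  disk <- (row(matrix(0, 61, 61)) - 31)^2 + (col(matrix(0, 61, 61)) - 31)^2 <= r^2
  len <- nrow(traceContour(disk))
  expect_gte(len, 2 * pi * r * 0.8)
  expect_lte(len, 2 * pi * r * 1.5)
  expect_error(traceContour(matrix(FALSE, 5, 5)), "no lesion")
})

test_that("full segmentation is accurate on clean synthetic lesions", {
  for (seed in c(31, 32)) {
    s <- generateLesionImage(cleanParams(), if (seed %% 2) 1 else -1, seed = seed)
    seg <- segmentLesion(sampleImage(s))
    expect_gte(maskIoU(seg$mask, sampleMask(s)), 0.95)
    expect_gte(nrow(seg$contour), 3L)
  }
  flat <- array(120, c(30, 30, 3))
  expect_error(segmentLesion(flat), "no lesion found")
})

test_that("segmentation stages preserve dimensions and determinism", {
  s <- generateLesionImage(syntheticParams(), 1, seed = 41)
  prep <- preprocessImage(sampleImage(s))
  a <- segmentLesion(prep)
  b <- segmentLesion(prep)
  expect_identical(a$mask, b$mask)
  expect_identical(a$contour, b$contour)
  expect_equal(dim(a$mask), dim(prep)[1:2])
})
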