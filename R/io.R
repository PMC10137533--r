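#' Read an image file
#'
#' PNG files are read with \pkg{png}; JPEG and TIFF need \pkg{EBImage}.
#' Intensities are returned on the 8-bit 0..255 scale, as a grayscale
#' matrix or an RGB array (any alpha channel is dropped).
#'
#' @param path image file path.
#' @return numeric matrix or height x width x 3 array.
#' @importFrom tools file_ext
#' @export
readLesionImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading ", ext, " files requires the EBImage package")
    img <- EBImage::readImage(path)
    a <- as.array(img)
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 1L) a <- a[, , 1L]
    else if (dim(a)[3] > 3L) a <- a[, , 1:3]
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 2L) a <- a[, , 1L]
  round(a * 255)
}

#' Write an image as PNG
#'
#' @param image grayscale matrix or RGB array on the 0..255 scale.
#' @param path output path.
#' @export
writeLesionImage <- function(image, path) {
  png::writePNG(.clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Write a binary mask as a black-and-white PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' @param path image path; pixels above half intensity are lesion.
#' @return logical matrix.
#' @export
readMaskPNG <- function(path) {
  m <- readLesionImage(path)
  if (.isRGB(m)) m <- m[, , 1L]
  m > 127.5
}

#' Write a synthetic dataset to disk
#'
#' Images as PNG, ground-truth masks as black-and-white PNG, and a CSV
#' manifest with columns \code{filename}, \code{label},
#' \code{mask_filename}.
#'
#' @param samples list of \linkS4class{LabeledSample}.
#' @param dir output directory (created if missing).
#' @return path of the written manifest, invisibly.
#' @export
writeDataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    fn <- sprintf("sample_%03d.png", i)
    mf <- sprintf("mask_%03d.png", i)
    writeLesionImage(sampleImage(samples[[i]]), file.path(dir, fn))
    writeMaskPNG(sampleMask(samples[[i]]), file.path(dir, mf))
    data.frame(filename = fn, label = sampleLabel(samples[[i]]),
               mask_filename = mf)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset described by a CSV manifest
#'
#' @param manifestPath path of a manifest with columns \code{filename},
#'   \code{label} and optionally \code{mask_filename}, resolved relative to
#'   the manifest's directory.
#' @return list of \linkS4class{LabeledSample}; when no mask column is
#'   present, all-false masks are attached.
#' @export
readDataset <- function(manifestPath) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(man)), function(i) {
    img <- readLesionImage(file.path(base, man$filename[i]))
    if (!.isRGB(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    mask <- if ("mask_filename" %in% names(man) &&
                nzchar(man$mask_filename[i]) && !is.na(man$mask_filename[i]))
      readMaskPNG(file.path(base, man$mask_filename[i]))
    else matrix(FALSE, dim(img)[1], dim(img)[2])
    methods::new("LabeledSample", image = img, mask = mask,
                 label = as.numeric(man$label[i]))
  })
}

#' Write a sparse N-LBP histogram as tab-separated text
#'
#' One \code{code<TAB>count} line per nonzero bin, codes ascending.
#'
#' @param hist a \linkS4class{SparseHistogram}.
#' @param path output path.
#' @export
writeSparseHistogram <- function(hist, path) {
  df <- histCounts(hist)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse histogram written by \code{writeSparseHistogram}
#'
#' @param path input path.
#' @param domainSize code-space size (default 2^24).
#' @return a \linkS4class{SparseHistogram}.
#' @export
readSparseHistogram <- function(path, domainSize = 2^24) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("code", "count"))
  methods::new("SparseHistogram", codes = as.numeric(df$code),
               counts = as.numeric(df$count), domainSize = domainSize)
}
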