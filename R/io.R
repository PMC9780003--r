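# PNG and manifest I/O plus small raster utilities.

#' Read an RGB image PNG as an H x W x 3 array in \[0,1\]
#' @param path PNG file.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an H x W x 3 array in \[0,1\] as an 8-bit RGB PNG
#' @param image array; values clipped to \[0,1\].
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}

#' Read a binary mask PNG (0/255) as a 0/1 matrix
#' @param path PNG file.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0.5) * 1
}

#' Write a 0/1 matrix as an 8-bit grayscale PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0.5) * 1, path)
  invisible(path)
}

#' Read a dataset manifest (CSV)
#'
#' Columns `image,tongue_mask,coating_mask,label`; relative paths are
#' resolved against the manifest's directory. Validates that every
#' referenced file exists and every label is a known class.
#'
#' @param path manifest CSV.
#' @param check if TRUE, verify referenced files exist.
#' @export
read_manifest <- function(path, check = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "tongue_mask", "coating_mask", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  base <- dirname(normalizePath(path))
  for (col in c("image", "tongue_mask", "coating_mask")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  bad <- !(m$label %in% TONGUE_CLASSES)
  if (any(bad)) stop("unknown label in manifest row(s) ",
                     paste(which(bad), collapse = ", "))
  if (check) {
    for (col in c("image", "tongue_mask", "coating_mask")) {
      miss <- !file.exists(m[[col]])
      if (any(miss))
        stop("manifest row ", which(miss)[1], ": missing file ",
             m[[col]][which(miss)[1]])
    }
  }
  m
}

#' Bilinear resize of an image or matrix
#' @param image H x W x C array or H x W matrix.
#' @param h,w target size.
#' @export
resize_bilinear <- function(image, h, w) {
  mat_in <- is.matrix(image)
  if (mat_in) image <- array(image, dim = c(dim(image), 1))
  d <- dim(image)
  sr <- pmin(pmax((seq_len(h) - 0.5) * d[1] / h + 0.5, 1), d[1])
  sc <- pmin(pmax((seq_len(w) - 0.5) * d[2] / w + 0.5, 1), d[2])
  r0 <- floor(sr); r1 <- pmin(r0 + 1, d[1]); fr <- sr - r0
  c0 <- floor(sc); c1 <- pmin(c0 + 1, d[2]); fc <- sc - c0
  out <- array(0, dim = c(h, w, d[3]))
  wrr <- outer(1 - fr, 1 - fc); wrc <- outer(1 - fr, fc)
  wcr <- outer(fr, 1 - fc); wcc <- outer(fr, fc)
  for (ch in seq_len(d[3])) {
    A <- image[, , ch]
    out[, , ch] <- A[r0, c0] * wrr + A[r0, c1] * wrc +
      A[r1, c0] * wcr + A[r1, c1] * wcc
  }
  if (mat_in) out[, , 1] else out
}

#' Intersection-over-union of two binary masks
#' @param a,b 0/1 matrices of the same size.
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(1)
  inter / uni
}
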