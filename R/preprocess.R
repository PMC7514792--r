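#' Read / write fundus images
#'
#' Reads an 8-bit RGB PNG or JPEG into the package's internal representation:
#' an H x W x 3 numeric array on the 0-255 scale, row-major, 1-based pixel
#' coordinates.
#'
#' @param path file path (extension decides the decoder).
#' @return numeric H x W x 3 array with values in \[0, 255\].
#' @export
readFundus <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' @rdname readFundus
#' @param img numeric H x W x 3 array (0-255) or a logical matrix (masks are
#'   written as 0/255 grayscale).
#' @export
writeFundus <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Estimate the field-of-view circle of a fundus image
#'
#' The FOV diameter is first estimated from the median-smoothed intensity
#' profile along the main image diagonal (first/last crossings of 10% of the
#' profile maximum); the circular Hough transform on a Sobel edge map of the
#' red channel, searched over radii within 10% of the profile estimate, then
#' fixes the center and refines the radius.
#'
#' @param img numeric H x W x 3 fundus array, values 0-255.
#' @return named numeric vector `c(centerRow, centerCol, diameter)` (pixels).
#' @export
estimateFovGeometry <- function(img) {
  assertFundus(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3

  L <- max(H, W)
  t <- seq_len(L)
  rr <- round(1 + (t - 1) * (H - 1) / (L - 1))
  cc <- round(1 + (t - 1) * (W - 1) / (L - 1))
  prof <- gray[cbind(rr, cc)]
  prof <- stats::runmed(prof, 15)
  if (max(prof) <= 1)
    stop("fov-not-found: no bright disk-like region in the image")
  thr <- 0.1 * max(prof)
  above <- which(prof > thr)
  i1 <- above[1]; i2 <- above[length(above)]
  dProfile <- sqrt((rr[i2] - rr[i1])^2 + (cc[i2] - cc[i1])^2)
  if (dProfile <= 0.3 * min(H, W) || dProfile >= 1.2 * min(H, W))
    stop("fov-not-found: diagonal profile yields an implausible diameter")

  # Sobel edge magnitude of the red channel
  red <- img[, , 1]
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- conv2Direct(red, sx)
  gy <- conv2Direct(red, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  keep <- which(mag >= 0.3 * max(mag))
  if (length(keep) > 1500) {
    keep <- keep[order(mag[keep], decreasing = TRUE)[1:1500]]
  }
  er <- ((keep - 1) %% H) + 1
  ec <- ((keep - 1) %/% H) + 1

  r0 <- dProfile / 2
  radii <- seq(round(0.9 * r0), round(1.1 * r0), by = max(1, round(r0 / 100)))
  hh <- hough_circle_cpp(as.integer(er), as.integer(ec), as.integer(radii),
                         H, W)
  center <- c(hh$row, hh$col)
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W)
    stop("fov-not-found: Hough center outside the grid")
  c(centerRow = center[1], centerCol = center[2], diameter = 2 * hh$radius)
}

#' Build a circular FOV mask
#'
#' @param centerRow,centerCol circle center (pixels, 1-based).
#' @param diameter circle diameter in pixels (> 0).
#' @param shape c(height, width) of the grid.
#' @return a [FovMask-class].
#' @export
buildFovMask <- function(centerRow, centerCol, diameter, shape) {
  if (diameter <= 0) stop("diameter must be positive")
  if (centerRow < 1 || centerRow > shape[1] ||
      centerCol < 1 || centerCol > shape[2])
    stop("center must lie inside the grid")
  r <- diameter / 2
  inside <- outer((seq_len(shape[1]) - centerRow)^2,
                  (seq_len(shape[2]) - centerCol)^2, "+") <= r^2
  new("FovMask", inside = inside, centerRow = centerRow,
      centerCol = centerCol, radius = r)
}

#' Iterative FOV extension
#'
#' Removes the hard aperture border: the FOV mask is dilated one step at a
#' time with a 4-neighborhood diamond structuring element, and each newly
#' included pixel takes the average of its 8-neighbors already inside the
#' previous mask, per RGB channel, until the mask covers the whole canvas.
#' Pixels inside the original mask are bit-identical to the input.
#'
#' @param img numeric H x W x 3 fundus array (0-255).
#' @param mask a [FovMask-class] with at least one interior pixel.
#' @return a [PreprocessedImage-class].
#' @export
extendFov <- function(img, mask) {
  assertFundus(img)
  if (!is(mask, "FovMask")) stop("mask must be a FovMask")
  if (!any(mask@inside)) stop("mask has no interior pixel")
  if (!identical(dim(img)[1:2], dim(mask@inside)))
    stop("image and mask differ in shape")
  res <- fov_extend_cpp(img * 1.0, mask@inside)
  new("PreprocessedImage", pixels = res$pixels, fov = mask,
      extension = list(iterations = res$iterations, added = res$added))
}

#' Full preprocessing: locate the FOV and extend it
#'
#' @param img numeric H x W x 3 fundus array (0-255).
#' @return a [PreprocessedImage-class].
#' @export
preprocessFundus <- function(img) {
  g <- estimateFovGeometry(img)
  mask <- buildFovMask(g["centerRow"], g["centerCol"], g["diameter"],
                       dim(img)[1:2])
  extendFov(img, mask)
}
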