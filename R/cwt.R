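# Mexican-hat continuous wavelet sharpness features: isotropic wavelet
# response at six dyadic scales, coefficient entropy over the FOV, and
# mean/SD of circular-window local variance maps.

#' Sampled 2-D Mexican-hat wavelet kernel
#'
#' Psi(x, y, s) = 1/(pi s^4) (1 - r^2/(2 s^2)) exp(-r^2/(2 s^2)) sampled on a
#' square support of half-width ceil(3.5 s); the (tiny) truncation-induced
#' mean is subtracted so the discrete kernel sums exactly to zero.
#'
#' @param s wavelet scale (>= 1).
#' @return square numeric matrix of odd size.
#' @export
mexicanHatKernel <- function(s) {
  if (s < 1) stop("scale must be >= 1")
  hw <- ceiling(3.5 * s)
  x <- seq(-hw, hw)
  r2 <- outer(x^2, x^2, "+") / (2 * s^2)
  k <- (1 / (pi * s^4)) * (1 - r2) * exp(-r2)
  k - mean(k)
}

#' Mexican-hat wavelet transform of an image channel
#'
#' Same-size 2-D convolution (FFT, reflect padding) of the channel with
#' [mexicanHatKernel()]; the isotropic wavelet makes the rotation angle
#' irrelevant.
#'
#' @param imgGreen numeric matrix (green channel of a preprocessed image).
#' @param s wavelet scale.
#' @return coefficient matrix, same shape as the input.
#' @export
cwtTransform <- function(imgGreen, s) {
  k <- mexicanHatKernel(s)
  if (nrow(k) > min(dim(imgGreen)))
    stop("wavelet kernel larger than the image")
  conv2FFT(imgGreen, k, "reflect", tag = sprintf("mh%g", s))[[1]]
}

#' Shannon entropy of wavelet coefficients over the FOV
#'
#' 256 equal-width bins spanning the coefficient range inside the FOV;
#' a (numerically) constant map has entropy 0.
#'
#' @param map coefficient matrix; @param fov a [FovMask-class].
#' @return entropy in \[0, 8\] bits.
#' @export
cwtEntropy <- function(map, fov) {
  v <- map[fovInside(fov)]
  if (length(v) < 1) stop("FOV is empty")
  rng <- range(v)
  if (diff(rng) <= 1e-8 * max(1, max(abs(v)))) return(0)
  b <- pmin(floor((v - rng[1]) / diff(rng) * 256), 255)
  shannonEntropyBits(tabulate(as.integer(b) + 1L, 256L) / length(v))
}

# Local standard deviation over a circular window of radius r (centers
# within distance <= r); windows clipped at the canvas edge use the
# available pixels only (zero-padded sums with exact counts).
diskSdMap <- function(map, r, tag = NULL) {
  disk <- diskKernel(r)
  key <- sprintf("cnt_%d_%d_r%g", nrow(map), ncol(map), r)
  if (is.null(.retiqa$counts)) .retiqa$counts <- new.env(parent = emptyenv())
  cnt <- .retiqa$counts[[key]]
  dtag <- sprintf("disk%g", r)
  if (is.null(cnt)) {
    ones <- matrix(1, nrow(map), ncol(map))
    cnt <- pmax(round(conv2FFT(ones, disk, "zero", tag = dtag)[[1]]), 1)
    .retiqa$counts[[key]] <- cnt
  }
  sm <- conv2FFT(map, disk, "zero", tag = dtag, x2 = map * map)
  s1 <- sm[[1]]; s2 <- sm[[2]]
  varm <- (s2 - s1^2 / cnt) / pmax(cnt - 1, 1)
  sqrt(pmax(varm, 0))
}

#' Local-variance sharpness features at one scale
#'
#' Applies a circular standard-deviation filter of radius `s` to the
#' coefficient map, then returns the mean and the sample standard deviation
#' (divisor N - 1) of the local-deviation map over the N FOV pixels.
#'
#' @param map coefficient matrix from [cwtTransform()].
#' @param fov a [FovMask-class]; @param s the scale (filter radius).
#' @return named vector `c(mean, sd)`.
#' @export
localVarianceFeatures <- function(map, fov, s) {
  v <- diskSdMap(map, s)[fovInside(fov)]
  if (length(v) < 2) stop("need at least 2 FOV pixels")
  c(mean = mean(v), sd = sd(v))
}

# All coefficient maps at once: one reflect-padded forward FFT shared by
# every scale, kernel spectra cached per grid, inverse transforms packed in
# pairs. Numerically equivalent to calling cwtTransform() per scale.
cwtMapsAll <- function(imgGreen, scales) {
  kernels <- lapply(scales, mexicanHatKernel)
  hws <- vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1))
  if (max(2 * hws + 1) > min(dim(imgGreen)))
    stop("wavelet kernel larger than the image")
  hw <- max(hws)
  H <- nrow(imgGreen); W <- ncol(imgGreen)
  S1 <- goodSize(H + 2 * hw); S2 <- goodSize(W + 2 * hw)
  xp <- padReflect(imgGreen, hw, hw)
  emb <- matrix(0, S1, S2)
  emb[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  FF <- fft2_real_cpp(emb)
  if (is.null(.retiqa$spectra)) .retiqa$spectra <- new.env(parent = emptyenv())
  specs <- lapply(seq_along(scales), function(i) {
    key <- sprintf("mh%g_%d_%d", scales[i], S1, S2)
    ks <- .retiqa$spectra[[key]]
    if (is.null(ks)) {
      ks <- kernel_spectrum_cpp(kernels[[i]], S1, S2)
      .retiqa$spectra[[key]] <- ks
    }
    ks
  })
  crop <- function(m) m[hw + seq_len(H), hw + seq_len(W), drop = FALSE]
  maps <- vector("list", length(scales))
  i <- 1
  while (i <= length(scales)) {
    if (i + 1 <= length(scales)) {
      res <- ifft2_pack2_cpp(FF, specs[[i]], specs[[i + 1]])
      maps[[i]] <- crop(res$a)
      maps[[i + 1]] <- crop(res$b)
      i <- i + 2
    } else {
      res <- ifft2_pack2_cpp(FF, specs[[i]], matrix(complex(0), 0, 0))
      maps[[i]] <- crop(res$a)
      i <- i + 1
    }
  }
  names(maps) <- paste0("s", scales)
  maps
}

#' All 18 wavelet sharpness features
#'
#' Coefficient entropy, local-variance mean and SD at scales
#' s = 2, 4, 8, 16, 32, 64 on the green channel.
#'
#' @param img a [PreprocessedImage-class].
#' @param scales wavelet scales.
#' @return named numeric vector of 18 features
#'   (`cwt_{ent,mean,sd}_s{2,...,64}`).
#' @export
cwtFeatures <- function(img, scales = c(2, 4, 8, 16, 32, 64)) {
  g <- greenChannel(imagePixels(img))
  fov <- img@fov
  maps <- cwtMapsAll(g, scales)
  out <- numeric(0)
  for (s in scales) {
    map <- maps[[paste0("s", s)]]
    lv <- localVarianceFeatures(map, fov, s)
    v <- c(cwtEntropy(map, fov), lv["mean"], lv["sd"])
    names(v) <- paste0("cwt_", c("ent", "mean", "sd"), "_s", s)
    out <- c(out, v)
  }
  out
}
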