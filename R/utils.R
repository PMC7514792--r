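# Internal numerical helpers: padding, FFT convolution with spectrum
# caching, separable/direct convolution, bicubic resampling, DCT basis.

# Validate an 8-bit RGB fundus array (H x W x 3, values 0-255, >= 64 px).
assertFundus <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("fundus image must be an H x W x 3 array")
  if (d[1] < 64 || d[2] < 64)
    stop("fundus image must be at least 64 x 64 pixels")
  if (min(img) < 0 || max(img) > 255)
    stop("fundus pixel values must lie in [0, 255]")
  invisible(TRUE)
}

greenChannel <- function(x) {
  if (length(dim(x)) == 3) x[, , 2] else x
}

# Mirror (reflect-without-repeat) padding; pad must be <= dim - 1.
padReflect <- function(x, pr, pc = pr) {
  H <- nrow(x); W <- ncol(x)
  if (pr > H - 1 || pc > W - 1)
    stop("reflect padding wider than the grid")
  ri <- c(rev(seq_len(pr) + 1L), seq_len(H), H - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(W), W - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

padZero <- function(x, pr, pc = pr) {
  out <- matrix(0, nrow(x) + 2 * pr, ncol(x) + 2 * pc)
  out[pr + seq_len(nrow(x)), pc + seq_len(ncol(x))] <- x
  out
}

# Smallest 2^a * 3^b * 5^c size >= n (FFT-friendly grid).
goodSize <- function(n) {
  if (is.null(.retiqa$goodSizes)) {
    s <- sort(unique(as.vector(outer(
      outer(2^(0:12), 3^(0:7)), 5^(0:5)))))
    .retiqa$goodSizes <- s[s <= 6000 & s >= 16]
  }
  g <- .retiqa$goodSizes
  g[which(g >= n)[1]]
}

# Centered 2-D convolution via FFT. `tag` enables caching of the kernel
# spectrum (and, for boundary = "zero", nothing else) across calls with the
# same grid; pass NULL to skip caching. `x2` optionally packs a second real
# image into the same transform. Output has the size of `x` (list of one or
# two matrices).
conv2FFT <- function(x, kernel, boundary = c("reflect", "zero"), tag = NULL,
                     x2 = NULL) {
  boundary <- match.arg(boundary)
  H <- nrow(x); W <- ncol(x)
  hr <- (nrow(kernel) - 1) %/% 2
  hc <- (ncol(kernel) - 1) %/% 2
  S1 <- goodSize(H + 2 * hr)
  S2 <- goodSize(W + 2 * hc)
  key <- if (!is.null(tag)) sprintf("%s_%d_%d", tag, S1, S2)
  if (is.null(.retiqa$spectra)) .retiqa$spectra <- new.env(parent = emptyenv())
  kspec <- if (!is.null(key)) .retiqa$spectra[[key]]
  if (is.null(kspec)) {
    kspec <- kernel_spectrum_cpp(kernel, S1, S2)
    if (!is.null(key)) .retiqa$spectra[[key]] <- kspec
  }
  embed <- function(z) {
    zp <- if (boundary == "reflect") padReflect(z, hr, hc) else padZero(z, hr, hc)
    out <- matrix(0, S1, S2)
    out[seq_len(nrow(zp)), seq_len(ncol(zp))] <- zp
    out
  }
  p1 <- embed(x)
  p2 <- if (!is.null(x2)) embed(x2) else matrix(0, 0, 0)
  res <- conv2_packed_cpp(p1, p2, kspec)
  crop <- function(m) m[hr + seq_len(H), hc + seq_len(W), drop = FALSE]
  out <- list(crop(res$a))
  if (!is.null(x2)) out[[2]] <- crop(res$b)
  out
}

# Direct centered convolution via shifted accumulation (small kernels).
conv2Direct <- function(x, kernel, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  H <- nrow(x); W <- ncol(x)
  hr <- (nrow(kernel) - 1) %/% 2
  hc <- (ncol(kernel) - 1) %/% 2
  xp <- if (boundary == "reflect") padReflect(x, hr, hc) else padZero(x, hr, hc)
  out <- matrix(0, H, W)
  for (j in seq_len(ncol(kernel))) {
    for (i in seq_len(nrow(kernel))) {
      k <- kernel[i, j]
      if (k == 0) next
      out <- out + k * xp[(nrow(kernel) - i) + seq_len(H),
                          (ncol(kernel) - j) + seq_len(W), drop = FALSE]
    }
  }
  out
}

# Normalized 2-D Gaussian kernel truncated at `hw` pixels.
gaussianKernel2d <- function(sigma, hw = ceiling(3 * sigma)) {
  x <- seq(-hw, hw)
  g1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Binary disk kernel: centers within distance <= r.
diskKernel <- function(r) {
  x <- seq(-floor(r), floor(r))
  (outer(x^2, x^2, "+") <= r^2) * 1
}

# Orthonormal type-II DCT basis matrix (cached per size).
dctMatrix <- function(n) {
  key <- sprintf("dct_%d", n)
  if (is.null(.retiqa$dct)) .retiqa$dct <- new.env(parent = emptyenv())
  D <- .retiqa$dct[[key]]
  if (is.null(D)) {
    k <- 0:(n - 1)
    D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
    D[1, ] <- sqrt(1 / n)
    .retiqa$dct[[key]] <- D
  }
  D
}

# Keys cubic (a = -0.5) interpolation kernel.
cubicKernel <- function(t) {
  a <- abs(t)
  ifelse(a <= 1, 1.5 * a^3 - 2.5 * a^2 + 1,
         ifelse(a < 2, -0.5 * a^3 + 2.5 * a^2 - 4 * a + 2, 0))
}

# Row/column resampling weight matrix (nOut x nIn), bicubic with
# antialiasing when shrinking (kernel stretched by 1/scale), edge clamp.
resampleWeights <- function(nIn, nOut) {
  scale <- nOut / nIn
  h <- max(1, 1 / scale)
  support <- 2 * h
  u <- (seq_len(nOut) - 0.5) / scale + 0.5  # source coordinate, 1-based
  lo <- floor(u - support) + 1
  ntap <- ceiling(2 * support) + 2
  W <- matrix(0, nOut, nIn)
  for (t in seq_len(ntap)) {
    idx <- lo + (t - 1)
    w <- cubicKernel((u - idx) / h) / h
    cl <- pmin(pmax(idx, 1), nIn)
    W[cbind(seq_len(nOut), cl)] <- W[cbind(seq_len(nOut), cl)] + w
  }
  W / rowSums(W)
}

# Resize a matrix to target dimensions (bicubic, antialiased).
resizeTo <- function(x, nrOut, ncOut) {
  if (nrOut == nrow(x) && ncOut == ncol(x)) return(x)
  Wr <- resampleWeights(nrow(x), nrOut)
  Wc <- resampleWeights(ncol(x), ncOut)
  Wr %*% x %*% t(Wc)
}

# Fisher-Pearson biased skewness g1 = m3 / m2^(3/2); 0 for a degenerate
# second moment.
skewnessG1 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  e1071::skewness(x, type = 1)
}

shannonEntropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
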