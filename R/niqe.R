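# Naturalness features: local luminance normalization, sharp-block
# selection, GGD/AGGD moment-matching fits of normalized coefficients and
# neighbor products at two scales, pooled into a multivariate Gaussian
# natural-scene statistics model, and the Mahalanobis-type naturalness
# distance between an image model and a trained reference model.

ggdGrid <- function() {
  if (is.null(.retiqa$ggdAlpha)) {
    a <- seq(0.2, 10, by = 0.001)
    .retiqa$ggdAlpha <- a
    .retiqa$ggdRatio <- gamma(1 / a) * gamma(3 / a) / gamma(2 / a)^2
    .retiqa$aggdRho <- gamma(2 / a)^2 / (gamma(1 / a) * gamma(3 / a))
  }
  invisible(NULL)
}

#' Local mean/deviation normalization of a luminance channel
#'
#' Subtracts the local (7 x 7 Gaussian-weighted, sd 7/6) mean and divides by
#' the local standard deviation plus one. The deviation field is returned for
#' sharpness-based block selection.
#'
#' @param x numeric matrix (image channel).
#' @return list with `norm` (normalized grid) and `sigma` (local deviation
#'   field, same shape).
#' @export
localNormalize <- function(x) {
  w <- gaussianKernel2d(7 / 6, hw = 3)
  mu <- conv2Direct(x, w, "reflect")
  m2 <- conv2Direct(x * x, w, "reflect")
  sigma <- sqrt(pmax(m2 - mu^2, 0))
  list(norm = (x - mu) / (sigma + 1), sigma = sigma)
}

#' Select sharp blocks from a local-deviation field
#'
#' Tiles the field into `P` x `P` blocks (from the top-left corner, partial
#' blocks discarded) and retains blocks whose mean local deviation
#' delta(b) is at least `T` times the maximum over blocks.
#'
#' @param sigmaField local deviation field from [localNormalize()].
#' @param P block size in pixels; must not exceed either grid dimension.
#' @param T sharpness threshold in \[0, 1\].
#' @return integer matrix with columns `row0`, `col0` (1-based top-left
#'   corners of the retained blocks) and attribute `"delta"`.
#' @export
selectSharpBlocks <- function(sigmaField, P, T) {
  if (T < 0 || T > 1) stop("T must lie in [0, 1]")
  if (P > min(dim(sigmaField))) stop("block size P larger than the image")
  nbr <- nrow(sigmaField) %/% P
  nbc <- ncol(sigmaField) %/% P
  delta <- matrix(0, nbr, nbc)
  for (bj in seq_len(nbc))
    for (bi in seq_len(nbr))
      delta[bi, bj] <- mean(sigmaField[(bi - 1) * P + seq_len(P),
                                       (bj - 1) * P + seq_len(P)])
  keep <- which(delta >= T * max(delta), arr.ind = TRUE)
  out <- cbind(row0 = (keep[, 1] - 1) * P + 1, col0 = (keep[, 2] - 1) * P + 1)
  attr(out, "delta") <- delta[keep]
  out
}

#' Fit a zero-mean generalized Gaussian distribution by moment matching
#'
#' Shape alpha is obtained by inverting r(alpha) =
#' Gamma(1/alpha) Gamma(3/alpha) / Gamma(2/alpha)^2 over a precomputed grid
#' alpha in \[0.2, 10\] against the sample ratio E\[x^2\] / E\[|x|\]^2;
#' spread beta follows from the second moment.
#'
#' @param x numeric vector of at least 16 samples, not all zero.
#' @return named vector `c(alpha, beta)`.
#' @export
fitGGD <- function(x) {
  if (length(x) < 16) stop("need at least 16 samples")
  m2 <- mean(x^2)
  if (m2 == 0) stop("degenerate input: all samples are zero")
  ggdGrid()
  rhat <- m2 / mean(abs(x))^2
  alpha <- .retiqa$ggdAlpha[which.min(abs(.retiqa$ggdRatio - rhat))]
  beta <- sqrt(m2 * gamma(1 / alpha) / gamma(3 / alpha))
  c(alpha = alpha, beta = beta)
}

#' Fit an asymmetric generalized Gaussian distribution by moment matching
#'
#' Left/right second moments and the overall absolute moment give the shape
#' `gamma` (grid inversion of rho(gamma) = Gamma(2/g)^2 /
#' (Gamma(1/g) Gamma(3/g)) against the asymmetry-corrected sample ratio),
#' the spreads `betaLeft`/`betaRight`, and the distribution mean `eta`.
#'
#' @param x numeric vector of at least 16 samples with both signs present.
#' @return named vector `c(gamma, betaLeft, betaRight, eta)`.
#' @export
fitAGGD <- function(x) {
  if (length(x) < 16) stop("need at least 16 samples")
  xl <- x[x < 0]; xr <- x[x > 0]
  if (length(xl) == 0 || length(xr) == 0)
    stop("degenerate input: both signs must be represented")
  ggdGrid()
  sl <- sqrt(mean(xl^2))
  sr <- sqrt(mean(xr^2))
  gh <- sl / sr
  rhat <- mean(abs(x))^2 / mean(x^2)
  rnorm_ <- rhat * (gh^3 + 1) * (gh + 1) / (gh^2 + 1)^2
  g <- .retiqa$ggdAlpha[which.min(abs(.retiqa$aggdRho - rnorm_))]
  conv <- sqrt(gamma(1 / g) / gamma(3 / g))
  bl <- sl * conv
  br <- sr * conv
  eta <- (br - bl) * gamma(2 / g) / gamma(1 / g)
  c(gamma = g, betaLeft = bl, betaRight = br, eta = eta)
}

# 36 NSS parameters of one block: GGD (alpha, beta) of the normalized
# coefficients plus AGGD (gamma, betaLeft, betaRight, eta) of the four
# adjacent-pixel products (horizontal, vertical, main- and anti-diagonal),
# at the given block of one scale.
blockParams18 <- function(sub) {
  P <- nrow(sub)
  h <- sub[, seq_len(P - 1)] * sub[, 2:P]
  v <- sub[seq_len(P - 1), ] * sub[2:P, ]
  d1 <- sub[seq_len(P - 1), seq_len(P - 1)] * sub[2:P, 2:P]
  d2 <- sub[2:P, seq_len(P - 1)] * sub[seq_len(P - 1), 2:P]
  c(fitGGD(as.vector(sub)),
    fitAGGD(as.vector(h)), fitAGGD(as.vector(v)),
    fitAGGD(as.vector(d1)), fitAGGD(as.vector(d2)))
}

#' Per-block NSS parameter vectors of one image
#'
#' Normalizes the channel at full scale and at a bicubic 1/2 scale, selects
#' sharp blocks at the full scale, and characterizes each retained block by
#' 36 parameters: GGD (2) + 4 AGGDs (16) at each of the two scales (the same
#' spatial blocks, coordinates and size halved, are used at scale 2).
#'
#' @param imgGreen numeric matrix (green channel of a preprocessed image).
#' @param P block size at the full scale; @param T sharpness threshold.
#' @return numeric matrix (retained blocks x 36).
#' @export
blockNssParams <- function(imgGreen, P = 64, T = 0.1) {
  if (P %% 2 != 0) stop("P must be even")
  n1 <- localNormalize(imgGreen)
  img2 <- downsampleBicubic(imgGreen, 1 / 2)
  n2 <- localNormalize(img2)
  blocks <- selectSharpBlocks(n1$sigma, P, T)
  if (nrow(blocks) == 0) stop("no block survives sharpness selection")
  half <- P %/% 2
  rows <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    r0 <- blocks[b, "row0"]; c0 <- blocks[b, "col0"]
    sub1 <- n1$norm[r0 + seq_len(P) - 1, c0 + seq_len(P) - 1]
    r2 <- (r0 - 1) %/% 2 + 1; c2 <- (c0 - 1) %/% 2 + 1
    sub2 <- n2$norm[r2 + seq_len(half) - 1, c2 + seq_len(half) - 1]
    # blocks whose coefficients are too flat for the distribution fits
    # (e.g. clipped-to-black regions) carry no NSS information: drop them
    rows[[b]] <- tryCatch(c(blockParams18(sub1), blockParams18(sub2)),
                          error = function(e) NULL)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no block survives sharpness selection")
  out <- do.call(rbind, rows)
  colnames(out) <- paste0(
    rep(c("s1_", "s2_"), each = 18),
    rep(c("ggd_alpha", "ggd_beta",
          paste0(rep(c("h_", "v_", "d1_", "d2_"), each = 4),
                 c("gamma", "beta_l", "beta_r", "eta"))), 2))
  out
}

#' Fit a multivariate Gaussian to NSS parameter rows
#'
#' @param paramRows numeric matrix (n >= 2 rows of block parameters).
#' @param P,T block-selection parameters recorded in the model.
#' @return an [NSSModel-class] with `nu` = column means and `sigma` = sample
#'   covariance (divisor n - 1).
#' @export
fitMVG <- function(paramRows, P = 64, T = 0.1) {
  if (nrow(paramRows) < 2) stop("need at least 2 parameter rows")
  sig <- cov(paramRows)
  sig <- (sig + t(sig)) / 2
  new("NSSModel", nu = colMeans(paramRows), sigma = sig,
      blockCount = nrow(paramRows), P = P, T = T)
}

#' Naturalness distance between two NSS models
#'
#' sqrt((nu1 - nu2)' ((Sigma1 + Sigma2)/2)^-1 (nu1 - nu2)); the pooled
#' covariance is inverted with a Moore-Penrose pseudo-inverse (singular
#' values below 1e-10 of the largest dropped) when singular.
#'
#' @param ref,imgModel [NSSModel-class] objects of matching dimension.
#' @return nonnegative naturalness distance (lower = closer to the
#'   reference).
#' @export
niqeDistance <- function(ref, imgModel) {
  if (length(ref@nu) != length(imgModel@nu))
    stop("model dimensions do not match")
  d <- ref@nu - imgModel@nu
  S <- (ref@sigma + imgModel@sigma) / 2
  q <- tryCatch(sum(d * solve(S, d)), error = function(e) {
    sv <- svd(S)
    pos <- sv$d > 1e-10 * max(sv$d)
    Sinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    sum(d * (Sinv %*% d))
  })
  sqrt(max(q, 0))
}

#' Build a reference NSS model from adequate-quality images
#'
#' Pools the per-block parameter vectors of all images and fits one
#' multivariate Gaussian.
#'
#' @param images list of [PreprocessedImage-class] objects (>= 2), or a list
#'   of green-channel matrices.
#' @param P,T block-selection parameters.
#' @return an [NSSModel-class].
#' @export
buildReferenceModel <- function(images, P = 64, T = 0.1) {
  if (length(images) < 2) stop("need at least 2 images")
  rows <- lapply(images, function(im) {
    g <- if (is(im, "PreprocessedImage")) greenChannel(imagePixels(im)) else im
    blockNssParams(g, P, T)
  })
  pooled <- do.call(rbind, rows)
  if (nrow(pooled) < 2) stop("fewer than 2 retained blocks in total")
  fitMVG(pooled, P, T)
}

#' Naturalness quality index of one image
#'
#' @param img a [PreprocessedImage-class] or green-channel matrix.
#' @param ref the reference [NSSModel-class].
#' @return nonnegative `niqe_q` value.
#' @export
niqeQuality <- function(img, ref) {
  g <- if (is(img, "PreprocessedImage")) greenChannel(imagePixels(img)) else img
  rows <- blockNssParams(g, ref@P, ref@T)
  niqeDistance(ref, fitMVG(rows, ref@P, ref@T))
}

#' Serialize / restore a reference NSS model as portable JSON
#'
#' @param model an [NSSModel-class]; @param path output file.
#' @export
writeNSSModel <- function(model, path) {
  jsonlite::write_json(
    list(nu = model@nu, sigma = model@sigma, P = model@P, T = model@T,
         count_blocks = model@blockCount),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeNSSModel
#' @export
readNSSModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- j$sigma
  if (is.list(s)) s <- do.call(rbind, lapply(s, unlist))
  s <- matrix(as.numeric(s), length(j$nu), length(j$nu))
  new("NSSModel", nu = as.numeric(j$nu), sigma = (s + t(s)) / 2,
      blockCount = as.integer(j$count_blocks), P = as.numeric(j$P),
      T = as.numeric(j$T))
}
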