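# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's internal helpers.

# Histogram entropy of integer gray levels (base 2).
oracleSpatialEntropy <- function(block) {
  lev <- pmin(pmax(round(as.vector(block)), 0), 255)
  p <- as.vector(table(lev)) / length(lev)
  -sum(p * log2(p))
}

# O(M^4) direct type-II orthonormal DCT, then AC-power entropy.
oracleSpectralEntropy <- function(block) {
  M <- nrow(block); N <- ncol(block)
  C <- matrix(0, M, N)
  for (k in 0:(M - 1)) for (l in 0:(N - 1)) {
    s <- 0
    for (i in 0:(M - 1)) for (j in 0:(N - 1))
      s <- s + block[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * k / (2 * M)) *
        cos(pi * (2 * j + 1) * l / (2 * N))
    ck <- if (k == 0) sqrt(1 / M) else sqrt(2 / M)
    cl <- if (l == 0) sqrt(1 / N) else sqrt(2 / N)
    C[k + 1, l + 1] <- ck * cl * s
  }
  pw <- C^2
  pw[1, 1] <- 0
  p <- as.vector(pw) / sum(pw)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Mirror padding (reflect without repeating the edge pixel).
oraclePadReflect <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  ri <- c(rev(seq_len(p) + 1), seq_len(H), H - seq_len(p))
  ci <- c(rev(seq_len(p) + 1), seq_len(W), W - seq_len(p))
  x[ri, ci]
}

# Sliding-window Gaussian-weighted local mean and sd (nested loops).
oracleLocalStats <- function(x, w) {
  hw <- (nrow(w) - 1) / 2
  xp <- oraclePadReflect(x, hw)
  H <- nrow(x); W <- ncol(x)
  mu <- sg <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- xp[i + 0:(2 * hw), j + 0:(2 * hw)]
    m <- sum(w * win)
    mu[i, j] <- m
    sg[i, j] <- sqrt(max(sum(w * win^2) - m^2, 0))
  }
  list(mu = mu, sigma = sg)
}

# Direct nested-loop centered convolution with reflect padding.
oracleConv2 <- function(x, k) {
  hr <- (nrow(k) - 1) / 2
  xp <- oraclePadReflect(x, hr)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  kf <- k[nrow(k):1, ncol(k):1]  # convolution flips the kernel
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(kf * xp[i + 0:(2 * hr), j + 0:(2 * hr)])
  out
}

# Sliding circular-window standard deviation (divisor n-1), clipped
# windows use available pixels only.
oracleDiskSd <- function(map, r) {
  H <- nrow(map); W <- ncol(map)
  out <- matrix(0, H, W)
  offs <- expand.grid(di = -floor(r):floor(r), dj = -floor(r):floor(r))
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- i + offs$di; jj <- j + offs$dj
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- map[cbind(ii[ok], jj[ok])]
    out[i, j] <- sd(v)
  }
  out
}

# Exact 5x5 median with mirror padding, sort-based.
oracleMedian5 <- function(x) {
  xp <- oraclePadReflect(x, 2)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- median(xp[i + 0:4, j + 0:4])
  out
}

# Two-pass covariance (divisor n-1) without stats::cov.
oracleCov <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  (t(Xc) %*% Xc) / (n - 1)
}

# Naive two-stage FCBF: SU relevance ranking then pairwise predominance
# sweep, written independently of the package's implementation.
oracleFcbf <- function(D, labels) {
  su <- function(a, b) {
    ent <- function(v) {
      p <- as.vector(table(v)) / length(v)
      -sum(p * log2(p))
    }
    ha <- ent(a); hb <- ent(b)
    if (ha + hb == 0) return(0)
    hab <- ent(paste(a, b))
    2 * (ha - (hab - hb)) / (ha + hb)
  }
  rel <- sapply(seq_len(ncol(D)), function(j) su(D[, j], labels))
  ord <- order(-rel, seq_along(rel))
  ord <- ord[rel[ord] > 0]
  kept <- logical(length(ord))
  removed <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (removed[i]) next
    kept[i] <- TRUE
    if (i < length(ord)) for (j in (i + 1):length(ord)) {
      if (removed[j]) next
      if (su(D[, ord[j]], D[, ord[i]]) >= rel[ord[j]]) removed[j] <- TRUE
    }
  }
  colnames(D)[ord[kept]]
}

# AGGD sampler: zero-mode density ~ exp(-(|x|/beta_side)^gamma).
sampleAGGD <- function(n, gam, bl, br) {
  side <- runif(n) < bl / (bl + br)
  mag <- (rgamma(n, shape = 1 / gam, scale = 1))^(1 / gam)
  ifelse(side, -bl * mag, br * mag)
}

# Linear-interpolation percentile (type 7) from first principles.
oraclePercentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, length(s))] - s[lo])
}
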