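test_that("bicubic downsampling follows the round-half-up size convention", {
  x <- matrix(0, 1956, 1934)
  expect_identical(dim(downsampleBicubic(x, 1 / 2)), c(978L, 967L))
  expect_identical(dim(downsampleBicubic(x, 1 / 3)), c(652L, 645L))
  y <- matrix(rnorm(100), 10, 10)
  expect_identical(downsampleBicubic(y, 1), y)
  expect_error(downsampleBicubic(y, 0.7), "factor")
})

test_that("spatial entropy matches hand-computable cases and the oracle", {
  expect_equal(spatialEntropy(matrix(7, 8, 8)), 0)
  half <- matrix(c(10, 200), 8, 8)
  expect_equal(spatialEntropy(half), 1)
  set.seed(11)
  blk <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  expect_equal(spatialEntropy(blk), oracleSpatialEntropy(blk),
               tolerance = 1e-12)
  # histogram shift invariance
  blk2 <- matrix(sample(0:200, 32 * 32, replace = TRUE), 32, 32)
  expect_equal(spatialEntropy(blk2), spatialEntropy(blk2 + 50),
               tolerance = 1e-12)
})

test_that("spectral entropy matches DCT basis cases and the oracle", {
  M <- 8
  basis <- function(k, l) {
    ck <- if (k == 0) sqrt(1 / M) else sqrt(2 / M)
    cl <- if (l == 0) sqrt(1 / M) else sqrt(2 / M)
    outer(ck * cos(pi * (2 * 0:(M - 1) + 1) * k / (2 * M)),
          cl * cos(pi * (2 * 0:(M - 1) + 1) * l / (2 * M)))
  }
  expect_equal(spectralEntropy(basis(2, 3)), 0, tolerance = 1e-9)
  expect_equal(spectralEntropy(basis(1, 0) + basis(0, 1)), 1,
               tolerance = 1e-9)
  expect_equal(spectralEntropy(matrix(5, 16, 16)), 0)
  set.seed(12)
  blk <- matrix(rnorm(12 * 12), 12, 12)
  expect_equal(spectralEntropy(blk), oracleSpectralEntropy(blk),
               tolerance = 1e-9)
  # power-normalization scale invariance
  expect_equal(spectralEntropy(blk), spectralEntropy(3.7 * blk),
               tolerance = 1e-9)
})

test_that("pooled features have the documented shape and bounds", {
  set.seed(13)
  img <- matrix(runif(150 * 150, 0, 255), 150, 150)
  f <- sseqFeatures(img)
  expect_length(f, 12)
  expect_identical(names(f)[1:4],
                   c("sseq_spacen_mean_s1", "sseq_spacen_skew_s1",
                     "sseq_specen_mean_s1", "sseq_specen_skew_s1"))
  spacMeans <- f[grep("spacen_mean", names(f))]
  expect_true(all(spacMeans >= 0 & spacMeans <= 8))
  specMeans <- f[grep("specen_mean", names(f))]
  expect_true(all(specMeans >= 0 & specMeans <= log2(32^2 - 1)))
  expect_error(sseqFeatures(matrix(0, 64, 64)), "too small")
})

test_that("pooling of a symmetric entropy list has zero skewness", {
  v <- c(2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 4)  # mirror-symmetric around 4
  pooled <- retiqa:::trimPool(v, lower = 0, upper = 1)
  expect_lt(abs(pooled["skew"]), 1e-9)
  # trimmed pooling is permutation-invariant
  set.seed(14)
  w <- runif(101)
  expect_equal(retiqa:::trimPool(w), retiqa:::trimPool(sample(w)))
})
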