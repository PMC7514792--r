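test_that("local normalization matches trivial cases and the oracle", {
  cst <- matrix(42, 20, 20)
  ln <- localNormalize(cst)
  expect_equal(max(abs(ln$norm)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ln$sigma)), 0, tolerance = 1e-6)

  chk <- 255 * outer(rep(c(0, 1), 8), rep(c(0, 1), 8), "==")
  ln2 <- localNormalize(chk)
  w <- retiqa:::gaussianKernel2d(7 / 6, hw = 3)
  ora <- oracleLocalStats(chk, w)
  expect_lt(max(abs(ln2$sigma - ora$sigma)), 1e-9)
  expect_lt(max(abs(ln2$norm - (chk - ora$mu) / (ora$sigma + 1))), 1e-9)
  # denominator >= 1 bounds the output
  expect_true(all(abs(ln2$norm) <= abs(chk - ora$mu) + 1e-12))
})

test_that("sharp-block selection follows the threshold rule", {
  sf <- matrix(1, 64, 64)
  expect_identical(nrow(selectSharpBlocks(sf, 16, 0.5)), 16L)
  sf2 <- matrix(0, 64, 64)
  sf2[1:16, 1:16] <- 3
  sel <- selectSharpBlocks(sf2, 16, 0.2)
  expect_equal(unname(sel[1, ]), c(1, 1))
  expect_identical(nrow(sel), 1L)
  expect_identical(nrow(selectSharpBlocks(sf2, 16, 0)), 16L)
  expect_error(selectSharpBlocks(sf2, 128, 0.1), "larger")
  expect_error(selectSharpBlocks(sf2, 16, 1.5), "\\[0, 1\\]")
})

test_that("GGD fitting recovers Gaussian and Laplace shapes", {
  x <- withr::with_seed(21, rnorm(1e5))
  a <- fitGGD(x)
  expect_gt(a["alpha"], 1.9); expect_lt(a["alpha"], 2.1)
  l <- withr::with_seed(22, sample(c(-1, 1), 1e5, TRUE) * rexp(1e5))
  b <- fitGGD(l)
  expect_gt(b["alpha"], 0.9); expect_lt(b["alpha"], 1.1)
  expect_error(fitGGD(rep(0, 100)), "degenerate")
  # grid inversion agrees with a direct scan of the same objective
  rhat <- mean(x^2) / mean(abs(x))^2
  grid <- seq(0.2, 10, by = 0.001)
  direct <- grid[which.min(abs(gamma(1 / grid) * gamma(3 / grid) /
                                 gamma(2 / grid)^2 - rhat))]
  expect_lt(abs(a["alpha"] - direct), 1e-3 + 1e-12)
})

test_that("AGGD fitting respects symmetry, recovery and scaling", {
  z <- withr::with_seed(23, rnorm(5e3))
  sym <- c(z, -z)
  fs <- fitAGGD(sym)
  expect_lt(abs(fs["betaLeft"] - fs["betaRight"]), 1e-9)
  expect_lt(abs(fs["eta"]), 1e-9)

  x <- withr::with_seed(24, sampleAGGD(1e5, gam = 1.5, bl = 1, br = 2))
  fx <- fitAGGD(x)
  expect_lt(abs(fx["gamma"] - 1.5) / 1.5, 0.1)
  expect_lt(abs(fx["betaLeft"] - 1) / 1, 0.1)
  expect_lt(abs(fx["betaRight"] - 2) / 2, 0.1)

  fc <- fitAGGD(2.5 * x)
  expect_lt(abs(fc["gamma"] - fx["gamma"]), 1e-6)
  expect_lt(abs(fc["betaLeft"] - 2.5 * fx["betaLeft"]), 1e-6)
  expect_lt(abs(fc["betaRight"] - 2.5 * fx["betaRight"]), 1e-6)
  expect_lt(abs(fc["eta"] - 2.5 * fx["eta"]), 1e-6)
  expect_error(fitAGGD(abs(z) + 1), "degenerate")
})

test_that("block parameter vectors have length 36 and white noise keeps all blocks", {
  img <- withr::with_seed(25, matrix(runif(192 * 192, 0, 255), 192, 192))
  rows <- blockNssParams(img, P = 64, T = 0)
  expect_identical(ncol(rows), 36L)
  expect_identical(nrow(rows), 9L)  # 3 x 3 blocks, T = 0 keeps all
  expect_true(all(is.finite(rows)))
})

test_that("MVG fitting matches the brute-force covariance", {
  X <- withr::with_seed(26, matrix(rnorm(50 * 36), 50, 36))
  m <- fitMVG(X)
  expect_equal(nssMean(m), colMeans(X), ignore_attr = TRUE)
  expect_lt(max(abs(nssCov(m) - oracleCov(X))), 1e-10)
  expect_identical(nssCov(m), t(nssCov(m)))
  same <- matrix(rep(1:36, each = 4), 4, 36)
  ms <- fitMVG(same)
  expect_equal(max(abs(nssCov(ms))), 0)
  expect_error(fitMVG(X[1, , drop = FALSE]), "at least 2")
})

test_that("the naturalness distance matches its 1-D closed form", {
  mk <- function(mu, s2) new("NSSModel", nu = mu, sigma = matrix(s2, 1, 1),
                             blockCount = 2L, P = 64, T = 0.1)
  expect_equal(niqeDistance(mk(1, 2), mk(1, 2)), 0)
  d <- niqeDistance(mk(0, 1), mk(3, 2))
  expect_equal(d, 3 / sqrt((1 + 2) / 2), tolerance = 1e-12)
  # symmetry under swapping models
  expect_equal(niqeDistance(mk(0, 1), mk(3, 2)),
               niqeDistance(mk(3, 2), mk(0, 1)))
  expect_error(niqeDistance(mk(0, 1), fitMVG(matrix(rnorm(8), 4, 2))),
               "dimension")
})

test_that("the distance is invariant to a common coordinate permutation", {
  X <- withr::with_seed(27, matrix(rnorm(60 * 6), 60, 6))
  Y <- withr::with_seed(28, matrix(rnorm(60 * 6), 60, 6) + 0.3)
  m1 <- fitMVG(X); m2 <- fitMVG(Y)
  p <- c(4, 1, 6, 2, 5, 3)
  mp1 <- new("NSSModel", nu = m1@nu[p], sigma = m1@sigma[p, p],
             blockCount = m1@blockCount, P = 64, T = 0.1)
  mp2 <- new("NSSModel", nu = m2@nu[p], sigma = m2@sigma[p, p],
             blockCount = m2@blockCount, P = 64, T = 0.1)
  expect_equal(niqeDistance(m1, m2), niqeDistance(mp1, mp2),
               tolerance = 1e-9)
})

test_that("reference pooling behaves like the single-image model for copies", {
  sc <- fixtureScene()
  g <- retiqa:::greenChannel(imagePixels(sc$prep))
  rows <- blockNssParams(g)
  single <- fitMVG(rows)
  ref <- buildReferenceModel(list(sc$prep, sc$prep))
  expect_equal(nssMean(ref), nssMean(single), tolerance = 1e-10)
  # duplicated rows shrink the n-1 covariance by 2(n-1)/(2n-1)
  n <- nrow(rows)
  expect_equal(nssCov(ref), nssCov(single) * 2 * (n - 1) / (2 * n - 1),
               tolerance = 1e-8)
  expect_identical(length(nssMean(ref)), 36L)
  # the distance of any model to itself is zero
  expect_equal(niqeDistance(ref, ref), 0)
})
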