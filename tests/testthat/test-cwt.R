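test_that("the Mexican-hat kernel has the stated shape and zero sum", {
  for (s in c(2, 8)) {
    k <- mexicanHatKernel(s)
    hw <- (nrow(k) - 1) / 2
    origin <- k[hw + 1, hw + 1]
    expect_equal(origin, 1 / (pi * s^4), tolerance = 1e-3)
    expect_identical(k, t(k))
    expect_identical(k, k[nrow(k):1, ncol(k):1])
    expect_lt(abs(sum(k)), 1e-3 * max(abs(k)))
  }
  expect_error(mexicanHatKernel(0.5), ">= 1")
})

test_that("the wavelet response of a constant image vanishes", {
  cst <- matrix(120, 80, 80)
  expect_lt(max(abs(cwtTransform(cst, 2))), 1e-6 * 120)
})

test_that("FFT convolution equals the direct nested-loop oracle", {
  x <- withr::with_seed(31, matrix(rnorm(64 * 64, 100, 30), 64, 64))
  k <- mexicanHatKernel(2)
  expect_lt(max(abs(cwtTransform(x, 2) - oracleConv2(x, k))), 1e-8)
})

test_that("a step edge responds in a band that decays away from the edge", {
  s <- 4
  img <- matrix(0, 100, 100)
  img[, 51:100] <- 200
  m <- abs(cwtTransform(img, s))
  prof <- m[50, ]
  peak <- max(prof)
  expect_gt(peak, 0)
  expect_lt(abs(which.max(prof) - 50.5), s + 1.5)  # peak hugs the edge
  far <- prof[abs(seq_len(100) - 50.5) > 4 * s]
  expect_lt(max(far), 0.1 * peak)
})

test_that("coefficient entropy matches the histogram oracle", {
  fov <- buildFovMask(24, 24, 40, c(48, 48))
  cst <- matrix(3.3, 48, 48)
  expect_equal(cwtEntropy(cst, fov), 0)
  map <- withr::with_seed(32, matrix(rnorm(48 * 48), 48, 48))
  v <- map[fovInside(fov)]
  rng <- range(v)
  b <- pmin(floor((v - rng[1]) / diff(rng) * 256), 255)
  p <- as.vector(table(b)) / length(v)
  expect_equal(cwtEntropy(map, fov), -sum(p * log2(p)), tolerance = 1e-12)
  expect_lte(cwtEntropy(map, fov), 8)
})

test_that("circular local-variance features match the sliding-window oracle", {
  fov <- buildFovMask(24, 24, 36, c(48, 48))
  cst <- matrix(1.5, 48, 48)
  lv0 <- localVarianceFeatures(cst, fov, 2)
  expect_lt(max(abs(unname(lv0))), 1e-6)
  map <- withr::with_seed(33, matrix(rnorm(48 * 48), 48, 48))
  lv <- localVarianceFeatures(map, fov, 2)
  sdmap <- oracleDiskSd(map, 2)
  v <- sdmap[fovInside(fov)]
  expect_equal(unname(lv["mean"]), mean(v), tolerance = 1e-9)
  expect_equal(unname(lv["sd"]), sd(v), tolerance = 1e-9)
})

test_that("the 18-feature vector is complete, finite and contrast-linear", {
  sc <- fixtureScene()
  f <- cwtFeatures(sc$prep)
  expect_length(f, 18)
  expect_true(all(is.finite(f)))
  expect_identical(names(f)[1:3], c("cwt_ent_s2", "cwt_mean_s2", "cwt_sd_s2"))

  g <- retiqa:::greenChannel(imagePixels(sc$prep))
  t1 <- cwtTransform(g, 4)
  t2 <- cwtTransform(2 * g, 4)
  expect_lt(max(abs(t2 - 2 * t1)), 1e-8 * max(abs(t1)))
})

test_that("a constant-FOV image yields all-zero sharpness features", {
  img <- array(90, c(450, 450, 3))
  mask <- buildFovMask(225, 225, 400, c(450, 450))
  prep <- new("PreprocessedImage", pixels = img * 1.0, fov = mask,
              extension = list(iterations = 0L, added = integer(0)))
  f <- cwtFeatures(prep)
  expect_lt(max(abs(f)), 1e-6)
})
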